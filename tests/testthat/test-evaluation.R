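test_that("overall correlation matches the covariance-formula oracle", {
  set.seed(37)
  a <- matrix(rnorm(200), 20, 10)
  b <- a + matrix(rnorm(200, sd = 0.3), 20, 10)
  expect_equal(overall_correlation(a, a), 1)
  expect_equal(overall_correlation(a, -a), -1)
  av <- as.vector(a); bv <- as.vector(b)
  want <- mean((av - mean(av)) * (bv - mean(bv))) / (sd(av) * sd(bv)) *
    length(av) / (length(av) - 1)
  expect_equal(overall_correlation(a, b), want, tolerance = 1e-12)
  expect_error(overall_correlation(matrix(1, 3, 3), a[1:3, 1:3]),
               "zero variance")
  # invariance under a common affine rescaling of both movies
  expect_equal(overall_correlation(2 * a + 5, 2 * b + 5),
               overall_correlation(a, b), tolerance = 1e-12)
})

test_that("correlation map is per-node and flags constant traces as undefined", {
  set.seed(41)
  a <- matrix(rnorm(60), 6, 10)
  expect_equal(correlation_map(a, a), rep(1, 6))
  b <- a
  b[2, ] <- rev(a[2, ])
  cm <- correlation_map(a, b)
  expect_lt(cm[2], 1)
  expect_equal(cm[-2], rep(1, 5))
  b[3, ] <- 7
  cm2 <- correlation_map(a, b)
  expect_true(is.na(cm2[3]))
  # map equals the scalar correlation loop
  d <- matrix(rnorm(60), 6, 10)
  expect_equal(correlation_map(a, d),
               vapply(1:6, function(i) cor(a[i, ], d[i, ]), numeric(1)),
               tolerance = 1e-12)
})

test_that("anterior sampling points are distinct, anterior-facing and spread out", {
  heart <- default_vc()$heart
  pts <- anterior_sample_points(heart, 16)
  expect_length(unique(pts), 16)
  nrm <- vertex_normals(heart)
  expect_true(all(nrm[pts, 2] > 0))
  p1 <- anterior_sample_points(heart, 1)
  expect_equal(unname(nrm[p1, 2] > 0), TRUE)
  # farthest-point sampling spreads at least as well as random draws
  # (minimum pairwise geodesic distance, median over 20 random draws)
  e <- surface_edges(heart)
  w <- sqrt(rowSums((heart$vertices[e$v1, ] - heart$vertices[e$v2, ])^2))
  g <- igraph::graph_from_edgelist(cbind(e$v1, e$v2), directed = FALSE)
  ant <- anterior_region(heart)
  mingeo <- function(nodes) {
    d <- igraph::distances(g, nodes, nodes, weights = w)
    min(d[upper.tri(d)])
  }
  set.seed(43)
  rnd <- replicate(20, mingeo(sample(ant, 16)))
  expect_gte(mingeo(pts), median(rnd))
})

test_that("forward-ECG consistency is 1 for a perfect pipeline and small under noise", {
  set.seed(47)
  A <- matrix(rnorm(8 * 12), 8, 12)
  TM <- transfer_matrix(A, rows = "electrode")
  src <- matrix(rnorm(12 * 50), 12, 50)
  rec <- potential_movie(A %*% src, role = "electrode")
  sol <- reconstruct_movie(TM, rec, inverse_config(lambda = 1e-8,
                                                   method = "fixed"))
  r <- ecg_consistency(TM, sol, rec)
  expect_true(all(r > 0.999))
  # pure-noise recording carries no reconstructable structure when the
  # source space is small relative to the channel count
  An <- matrix(rnorm(128 * 4), 128, 4)
  TMn <- transfer_matrix(An, rows = "electrode")
  noise <- potential_movie(matrix(rnorm(128 * 200), 128, 200),
                           role = "electrode")
  soln <- reconstruct_movie(TMn, noise)
  rn <- ecg_consistency(TMn, soln, noise)
  expect_lt(median(abs(rn)), 0.2)
})

test_that("earliest site and localization are exact on a source movie", {
  heart <- tiny_vc()$heart
  g <- conduction_graph(heart, 0.8)
  stim <- 25L
  am <- activation_times(g, stim)
  mv <- make_source_movie(am, activation_curve(), rate = 1024)
  site <- earliest_activation_site(mv, heart)
  expect_equal(am$times[site$node], min(am$times))
  expect_equal(localization_error(mv, heart, heart$vertices[stim, ]), 0)
  flat <- potential_movie(matrix(0, nrow(heart$vertices), 10), rate = 1024,
                          role = "epicardial_source")
  expect_error(earliest_activation_site(flat, heart), "no depolarization")
})

test_that("point spread never splits a single bump and shrinks monotonically", {
  heart <- scaled_sphere(6, 30, "h")
  d <- sqrt(rowSums(sweep(heart$vertices, 2, heart$vertices[1, ])^2))
  bump <- -20 * exp(-(d / 8)^2)
  ps <- point_spread(bump, heart, peak_node = 1L)
  expect_lt(ps$cross_section_mm, 10)
  expect_lt(ps$threshold_mv, -18)   # tightened almost to the peak
  # extent shrinks monotonically as the sweep tightens: probe a few levels
  exts <- vapply(c(-3, -7, -11), function(thr) {
    nodes <- which(bump <= thr)
    if (length(nodes) < 2) 0 else max(dist(heart$vertices[nodes, , drop = FALSE]))
  }, numeric(1))
  expect_true(all(diff(exts) <= 1e-9))
  expect_lt(exts[3], exts[1])
})

test_that("point spread splits at the saddle between two equal bumps", {
  heart <- scaled_sphere(8, 30, "h")
  p1 <- which.max(heart$vertices[, 3])
  d0 <- sqrt(rowSums(sweep(heart$vertices, 2, heart$vertices[p1, ])^2))
  p2 <- which.min(abs(d0 - 30))   # second bump centre 30 mm away
  d1 <- d0
  d2 <- sqrt(rowSums(sweep(heart$vertices, 2, heart$vertices[p2, ])^2))
  field <- -20 * exp(-(d1 / 10)^2) - 20 * exp(-(d2 / 10)^2)
  # independent split-level oracle: candidate-component count by igraph BFS
  e <- surface_edges(heart)
  gg <- igraph::graph_from_edgelist(cbind(e$v1, e$v2), directed = FALSE)
  baseline <- median(field)
  half <- baseline - 0.5 * (baseline - min(field))
  count_cand <- function(thr) {
    nodes <- which(field <= thr)
    cmp <- igraph::components(igraph::induced_subgraph(gg, nodes))
    sum(tapply(field[nodes], cmp$membership, min) <= half)
  }
  fine <- seq(min(field), baseline, length.out = 400)
  saddle <- max(fine[vapply(fine, count_cand, numeric(1)) >= 2])
  ps <- point_spread(field, heart, peak_node = which.min(field))
  # the sweep stops at the saddle: returned threshold just above it
  expect_gte(ps$threshold_mv, saddle)
  expect_lt(ps$threshold_mv, saddle + 1)
  # the blob just above the saddle spans both bumps
  expect_gt(ps$cross_section_mm, 25)
  expect_error(point_spread(rep(0, nrow(heart$vertices)), heart,
                            peak_node = 1L), "no peak")
})
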