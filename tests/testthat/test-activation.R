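test_that("Moller-Trumbore kernel matches the axis-aligned construction", {
  r <- ray_triangle_intersect(c(0.2, 0.2, -1), c(0, 0, 1),
                              rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_true(r$hit)
  expect_equal(r$t, 1)
  expect_equal(c(r$u, r$v), c(0.2, 0.2))

  miss <- ray_triangle_intersect(c(0.2, 0.2, -1), c(1, 0, 0),
                                 rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_false(miss$hit)

  expect_error(ray_triangle_intersect(c(0, 0, -1), c(0, 0, 1),
                                      rbind(c(0, 0, 0), c(1, 0, 0),
                                            c(2, 0, 0))),
               "degenerate")
  expect_error(ray_triangle_intersect(c(0, 0, 0), c(0, 0, 0),
                                      rbind(c(0, 0, 0), c(1, 0, 0),
                                            c(0, 1, 0))),
               "zero direction")
})

test_that("Moller-Trumbore agrees with the plane/barycentric oracle on 1e4 rays", {
  set.seed(7)
  n <- 10000
  mism <- 0
  dt_max <- 0
  for (i in seq_len(n)) {
    o <- runif(3, -2, 2); d <- rnorm(3)
    v1 <- rnorm(3); v2 <- rnorm(3); v3 <- rnorm(3)
    got <- ray_triangle_intersect(o, d, rbind(v1, v2, v3))
    want <- raytri_oracle(o, d, v1, v2, v3)
    if (got$hit != want$hit) mism <- mism + 1
    if (got$hit && want$hit) dt_max <- max(dt_max, abs(got$t - want$t))
  }
  expect_equal(mism, 0)
  expect_lt(dt_max, 1e-9)
})

test_that("line of sight is blocked exactly by intervening triangles", {
  wall <- tri_surface(rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0),
                            c(-1, 1, 0)),
                      rbind(c(1, 2, 3), c(1, 3, 4)), "wall")
  expect_false(line_of_sight(wall, c(0, 0, -1), c(0, 0, 1)))
  expect_true(line_of_sight(wall, c(2, 2, -1), c(2, 2, 1)))
  expect_true(line_of_sight(list(), c(0, 0, -1), c(0, 0, 1)))

  # exhaustive segment/triangle oracle on random segments
  set.seed(11)
  s <- icosphere(2)
  for (i in 1:300) {
    p <- runif(3, -1.5, 1.5); q <- runif(3, -1.5, 1.5)
    if (q[1] < p[1]) { tmp <- p; p <- q; q <- tmp }  # canonical order
    want <- TRUE
    for (f in seq_len(nrow(s$triangles))) {
      tr <- s$vertices[s$triangles[f, ], ]
      delta <- 1e-4
      o <- p + delta * (q - p)
      r <- raytri_oracle(o, q - p, tr[1, ], tr[2, ], tr[3, ])
      if (r$hit && r$t < 1 - 2 * delta) { want <- FALSE; break }
    }
    expect_identical(line_of_sight(s, p, q), want)
  }
})

test_that("conduction graph delays convert mm and m/s into ms", {
  # two vertices 1 mm apart at 1 m/s -> 1 ms delay (tiny two-triangle sheet)
  heart <- icosphere(2, "h")
  heart$vertices <- heart$vertices * 10
  g <- conduction_graph(heart, velocity = 1)
  i <- g$edges$i[1]; j <- g$edges$j[1]
  d <- sqrt(sum((heart$vertices[i, ] - heart$vertices[j, ])^2))
  expect_equal(g$edges$delay_ms[1], d / 1)
  g2 <- conduction_graph(heart, velocity = 2)
  expect_equal(g2$edges$delay_ms, g$edges$delay_ms / 2)
})

test_that("conduction edges equal the brute-force visibility construction", {
  heart <- tiny_vc()$heart
  radius <- 2 * mean_edge_length(heart)
  g <- conduction_graph(heart, 0.8, radius = radius)
  v <- heart$vertices
  got <- paste(g$edges$i, g$edges$j)
  # brute force: all pairs within radius with unblocked segments
  dm <- as.matrix(dist(v))
  want <- character()
  for (i in seq_len(nrow(v) - 1)) for (j in seq(i + 1, nrow(v))) {
    if (dm[i, j] <= radius && line_of_sight(heart, v[i, ], v[j, ])) {
      want <- c(want, paste(i, j))
    }
  }
  expect_setequal(got, want)
})

test_that("radius below the longest mesh edge is rejected", {
  heart <- tiny_vc()$heart
  expect_error(conduction_graph(heart, 0.8, radius = 1), "radius")
})

test_that("activation times follow shortest paths from the stimuli", {
  # explicit chain 1-2-3 with delays 1 and 2 ms
  g <- structure(list(edges = tibble::tibble(i = c(1L, 2L), j = c(2L, 3L),
                                             dist_mm = c(1, 2),
                                             delay_ms = c(1, 2)),
                      positions = diag(3), n = 3L, velocity = rep(1, 3),
                      radius = 3), class = "conduction_graph")
  am <- activation_times(g, 1L)
  expect_equal(am$times, c(0, 1, 3))
  am2 <- activation_times(g, cbind(node = c(1, 3), time_ms = c(0, 0)))
  expect_equal(am2$times, pmin(activation_times(g, 1L)$times,
                               activation_times(g, 3L)$times))
})

test_that("Floyd-Warshall equals Dijkstra on random 200-node graphs, exactly", {
  set.seed(3)
  for (rep in 1:3) {
    n <- 200
    pos <- matrix(runif(3 * n), n, 3)
    dm <- as.matrix(dist(pos))
    adj <- dm < 0.25
    diag(adj) <- FALSE
    edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
    D <- matrix(Inf, n, n); diag(D) <- 0
    D[edges] <- dm[edges]; D[edges[, 2:1]] <- dm[edges]
    got <- ipmap:::floyd_warshall_cpp(D)
    ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    want <- igraph::distances(ig, weights = dm[edges], algorithm = "dijkstra")
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("activation maps obey the edge inequality and scale with velocity", {
  heart <- tiny_vc()$heart
  g <- conduction_graph(heart, 0.8)
  am <- activation_times(g, 5L)
  slack <- am$times[g$edges$j] - am$times[g$edges$i]
  expect_true(all(abs(slack) <= g$edges$delay_ms + 1e-9))
  # doubling velocity exactly halves activation times (single stimulus at 0)
  g2 <- conduction_graph(heart, 1.6)
  am2 <- activation_times(g2, 5L)
  expect_equal(am2$times, am$times / 2, tolerance = 1e-12)
})

test_that("isochrones are invariant under vertex relabelling", {
  heart <- tiny_vc()$heart
  g <- conduction_graph(heart, 0.8)
  am <- activation_times(g, 10L)
  set.seed(5)
  perm <- sample(nrow(heart$vertices))
  hp <- tri_surface(heart$vertices[perm, ],
                    matrix(match(heart$triangles, perm),
                           ncol = 3), "perm")
  gp <- conduction_graph(hp, 0.8)
  amp <- activation_times(gp, which(perm == 10L))
  expect_equal(amp$times[match(seq_along(perm), perm)], am$times,
               tolerance = 1e-9)
})

test_that("activation curves follow the closed-form smoothstep pieces", {
  cv <- activation_curve(resting = -90, plateau = 10, upstroke = 2,
                         apd = 250, repol = 80)
  expect_equal(activation_curve_value(cv, -50, 0), -90)
  expect_equal(activation_curve_value(cv, 2 + 125, 0), 10)
  # closed form over dense samples
  t <- seq(-10, 400, by = 0.25)
  sstep <- function(u) { u <- pmin(pmax(u, 0), 1); u^2 * (3 - 2 * u) }
  want <- -90 + 100 * (sstep(t / 2) - sstep((t - 250) / 80))
  expect_equal(activation_curve_value(cv, t, 0), want, tolerance = 1e-12)
  expect_error(activation_curve(upstroke = -1), "upstroke")
})

test_that("source movies place each node's curve at its activation time", {
  heart <- tiny_vc()$heart
  g <- conduction_graph(heart, 0.8)
  am <- activation_times(g, 1L)
  curves <- list(atrium = activation_curve(apd = 120, region = "atrium"),
                 ventricle = activation_curve(apd = 200))
  regions <- heart_regions(heart)
  mv <- make_source_movie(am, curves, regions, rate = 512)
  tf <- frame_times(mv)
  set.seed(9)
  for (i in 1:100) {
    v <- sample(nrow(mv$values), 1); f <- sample(ncol(mv$values), 1)
    cv <- curves[[regions[v]]]
    expect_equal(mv$values[v, f],
                 activation_curve_value(cv, tf[f], am$times[v]))
  }
  # all nodes at the same activation time give spatially uniform frames
  am0 <- am; am0$times[] <- 3
  mv0 <- make_source_movie(am0, activation_curve(), rate = 512)
  expect_equal(apply(mv0$values, 2, function(col) diff(range(col))),
               rep(0, ncol(mv0$values)))
  expect_error(make_source_movie(am, curves, regions, rate = 512,
                                 duration = 10), "truncation")
})
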