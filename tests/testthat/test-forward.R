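small_sphere_vc <- function() memo_fixture("sphere_vc", function() {
  volume_conductor(scaled_sphere(6, 100, "torso"), list(),
                   scaled_sphere(4, 30, "heart"), torso_sigma = 0.2)
})

test_that("transfer-matrix rows sum to one (constant-source property)", {
  TM <- memo_fixture("sphere_T", function() bem_transfer_matrix(small_sphere_vc()))
  expect_true(all(abs(rowSums(TM$matrix) - 1) < 1e-3))
  expect_identical(TM$rows, "torso")
  # uniform heart potential extends as the same constant
  c0 <- 12.5
  out <- TM$matrix %*% rep(c0, ncol(TM$matrix))
  expect_lt(max(abs(out - c0)), 1e-3 * abs(c0))
})

test_that("organ compartments preserve the constant-source property", {
  TM <- memo_fixture("tiny_T", function() bem_transfer_matrix(tiny_vc()))
  expect_true(all(abs(rowSums(TM$matrix) - 1) < 1e-3))
})

test_that("BEM solution is invariant under rigid rotation of the model", {
  vc <- small_sphere_vc()
  TM <- memo_fixture("sphere_T", function() bem_transfer_matrix(vc))
  R <- rotation <- ipmap:::rotation_matrix_zto(c(1, 2, 3) / sqrt(14))
  rot <- function(s) { s$vertices <- s$vertices %*% t(R); s }
  vc2 <- volume_conductor(rot(vc$torso), list(), rot(vc$heart),
                          torso_sigma = vc$torso_sigma)
  TM2 <- bem_transfer_matrix(vc2)
  # same Dirichlet data expressed in rotated coordinates
  phi <- vc$heart$vertices[, 3] / 30
  out1 <- TM$matrix %*% phi
  out2 <- TM2$matrix %*% phi     # rotated nodes carry the same nodal values
  expect_lt(sqrt(sum((out1 - out2)^2) / sum(out1^2)), 0.01)
})

test_that("apply_forward is linear and matches the naive per-frame loop", {
  TM <- transfer_matrix(matrix(runif(20), 4, 5), rows = "electrode")
  X <- potential_movie(matrix(rnorm(15), 5, 3), role = "epicardial_source")
  Y <- potential_movie(matrix(rnorm(15), 5, 3), role = "epicardial_source")
  aXbY <- potential_movie(2 * X$values - 3 * Y$values,
                          role = "epicardial_source")
  lhs <- apply_forward(TM, aXbY)$values
  rhs <- 2 * apply_forward(TM, X)$values - 3 * apply_forward(TM, Y)$values
  expect_equal(lhs, rhs, tolerance = 1e-14)
  loop <- sapply(1:3, function(f) as.vector(TM$matrix %*% X$values[, f]))
  expect_equal(apply_forward(TM, X)$values, loop, tolerance = 1e-14)
  expect_error(apply_forward(TM, potential_movie(matrix(0, 4, 2),
                                                 role = "epicardial_source")),
               "dimension")
  id <- transfer_matrix(diag(5), rows = "electrode")
  expect_equal(apply_forward(id, X)$values, X$values)
})

test_that("electrode sampling equals the explicit barycentric solve", {
  vc <- tiny_vc()
  torso <- vc$torso
  mv <- potential_movie(matrix(rnorm(nrow(torso$vertices) * 4),
                               ncol = 4), role = "body_surface")
  # electrode exactly at a vertex reproduces that node's trace
  vtx <- 17L
  e_v <- electrode_set(torso$vertices[vtx, , drop = FALSE], torso = torso)
  got <- sample_electrodes(mv, torso, e_v)
  expect_equal(got$values[1, ], mv$values[vtx, ], tolerance = 1e-9)
  # electrode at a triangle centroid averages the three vertex traces
  tri <- torso$triangles[5, ]
  cen <- colMeans(torso$vertices[tri, ])
  e_c <- electrode_set(rbind(cen), torso = torso)
  got_c <- sample_electrodes(mv, torso, e_c)
  expect_equal(got_c$values[1, ], colMeans(mv$values[tri, ]),
               tolerance = 1e-9)
  # random in-triangle points vs explicit barycentric solve
  set.seed(21)
  for (i in 1:25) {
    f <- sample(nrow(torso$triangles), 1)
    w <- runif(3); w <- w / sum(w)
    tri <- torso$triangles[f, ]
    p <- colSums(torso$vertices[tri, ] * w)
    e <- electrode_set(rbind(p), torso = torso)
    got <- sample_electrodes(mv, torso, e)$values[1, ]
    expect_equal(got, colSums(mv$values[tri, ] * w), tolerance = 1e-6)
  }
  far <- electrode_set(rbind(c(0, 0, 1e4)))
  expect_error(sample_electrodes(mv, torso, far), "registration")
})

test_that("added noise realizes the requested SNR within 0.5 dB", {
  set.seed(2)
  x <- matrix(sin(seq(0, 40 * pi, length.out = 1e5)), 1) * 3 + 5
  m <- potential_movie(x, role = "electrode")
  noisy <- add_noise(m, noise_spec(21, seed = 4))
  noise <- noisy$values - x
  snr_hat <- 10 * log10(mean((x - mean(x))^2) / mean(noise^2))
  expect_lt(abs(snr_hat - 21), 0.5)
})

test_that("noise is seed-reproducible, silent for infinite SNR, and guarded", {
  m <- potential_movie(matrix(rnorm(200), 4), role = "electrode")
  a <- add_noise(m, noise_spec(10, seed = 3))
  b <- add_noise(m, noise_spec(10, seed = 3))
  expect_identical(a$values, b$values)
  d <- add_noise(m, noise_spec(10, seed = 4))
  expect_false(identical(a$values, d$values))
  expect_identical(add_noise(m, noise_spec(Inf))$values, m$values)
  silent <- potential_movie(matrix(1, 3, 10), role = "electrode")
  expect_error(add_noise(silent, noise_spec(21)), "silent signal")
})
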