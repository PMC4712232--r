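test_that("Tikhonov solution equals the normal-equations factorization route", {
  set.seed(13)
  for (i in 1:100) {
    m <- sample(4:10, 1); n <- sample(4:12, 1)
    A <- matrix(rnorm(m * n), m, n)
    b <- rnorm(m)
    l <- 10^runif(1, -3, 0.5)
    got <- tikhonov_solve(A, b, l)
    want <- solve(crossprod(A) + l^2 * diag(n), crossprod(A, b))
    expect_equal(got, drop(want), tolerance = 1e-8)
  }
})

test_that("Tikhonov matches the SVD filter-factor form on a 6x8 system", {
  set.seed(17)
  A <- matrix(rnorm(48), 6, 8)
  b <- rnorm(6)
  sv <- svd(A)
  for (l in c(0.01, 0.3, 2)) {
    want <- sv$v %*% ((sv$d / (sv$d^2 + l^2)) * (t(sv$u) %*% b))
    expect_equal(tikhonov_solve(A, b, l), drop(want), tolerance = 1e-10)
  }
})

test_that("identity transfer with zero lambda reproduces the data exactly", {
  b <- rnorm(7)
  expect_equal(tikhonov_solve(diag(7), b, 0), b)
  # rank-deficient with lambda = 0 is refused
  A <- cbind(1:4, 2 * (1:4))
  expect_error(tikhonov_solve(A, rnorm(4), 0), "ill-posed")
})

test_that("residual rises and solution norm shrinks monotonically in lambda", {
  set.seed(19)
  A <- matrix(rnorm(80), 8, 10)
  b <- rnorm(8)
  ls <- 10^seq(-4, 1, length.out = 30)
  rho <- eta <- numeric(30)
  for (i in seq_along(ls)) {
    x <- tikhonov_solve(A, b, ls[i])
    rho[i] <- sqrt(sum((A %*% x - b)^2))
    eta[i] <- sqrt(sum(x^2))
  }
  expect_true(all(diff(rho) >= -1e-12))
  expect_true(all(diff(eta) <= 1e-12))
  # shrinkage against the unregularized solution (full column rank)
  B <- matrix(rnorm(50), 10, 5)
  y <- rnorm(10)
  x0 <- tikhonov_solve(B, y, 0)
  for (l in c(0.1, 1)) expect_lte(sum(tikhonov_solve(B, y, l)^2), sum(x0^2))
})

test_that("L-curve choice lands within a decade of the error-optimal lambda", {
  set.seed(23)
  A <- matrix(rnorm(40 * 60), 40, 60)
  x_true <- rnorm(60)
  clean <- drop(A %*% x_true)
  noise_sd <- sqrt(mean(clean^2) / 10^(21 / 10))
  b <- clean + rnorm(40, sd = noise_sd)
  grid <- max(svd(A)$d) * 10^seq(-6, 1, length.out = 60)
  err <- vapply(grid, function(l)
    sqrt(sum((tikhonov_solve(A, b, l) - x_true)^2)), numeric(1))
  l_opt <- grid[which.min(err)]
  l_hat <- choose_lambda(A, b, grid = grid)
  expect_lt(abs(log10(l_hat) - log10(l_opt)), 1)
})

test_that("noiseless consistent data drive the L-curve corner to small lambda", {
  set.seed(29)
  A <- matrix(rnorm(40 * 30), 40, 30)   # overdetermined, consistent
  b <- drop(A %*% rnorm(30))
  grid <- max(svd(A)$d) * 10^seq(-6, 1, length.out = 60)
  l_hat <- choose_lambda(A, b, grid = grid)
  expect_lte(l_hat, grid[1] * 10)   # lowest grid decade
})

test_that("movie reconstruction equals the frame-wise loop and records norms", {
  set.seed(31)
  A <- matrix(rnorm(6 * 9), 6, 9)
  TM <- transfer_matrix(A, rows = "electrode")
  P <- potential_movie(matrix(rnorm(6 * 12), 6, 12), role = "electrode")
  sol <- reconstruct_movie(TM, P, inverse_config(lambda = 0.4,
                                                 method = "fixed"))
  expect_equal(sol$lambda, 0.4)
  loop <- sapply(1:12, function(f) tikhonov_solve(A, P$values[, f], 0.4))
  expect_equal(sol$movie$values, loop, tolerance = 1e-12)
  expect_equal(sol$residual_norms,
               sqrt(colSums((A %*% loop - P$values)^2)), tolerance = 1e-12)
  expect_equal(sol$solution_norms, sqrt(colSums(loop^2)), tolerance = 1e-12)
  # identity, noiseless: reconstruction equals the input movie
  id <- transfer_matrix(diag(6), rows = "electrode")
  sol_id <- reconstruct_movie(id, P, inverse_config(lambda = 0,
                                                    method = "fixed"))
  expect_equal(sol_id$movie$values, P$values, tolerance = 1e-12)
  # zero movie reconstructs to zero with zero norms (L-curve path)
  z <- potential_movie(matrix(0, 6, 4), role = "electrode")
  sol_z <- reconstruct_movie(TM, z)
  expect_equal(sol_z$movie$values, matrix(0, 9, 4))
  expect_equal(sol_z$solution_norms, rep(0, 4))
})

test_that("tidy and glance summarize inverse solutions", {
  A <- matrix(rnorm(12), 3, 4)
  sol <- reconstruct_movie(transfer_matrix(A, rows = "electrode"),
                           potential_movie(matrix(rnorm(9), 3, 3),
                                           role = "electrode"),
                           inverse_config(lambda = 0.5, method = "fixed"))
  td <- tidy(sol)
  expect_named(td, c("frame", "time_ms", "residual_norm", "solution_norm"))
  expect_equal(nrow(td), 3)
  gl <- glance(sol)
  expect_equal(gl$lambda, 0.5)
  expect_equal(gl$nodes, 4)
})

test_that("inverse configuration validates its arguments", {
  expect_error(inverse_config(method = "fixed"), "lambda")
  expect_error(inverse_config(grid_points = 5), ">= 20")
  cfg <- inverse_config()
  expect_identical(cfg$method, "l_curve")
  expect_identical(cfg$lambda_reference, "avg")
})
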