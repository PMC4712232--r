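#' Inverse reconstruction configuration
#'
#' @param lambda Regularization strength (same scale as the singular values
#'   of the transfer matrix); required when `method = "fixed"`.
#' @param method `"l_curve"` (default: corner of the L-curve picked on the
#'   frame of maximal signal power) or `"fixed"`.
#' @param grid_points,grid_range L-curve search grid: `grid_points` (>= 20)
#'   log-spaced multipliers of the largest singular value spanning
#'   `grid_range`.
#' @param lambda_reference Referencing of the calibration data before the
#'   L-curve is traced: `"avg"` (default) removes the per-frame channel mean
#'   so the corner reflects the informative spatial-pattern components rather
#'   than the arbitrary-reference common mode; `"none"` uses raw potentials.
#'   The reconstruction itself always uses the raw potentials.
#' @return Object of class `inverse_config`.
#' @export
inverse_config <- function(lambda = NULL, method = c("l_curve", "fixed"),
                           grid_points = 60, grid_range = c(1e-6, 10),
                           lambda_reference = c("avg", "none")) {
  method <- match.arg(method)
  lambda_reference <- match.arg(lambda_reference)
  if (method == "fixed" && (is.null(lambda) || lambda < 0)) {
    stop("fixed method needs lambda >= 0", call. = FALSE)
  }
  if (method == "l_curve" && grid_points < 20) {
    stop("l_curve grid needs >= 20 points", call. = FALSE)
  }
  structure(list(lambda = lambda, method = method,
                 grid_points = as.integer(grid_points),
                 grid_range = grid_range,
                 lambda_reference = lambda_reference),
            class = "inverse_config")
}

tm_matrix <- function(T_mat) {
  if (inherits(T_mat, "transfer_matrix")) T_mat$matrix else as.matrix(T_mat)
}

#' Zero-order Tikhonov solution
#'
#' Exact minimizer of `||T x - p||^2 + lambda^2 ||x||^2`, the regularized
#' inverse `x = (T'T + lambda^2 I)^(-1) T' p`, computed through the SVD
#' filter-factor form `x = V diag(s / (s^2 + lambda^2)) U' p` (numerically
#' equivalent to the normal-equations factorization for lambda > 0).
#'
#' @param T_mat A [transfer_matrix()] or plain matrix.
#' @param p_bs Electrode potential vector (or matrix of frames as columns).
#' @param lambda Regularization strength, >= 0.
#' @return Solution vector (or matrix of frame solutions).
#' @export
tikhonov_solve <- function(T_mat, p_bs, lambda) {
  stopifnot(lambda >= 0)
  A <- tm_matrix(T_mat)
  p <- as.matrix(p_bs)
  if (nrow(p) != nrow(A)) stop("dimension mismatch", call. = FALSE)
  sv <- svd(A)
  if (lambda == 0 && min(sv$d) < 1e-10 * max(sv$d)) {
    stop("ill-posed: T is rank deficient; use lambda > 0", call. = FALSE)
  }
  f <- sv$d / (sv$d^2 + lambda^2)
  x <- sv$v %*% (f * (t(sv$u) %*% p))
  if (ncol(x) == 1 && is.null(dim(p_bs))) drop(x) else x
}

#' Choose the regularization strength at the L-curve corner
#'
#' Evaluates residual norm and solution norm over a log-spaced lambda grid
#' and returns the grid point maximizing the discrete curvature of the
#' log-log L-curve (corner criterion). With a matrix of frames the L-curve
#' of the whole recording is traced (Frobenius norms), giving one stable
#' lambda per recording. Deterministic.
#'
#' @param T_mat A [transfer_matrix()] or matrix.
#' @param p_bs Electrode potential vector, or a channels-by-frames matrix
#'   for a recording-level L-curve.
#' @param grid Lambda grid; defaults to the [inverse_config()] grid scaled by
#'   the largest singular value.
#' @param cfg An [inverse_config()] supplying grid defaults.
#' @return The selected lambda (scalar).
#' @export
choose_lambda <- function(T_mat, p_bs, grid = NULL, cfg = inverse_config()) {
  A <- tm_matrix(T_mat)
  sv <- svd(A)
  if (is.null(grid)) {
    grid <- max(sv$d) * 10^seq(log10(cfg$grid_range[1]),
                               log10(cfg$grid_range[2]),
                               length.out = cfg$grid_points)
  }
  grid <- sort(grid)
  P <- as.matrix(p_bs)
  up <- t(sv$u) %*% P
  res_perp2 <- sum(P^2) - sum(up^2)   # component outside range(T)
  rho <- eta <- numeric(length(grid))
  for (i in seq_along(grid)) {
    f <- sv$d / (sv$d^2 + grid[i]^2)
    xs <- f * up
    eta[i] <- sqrt(sum(xs^2))
    rho[i] <- sqrt(sum((sv$d * xs - up)^2) + max(res_perp2, 0))
  }
  lr <- log(pmax(rho, 1e-300)); le <- log(pmax(eta, 1e-300))
  if (diff(range(lr)) < 1e-12 && diff(range(le)) < 1e-12) {
    stop("uninformative: flat L-curve; use a fixed lambda", call. = FALSE)
  }
  # numerically consistent data with a unique least-squares solution need no
  # regularization: the whole curve is one smooth bend and the smallest grid
  # value is the right answer
  if (nrow(A) >= ncol(A) && min(sv$d) > 1e-10 * max(sv$d) &&
      rho[1] < 1e-7 * sqrt(sum(P^2))) {
    return(grid[1])
  }
  # curvature of (log rho, log eta) parameterized by log lambda; the corner
  # is the point of maximal unsigned curvature (its sign depends on whether
  # the curve has a residual floor), boundary stencils excluded
  s <- log(grid)
  d1r <- finite_diff(lr, s); d2r <- finite_diff(d1r, s)
  d1e <- finite_diff(le, s); d2e <- finite_diff(d1e, s)
  kappa <- abs(d1r * d2e - d1e * d2r) / (d1r^2 + d1e^2)^1.5
  inner <- seq(3, length(grid) - 2)
  if (diff(range(kappa[inner], na.rm = TRUE)) < 1e-12) {
    stop("uninformative: flat L-curve; use a fixed lambda", call. = FALSE)
  }
  grid[inner[which.max(kappa[inner])]]
}

finite_diff <- function(y, x) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d
}

#' Reconstruct an epicardial potential movie
#'
#' Applies the Tikhonov inverse frame by frame with a single lambda per
#' recording: either the configured fixed value, or the corner of the
#' recording-level L-curve (traced over a subsample of frames, after the
#' referencing configured in [inverse_config()]).
#'
#' @param T_mat A [transfer_matrix()] (electrode rows).
#' @param p_bs_movie Recorded/simulated electrode [potential_movie()].
#' @param cfg An [inverse_config()].
#' @return Object of class `inverse_solution`: the reconstructed movie (role
#'   `"epicardial_source"`), the lambda used, and per-frame residual and
#'   solution norms.
#' @export
reconstruct_movie <- function(T_mat, p_bs_movie, cfg = inverse_config()) {
  stopifnot(inherits(p_bs_movie, "potential_movie"))
  A <- tm_matrix(T_mat)
  P <- p_bs_movie$values
  lambda <- if (cfg$method == "fixed") cfg$lambda else {
    if (all(P == 0)) 0 else {
      Pc <- P[, unique(as.integer(round(seq(1, ncol(P),
                                            length.out = min(128, ncol(P)))))),
              drop = FALSE]
      if (cfg$lambda_reference == "avg" && nrow(Pc) > 1) {
        Pc <- sweep(Pc, 2, colMeans(Pc))
      }
      choose_lambda(A, Pc, cfg = cfg)
    }
  }
  X <- tikhonov_solve(A, P, lambda)
  X <- as.matrix(X)
  structure(list(
    movie = potential_movie(X, rate = p_bs_movie$rate,
                            role = "epicardial_source"),
    lambda = lambda,
    residual_norms = sqrt(colSums((A %*% X - P)^2)),
    solution_norms = sqrt(colSums(X^2))),
    class = "inverse_solution")
}

#' @export
print.inverse_solution <- function(x, ...) {
  cat(sprintf("<inverse_solution: %d nodes x %d frames, lambda = %.4g>\n",
              nrow(x$movie$values), ncol(x$movie$values), x$lambda))
  invisible(x)
}

#' Tidy per-frame norms of an inverse solution
#' @param x An `inverse_solution`.
#' @param ... Unused.
#' @return Tibble with `frame`, `time_ms`, `residual_norm`, `solution_norm`.
#' @export
tidy.inverse_solution <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$residual_norms),
                 time_ms = frame_times(x$movie),
                 residual_norm = x$residual_norms,
                 solution_norm = x$solution_norms)
}

#' One-row summary of an inverse solution
#' @param x An `inverse_solution`.
#' @param ... Unused.
#' @return Tibble with lambda and aggregate norms.
#' @export
glance.inverse_solution <- function(x, ...) {
  tibble::tibble(lambda = x$lambda,
                 nodes = nrow(x$movie$values),
                 frames = ncol(x$movie$values),
                 mean_residual_norm = mean(x$residual_norms),
                 mean_solution_norm = mean(x$solution_norms))
}
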