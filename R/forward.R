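#' Transfer matrix container
#'
#' Linear map from epicardial node potentials to torso-surface (or electrode)
#' potentials. Rows sum to 1 (a uniform epicardial potential extends as the
#' same constant through the source-free conductor).
#'
#' @param matrix Numeric matrix, rows = torso nodes or electrodes, columns =
#'   heart nodes.
#' @param rows `"torso"` or `"electrode"`.
#' @param geometry_hash,electrode_hash Provenance fingerprints.
#' @return Object of class `transfer_matrix`.
#' @export
transfer_matrix <- function(matrix, rows = c("torso", "electrode"),
                            geometry_hash = NA_character_,
                            electrode_hash = NA_character_) {
  rows <- match.arg(rows)
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix))) stop("non-finite transfer matrix", call. = FALSE)
  structure(list(matrix = matrix, rows = rows,
                 geometry_hash = geometry_hash,
                 electrode_hash = electrode_hash),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  rs <- range(rowSums(x$matrix))
  cat(sprintf("<transfer_matrix [%s]: %d x %d, row sums in [%.4f, %.4f]>\n",
              x$rows, nrow(x$matrix), ncol(x$matrix), rs[1], rs[2]))
  invisible(x)
}

cheap_hash <- function(...) {
  xs <- list(...)
  v <- unlist(lapply(xs, function(x) {
    x <- as.numeric(unlist(x))
    c(length(x), sum(x), sum(x^2), sum(abs(x) * seq_along(x) %% 97))
  }))
  paste(format(v, digits = 12), collapse = "|")
}

#' Geometry fingerprint of a volume conductor
#' @param vc A [volume_conductor()].
#' @return Character fingerprint (not cryptographic).
#' @export
geometry_hash <- function(vc) {
  ss <- anatomy_surfaces(vc)
  cheap_hash(lapply(ss, function(s) list(s$vertices, s$triangles)))
}

# Boundary-element system for the piecewise-homogeneous volume conductor:
# region 0 = torso minus organs minus heart interior (sigma0), organ regions
# embedded, air outside (zero normal current on the torso), Dirichlet data on
# the heart surface. Collocation at vertices; per-triangle solid-angle and
# single-layer kernels lumped onto vertices; the local solid-angle fraction
# is set from the double-layer row sums so constants are exactly in the null
# space (auto solid angle).
bem_system <- function(vc) {
  torso <- vc$torso
  heart <- vc$heart
  organs <- vc$organs
  sig0 <- vc$torso_sigma
  NT <- nrow(torso$vertices)
  NOk <- vapply(organs, function(o) nrow(o$surface$vertices), integer(1))
  NO <- sum(NOk)
  NH <- nrow(heart$vertices)
  X <- rbind(torso$vertices,
             do.call(rbind, lapply(organs, function(o) o$surface$vertices)),
             heart$vertices)
  blocks <- function(s) bem_blocks_cpp(X, s$vertices, s$triangles - 1L)
  bt <- blocks(torso)
  bo <- lapply(organs, function(o) blocks(o$surface))
  bh <- blocks(heart)
  m0 <- NT + NO + NH
  D_O <- if (NO > 0) do.call(cbind, lapply(bo, `[[`, "D")) else matrix(0, m0, 0)
  S_O <- if (NO > 0) do.call(cbind, lapply(bo, `[[`, "S")) else matrix(0, m0, 0)
  # region-0 collocation: c0 phi + D_T phi_T - D_O phi_O + S_O q_O
  #                        - D_H phi_H + S_H q_H = 0
  rs_O <- if (NO > 0) rowSums(D_O) else 0
  c0 <- -(rowSums(bt$D) - rs_O - rowSums(bh$D))
  A_phiT <- bt$D
  A_phiO <- -D_O
  idxT <- seq_len(NT)
  idxO <- NT + seq_len(NO)
  idxH <- NT + NO + seq_len(NH)
  A_phiT[cbind(idxT, idxT)] <- A_phiT[cbind(idxT, idxT)] + c0[idxT]
  if (NO > 0) {
    A_phiO[cbind(idxO, seq_len(NO))] <- A_phiO[cbind(idxO, seq_len(NO))] +
      c0[idxO]
  }
  B0 <- bh$D
  B0[cbind(idxH, seq_len(NH))] <- B0[cbind(idxH, seq_len(NH))] - c0[idxH]
  A0 <- cbind(A_phiT, A_phiO, S_O, bh$S)
  # organ-interior collocation: c_k phi_k + D_kk phi_k - (s0/sk) S_kk q_k = 0
  Ak_phiO <- matrix(0, NO, NO)
  Ak_qO <- matrix(0, NO, NO)
  off <- 0L
  for (k in seq_along(organs)) {
    sk <- organs[[k]]$surface
    Xk <- sk$vertices
    bk <- bem_blocks_cpp(Xk, sk$vertices, sk$triangles - 1L)
    ck <- -rowSums(bk$D)
    Dkk <- bk$D
    diag(Dkk) <- diag(Dkk) + ck
    rows <- off + seq_len(NOk[k])
    Ak_phiO[rows, rows] <- Dkk
    Ak_qO[rows, rows] <- -(sig0 / organs[[k]]$sigma) * bk$S
    off <- off + NOk[k]
  }
  A1 <- cbind(matrix(0, NO, NT), Ak_phiO, Ak_qO, matrix(0, NO, NH))
  list(A = rbind(A0, A1), B = rbind(B0, matrix(0, NO, NH)),
       NT = NT, NO = NO, NH = NH)
}

#' Boundary-element transfer matrix of a volume conductor
#'
#' Solves the quasi-static potential problem for the nested piecewise-
#' homogeneous compartments (organs embedded in the torso, air outside) with
#' Dirichlet data on the heart surface and zero normal current through the
#' torso, by vertex collocation with analytic solid-angle (double-layer) and
#' single-layer triangle integrals. Returns the map from heart-node
#' potentials to all torso-node potentials, restricted to electrode rows by
#' in-triangle barycentric interpolation when an [electrode_set()] is given.
#'
#' @param vc A [volume_conductor()].
#' @param electrodes Optional [electrode_set()] on the torso surface.
#' @return A [transfer_matrix()].
#' @export
bem_transfer_matrix <- function(vc, electrodes = NULL) {
  sys <- bem_system(vc)
  sol <- tryCatch(solve(sys$A, sys$B), error = function(e) {
    stop("geometry: singular boundary-element system after deflation",
         call. = FALSE)
  })
  T_full <- sol[seq_len(sys$NT), , drop = FALSE]
  ghash <- geometry_hash(vc)
  if (is.null(electrodes)) {
    return(transfer_matrix(T_full, rows = "torso", geometry_hash = ghash))
  }
  E <- electrode_interpolation(vc$torso, electrodes)
  transfer_matrix(E %*% T_full, rows = "electrode", geometry_hash = ghash,
                  electrode_hash = cheap_hash(electrode_positions(electrodes)))
}

# n_e x n_torso sparse-pattern barycentric interpolation matrix
electrode_interpolation <- function(torso, electrodes, tol = 0.5) {
  p <- electrode_positions(electrodes)
  cp <- closest_point_on_surface(torso, p)
  if (any(cp$dist > tol)) {
    stop(sprintf("registration: %d electrode(s) farther than %.2g mm from the surface",
                 sum(cp$dist > tol), tol), call. = FALSE)
  }
  E <- matrix(0, nrow(p), nrow(torso$vertices))
  for (i in seq_len(nrow(p))) {
    tri <- torso$triangles[cp$triangle[i], ]
    E[i, tri] <- E[i, tri] + cp$bary[i, ]
  }
  E
}

#' Apply a transfer matrix to a source movie
#'
#' Frame-wise matrix-vector product mapping epicardial source potentials to
#' body-surface or electrode potentials.
#'
#' @param T_mat A [transfer_matrix()].
#' @param src A [potential_movie()] on the heart nodes.
#' @param expected_hash Optional geometry hash to enforce.
#' @param force Apply despite a hash mismatch.
#' @return A [potential_movie()] (role `"body_surface"` or `"electrode"`).
#' @export
apply_forward <- function(T_mat, src, expected_hash = NULL, force = FALSE) {
  stopifnot(inherits(T_mat, "transfer_matrix"), inherits(src, "potential_movie"))
  if (ncol(T_mat$matrix) != nrow(src$values)) {
    stop(sprintf("dimension mismatch: transfer has %d columns, source %d nodes",
                 ncol(T_mat$matrix), nrow(src$values)), call. = FALSE)
  }
  if (!is.null(expected_hash) && !identical(expected_hash, T_mat$geometry_hash) &&
      !force) {
    stop("provenance: geometry hash mismatch (use force = TRUE to override)",
         call. = FALSE)
  }
  potential_movie(T_mat$matrix %*% src$values, rate = src$rate,
                  role = if (T_mat$rows == "torso") "body_surface" else "electrode")
}

#' Sample electrode channels from a full-surface movie
#'
#' Barycentric interpolation of the torso-surface potential within the
#' triangle containing each electrode.
#'
#' @param surface_movie [potential_movie()] on the torso nodes.
#' @param torso Torso [tri_surface()].
#' @param electrodes An [electrode_set()].
#' @return A [potential_movie()] with role `"electrode"`.
#' @export
sample_electrodes <- function(surface_movie, torso, electrodes) {
  stopifnot(nrow(surface_movie$values) == nrow(torso$vertices))
  E <- electrode_interpolation(torso, electrodes)
  potential_movie(E %*% surface_movie$values, rate = surface_movie$rate,
                  role = "electrode")
}

#' Noise specification
#'
#' @param snr_db Target signal-to-noise ratio in dB (the simulated recordings
#'   use 21 dB); `Inf` means no noise.
#' @param seed Integer seed.
#' @param scope `"per_channel"` (each channel scaled to its own power) or
#'   `"global"`.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(snr_db = 21, seed = 1L,
                       scope = c("per_channel", "global")) {
  scope <- match.arg(scope)
  stopifnot(!is.na(snr_db))
  structure(list(snr_db = snr_db, seed = as.integer(seed), scope = scope),
            class = "noise_spec")
}

#' Add white Gaussian measurement noise at a target SNR
#'
#' Adds zero-mean white Gaussian noise scaled so that
#' `10 log10(signal power / noise power)` equals the requested SNR. Signal
#' power is the variance of each channel about its temporal mean (the
#' waveform power; the DC reference level carries no noise scaling
#' information). Seeded and reproducible; the global RNG state is untouched.
#'
#' @param m A [potential_movie()].
#' @param spec A [noise_spec()].
#' @return A [potential_movie()] of the same shape.
#' @export
add_noise <- function(m, spec) {
  stopifnot(inherits(m, "potential_movie"), inherits(spec, "noise_spec"))
  if (is.infinite(spec$snr_db)) return(m)
  x <- m$values
  pw <- rowMeans((x - rowMeans(x))^2)
  if (spec$scope == "global") pw <- rep(mean(pw), nrow(x))
  if (all(pw == 0)) stop("silent signal: zero-power input", call. = FALSE)
  sdn <- sqrt(pw / 10^(spec$snr_db / 10))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  noise <- matrix(rnorm(length(x)), nrow(x), ncol(x)) * sdn
  potential_movie(x + noise, rate = m$rate, role = m$role)
}

#' Write / read a transfer matrix with its JSON sidecar
#'
#' The sidecar stores the geometry and electrode fingerprints;
#' [apply_forward()] can enforce them via `expected_hash`.
#'
#' @param T_mat A [transfer_matrix()].
#' @param path Matrix file path (tab-separated).
#' @return `write_transfer_matrix()` returns `path` invisibly.
#' @export
write_transfer_matrix <- function(T_mat, path) {
  utils::write.table(T_mat$matrix, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(rows = T_mat$rows,
                            geometry_hash = T_mat$geometry_hash,
                            electrode_hash = T_mat$electrode_hash),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transfer_matrix
#' @export
read_transfer_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(vals) <- NULL
  transfer_matrix(vals, rows = meta$rows, geometry_hash = meta$geometry_hash,
                  electrode_hash = meta$electrode_hash)
}
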