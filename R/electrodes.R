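#' Electrode set
#'
#' A tibble of electrode positions (mm) on the torso surface with layout
#' metadata. Invariants: every electrode within 0.5 mm of the torso surface
#' and all pairwise distances above 5 mm.
#'
#' @param positions n x 3 matrix of electrode coordinates (mm).
#' @param labels Character electrode labels (defaults to `E001`, ...).
#' @param layout_kind `"surrounding"` or `"concentrated"`.
#' @param spacing Nominal inter-electrode spacing (mm) or `NA`.
#' @param torso Torso [tri_surface()] used to verify the on-surface invariant.
#' @return A tibble of class `electrode_set` with columns `label`, `x`, `y`,
#'   `z`.
#' @export
electrode_set <- function(positions, labels = NULL,
                          layout_kind = c("surrounding", "concentrated"),
                          spacing = NA_real_, torso = NULL) {
  layout_kind <- match.arg(layout_kind)
  positions <- rbind(positions)
  n <- nrow(positions)
  if (is.null(labels)) labels <- sprintf("E%03d", seq_len(n))
  if (!is.null(torso)) {
    d <- closest_point_on_surface(torso, positions)$dist
    if (any(d > 0.5)) {
      stop(sprintf("registration: %d electrode(s) farther than 0.5 mm from the torso surface",
                   sum(d > 0.5)), call. = FALSE)
    }
  }
  if (n > 1) {
    dm <- as.matrix(stats::dist(positions))
    diag(dm) <- Inf
    if (min(dm) <= 5) {
      stop(sprintf("density: minimum inter-electrode distance %.2f mm <= 5 mm",
                   min(dm)), call. = FALSE)
    }
  }
  out <- tibble::tibble(label = labels, x = positions[, 1], y = positions[, 2],
                        z = positions[, 3])
  class(out) <- c("electrode_set", class(out))
  attr(out, "layout_kind") <- layout_kind
  attr(out, "spacing") <- spacing
  out
}

electrode_positions <- function(e) {
  unname(as.matrix(e[, c("x", "y", "z")]))
}

# boundary point of the torso cross-section at height z, direction angle
# theta measured from +y (anterior) towards +x, found by ray casting
torso_boundary_points <- function(torso, z, theta) {
  n <- length(theta)
  orig <- cbind(0, 0, rep(z, n))
  dir <- cbind(sin(theta), cos(theta), 0)
  hit_farthest_on_mesh(torso, orig, dir)
}

hit_on_mesh <- function(torso, orig, dir, farthest = TRUE) {
  Fc <- torso$triangles
  nf <- nrow(Fc)
  n <- nrow(orig)
  out <- matrix(NA_real_, n, 3)
  A <- torso$vertices[Fc[, 1], , drop = FALSE]
  B <- torso$vertices[Fc[, 2], , drop = FALSE]
  C <- torso$vertices[Fc[, 3], , drop = FALSE]
  for (i in seq_len(n)) {
    O <- matrix(orig[i, ], nf, 3, byrow = TRUE)
    D <- matrix(dir[i, ], nf, 3, byrow = TRUE)
    r <- mt_batch_cpp(O, D, A, B, C, 1e-9, 1e-12)
    t <- r$t[r$hit]
    if (length(t) == 0) next
    tt <- if (farthest) max(t) else min(t)
    out[i, ] <- orig[i, ] + tt * dir[i, ]
  }
  out
}

hit_farthest_on_mesh <- function(torso, orig, dir) hit_on_mesh(torso, orig, dir, TRUE)

#' Band layout: electrodes surrounding the thorax
#'
#' Places `n` electrodes in horizontal bands encircling the torso between
#' axial bounds covering the heart plus one band margin, with near-uniform
#' spacing along each band and staggered band offsets. Positions are obtained
#' by ray casting from the torso axis, so they lie exactly on the surface
#' mesh. The layout is deterministic.
#'
#' @param torso Torso [tri_surface()].
#' @param n Electrode count (the reference configurations use 252 and 62).
#' @param heart Optional heart [tri_surface()]; its axial extent sets the band
#'   range. Without it the central 40 % of the torso height is used.
#' @param z_extent Optional total axial height (mm) of the banded region,
#'   centred on the heart. Overrides the default heart-spanning bounds;
#'   vest-style whole-trunk arrays use about 260 mm.
#' @return An [electrode_set()].
#' @export
layout_surrounding <- function(torso, n, heart = NULL, z_extent = NULL) {
  stopifnot(n >= 1)
  zr <- if (!is.null(heart)) range(heart$vertices[, 3]) else {
    quantile(torso$vertices[, 3], c(0.3, 0.7))
  }
  if (!is.null(z_extent)) zr <- mean(zr) + c(-0.5, 0.5) * z_extent
  span <- diff(zr)
  zmid <- mean(zr)
  if (n == 1) {
    pos <- torso_boundary_points(torso, zmid, 0)
    return(electrode_set(pos, layout_kind = "surrounding", torso = torso))
  }
  circ <- band_circumference(torso, zmid)
  B <- max(2L, as.integer(round(sqrt(n * 1.4 * span / circ))))
  B <- min(B, n)
  if (circ / ceiling(n / B) <= 5 || span * 1.5 / B <= 5) {
    stop(sprintf("density: n = %d exceeds what the 5 mm minimum spacing permits", n),
         call. = FALSE)
  }
  margin <- span / (2 * B)
  z_lo <- zr[1] - margin
  z_hi <- zr[2] + margin
  zs <- seq(z_lo, z_hi, length.out = B + 1)
  zb <- (zs[-1] + zs[-(B + 1)]) / 2
  counts <- rep(n %/% B, B)
  extra <- n - sum(counts)
  if (extra > 0) {
    mid_first <- order(abs(seq_len(B) - (B + 1) / 2))
    counts[mid_first[seq_len(extra)]] <- counts[mid_first[seq_len(extra)]] + 1L
  }
  pos <- NULL
  for (b in seq_len(B)) {
    nb <- counts[b]
    th <- 2 * pi * (seq_len(nb) - 1 + 0.5 * (b %% 2)) / nb
    pos <- rbind(pos, torso_boundary_points(torso, zb[b], th))
  }
  if (anyNA(pos)) stop("geometry: band ray casting missed the torso surface", call. = FALSE)
  es <- tryCatch(
    electrode_set(pos, layout_kind = "surrounding", torso = torso),
    error = function(e) {
      if (grepl("^density", conditionMessage(e))) {
        stop(sprintf("density: n = %d exceeds what the 5 mm minimum spacing permits", n),
             call. = FALSE)
      }
      stop(e)
    })
  es
}

band_circumference <- function(torso, z) {
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  p <- torso_boundary_points(torso, z, th)
  p <- p[!is.na(p[, 1]), , drop = FALSE]
  sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), ])^2)))
}

#' Concentrated layout: anterior grid directly overlaying the heart
#'
#' Places `n` electrodes on a staggered (triangular) grid in the tangent
#' plane at the orthogonal projection of the heart centroid onto the anterior
#' torso, rows parallel to the transverse plane, then projects each grid
#' point onto the torso surface along the inward patch normal. Inter-electrode
#' distance is the nominal planar `spacing`; the reference concentrated and
#' super-concentrated configurations use 30 mm and 20 mm.
#'
#' @param torso Torso [tri_surface()].
#' @param n Electrode count (62 in the reference configurations).
#' @param spacing Grid spacing (mm), > 5.
#' @param center_hint Point whose anterior projection centres the grid;
#'   defaults to the heart centroid when `heart` is given.
#' @param heart Optional heart [tri_surface()] supplying the default centre.
#' @return An [electrode_set()].
#' @export
layout_concentrated <- function(torso, n, spacing, center_hint = NULL,
                                heart = NULL) {
  stopifnot(n >= 1, spacing > 5)
  if (is.null(center_hint)) {
    if (is.null(heart)) stop("need `center_hint` or `heart`", call. = FALSE)
    center_hint <- colMeans(heart$vertices)
  }
  center <- hit_farthest_on_mesh(torso, rbind(center_hint), rbind(c(0, 1, 0)))[1, ]
  if (anyNA(center)) stop("coverage: centre does not project onto the anterior torso", call. = FALSE)
  cp <- closest_point_on_surface(torso, center)
  tri <- torso$triangles[cp$triangle[1], ]
  a <- torso$vertices[tri[1], ]; b <- torso$vertices[tri[2], ]; c3 <- torso$vertices[tri[3], ]
  nrm <- c((b - a)[2] * (c3 - a)[3] - (b - a)[3] * (c3 - a)[2],
           (b - a)[3] * (c3 - a)[1] - (b - a)[1] * (c3 - a)[3],
           (b - a)[1] * (c3 - a)[2] - (b - a)[2] * (c3 - a)[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  if (nrm[2] < 0) nrm <- -nrm
  e1 <- c(nrm[2], -nrm[1], 0)           # cross(nrm, ez): horizontal tangent
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])  # roughly vertical
  # staggered grid, n sites closest to the centre (deterministic tie-break)
  m <- ceiling(sqrt(n)) + 3
  g <- expand.grid(row = -m:m, col = -m:m)
  u <- (g$col + 0.5 * (g$row %% 2)) * spacing
  v <- g$row * spacing * sqrt(3) / 2
  ord <- order(u^2 + v^2, g$row, g$col)
  u <- u[ord][seq_len(n)]; v <- v[ord][seq_len(n)]
  orig <- sweep(outer(u, e1) + outer(v, e2), 2, center + 60 * nrm, "+")
  pos <- hit_on_mesh(torso, orig, matrix(-nrm, n, 3, byrow = TRUE), farthest = FALSE)
  if (anyNA(pos)) {
    stop(sprintf("coverage: grid extends past the anterior patch (achievable n <= %d)",
                 sum(!is.na(pos[, 1]))), call. = FALSE)
  }
  electrode_set(pos, layout_kind = "concentrated", spacing = spacing,
                torso = torso)
}

#' Median nearest-neighbour distance of an electrode set (mm)
#' @param e An [electrode_set()].
#' @return Scalar median over electrodes.
#' @export
nearest_neighbour_spacing <- function(e) {
  p <- electrode_positions(e)
  dm <- as.matrix(stats::dist(p))
  diag(dm) <- Inf
  median(apply(dm, 1, min))
}

#' Write / read electrode sets as CSV (label, x_mm, y_mm, z_mm)
#' @param e An [electrode_set()].
#' @param path File path.
#' @return `write_electrodes()` returns `path` invisibly; `read_electrodes()`
#'   returns an [electrode_set()] (on-surface check skipped: no torso context).
#' @export
write_electrodes <- function(e, path) {
  readr::write_csv(tibble::tibble(label = e$label, x_mm = e$x, y_mm = e$y,
                                  z_mm = e$z), path)
  invisible(path)
}

#' @rdname write_electrodes
#' @export
read_electrodes <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  electrode_set(as.matrix(d[, c("x_mm", "y_mm", "z_mm")]), labels = d$label)
}
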