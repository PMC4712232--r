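#' Overall Pearson correlation between two potential movies
#'
#' Pearson product-moment correlation over the flattened node-by-frame
#' matrices (joint space-time convention).
#'
#' @param src,rec [potential_movie()] objects (or plain matrices) of matching
#'   shape.
#' @return Scalar correlation in \[-1, 1\].
#' @export
overall_correlation <- function(src, rec) {
  a <- if (inherits(src, "potential_movie")) src$values else as.matrix(src)
  b <- if (inherits(rec, "potential_movie")) rec$values else as.matrix(rec)
  stopifnot(all(dim(a) == dim(b)))
  if (sd(a) == 0 || sd(b) == 0) {
    stop("zero variance: constant movie", call. = FALSE)
  }
  cor(as.vector(a), as.vector(b))
}

#' Per-node temporal correlation map
#'
#' Pearson correlation of each node's time trace between source and
#' reconstruction; constant traces give `NA` (undefined), not an error.
#'
#' @inheritParams overall_correlation
#' @return Numeric vector, one correlation per node (`NA` where undefined).
#' @export
correlation_map <- function(src, rec) {
  a <- if (inherits(src, "potential_movie")) src$values else as.matrix(src)
  b <- if (inherits(rec, "potential_movie")) rec$values else as.matrix(rec)
  stopifnot(all(dim(a) == dim(b)))
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  sa <- sqrt(rowSums(ac^2)); sb <- sqrt(rowSums(bc^2))
  out <- rowSums(ac * bc) / (sa * sb)
  out[sa == 0 | sb == 0] <- NA_real_
  out
}

#' Anterior epicardial sampling points
#'
#' Selects `k` well-spread nodes among heart vertices whose outward normal
#' faces anterior (+y), by farthest-point sampling seeded at the most
#' anterior node. Deterministic; used for the 16-point correlation plots.
#'
#' @param heart Heart [tri_surface()].
#' @param k Number of points (default 16).
#' @return Integer vector of `k` distinct vertex indices.
#' @export
anterior_sample_points <- function(heart, k = 16) {
  nrm <- vertex_normals(heart)
  ant <- which(nrm[, 2] > 0)
  if (length(ant) == 0) stop("orientation: no anterior-facing nodes", call. = FALSE)
  if (k > length(ant)) {
    stop(sprintf("k = %d exceeds the %d anterior nodes", k, length(ant)),
         call. = FALSE)
  }
  pts <- heart$vertices[ant, , drop = FALSE]
  sel <- which.max(pts[, 2])
  if (k > 1) {
    d <- sqrt(rowSums(sweep(pts, 2, pts[sel, ])^2))
    while (length(sel) < k) {
      nxt <- which.max(d)
      sel <- c(sel, nxt)
      d <- pmin(d, sqrt(rowSums(sweep(pts, 2, pts[nxt, ])^2)))
    }
  }
  ant[sel]
}

#' Forward-reconstructed ECG consistency
#'
#' Re-computes electrode potentials from the inverse solution through the
#' transfer matrix and correlates them channel by channel with the recorded
#' potentials, the standard internal quality check when no source truth is
#' available.
#'
#' @param T_mat The [transfer_matrix()] used for the inverse (electrode rows).
#' @param solution An `inverse_solution` from [reconstruct_movie()].
#' @param recorded The recorded electrode [potential_movie()].
#' @return Numeric per-channel correlations (`NA` for zero-variance
#'   channels).
#' @export
ecg_consistency <- function(T_mat, solution, recorded) {
  pred <- tm_matrix(T_mat) %*% solution$movie$values
  stopifnot(all(dim(pred) == dim(recorded$values)))
  correlation_map(recorded$values, pred)
}

#' Site of earliest depolarization in a potential movie
#'
#' Each node's depolarization time is the first frame at which its trace
#' drops below its own half-depth level `resting - 0.5 (resting - min of the
#' trace)`, with the resting level taken as the median potential over the
#' first 2 ms. The per-node criterion is monotone in activation order and,
#' unlike a criterion tied to the global movie minimum, robust to the
#' localized overshoot (ringing) of regularized reconstructions. Only nodes
#' whose deflection reaches at least half the deepest deflection are
#' candidate pacing sites. Returns the candidate with the earliest crossing;
#' ties break to the deepest trace, then to the lowest index.
#'
#' @param rec A [potential_movie()] on the heart nodes.
#' @param heart The matching heart [tri_surface()].
#' @return List with `node`, `time_ms` and `position` (mm).
#' @export
earliest_activation_site <- function(rec, heart) {
  X <- rec$values
  stopifnot(nrow(X) == nrow(heart$vertices))
  n0 <- max(1L, min(ncol(X), as.integer(round(rec$rate * 0.002))))
  resting <- median(X[, seq_len(n0)])
  mins <- apply(X, 1, min)
  depth <- resting - mins
  if (max(depth) <= 0) stop("no depolarization: movie has no negative peak",
                            call. = FALSE)
  cand <- which(depth >= 0.5 * max(depth))
  thr <- resting - 0.5 * depth[cand]
  first <- vapply(seq_along(cand), function(i) {
    w <- which(X[cand[i], ] < thr[i])
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
  if (all(is.na(first))) stop("no depolarization: no node crosses the criterion",
                              call. = FALSE)
  fmin <- min(first, na.rm = TRUE)
  # centre of the emerging negative region at the detection frame: the
  # depth-weighted centroid of the nodes at or below half the frame's
  # maximal depth (the in-silico analogue of marking the centre of the
  # first negative spot on the colour-coded map)
  depth_f <- resting - X[, fmin]
  sel <- which(depth_f >= 0.5 * max(depth_f))
  w <- depth_f[sel]
  centroid <- colSums(heart$vertices[sel, , drop = FALSE] * w) / sum(w)
  node <- which.min(rowSums(sweep(heart$vertices, 2, centroid)^2))
  list(node = node, time_ms = (fmin - 1) / rec$rate * 1000,
       position = heart$vertices[node, ])
}

#' Pacing-site localization error (mm)
#'
#' Euclidean distance between the true pacing site and the position of the
#' earliest-depolarization node of the reconstruction.
#'
#' @inheritParams earliest_activation_site
#' @param true_site Length-3 true pacing position (mm).
#' @return Distance in mm.
#' @export
localization_error <- function(rec, heart, true_site) {
  site <- earliest_activation_site(rec, heart)
  sqrt(sum((site$position - true_site)^2))
}

mesh_adjacency <- function(heart) {
  e <- surface_edges(heart)
  igraph::graph_from_edgelist(cbind(e$v1, e$v2), directed = FALSE)
}

#' Point-spread threshold test on a pacing peak
#'
#' Tightens a display threshold from the baseline towards the (negative)
#' pacing peak, tracking the connected suprathreshold component (nodes more
#' negative than the threshold, on the mesh vertex adjacency) that contains
#' the peak. When the threshold becomes too strict, that blob splits into
#' two or more candidate sub-peaks (pieces whose minimum is deeper than
#' halfway between baseline and peak) -- the false-detail signature. The
#' returned threshold is the most extreme one at which the peak's blob is
#' still a single candidate component, and the cross-section is the blob's
#' maximal pairwise Euclidean extent (mm) at that threshold: the size of the
#' smallest trustworthy detail.
#'
#' @param frame Numeric per-node potentials (mV) at the analysis instant.
#' @param heart Heart [tri_surface()].
#' @param peak_node Index of the pacing peak; defaults to the global
#'   minimum.
#' @param n_levels Number of threshold levels swept.
#' @return List with `threshold_mv` and `cross_section_mm`.
#' @export
point_spread <- function(frame, heart, peak_node = which.min(frame),
                         n_levels = 120) {
  stopifnot(length(frame) == nrow(heart$vertices))
  baseline <- median(frame)
  peak <- frame[peak_node]
  if (peak >= baseline) stop("no peak: frame has no negative pacing peak",
                             call. = FALSE)
  g <- mesh_adjacency(heart)
  half <- baseline - 0.5 * (baseline - peak)
  levels <- seq(baseline, peak, length.out = n_levels + 2)[-c(1, n_levels + 2)]
  best <- NULL
  prev_blob <- NULL
  for (thr in levels) {   # baseline -> peak: tighten until the blob splits
    nodes <- which(frame <= thr)
    sub <- igraph::induced_subgraph(g, nodes)
    comp <- igraph::components(sub)
    if (!is.null(prev_blob)) {
      # pieces the previous blob decomposed into at this stricter level
      keep <- nodes %in% prev_blob
      piece_id <- comp$membership[keep]
      piece_min <- tapply(frame[nodes][keep], piece_id, min)
      if (sum(piece_min <= half) > 1) break
    }
    blob_id <- comp$membership[match(peak_node, nodes)]
    blob <- nodes[comp$membership == blob_id]
    pts <- heart$vertices[blob, , drop = FALSE]
    ext <- if (nrow(pts) > 1) max(stats::dist(pts)) else 0
    best <- list(threshold_mv = thr, cross_section_mm = ext)
    prev_blob <- blob
  }
  if (is.null(best)) {
    stop("no peak: the blob splits at the loosest threshold", call. = FALSE)
  }
  best
}

#' Evaluation report for one reconstruction
#'
#' Bundles the quality metrics of a reconstruction against its source:
#' overall correlation, per-node temporal correlation map, the 16-point
#' anterior correlations, and per-lead forward-ECG consistency.
#'
#' @param src Source [potential_movie()] mapped onto the reconstruction grid.
#' @param rec Reconstructed [potential_movie()].
#' @param heart Reconstruction-grid heart [tri_surface()].
#' @param T_mat,solution,recorded Optional arguments for the forward-ECG
#'   consistency block.
#' @param k Number of anterior sampling points.
#' @return Object of class `evaluation_report`. `anterior_r` is the overall
#'   correlation restricted to the anterior-facing epicardium (the region the
#'   anterior potential maps display and the only region anterior electrode
#'   patches can resolve).
#' @export
evaluation_report <- function(src, rec, heart, T_mat = NULL, solution = NULL,
                              recorded = NULL, k = 16) {
  cmap <- correlation_map(src, rec)
  pts <- anterior_sample_points(heart, k)
  ecg_r <- if (!is.null(T_mat) && !is.null(solution) && !is.null(recorded)) {
    ecg_consistency(T_mat, solution, recorded)
  }
  a <- if (inherits(src, "potential_movie")) src$values else as.matrix(src)
  b <- if (inherits(rec, "potential_movie")) rec$values else as.matrix(rec)
  ant <- anterior_region(heart)
  structure(list(overall_r = overall_correlation(src, rec),
                 anterior_r = overall_correlation(a[ant, , drop = FALSE],
                                                  b[ant, , drop = FALSE]),
                 correlation_map = cmap,
                 sample_points = tibble::tibble(node = pts, r = cmap[pts]),
                 ecg_r = ecg_r,
                 n_undefined = sum(is.na(cmap))),
            class = "evaluation_report")
}

#' Anterior-facing heart nodes
#'
#' Vertices whose outward normal has a positive anterior (+y) component,
#' i.e. the part of the epicardium visible in an anterior view.
#'
#' @param heart Heart [tri_surface()].
#' @return Integer vertex indices.
#' @export
anterior_region <- function(heart) {
  which(vertex_normals(heart)[, 2] > 0)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: overall R = %.3f, map mean R = %.3f (%d undefined)>\n",
              x$overall_r, mean(x$correlation_map, na.rm = TRUE), x$n_undefined))
  if (!is.null(x$ecg_r)) {
    cat(sprintf("  forward-ECG consistency: median R = %.3f\n",
                median(x$ecg_r, na.rm = TRUE)))
  }
  invisible(x)
}

#' One-row summary of an evaluation report
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Tibble.
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(overall_r = x$overall_r,
                 anterior_r = x$anterior_r,
                 map_mean_r = mean(x$correlation_map, na.rm = TRUE),
                 sample_mean_r = mean(x$sample_points$r, na.rm = TRUE),
                 ecg_median_r = if (is.null(x$ecg_r)) NA_real_ else
                   median(x$ecg_r, na.rm = TRUE),
                 n_undefined = x$n_undefined)
}

#' Export a per-vertex scalar (e.g. a correlation map) as ASCII PLY
#'
#' @param heart Heart [tri_surface()].
#' @param scalar Per-vertex values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vertex_scalar_ply <- function(heart, scalar, path) {
  stopifnot(length(scalar) == nrow(heart$vertices))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(heart$vertices)),
               "property float x", "property float y", "property float z",
               "property float quality",
               sprintf("element face %d", nrow(heart$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(cbind(heart$vertices, scalar), con, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cbind(3L, heart$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
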