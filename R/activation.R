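#' Moller-Trumbore ray/triangle intersection
#'
#' Exact Moller-Trumbore kernel: a hit requires barycentric `u >= 0`,
#' `v >= 0`, `u + v <= 1` and ray parameter `t > eps`.
#'
#' @param origin,direction Length-3 ray origin and (non-zero) direction.
#' @param triangle 3 x 3 matrix, one vertex per row.
#' @param eps Minimal ray parameter counted as a hit.
#' @return List with `hit` (logical), `t`, `u`, `v` (`NA` on miss).
#' @export
ray_triangle_intersect <- function(origin, direction, triangle, eps = 1e-9) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  if (sqrt(sum(direction^2)) == 0) stop("zero direction", call. = FALSE)
  triangle <- rbind(triangle)
  stopifnot(nrow(triangle) == 3, ncol(triangle) == 3)
  e1 <- triangle[2, ] - triangle[1, ]
  e2 <- triangle[3, ] - triangle[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  if (0.5 * sqrt(sum(cr^2)) < 1e-12) {
    stop("degenerate: triangle area below tolerance", call. = FALSE)
  }
  r <- mt_batch_cpp(rbind(origin), rbind(direction),
                    rbind(triangle[1, ]), rbind(triangle[2, ]),
                    rbind(triangle[3, ]), eps, 1e-14)
  list(hit = r$hit[1], t = r$t[1], u = r$u[1], v = r$v[1])
}

#' Line-of-sight test between two points
#'
#' `TRUE` iff the open segment from `p` to `q` crosses no blocker triangle.
#' The segment is shrunk by a small relative offset at both ends so that
#' triangles incident to `p` or `q` themselves (when these are mesh vertices)
#' do not block.
#'
#' @param blockers A [tri_surface()] or list of them.
#' @param p,q Length-3 endpoints, `p != q`.
#' @return Logical.
#' @export
line_of_sight <- function(blockers, p, q) {
  stopifnot(!isTRUE(all.equal(p, q)))
  # canonical endpoint order: verdicts do not depend on argument order
  if (q[1] < p[1] || (q[1] == p[1] && q[2] < p[2]) ||
      (q[1] == p[1] && q[2] == p[2] && q[3] < p[3])) {
    tmp <- p; p <- q; q <- tmp
  }
  if (inherits(blockers, "tri_surface")) blockers <- list(blockers)
  for (s in blockers) {
    if (seg_blocked_cpp(rbind(p), rbind(q), s$vertices, s$triangles - 1L,
                        1e-4, 1e-14)[1]) {
      return(FALSE)
    }
  }
  TRUE
}

#' Conduction graph over the heart surface
#'
#' Connects heart vertices closer than `radius` whose connecting segment does
#' not cross the blocking surface (visibility rule, preventing conduction
#' short-circuits across concavities). Edge delay is Euclidean distance over
#' conduction velocity; with distance in mm and velocity in m/s the delay is
#' directly in ms.
#'
#' @param heart Heart [tri_surface()].
#' @param velocity Conduction velocity in m/s: scalar, or per-vertex vector
#'   for region-specific velocities (edge velocity = mean of its endpoints).
#'   Default 0.8 m/s, a standard working-myocardium value.
#' @param radius Neighbourhood radius (mm), at least the maximal edge length;
#'   defaults to twice the mean edge length.
#' @param blockers Blocking surfaces for the visibility rule; defaults to the
#'   heart surface itself.
#' @return Object of class `conduction_graph`: tibble of edges `(i, j,
#'   dist_mm, delay_ms)` plus node positions.
#' @export
conduction_graph <- function(heart, velocity = 0.8, radius = NULL,
                             blockers = NULL) {
  stopifnot(all(velocity > 0))
  e <- surface_edges(heart)
  elen <- sqrt(rowSums((heart$vertices[e$v1, , drop = FALSE] -
                        heart$vertices[e$v2, , drop = FALSE])^2))
  if (is.null(radius)) radius <- 2 * mean(elen)
  if (radius < max(elen)) {
    stop(sprintf("radius %.2f mm below maximal mesh edge length %.2f mm",
                 radius, max(elen)), call. = FALSE)
  }
  if (is.null(blockers)) blockers <- heart
  if (inherits(blockers, "tri_surface")) blockers <- list(blockers)
  edges <- NULL
  for (s in blockers) {
    em <- graph_edges_cpp(heart$vertices, s$vertices, s$triangles - 1L,
                          radius, 1e-4, 1e-14)
    edges <- if (is.null(edges)) em else {
      keep <- paste(edges[, 1], edges[, 2]) %in% paste(em[, 1], em[, 2])
      edges[keep, , drop = FALSE]
    }
  }
  n <- nrow(heart$vertices)
  vel <- if (length(velocity) == 1) rep(velocity, n) else velocity
  stopifnot(length(vel) == n)
  i <- as.integer(edges[, 1]); j <- as.integer(edges[, 2])
  delay <- edges[, 3] / ((vel[i] + vel[j]) / 2)
  g <- igraph::graph_from_edgelist(cbind(i, j), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    stop(sprintf("disconnected: conduction graph has %d components (sizes %s)",
                 comp$no, paste(comp$csize, collapse = ", ")), call. = FALSE)
  }
  structure(list(edges = tibble::tibble(i = i, j = j, dist_mm = edges[, 3],
                                        delay_ms = delay),
                 positions = heart$vertices,
                 n = n, velocity = vel, radius = radius),
            class = "conduction_graph")
}

#' @export
print.conduction_graph <- function(x, ...) {
  cat(sprintf("<conduction_graph: %d nodes, %d edges, mean delay %.3f ms>\n",
              x$n, nrow(x$edges), mean(x$edges$delay_ms)))
  invisible(x)
}

delay_matrix <- function(g) {
  D <- matrix(Inf, g$n, g$n)
  diag(D) <- 0
  idx1 <- cbind(g$edges$i, g$edges$j)
  D[idx1] <- g$edges$delay_ms
  D[idx1[, 2:1, drop = FALSE]] <- g$edges$delay_ms
  D
}

#' Activation times by all-pairs shortest paths
#'
#' Computes per-node activation times (isochrones) as the minimum over
#' stimuli of stimulus time plus shortest-path delay, with the all-pairs
#' distances from a dense Floyd-Warshall pass over the conduction graph.
#'
#' @param g A [conduction_graph()].
#' @param stimuli Two-column matrix or data frame `(node, time_ms)`; a bare
#'   integer vector means stimulation at time 0.
#' @return Object of class `activation_map`: list with `times` (ms, per
#'   node), `stimuli`, and the node `positions`.
#' @export
activation_times <- function(g, stimuli) {
  if (is.null(dim(stimuli))) stimuli <- cbind(node = stimuli, time_ms = 0)
  stimuli <- as.matrix(stimuli)
  stopifnot(nrow(stimuli) >= 1, all(stimuli[, 1] >= 1), all(stimuli[, 1] <= g$n))
  D <- floyd_warshall_cpp(delay_matrix(g))
  t <- rep(Inf, g$n)
  for (s in seq_len(nrow(stimuli))) {
    t <- pmin(t, stimuli[s, 2] + D[stimuli[s, 1], ])
  }
  if (any(!is.finite(t))) {
    stop(sprintf("disconnected: %d node(s) unreachable from the stimuli",
                 sum(!is.finite(t))), call. = FALSE)
  }
  structure(list(times = unname(t),
                 stimuli = tibble::tibble(node = as.integer(stimuli[, 1]),
                                          time_ms = stimuli[, 2]),
                 positions = g$positions),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map: %d nodes, %d stimuli, t in [%.1f, %.1f] ms>\n",
              length(x$times), nrow(x$stimuli), min(x$times), max(x$times)))
  invisible(x)
}

#' Activation curve (local potential template)
#'
#' Piecewise smoothstep waveform of the local epicardial potential after
#' activation: resting before `t_act`, a monotone deflection of duration
#' `upstroke` to the plateau, plateau until the action-potential duration
#' `apd` has elapsed, then monotone repolarization of duration `repol` back
#' to resting. The defaults follow the extracellular (unipolar electrogram)
#' convention in which activated tissue is negative -- 0 mV baseline, -25 mV
#' plateau -- so that a pacing stimulus induces a potential minimum, with a
#' 2 ms upstroke, 250 ms APD and 80 ms repolarization. Transmembrane-style
#' curves (e.g. -90 mV resting, +10 mV plateau) are an affine re-mapping and
#' equally valid parameterizations.
#'
#' @param resting,plateau Potentials (mV).
#' @param upstroke,apd,repol Durations (ms), all > 0, `apd >= upstroke`.
#' @param region Region label this curve applies to.
#' @return Object of class `activation_curve`.
#' @export
activation_curve <- function(resting = 0, plateau = -25, upstroke = 2,
                             apd = 250, repol = 80, region = "ventricle") {
  stopifnot(upstroke > 0, apd > 0, repol > 0, apd >= upstroke)
  structure(list(resting = resting, plateau = plateau, upstroke = upstroke,
                 apd = apd, repol = repol, region = region),
            class = "activation_curve")
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Evaluate an activation curve
#'
#' @param curve An [activation_curve()].
#' @param t Time(s) in ms (vector or matrix).
#' @param t_act Local activation time(s) in ms (recycled against `t`).
#' @return Potential(s) in mV, same shape as `t`.
#' @export
activation_curve_value <- function(curve, t, t_act = 0) {
  dt <- t - t_act
  up <- smoothstep(dt / curve$upstroke)
  down <- smoothstep((dt - curve$apd) / curve$repol)
  v <- curve$resting + (curve$plateau - curve$resting) * (up - down)
  if (is.matrix(t)) matrix(v, nrow(t), ncol(t)) else v
}

#' Label heart vertices by region
#'
#' Splits the epicardial surface into an atrial cap (base side of the long
#' axis) and a ventricular remainder, for location-specific activation
#' curves.
#'
#' @param heart Heart [tri_surface()].
#' @param apex_axis Base-to-apex direction.
#' @param atrial_fraction Fraction of the long-axis extent labelled atrial.
#' @return Character vector of per-vertex labels (`"atrium"`/`"ventricle"`).
#' @export
heart_regions <- function(heart, apex_axis = c(0.45, 0.35, -0.82),
                          atrial_fraction = 0.25) {
  apex_axis <- apex_axis / sqrt(sum(apex_axis^2))
  proj <- heart$vertices %*% apex_axis
  cut <- quantile(proj, atrial_fraction)   # small proj = base side
  ifelse(proj <= cut, "atrium", "ventricle")
}

#' Time-dependent epicardial source potentials from an activation map
#'
#' Samples every node's activation curve at the movie frame times, placing
#' each node's waveform at its activation time.
#'
#' @param map An [activation_map()].
#' @param curves Named list of [activation_curve()] by region, or a single
#'   curve for all nodes.
#' @param regions Per-node region labels matching `names(curves)` (ignored
#'   for a single curve).
#' @param rate Sampling rate (Hz), default 2048.
#' @param duration Movie duration (ms); must cover the last activation plus
#'   APD and repolarization.
#' @return A [potential_movie()] with role `"epicardial_source"`.
#' @export
make_source_movie <- function(map, curves = activation_curve(), regions = NULL,
                              rate = 2048, duration = NULL) {
  if (inherits(curves, "activation_curve")) curves <- list(all = curves)
  if (is.null(regions)) regions <- rep(names(curves)[1], length(map$times))
  stopifnot(length(regions) == length(map$times),
            all(regions %in% names(curves)))
  need <- max(map$times) + max(vapply(curves, function(cv) cv$apd + cv$repol,
                                      numeric(1)))
  if (is.null(duration)) duration <- need + 10
  if (duration < need) {
    stop(sprintf("truncation: duration %.0f ms < required %.0f ms",
                 duration, need), call. = FALSE)
  }
  nf <- max(1L, as.integer(round(duration / 1000 * rate)))
  tf <- (seq_len(nf) - 1) / rate * 1000
  vals <- matrix(0, length(map$times), nf)
  for (rg in names(curves)) {
    idx <- which(regions == rg)
    if (length(idx) == 0) next
    dt <- outer(-map$times[idx], tf, "+")
    vals[idx, ] <- activation_curve_value(curves[[rg]], dt, 0)
  }
  potential_movie(vals, rate = rate, role = "epicardial_source")
}
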