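#' Triangulated surface
#'
#' `tri_surface()` constructs the basic geometric container of the package: a
#' closed, consistently oriented triangulated surface in millimetres. All
#' anatomy compartments (torso, lungs, liver, spleen, heart) are
#' `tri_surface` objects.
#'
#' @param vertices Numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param triangles Integer matrix, one row per triangle, 1-based vertex
#'   indices, wound counter-clockwise as seen from outside.
#' @param label Compartment name (e.g. `"torso"`, `"heart"`).
#' @return An object of class `tri_surface` with fields `vertices`,
#'   `triangles` and `label`.
#' @seealso [validate_surface()], [point_in_surface()]
#' @export
tri_surface <- function(vertices, triangles, label = "surface") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns", call. = FALSE)
  if (ncol(triangles) != 3L) stop("`triangles` must have 3 columns", call. = FALSE)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices))) {
    stop("triangle indices out of range", call. = FALSE)
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(triangles) <- NULL
  structure(list(vertices = vertices, triangles = triangles,
                 label = as.character(label)[1]),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface '%s': %d vertices, %d triangles>\n",
              x$label, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' @export
format.tri_surface <- function(x, ...) {
  sprintf("tri_surface '%s' (%dV/%dT)", x$label, nrow(x$vertices), nrow(x$triangles))
}

tri_corners <- function(s) {
  list(a = s$vertices[s$triangles[, 1], , drop = FALSE],
       b = s$vertices[s$triangles[, 2], , drop = FALSE],
       c = s$vertices[s$triangles[, 3], , drop = FALSE])
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-triangle areas of a surface (mm^2)
#' @param s A [tri_surface()].
#' @return Numeric vector, one area per triangle.
#' @export
triangle_areas <- function(s) {
  co <- tri_corners(s)
  cr <- row_cross(co$b - co$a, co$c - co$a)
  0.5 * sqrt(rowSums(cr^2))
}

#' Signed enclosed volume of a closed surface (mm^3)
#'
#' Positive for outward-oriented surfaces (divergence theorem over the
#' triangle fan from the origin).
#' @param s A [tri_surface()].
#' @return Scalar signed volume.
#' @export
signed_volume <- function(s) {
  co <- tri_corners(s)
  sum(rowSums(co$a * row_cross(co$b, co$c))) / 6
}

#' Area-weighted outward vertex normals
#' @param s A [tri_surface()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(s) {
  co <- tri_corners(s)
  fn <- row_cross(co$b - co$a, co$c - co$a)  # face normal, length 2*area
  n <- matrix(0, nrow(s$vertices), 3)
  for (k in 1:3) {
    idx <- s$triangles[, k]
    for (d in 1:3) {
      acc <- rowsum(fn[, d], group = idx)
      rows <- as.integer(rownames(acc))
      n[rows, d] <- n[rows, d] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Edge table of a triangulation
#'
#' @param s A [tri_surface()].
#' @return Tibble with columns `v1`, `v2` (v1 < v2) and `count`, the number of
#'   triangles sharing the edge.
#' @export
surface_edges <- function(s) {
  tr <- s$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  tibble::tibble(v1 = as.integer(parts[, 1]), v2 = as.integer(parts[, 2]),
                 count = as.integer(tab))
}

#' Mean edge length of a surface (mm)
#' @param s A [tri_surface()].
#' @return Scalar mean over unique mesh edges.
#' @export
mean_edge_length <- function(s) {
  e <- surface_edges(s)
  mean(sqrt(rowSums((s$vertices[e$v1, , drop = FALSE] -
                     s$vertices[e$v2, , drop = FALSE])^2)))
}

#' Euler characteristic V - E + F
#' @param s A [tri_surface()].
#' @return Integer; 2 for sphere-topology surfaces.
#' @export
euler_characteristic <- function(s) {
  nrow(s$vertices) - nrow(surface_edges(s)) + nrow(s$triangles)
}

#' Validate the invariants of a triangulated surface
#'
#' Checks that the surface is closed and manifold (every edge shared by
#' exactly two triangles), outward-oriented (signed volume > 0), and free of
#' degenerate triangles (area below `1e-9` mm^2). This is a reporting
#' operation: it never throws.
#'
#' @param s A [tri_surface()].
#' @return Character vector of violation descriptions naming the invariant and
#'   the offending simplex indices; empty when all invariants hold.
#' @export
validate_surface <- function(s) {
  out <- character()
  e <- surface_edges(s)
  bad <- e[e$count != 2L, , drop = FALSE]
  if (nrow(bad) > 0) {
    out <- c(out, sprintf(
      "non-manifold/open edges (shared by != 2 triangles): %s",
      paste(sprintf("%d-%d(x%d)", bad$v1, bad$v2, bad$count), collapse = ", ")))
  }
  vol <- signed_volume(s)
  if (!is.finite(vol) || vol <= 0) {
    out <- c(out, sprintf("negative or zero signed volume (%.6g mm^3): inconsistent/inward winding", vol))
  }
  ar <- triangle_areas(s)
  tiny <- which(ar < 1e-9)
  if (length(tiny) > 0) {
    out <- c(out, sprintf("degenerate triangles (area < 1e-9 mm^2): %s",
                          paste(tiny, collapse = ", ")))
  }
  out
}

#' Point-in-surface test by ray parity
#'
#' Casts a ray from `p` and counts crossings with the surface using the same
#' Moller-Trumbore kernel as the activation module; odd parity means inside.
#' Directions are retried deterministically when a crossing lands too close to
#' a triangle edge.
#'
#' @param s A closed [tri_surface()].
#' @param p Numeric length-3 point (mm), or an n x 3 matrix of points.
#' @return Logical (vector): `TRUE` iff strictly inside.
#' @export
point_in_surface <- function(s, p) {
  p <- rbind(p)
  stopifnot(ncol(p) == 3)
  Fc0 <- s$triangles - 1L
  scale <- max(apply(s$vertices, 2, function(v) diff(range(v))))
  cp <- closest_point_cpp(p, s$vertices, Fc0)
  if (any(cp$dist < 1e-6)) {
    stop("degenerate: point lies on the surface (within 1e-6 mm)", call. = FALSE)
  }
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(0.280351, 0.647816, 0.708290),
                c(-0.554700, 0.133631, 0.821584),
                c(0.722897, -0.496139, 0.481063))
  out <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    verdict <- NA
    for (d in seq_len(nrow(dirs))) {
      res <- ray_parity_cpp(p[i, ], dirs[d, ], s$vertices, Fc0,
                            1e-12 * scale, 1e-9)
      if (res[2] == 1L) { verdict <- (res[1] %% 2L) == 1L; break }
    }
    if (is.na(verdict)) {
      stop("degenerate: could not find a clean ray direction", call. = FALSE)
    }
    out[i] <- verdict
  }
  out
}

#' k-fold subdivided icosahedron projected to the unit sphere
#'
#' Each icosahedron face is split into `k^2` triangles on a barycentric
#' lattice and vertices are radially projected, giving `10 k^2 + 2` vertices.
#' Unlike recursive bisection this allows fine-grained control of resolution.
#'
#' @param k Subdivision order (>= 1).
#' @param label Label for the resulting surface.
#' @return A unit-sphere [tri_surface()].
#' @export
icosphere <- function(k = 4, label = "sphere") {
  stopifnot(k >= 1)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  if (k == 1L) return(tri_surface(v, f, label))
  # global vertex dedup via exact rational barycentric keys
  vert_env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list()
  get_vertex <- function(p, key) {
    id <- vert_env[[key]]
    if (!is.null(id)) return(id)
    id <- length(verts) + 1L
    verts[[id]] <<- p
    vert_env[[key]] <- id
    id
  }
  tris <- vector("list", nrow(f) * k * k)
  nt <- 0L
  for (fi in seq_len(nrow(f))) {
    ia <- f[fi, 1]; ib <- f[fi, 2]; ic <- f[fi, 3]
    A <- v[ia, ]; B <- v[ib, ]; C <- v[ic, ]
    # lattice point (i, j): bary (k - i - j, i, j) / k; key must be
    # edge/corner-consistent across faces -> canonical key by vertex ids
    key_of <- function(i, j) {
      w <- c(k - i - j, i, j)
      ids <- c(ia, ib, ic)
      keep <- w > 0
      o <- order(ids[keep])
      paste(ids[keep][o], w[keep][o], sep = ":", collapse = "|")
    }
    idx <- matrix(0L, k + 1, k + 1)
    for (i in 0:k) for (j in 0:(k - i)) {
      p <- ((k - i - j) * A + i * B + j * C) / k
      p <- p / sqrt(sum(p^2))
      idx[i + 1, j + 1] <- get_vertex(p, key_of(i, j))
    }
    for (i in 0:(k - 1)) for (j in 0:(k - 1 - i)) {
      nt <- nt + 1L
      tris[[nt]] <- c(idx[i + 1, j + 1], idx[i + 2, j + 1], idx[i + 1, j + 2])
      if (j < k - 1 - i) {
        nt <- nt + 1L
        tris[[nt]] <- c(idx[i + 2, j + 1], idx[i + 2, j + 2], idx[i + 1, j + 2])
      }
    }
  }
  tri_surface(do.call(rbind, verts), do.call(rbind, tris[seq_len(nt)]), label)
}

#' Closest point on a surface
#'
#' @param s A [tri_surface()].
#' @param p Length-3 point or n x 3 matrix.
#' @return List with `point` (n x 3), `triangle` (index), `bary` (n x 3
#'   barycentric weights) and `dist` (mm).
#' @export
closest_point_on_surface <- function(s, p) {
  p <- rbind(p)
  closest_point_cpp(p, s$vertices, s$triangles - 1L)
}

rotation_matrix_zto <- function(axis) {
  # rotation taking +z onto `axis` (minimal rotation)
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  cth <- sum(z * axis)
  if (abs(cth + 1) < 1e-12) return(diag(c(1, -1, -1)))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}
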