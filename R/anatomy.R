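#' Parameters of the synthetic thorax anatomy
#'
#' The synthetic anatomy stands in for an MRI-segmented patient model: torso,
#' two lungs, liver and spleen as deformed superellipsoids, plus a closed
#' epicardial heart surface. Sizes are adult-scale, in millimetres, in a
#' body-fixed frame with +x to the subject's left, +y anterior and +z
#' cranial.
#'
#' @param torso_semiaxes Torso semi-axes (mm), lateral/AP/vertical.
#' @param torso_exponent Superellipsoid exponent of the torso (2 = ellipsoid;
#'   larger values flatten towards a rounded box).
#' @param heart_center,heart_semiaxes Heart position and semi-axes (mm).
#' @param heart_axis Base-to-apex direction of the heart's long axis.
#' @param organs Named list (`lung_L`, `lung_R`, `liver`, `spleen`) of lists
#'   with `center`, `semiaxes` and optional `exponent`.
#' @param target_edge Named numeric target edge lengths (mm) per compartment
#'   (`torso`, `heart`, `lung`, `liver`, `spleen`).
#' @param jitter Amplitude (mm, >= 0) of seeded vertex jitter along normals.
#' @param seed Integer seed making the generated anatomy reproducible.
#' @return A list of class `anatomy_params`.
#' @export
anatomy_params <- function(torso_semiaxes = c(170, 110, 280),
                           torso_exponent = 2.5,
                           heart_center = c(25, 50, 30),
                           heart_semiaxes = c(40, 34, 52),
                           heart_axis = c(0.45, 0.35, -0.82),
                           organs = list(
                             lung_L = list(center = c(100, -10, 120),
                                           semiaxes = c(45, 70, 105)),
                             lung_R = list(center = c(-100, -10, 120),
                                           semiaxes = c(45, 70, 105)),
                             liver = list(center = c(-60, 10, -120),
                                          semiaxes = c(70, 75, 55)),
                             spleen = list(center = c(90, -35, -110),
                                           semiaxes = c(35, 40, 50))),
                           target_edge = c(torso = 20, heart = 5.5, lung = 25,
                                           liver = 25, spleen = 25),
                           jitter = 0.3,
                           seed = 1L) {
  stopifnot(all(target_edge > 0), jitter >= 0, all(torso_semiaxes > 0),
            all(heart_semiaxes > 0))
  structure(list(torso_semiaxes = torso_semiaxes,
                 torso_exponent = torso_exponent,
                 heart_center = heart_center,
                 heart_semiaxes = heart_semiaxes,
                 heart_axis = heart_axis / sqrt(sum(heart_axis^2)),
                 organs = organs,
                 target_edge = target_edge,
                 jitter = jitter,
                 seed = as.integer(seed)),
            class = "anatomy_params")
}

#' Default tissue conductivities (S/m)
#'
#' Thorax 0.2, lungs 0.04, liver 0.03, spleen 0.04 S/m; the heart surface is
#' the source surface and carries no interior conductivity of its own.
#' @return Named numeric vector.
#' @export
default_conductivities <- function() {
  c(torso = 0.2, lung_L = 0.04, lung_R = 0.04, liver = 0.03, spleen = 0.04)
}

# superellipsoid radius along unit direction u for semi-axes r, exponent p
superellipsoid_surface <- function(k, semiaxes, exponent = 2, label = "organ") {
  s <- icosphere(k, label = label)
  u <- s$vertices
  t <- rowSums(abs(sweep(u, 2, semiaxes, "/"))^exponent)^(-1 / exponent)
  s$vertices <- u * t
  s
}

subdiv_order <- function(mean_semiaxis, target_edge, label) {
  unit_edge <- 1.0515 * mean_semiaxis   # icosahedron edge length at this scale
  k <- as.integer(round(unit_edge / target_edge))
  if (k < 2) {
    stop(sprintf("resolution: target edge %.1f mm too large to resolve '%s'",
                 target_edge, label), call. = FALSE)
  }
  k
}

# seeded jitter along vertex normals; own RNG stream, restores global state
jitter_surface <- function(s, amplitude, seed) {
  if (amplitude <= 0) return(s)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- vertex_normals(s)
  s$vertices <- s$vertices + n * rnorm(nrow(s$vertices), sd = amplitude)
  s
}

label_seed <- function(seed, label) {
  seed + sum(utf8ToInt(label)) %% 1009L
}

build_compartment <- function(label, center, semiaxes, exponent, target_edge,
                              jitter, seed, rotation = NULL) {
  k <- subdiv_order(mean(semiaxes), target_edge, label)
  s <- superellipsoid_surface(k, semiaxes, exponent, label = label)
  if (!is.null(rotation)) s$vertices <- s$vertices %*% t(rotation)
  s$vertices <- sweep(s$vertices, 2, center, "+")
  jitter_surface(s, jitter, label_seed(seed, label))
}

#' Volume conductor container
#'
#' Bundles the torso surface, the passive organ compartments with their
#' conductivities, and the epicardial source surface.
#'
#' @param torso Torso [tri_surface()].
#' @param organs List of lists with fields `surface` and `sigma` (S/m).
#' @param heart Heart (epicardial) [tri_surface()].
#' @param torso_sigma Background thorax conductivity (S/m).
#' @return Object of class `volume_conductor`.
#' @export
volume_conductor <- function(torso, organs, heart, torso_sigma = 0.2) {
  stopifnot(inherits(torso, "tri_surface"), inherits(heart, "tri_surface"))
  structure(list(torso = torso, torso_sigma = torso_sigma,
                 organs = organs, heart = heart),
            class = "volume_conductor")
}

#' @export
print.volume_conductor <- function(x, ...) {
  cat(sprintf("<volume_conductor: torso %dV (%.2f S/m), heart %dV, %d organs>\n",
              nrow(x$torso$vertices), x$torso_sigma, nrow(x$heart$vertices),
              length(x$organs)))
  for (o in x$organs) {
    cat(sprintf("  %-7s %4dV  sigma = %.3f S/m\n",
                o$surface$label, nrow(o$surface$vertices), o$sigma))
  }
  invisible(x)
}

check_nesting <- function(torso, inner_surfaces) {
  # all inner vertices strictly inside the torso, and pairwise disjoint
  # (vertex containment test, with a bounding-box prefilter)
  for (s in inner_surfaces) {
    if (!all(point_in_surface(torso, s$vertices))) return(FALSE)
  }
  n <- length(inner_surfaces)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- inner_surfaces[[i]]; b <- inner_surfaces[[j]]
      ra <- apply(a$vertices, 2, range); rb <- apply(b$vertices, 2, range)
      overlap <- all(ra[1, ] <= rb[2, ] & rb[1, ] <= ra[2, ])
      if (!overlap) next
      inb <- b$vertices[, 1] >= ra[1, 1] & b$vertices[, 1] <= ra[2, 1] &
             b$vertices[, 2] >= ra[1, 2] & b$vertices[, 2] <= ra[2, 2] &
             b$vertices[, 3] >= ra[1, 3] & b$vertices[, 3] <= ra[2, 3]
      if (any(inb) && any(point_in_surface(a, b$vertices[inb, , drop = FALSE]))) {
        return(FALSE)
      }
      ina <- a$vertices[, 1] >= rb[1, 1] & a$vertices[, 1] <= rb[2, 1] &
             a$vertices[, 2] >= rb[1, 2] & a$vertices[, 2] <= rb[2, 2] &
             a$vertices[, 3] >= rb[1, 3] & a$vertices[, 3] <= rb[2, 3]
      if (any(ina) && any(point_in_surface(b, a$vertices[ina, , drop = FALSE]))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Generate the synthetic multi-compartment thorax anatomy
#'
#' Builds six closed surfaces (torso, two lungs, liver, spleen, heart) as
#' seeded, jittered superellipsoids and assembles them into a
#' [volume_conductor()] with the default tissue conductivities. The result is
#' deterministic given `params$seed`. If the vertex jitter breaks the nesting
#' invariants the anatomy is regenerated with halved jitter (with a warning).
#'
#' @param params An [anatomy_params()] object.
#' @return A valid [volume_conductor()].
#' @export
make_synthetic_anatomy <- function(params = anatomy_params()) {
  stopifnot(inherits(params, "anatomy_params"))
  sig <- default_conductivities()
  jit <- params$jitter
  for (attempt in 1:4) {
    torso <- build_compartment("torso", c(0, 0, 0), params$torso_semiaxes,
                               params$torso_exponent,
                               params$target_edge[["torso"]], jit, params$seed)
    rot <- rotation_matrix_zto(-params$heart_axis)  # apex at the local -z pole
    heart <- build_compartment("heart", params$heart_center,
                               params$heart_semiaxes, 2,
                               params$target_edge[["heart"]], jit, params$seed,
                               rotation = rot)
    organs <- lapply(names(params$organs), function(nm) {
      o <- params$organs[[nm]]
      te_key <- if (grepl("^lung", nm)) "lung" else nm
      list(surface = build_compartment(nm, o$center, o$semiaxes,
                                       o$exponent %||% 2,
                                       params$target_edge[[te_key]], jit,
                                       params$seed),
           sigma = unname(sig[[nm]]))
    })
    names(organs) <- names(params$organs)
    inner <- c(lapply(organs, `[[`, "surface"), list(heart))
    ok <- all(vapply(c(list(torso), inner), function(s)
      length(validate_surface(s)) == 0, logical(1))) &&
      check_nesting(torso, inner)
    if (ok) {
      return(volume_conductor(torso, organs, heart,
                              torso_sigma = unname(sig[["torso"]])))
    }
    warning(sprintf("jitter %.2f mm broke nesting invariants; retrying with %.2f mm",
                    jit, jit / 2), call. = FALSE)
    jit <- jit / 2
  }
  stop("geometry: could not generate a valid anatomy (jitter too large?)",
       call. = FALSE)
}

#' Convenience accessor: all labelled surfaces of a volume conductor
#' @param vc A [volume_conductor()].
#' @return Named list of [tri_surface()] objects.
#' @export
anatomy_surfaces <- function(vc) {
  c(list(torso = vc$torso),
    setNames(lapply(vc$organs, `[[`, "surface"), names(vc$organs)),
    list(heart = vc$heart))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
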