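#' Configuration of the packaged simulation studies
#'
#' Aggregates every knob of the electrode-configuration and pacing studies:
#' the two independently meshed anatomies (sources are simulated on grid A,
#' the inverse is computed on grid B of differing resolution, excluding
#' systematic grid artefacts), the electrode layouts under comparison, the
#' propagation and activation-curve parameters, the measurement noise, the
#' regularization policy and the seeds.
#'
#' @param anatomy [anatomy_params()] of the source/forward grid (A).
#' @param anatomy_b [anatomy_params()] of the independent inverse grid (B);
#'   defaults to the same shapes at coarser target edges with another seed.
#' @param layouts List of layout descriptors `list(name, kind, n, spacing)`.
#'   The defaults are the four reference configurations: 252 surrounding,
#'   62 surrounding, 62 concentrated at 30 mm, 62 super-concentrated at
#'   20 mm.
#' @param velocity Conduction velocity (m/s).
#' @param curves Named list of [activation_curve()] per region.
#' @param atrial_fraction Long-axis fraction labelled atrial.
#' @param stimulus_site Pacing site name for the configuration study (one of
#'   [standard_pacing_sites()] names).
#' @param snr_db Measurement SNR in dB (21 dB in the reference protocol).
#' @param inverse An [inverse_config()].
#' @param seeds Integer seeds for the noise realizations (one run each).
#' @param rate Sampling rate (Hz).
#' @param duration Movie duration (ms); `NULL` = cover the full QRST
#'   automatically.
#' @param pacing_sites Site names for the pacing study.
#' @param pacing_seeds Seeds for the pacing study.
#' @return Object of class `study_config`.
#' @export
study_config <- function(anatomy = anatomy_params(),
                         anatomy_b = anatomy_params(
                           target_edge = c(torso = 24, heart = 6.5,
                                           lung = 30, liver = 30, spleen = 22),
                           seed = 102L),
                         layouts = list(
                           list(name = "surround_252", kind = "surrounding",
                                n = 252, z_extent = 260),
                           list(name = "surround_62", kind = "surrounding",
                                n = 62, z_extent = 260),
                           list(name = "concentrated_30",
                                kind = "concentrated", n = 62, spacing = 30),
                           list(name = "concentrated_20",
                                kind = "concentrated", n = 62, spacing = 20)),
                         velocity = 0.8,
                         curves = list(
                           atrium = activation_curve(apd = 180,
                                                     region = "atrium"),
                           ventricle = activation_curve(apd = 250,
                                                        region = "ventricle")),
                         atrial_fraction = 0.25,
                         stimulus_site = "apex_1",
                         snr_db = 21,
                         inverse = inverse_config(),
                         seeds = 1:10,
                         rate = 2048,
                         duration = NULL,
                         pacing_sites = c("apex_1", "apex_2",
                                          "rvot_1", "rvot_2"),
                         pacing_seeds = 1:5) {
  stopifnot(length(seeds) >= 1, length(pacing_seeds) >= 1, velocity > 0,
            rate > 0)
  structure(list(anatomy = anatomy, anatomy_b = anatomy_b, layouts = layouts,
                 velocity = velocity, curves = curves,
                 atrial_fraction = atrial_fraction,
                 stimulus_site = stimulus_site, snr_db = snr_db,
                 inverse = inverse, seeds = as.integer(seeds), rate = rate,
                 duration = duration, pacing_sites = pacing_sites,
                 pacing_seeds = as.integer(pacing_seeds)),
            class = "study_config")
}

#' Study configuration for the pacing-localization experiment
#'
#' Same protocol as [study_config()] but with finer heart grids (mean edge
#' length at or below 4 mm) so that the localization error is not dominated
#' by mesh quantization, and the super-concentrated 20 mm layout only.
#'
#' @param ... Overrides passed to [study_config()].
#' @return A `study_config`.
#' @export
pacing_study_config <- function(...) {
  study_config(
    anatomy = anatomy_params(target_edge = c(torso = 20, heart = 3.4,
                                             lung = 25, liver = 25,
                                             spleen = 25)),
    anatomy_b = anatomy_params(target_edge = c(torso = 24, heart = 3.1,
                                               lung = 30, liver = 30,
                                               spleen = 22),
                               seed = 102L),
    layouts = list(list(name = "concentrated_20", kind = "concentrated",
                        n = 62, spacing = 20)),
    ...)
}

#' Canonical pacing sites on a heart surface
#'
#' Returns four deterministic stimulus vertices: two in the apex region
#' (apex vertex and a neighbour 10-18 mm away) and two in the outflow region
#' (anterior base, emulating right-ventricular outflow-tract lead
#' positions).
#'
#' @param heart Heart [tri_surface()].
#' @param apex_axis Base-to-apex direction.
#' @return Tibble with columns `site` and `node`.
#' @export
standard_pacing_sites <- function(heart, apex_axis = c(0.45, 0.35, -0.82)) {
  apex_axis <- apex_axis / sqrt(sum(apex_axis^2))
  v <- heart$vertices
  proj <- drop(v %*% apex_axis)
  apex1 <- which.max(proj)
  d1 <- sqrt(rowSums(sweep(v, 2, v[apex1, ])^2))
  ring <- which(d1 >= 10 & d1 <= 18)
  apex2 <- ring[which.max(proj[ring])]
  base <- which(proj <= quantile(proj, 0.3))
  rvot1 <- base[which.max(v[base, 2])]
  d2 <- sqrt(rowSums(sweep(v, 2, v[rvot1, ])^2))
  ring2 <- base[d2[base] >= 10 & d2[base] <= 18]
  rvot2 <- ring2[which.max(v[ring2, 2])]
  tibble::tibble(site = c("apex_1", "apex_2", "rvot_1", "rvot_2"),
                 node = as.integer(c(apex1, apex2, rvot1, rvot2)))
}

make_layout <- function(torso, heart, layout) {
  if (layout$kind == "surrounding") {
    layout_surrounding(torso, layout$n, heart = heart,
                       z_extent = layout$z_extent %||% NULL)
  } else {
    layout_concentrated(torso, layout$n, layout$spacing, heart = heart)
  }
}

#' Re-register an electrode set onto another torso mesh
#'
#' Snaps electrode positions to their closest points on a second torso grid
#' (the in-silico analogue of registering measured electrode positions to a
#' patient-specific model).
#'
#' @param e An [electrode_set()].
#' @param torso Target torso [tri_surface()].
#' @return An [electrode_set()] on the target surface.
#' @export
snap_electrodes <- function(e, torso) {
  cp <- closest_point_on_surface(torso, electrode_positions(e))
  electrode_set(cp$point, labels = e$label,
                layout_kind = attr(e, "layout_kind"),
                spacing = attr(e, "spacing"), torso = torso)
}

#' Map a movie defined on one surface onto another surface's vertices
#'
#' Each target vertex takes the barycentric interpolation of the source
#' movie at its closest point on the source surface (used to compare grids
#' of differing resolution).
#'
#' @param movie [potential_movie()] on `from` vertices.
#' @param from,to [tri_surface()] objects.
#' @return A [potential_movie()] on `to` vertices.
#' @export
map_movie_to_surface <- function(movie, from, to) {
  cp <- closest_point_on_surface(from, to$vertices)
  M <- matrix(0, nrow(to$vertices), nrow(from$vertices))
  for (i in seq_len(nrow(to$vertices))) {
    tri <- from$triangles[cp$triangle[i], ]
    M[i, tri] <- M[i, tri] + cp$bary[i, ]
  }
  potential_movie(M %*% movie$values, rate = movie$rate, role = movie$role)
}

# shared simulation state of a study: anatomies, activation source, forward
# operators and the grid-B projection of the source
study_context <- function(cfg, stimulus_node = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating anatomies (grids A and B)")
  vcA <- make_synthetic_anatomy(cfg$anatomy)
  vcB <- make_synthetic_anatomy(cfg$anatomy_b)
  regions <- heart_regions(vcA$heart, cfg$anatomy$heart_axis,
                           cfg$atrial_fraction)
  say("building conduction graph (%d nodes)", nrow(vcA$heart$vertices))
  g <- conduction_graph(vcA$heart, cfg$velocity)
  sites <- standard_pacing_sites(vcA$heart, cfg$anatomy$heart_axis)
  say("assembling forward BEM (grid A)")
  TA <- bem_transfer_matrix(vcA)
  say("assembling inverse BEM (grid B)")
  TBfull <- bem_transfer_matrix(vcB)
  list(cfg = cfg, vcA = vcA, vcB = vcB, regions = regions, graph = g,
       sites = sites, TA = TA, TBfull = TBfull)
}

simulate_beat <- function(ctx, stimulus_node) {
  cfg <- ctx$cfg
  amap <- activation_times(ctx$graph, stimulus_node)
  src <- make_source_movie(amap, cfg$curves, ctx$regions, cfg$rate,
                           cfg$duration)
  surf <- apply_forward(ctx$TA, src)
  srcB <- map_movie_to_surface(src, ctx$vcA$heart, ctx$vcB$heart)
  list(amap = amap, src = src, surf = surf, srcB = srcB)
}

layout_operators <- function(ctx, layout) {
  el <- make_layout(ctx$vcA$torso, ctx$vcA$heart, layout)
  elB <- snap_electrodes(el, ctx$vcB$torso)
  TB <- transfer_matrix(
    electrode_interpolation(ctx$vcB$torso, elB) %*% ctx$TBfull$matrix,
    rows = "electrode",
    geometry_hash = ctx$TBfull$geometry_hash,
    electrode_hash = cheap_hash(electrode_positions(elB)))
  list(electrodes = el, electrodes_b = elB, TB = TB)
}

#' Run the electrode-configuration simulation study
#'
#' For each layout and seed: simulate a paced beat on source grid A, compute
#' body-surface potentials through the grid-A transfer matrix, sample the
#' layout's electrodes, add measurement noise, reconstruct epicardial
#' potentials on the independently meshed grid B, and correlate with the
#' source projected onto grid B. Errors in a (layout, seed) cell are
#' recorded and the run continues.
#'
#' @param cfg A [study_config()].
#' @param verbose Emit progress messages.
#' @return Object of class `study_result` with per-cell metrics
#'   (`tidy()`), per-layout aggregates (`glance()`), the 16-point anterior
#'   correlation data, and the layout ranking.
#' @export
run_configuration_study <- function(cfg = study_config(), verbose = FALSE) {
  ctx <- study_context(cfg, verbose = verbose)
  stim <- ctx$sites$node[match(cfg$stimulus_site, ctx$sites$site)]
  beat <- simulate_beat(ctx, stim)
  cells <- list()
  spoints <- list()
  for (layout in cfg$layouts) {
    if (verbose) message("layout ", layout$name)
    ops <- tryCatch(layout_operators(ctx, layout), error = identity)
    for (s in cfg$seeds) {
      cell <- tibble::tibble(layout = layout$name, seed = s,
                             anterior_r = NA_real_, overall_r = NA_real_,
                             lambda = NA_real_, ecg_median_r = NA_real_,
                             error = NA_character_)
      if (inherits(ops, "condition")) {
        cell$error <- conditionMessage(ops)
      } else {
        res <- tryCatch({
          pel <- sample_electrodes(beat$surf, ctx$vcA$torso, ops$electrodes)
          pn <- add_noise(pel, noise_spec(cfg$snr_db, seed = s))
          sol <- reconstruct_movie(ops$TB, pn, cfg$inverse)
          rep <- evaluation_report(beat$srcB, sol$movie, ctx$vcB$heart,
                                   ops$TB, sol, pn)
          spoints[[length(spoints) + 1]] <-
            dplyr::mutate(rep$sample_points, layout = layout$name, seed = s)
          cell$anterior_r <- rep$anterior_r
          cell$overall_r <- rep$overall_r
          cell$lambda <- sol$lambda
          cell$ecg_median_r <- median(rep$ecg_r, na.rm = TRUE)
          cell
        }, error = function(e) {
          cell$error <- conditionMessage(e)
          cell
        })
        cell <- res
      }
      cells[[length(cells) + 1]] <- cell
    }
  }
  cells <- dplyr::bind_rows(cells)
  summary <- cells |>
    dplyr::group_by(.data$layout) |>
    dplyr::summarise(mean_r = mean(.data$anterior_r, na.rm = TRUE),
                     sd_r = sd(.data$anterior_r, na.rm = TRUE),
                     mean_overall_r = mean(.data$overall_r, na.rm = TRUE),
                     n_ok = sum(!is.na(.data$anterior_r)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_r)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(kind = "configuration", cells = cells, summary = summary,
                 sample_points = dplyr::bind_rows(spoints),
                 config = cfg),
            class = "study_result")
}

#' Run the in-silico pacing localization study
#'
#' For each pacing site and seed: single-site stimulus, body-surface
#' potentials at the super-concentrated layout with measurement noise,
#' Tikhonov reconstruction on the independent grid, then the localization
#' error (distance from the true stimulus to the earliest-depolarization
#' node) and the point-spread threshold test on the frame of peak pacing
#' deflection.
#'
#' @param cfg A [study_config()]; [pacing_study_config()] gives the default
#'   protocol.
#' @param verbose Emit progress messages.
#' @return A `study_result` with per-run localization errors (mm) and
#'   point-spread cross-sections (mm).
#' @export
run_pacing_study <- function(cfg = pacing_study_config(), verbose = FALSE) {
  ctx <- study_context(cfg, verbose = verbose)
  layout <- cfg$layouts[[1]]
  ops <- layout_operators(ctx, layout)
  cells <- list()
  for (site in cfg$pacing_sites) {
    if (verbose) message("pacing site ", site)
    node <- ctx$sites$node[match(site, ctx$sites$site)]
    beat <- simulate_beat(ctx, node)
    true_pos <- ctx$vcA$heart$vertices[node, ]
    pel <- sample_electrodes(beat$surf, ctx$vcA$torso, ops$electrodes)
    for (s in cfg$pacing_seeds) {
      cell <- tibble::tibble(layout = layout$name, site = site, seed = s,
                             localization_error_mm = NA_real_,
                             point_spread_mm = NA_real_,
                             threshold_mv = NA_real_, lambda = NA_real_,
                             error = NA_character_)
      res <- tryCatch({
        pn <- add_noise(pel, noise_spec(cfg$snr_db,
                                        seed = 1000L * node %% 7919L + s))
        sol <- reconstruct_movie(ops$TB, pn, cfg$inverse)
        rec <- sol$movie
        site_hat <- earliest_activation_site(rec, ctx$vcB$heart)
        cell$localization_error_mm <-
          sqrt(sum((site_hat$position - true_pos)^2))
        # analyse the pacing peak while the spot is still compact: the
        # frame of the detected site's own deepest deflection shortly
        # after its depolarization
        win <- which(frame_times(rec) <= site_hat$time_ms + 20)
        pk_frame <- win[which.min(rec$values[site_hat$node, win])]
        ps <- point_spread(rec$values[, pk_frame], ctx$vcB$heart,
                           peak_node = site_hat$node)
        cell$point_spread_mm <- ps$cross_section_mm
        cell$threshold_mv <- ps$threshold_mv
        cell$lambda <- sol$lambda
        cell
      }, error = function(e) { cell$error <- conditionMessage(e); cell })
      cells[[length(cells) + 1]] <- res
    }
  }
  cells <- dplyr::bind_rows(cells)
  summary <- tibble::tibble(
    layout = layout$name,
    mean_localization_error_mm = mean(cells$localization_error_mm,
                                      na.rm = TRUE),
    sd_localization_error_mm = sd(cells$localization_error_mm, na.rm = TRUE),
    mean_point_spread_mm = mean(cells$point_spread_mm, na.rm = TRUE),
    sd_point_spread_mm = sd(cells$point_spread_mm, na.rm = TRUE),
    n_ok = sum(!is.na(cells$localization_error_mm)))
  structure(list(kind = "pacing", cells = cells, summary = summary,
                 config = cfg),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result [%s]: %d runs>\n", x$kind, nrow(x$cells)))
  print(x$summary)
  invisible(x)
}

#' Per-run metrics of a study
#' @param x A `study_result`.
#' @param ... Unused.
#' @return Tibble of per-(layout, seed) cells.
#' @export
tidy.study_result <- function(x, ...) x$cells

#' Per-layout aggregates of a study
#' @param x A `study_result`.
#' @param ... Unused.
#' @return Tibble of layout summaries.
#' @export
glance.study_result <- function(x, ...) x$summary

#' Generate small seeded test fixtures on disk
#'
#' Writes regenerable, documented fixtures used by the test suite:
#' `tiny_anatomy` (six valid coarse surfaces plus manifest, under 2000
#' triangles), `toy_transfer` (an 8 x 12 transfer matrix with unit row sums),
#' or `paced_movie` (a small paced source movie with JSON sidecar).
#' Regeneration with the same seed is bit-identical.
#'
#' @param kind One of `"tiny_anatomy"`, `"toy_transfer"`, `"paced_movie"`.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Character vector of the files written.
#' @export
fixture_generator <- function(kind, seed = 1L, dir = tempdir()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (kind == "tiny_anatomy") {
    params <- anatomy_params(target_edge = c(torso = 40, heart = 12,
                                             lung = 40, liver = 38,
                                             spleen = 22),
                             jitter = 0.2, seed = seed)
    vc <- make_synthetic_anatomy(params)
    write_anatomy(vc, file.path(dir, "tiny_anatomy"), format = "off")
    list.files(file.path(dir, "tiny_anatomy"), full.names = TRUE)
  } else if (kind == "toy_transfer") {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    m <- matrix(abs(rnorm(8 * 12)) + 0.1, 8, 12)
    m <- m / rowSums(m)
    path <- file.path(dir, "toy_transfer.tsv")
    write_transfer_matrix(transfer_matrix(m, rows = "electrode"), path)
    c(path, paste0(path, ".json"))
  } else if (kind == "paced_movie") {
    heart <- icosphere(3, label = "heart")
    heart$vertices <- heart$vertices * 25
    g <- conduction_graph(heart, velocity = 0.8)
    amap <- activation_times(g, 1L + seed %% nrow(heart$vertices))
    mv <- make_source_movie(amap, activation_curve(apd = 120, repol = 40),
                            rate = 512)
    path <- file.path(dir, "paced_movie.tsv")
    write_movie(mv, path)
    c(path, paste0(path, ".json"))
  } else {
    stop("unknown fixture kind: ", kind, call. = FALSE)
  }
}
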