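mini_cfg <- function(seeds = 1:2) {
  study_config(
    anatomy = tiny_params(),
    anatomy_b = anatomy_params(target_edge = c(torso = 35, heart = 14,
                                               lung = 42, liver = 40,
                                               spleen = 22),
                               jitter = 0.2, seed = 102L),
    layouts = list(list(name = "c20", kind = "concentrated", n = 16,
                        spacing = 20)),
    seeds = seeds, rate = 512)
}

mini_result <- function() memo_fixture("mini_study", function() {
  run_configuration_study(mini_cfg())
})

test_that("fixture generator writes valid, regenerable fixtures", {
  dir <- withr::local_tempdir()
  files <- fixture_generator("tiny_anatomy", seed = 1L, dir = dir)
  expect_true(any(grepl("manifest.json", files)))
  vc <- read_anatomy(file.path(dir, "tiny_anatomy"))
  ss <- anatomy_surfaces(vc)
  expect_length(ss, 6)
  for (s in ss) expect_length(validate_surface(s), 0)
  expect_lt(sum(vapply(ss, function(s) nrow(s$triangles), numeric(1))), 2000)

  tf <- fixture_generator("toy_transfer", seed = 2L, dir = dir)
  tm <- read_transfer_matrix(tf[1])
  expect_equal(dim(tm$matrix), c(8, 12))
  expect_true(all(abs(rowSums(tm$matrix) - 1) < 1e-6))

  p1 <- fixture_generator("paced_movie", seed = 3L, dir = dir)
  bytes1 <- readBin(p1[1], "raw", file.size(p1[1]))
  p2 <- fixture_generator("paced_movie", seed = 3L,
                          dir = withr::local_tempdir())
  bytes2 <- readBin(p2[1], "raw", file.size(p2[1]))
  expect_identical(bytes1, bytes2)

  expect_error(fixture_generator("nope"), "unknown fixture kind")
})

test_that("electrode re-registration snaps onto the target grid", {
  vcA <- tiny_vc()
  vcB <- make_synthetic_anatomy(anatomy_params(
    target_edge = c(torso = 35, heart = 14, lung = 42, liver = 40,
                    spleen = 22), jitter = 0.2, seed = 102L))
  e <- layout_surrounding(vcA$torso, 16, heart = vcA$heart)
  eB <- snap_electrodes(e, vcB$torso)
  d <- closest_point_on_surface(vcB$torso,
                                as.matrix(eB[, c("x", "y", "z")]))$dist
  expect_true(all(d < 1e-6))
  expect_equal(eB$label, e$label)
})

test_that("movies map onto an identical surface without change", {
  heart <- tiny_vc()$heart
  mv <- potential_movie(matrix(rnorm(nrow(heart$vertices) * 3), ncol = 3),
                        role = "epicardial_source")
  back <- map_movie_to_surface(mv, heart, heart)
  expect_equal(back$values, mv$values, tolerance = 1e-9)
})

test_that("study results are a pure function of the configuration", {
  r1 <- mini_result()
  r2 <- run_configuration_study(mini_cfg())
  expect_equal(r1$cells, r2$cells, tolerance = 1e-12)
  expect_equal(r1$summary, r2$summary, tolerance = 1e-12)
  expect_true(all(is.na(r1$cells$error)))
  expect_equal(nrow(r1$cells), 2)   # one layout x two seeds
})

test_that("pacing sites sit in the apex and outflow regions", {
  heart <- default_vc()$heart
  sites <- standard_pacing_sites(heart)
  expect_equal(sites$site, c("apex_1", "apex_2", "rvot_1", "rvot_2"))
  expect_length(unique(sites$node), 4)
  axis <- anatomy_params()$heart_axis
  proj <- drop(heart$vertices %*% axis)
  expect_true(all(proj[sites$node[1:2]] > quantile(proj, 0.8)))
  expect_true(all(proj[sites$node[3:4]] < quantile(proj, 0.35)))
  d12 <- sqrt(sum((heart$vertices[sites$node[1], ] -
                   heart$vertices[sites$node[2], ])^2))
  expect_gte(d12, 10); expect_lte(d12, 18)
})

test_that("autoplot methods return ggplot objects", {
  heart <- tiny_vc()$heart
  g <- conduction_graph(heart, 0.8)
  am <- activation_times(g, 1L)
  expect_s3_class(autoplot(am), "ggplot")
  expect_s3_class(autoplot(mini_result()), "ggplot")
  rep <- evaluation_report(
    potential_movie(matrix(rnorm(nrow(heart$vertices) * 5), ncol = 5),
                    role = "epicardial_source"),
    potential_movie(matrix(rnorm(nrow(heart$vertices) * 5), ncol = 5),
                    role = "epicardial_source"),
    heart)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(glance(rep), "tbl_df")
})

test_that("study tidiers expose per-run and per-layout tables", {
  r <- mini_result()
  expect_s3_class(tidy(r), "tbl_df")
  expect_named(glance(r),
               c("layout", "mean_r", "sd_r", "mean_overall_r", "n_ok",
                 "rank"))
})
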