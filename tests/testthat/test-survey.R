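test_that("the sample grid enumerates the polar design", {
  cfg <- survey_config()          # default design: 10..360 x 0.5..40
  g <- sample_grid(cfg)
  expect_equal(nrow(g), 2880)
  expect_equal(length(unique(g$theta)), 36)
  expect_equal(length(unique(g$distance)), 80)
  expect_equal(g$theta[1:3], c(10, 10, 10))        # azimuth-major ordering
  expect_equal(g$distance[1:3], c(0.5, 1, 1.5))

  one <- survey_config(start_angle = 90, end_angle = 90,
                       max_distance = 5, distance_step = 5)
  expect_equal(nrow(sample_grid(one)), 1)

  wrap <- survey_config(start_angle = 0, end_angle = 350)
  expect_equal(length(unique(sample_grid(wrap)$theta)), 36)
})

test_that("an environment with nothing in the sight band is fully visible", {
  # canopy floating far above the target rectangle: no candidate points
  set.seed(41)
  cl <- point_cloud(runif(500, -15, 15), runif(500, -15, 15), runif(500, 5, 8),
                    label = rep("non_ground", 500))
  cfg <- survey_config(observer(0, 0, 0), start_angle = 45, end_angle = 360,
                       angle_step = 45, max_distance = 10, distance_step = 2.5,
                       resolution = 0.01, densify_spacing = 0)
  sv <- run_survey(cl, cfg)
  expect_true(all(sv$records$visibility == 100))
})

test_that("bare flat ground occupies at most its pixel row", {
  sc <- label_from_truth(make_scene(scene_spec(extent = 24, terrain = "flat",
                                               ground_spacing = 0.4, seed = 42)))
  cfg <- survey_config(observer(0, 0, 0), h = 2, resolution = 0.005,
                       start_angle = 120, end_angle = 360, angle_step = 120,
                       max_distance = 8, distance_step = 2)
  sv <- shield_survey(sc, cfg)
  expect_true(all(sv$records$visibility >= 100 * (1 - 1 / 400)))
  expect_lt(min(sv$records$visibility), 100)   # densified ground does occlude
})

test_that("a wall taller than the target blanks every farther sample", {
  sc <- make_scene(scene_spec(extent = 30, terrain = "flat",
                              ground_spacing = 0.4,
                              walls = list(c(5, -2, 5, 2, 3)),
                              wall_spacing = 0.02, seed = 43))
  sc <- label_from_truth(sc)
  cfg <- survey_config(observer(0, 0, 0), w = 1.5, h = 2, resolution = 0.05,
                       start_angle = 360, end_angle = 360,
                       max_distance = 12, distance_step = 1,
                       densify_spacing = 0.05)
  sv <- shield_survey(sc, cfg)
  r <- sv$records
  expect_true(all(r$visibility[r$distance > 5] == 0))
  expect_true(all(r$visibility[r$distance < 5] > 50))
})

test_that("surveys are deterministic and sized by the grid", {
  sc <- label_from_truth(flat_forest(seed = 44, extent = 24, n_trees = 6))
  cfg <- survey_config(observer(0, 0, 0), start_angle = 90, end_angle = 360,
                       angle_step = 90, max_distance = 8, distance_step = 2,
                       resolution = 0.05)
  a <- shield_survey(sc, cfg)
  b <- shield_survey(sc, cfg)
  expect_identical(a$records, b$records)
  expect_equal(nrow(a$records), nrow(sample_grid(cfg)))
})

test_that("samples beyond ground coverage are flagged invalid, not fatal", {
  sc <- label_from_truth(make_scene(scene_spec(extent = 12, terrain = "tilt",
                                               slope = 0.1, ground_spacing = 0.5,
                                               seed = 45)))
  cfg <- survey_config(observer(0, 0, 0), normalized = FALSE,
                       start_angle = 360, end_angle = 360,
                       max_distance = 12, distance_step = 3,
                       resolution = 0.05, densify_spacing = 0)
  expect_warning(sv <- run_survey(sc, cfg), "coverage")
  r <- sv$records
  expect_true(any(is.na(r$visibility)))          # 12 m is far outside the plot
  expect_true(any(is.finite(r$visibility)))      # near samples still computed
})

test_that("the observer must stand inside the cloud extent", {
  sc <- label_from_truth(flat_forest(seed = 46, extent = 12, n_trees = 0))
  cfg <- survey_config(observer(50, 0, 0), max_distance = 4, distance_step = 2,
                       start_angle = 90, end_angle = 90, resolution = 0.05)
  expect_error(run_survey(sc, cfg), "outside")
})

test_that("per-sample occlusion images can be written to disk", {
  sc <- label_from_truth(flat_forest(seed = 47, extent = 16, n_trees = 4))
  dir <- withr::local_tempdir()
  cfg <- survey_config(observer(0, 0, 0), start_angle = 180, end_angle = 360,
                       angle_step = 180, max_distance = 4, distance_step = 2,
                       resolution = 0.05)
  sv <- shield_survey(sc, cfg, image_dir = dir)
  files <- list.files(dir)
  expect_setequal(files, c("theta180_d2.png", "theta180_d4.png",
                           "theta360_d2.png", "theta360_d4.png"))
  img <- read_occlusion_image(file.path(dir, files[1]))
  expect_equal(dim(img), c(40, 30))
})

test_that("the survey loop reproduces the operation-by-operation pipeline", {
  sc <- oracle_scene(seed = 48)
  for (norm in c(TRUE, FALSE)) {
    cloud <- if (norm) normalize_heights(sc) else sc
    cfg <- survey_config(observer(0.5, -0.5, if (norm) 0 else 0.025),
                         w = 1.5, h = 2,
                         start_angle = 72, end_angle = 360, angle_step = 72,
                         max_distance = 9, distance_step = 3,
                         resolution = 0.05, normalized = norm,
                         densify_spacing = 0)
    sv <- run_survey(cloud, cfg)
    ground <- if (norm) NULL else cloud
    for (k in seq_len(nrow(sv$records))) {
      r <- sv$records[k, ]
      ref <- op_path_visibility(cloud, cfg$observer, r$theta, r$distance,
                                cfg$w, cfg$h, cfg$resolution, norm,
                                ground = ground)
      expect_identical(unname(r$visibility), ref)
    }
  }
})
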