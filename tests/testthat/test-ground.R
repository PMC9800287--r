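truth_accuracy <- function(cloud, classified, min_hag = 0.5) {
  tr <- attr(cloud, "truth")
  is_gnd <- tr$label == "ground"
  eval_set <- is_gnd | tr$hag >= min_hag
  pred_gnd <- classified$label == "ground"
  mean((pred_gnd == is_gnd)[eval_set])
}

test_that("flat plane plus trees classifies exactly", {
  sc <- make_scene(scene_spec(extent = 24, terrain = "flat", n_trees = 8,
                              ground_spacing = 0.5, seed = 2))
  cl <- classify_ground(sc)
  tr <- attr(sc, "truth")
  # every true ground point recovered; everything >= 0.5 m up rejected
  expect_true(all(cl$label[tr$label == "ground"] == "ground"))
  expect_true(all(cl$label[tr$hag >= 0.5] == "non_ground"))
})

test_that("single and degenerate clouds are handled", {
  expect_equal(classify_ground(point_cloud(1, 2, 3))$label, "ground")
  degen <- point_cloud(c(1, 1, 1), c(2, 2, 2), c(0, 1, 2))
  expect_error(classify_ground(degen), "degenerate")
})

test_that("ground recall stays above 99% on undulating terrain with trees", {
  for (seed in c(31, 32)) {
    sc <- make_scene(scene_spec(extent = 40, terrain = "sinusoid",
                                amplitude = 1, wavelength = 20,
                                n_trees = 20, ground_spacing = 0.35,
                                seed = seed))
    cl <- classify_ground(sc, cell_size = 1, z_tolerance = 0.15)
    tr <- attr(sc, "truth")
    recall <- mean(cl$label[tr$label == "ground"] == "ground")
    expect_gte(recall, 0.99)
    expect_gte(truth_accuracy(sc, cl), 0.99)
  }
})

test_that("normalization flattens the ground and preserves tree heights", {
  lift <- function(x, y) rep(5, length(x))
  sc <- make_scene(scene_spec(extent = 24, terrain = "custom", terrain_fn = lift,
                              n_trees = 6, tree_height_mean = 3,
                              tree_height_sd = 0, ground_spacing = 0.5,
                              seed = 4))
  cl <- classify_ground(sc)
  nz <- normalize_heights(cl)
  g <- nz$label == "ground"
  expect_lt(max(abs(nz$z[g])), 0.15)
  expect_equal(nz$x, sc$x)               # planimetric coordinates untouched
  expect_gt(max(nz$z), 2.5)              # tree tops near 3 m
  expect_lt(max(nz$z), 3.3)

  # idempotent within the classification tolerance (stem points within the
  # ground band keep the re-fitted surface within z_tolerance of zero)
  again <- normalize_heights(nz)
  expect_lt(max(abs(again$z - nz$z)), 0.15)
})

test_that("normalization on truth labels is exact for planar terrain", {
  sc <- label_from_truth(make_scene(scene_spec(extent = 20, terrain = "tilt",
                                               slope = 0.1, n_trees = 5,
                                               ground_spacing = 0.5, seed = 6)))
  nz <- normalize_heights(sc)
  g <- nz$label == "ground"
  expect_lt(max(abs(nz$z[g])), 1e-9)     # TIN reproduces its vertices
  tr <- attr(sc, "truth")
  expect_lt(max(abs(nz$z[!g] - tr$hag[!g])), 1e-6)
  expect_error(normalize_heights(point_cloud(1:3, 1:3, 1:3)), "ground")
})

test_that("densification fills a regular grid on the interpolated surface", {
  sq <- point_cloud(c(0, 10, 0, 10), c(0, 0, 10, 10), rep(0, 4),
                    label = rep("ground", 4))
  dense <- densify_ground(sq, spacing = 1)
  expect_gte(sum(dense$label == "ground"), 121)
  expect_equal(dense$x[1:4], sq$x)       # originals retained, order preserved
  expect_true(all(dense$z == 0))

  sparse <- densify_ground(sq, spacing = 20)
  expect_gte(n_points(sparse), 5)

  tilt <- point_cloud(c(0, 10, 0, 10), c(0, 0, 10, 10), c(0, 1, 0, 1),
                      label = rep("ground", 4))
  dd <- densify_ground(tilt, spacing = 0.5)
  added <- seq(5, n_points(dd))
  expect_lt(max(abs(dd$z[added] - 0.1 * dd$x[added])), 1e-6)

  line <- point_cloud(c(0, 1, 2), c(0, 0, 0), c(0, 0, 0),
                      label = rep("ground", 3))
  expect_error(densify_ground(line, 0.5), "non-collinear")
})

test_that("ground elevation queries interpolate exactly on planes", {
  tilt <- point_cloud(c(0, 10, 0, 10, 5), c(0, 0, 10, 10, 5),
                      c(0, 1, 0, 1, 0.5), label = rep("ground", 5))
  expect_lt(abs(ground_elevation_at(tilt, 7.3, 4) - 0.73), 1e-6)
  expect_lt(abs(ground_elevation_at(tilt, 5, 5) - 0.5), 1e-9)   # vertex
  flat <- point_cloud(c(0, 8, 0, 8), c(0, 0, 8, 8), rep(2, 4),
                      label = rep("ground", 4))
  expect_equal(ground_elevation_at(flat, c(1, 4, 7), c(1, 2, 3)), rep(2, 3))
  # nearest-neighbour fallback within 2 m of the hull, error beyond
  expect_equal(ground_elevation_at(flat, 9.5, 4), 2)
  expect_error(ground_elevation_at(flat, 15, 4), "coverage")
})
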