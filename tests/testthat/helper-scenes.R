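# Shared fixtures: small synthetic scenes built in code.

# Attach the generator's ground-truth labels as classification labels
# (used where a test targets the projection frameworks, not the classifier).
label_from_truth <- function(cloud) {
  tr <- attr(cloud, "truth")
  cloud$label <- ifelse(tr$label == "ground", "ground", "non_ground")
  cloud
}

# A small flat forest plot.
flat_forest <- function(seed = 11, extent = 30, n_trees = 12) {
  make_scene(scene_spec(extent = extent, terrain = "flat", n_trees = n_trees,
                        ground_spacing = 0.4, seed = seed))
}

# A tiny cloud (<= 1000 points) for brute-force oracle runs: coarse tilted
# ground plus uniform "vegetation" points.
oracle_scene <- function(seed, tilt = 0.05) {
  set.seed(seed)
  gs <- seq(-12, 12, by = 1.6)
  gx <- rep(gs, times = length(gs)) + stats::runif(length(gs)^2, -0.5, 0.5)
  gy <- rep(gs, each = length(gs)) + stats::runif(length(gs)^2, -0.5, 0.5)
  gz <- tilt * gx
  n <- 500
  vx <- stats::runif(n, -12, 12); vy <- stats::runif(n, -12, 12)
  vz <- tilt * vx + stats::runif(n, 0, 2.5)
  point_cloud(c(gx, vx), c(gy, vy), c(gz, vz),
              label = c(rep("ground", length(gx)), rep("non_ground", n)))
}
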