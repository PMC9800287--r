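test_that("target placement follows the polar convention and wraps at 360", {
  obs <- observer(0, 0, 0)
  tg <- target_position(obs, 90, 10)
  expect_equal(c(tg$base_x, tg$base_y), c(0, 10), tolerance = 1e-12)
  expect_equal(tg$z_base, 0)
  t0 <- target_position(obs, 0, 40)
  t360 <- target_position(obs, 360, 40)
  expect_equal(c(t360$base_x, t360$base_y), c(t0$base_x, t0$base_y),
               tolerance = 1e-9)
  expect_error(target_position(obs, 10, 0), "positive")
})

test_that("target base elevation comes from the ground surface", {
  tiltY <- point_cloud(c(-20, 20, -20, 20), c(-20, -20, 20, 20),
                       0.1 * c(-20, -20, 20, 20), label = rep("ground", 4))
  tg <- target_position(observer(0, 0, 0), 90, 10, ground = tiltY)
  expect_equal(tg$z_base, 1.0, tolerance = 1e-6)
})

test_that("elevation angle matches its closed form", {
  obs <- observer(0, 0, 0)
  mk <- function(zb, i) structure(list(theta = 0, i = i, w = 1, h = 1,
                                       base_x = i, base_y = 0, z_base = zb),
                                  class = "target_rectangle")
  expect_equal(elevation_angle(obs, mk(0, 5)), 0)
  expect_equal(elevation_angle(obs, mk(1, 1)), 45)
  expect_equal(elevation_angle(obs, mk(-1, 2)), -26.565, tolerance = 1e-3)
})

test_that("the normalized slab is the axis-aligned sight corridor", {
  obs <- observer(0, 0, 0)
  tg <- target_position(obs, 0, 10, w = 2, h = 2)
  slab <- build_slab(obs, tg, normalized = TRUE)
  expect_equal(c(slab$x1, slab$x2), c(0, 10), tolerance = 1e-5)
  expect_equal(c(slab$y1, slab$y2), c(-1, 1), tolerance = 1e-5)
  expect_equal(slab$omega, 0)
})

test_that("the tilted slab bounds points between the two 45-degree planes", {
  obs <- observer(0, 0, 0)
  # z_base = i makes tan(Omega) = 1; at s = 1 the band is [1, 3] for h = 2
  tg <- structure(list(theta = 0, i = 5, w = 2, h = 2,
                       base_x = 5, base_y = 0, z_base = 5),
                  class = "target_rectangle")
  slab <- build_slab(obs, tg, normalized = FALSE)
  pts <- point_cloud(c(1, 1, 1), c(0, 0, 0), c(0.9, 2, 3.1))
  expect_equal(select_candidates(pts, slab, obs), 2L)
})

test_that("candidate selection excludes the observer side and the target plane", {
  obs <- observer(0, 0, 0)
  tg <- target_position(obs, 0, 10, w = 2, h = 2)
  slab <- build_slab(obs, tg, normalized = TRUE)
  pts <- point_cloud(c(-1, 0, 5, 10, 11), rep(0, 5), rep(1, 5))
  expect_equal(select_candidates(pts, slab, obs), 3L)  # strict 0 < s < i
  empty <- point_cloud(0, 0, 50)                        # outside the band
  expect_length(select_candidates(empty, slab, obs), 0)
})

test_that("vectorized candidate selection equals the per-point brute force", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    n <- 1000
    pts <- point_cloud(runif(n, -15, 15), runif(n, -15, 15), runif(n, -2, 6))
    obs <- observer(runif(1, -2, 2), runif(1, -2, 2), 0)
    for (case in list(list(th = 37, i = 9, norm = TRUE, zb = 0),
                      list(th = 190, i = 12, norm = FALSE, zb = 1.3))) {
      tg <- structure(list(theta = case$th, i = case$i, w = 1.5, h = 2,
                           base_x = obs$x0 + case$i * cos(case$th * pi / 180),
                           base_y = obs$y0 + case$i * sin(case$th * pi / 180),
                           z_base = case$zb),
                      class = "target_rectangle")
      slab <- build_slab(obs, tg, normalized = case$norm)
      fast <- select_candidates(pts, slab, obs)
      slow <- which(vapply(seq_len(n), function(k)
        brute_in_slab(pts$x[k], pts$y[k], pts$z[k], obs, case$th, case$i,
                      1.5, 2, case$zb, case$norm), logical(1)))
      expect_identical(fast, slow)
    }
  }
})

test_that("projection reproduces the worked axis-aligned and tilted cases", {
  obs <- observer(0, 0, 0)
  tg <- target_position(obs, 0, 10, w = 2, h = 2)
  prj <- project_points(point_cloud(3, 0.2, 1.4), obs, tg, normalized = TRUE)
  expect_equal(prj$u, 0.2)
  expect_equal(prj$v, 1.4)

  # tan(Omega) = 1, point 2 m before the target plane at z = 1, base at 2:
  # v = 1 + tan(45 deg) * 2 - 2 = 1
  tg2 <- structure(list(theta = 0, i = 2, w = 2, h = 2,
                        base_x = 2, base_y = 0, z_base = 2),
                   class = "target_rectangle")
  prj2 <- project_points(point_cloud(0, 0, 1), obs, tg2, normalized = FALSE)
  expect_equal(prj2$v, 1.0, tolerance = 1e-12)

  # on the sight line at the target plane: u = 0, v = z - z_base
  prj3 <- project_points(point_cloud(2, 0, 2.7), obs, tg2, normalized = FALSE)
  expect_equal(prj3$u, 0)
  expect_equal(prj3$v, 0.7, tolerance = 1e-12)
})

test_that("projection agrees with an independent 3D construction to 1e-9", {
  set.seed(8)
  n <- 1000
  pts <- point_cloud(runif(n, -20, 20), runif(n, -20, 20), runif(n, -3, 8))
  obs <- observer(0.7, -0.3, 0.4)
  for (case in list(list(th = 62, i = 11, norm = TRUE, zb = 0),
                    list(th = 285, i = 7, norm = FALSE, zb = -0.9))) {
    tg <- structure(list(theta = case$th, i = case$i, w = 1.5, h = 2,
                         base_x = obs$x0 + case$i * cos(case$th * pi / 180),
                         base_y = obs$y0 + case$i * sin(case$th * pi / 180),
                         z_base = case$zb),
                    class = "target_rectangle")
    # projection is defined for points between observer and target plane
    a <- case$th * pi / 180
    s <- (pts$x - obs$x0) * cos(a) + (pts$y - obs$y0) * sin(a)
    dom <- which(s > 0 & s < case$i)
    prj <- project_points(pts, obs, tg, normalized = case$norm,
                          candidates = dom)
    ref <- t(vapply(dom, function(k)
      brute_project(pts$x[k], pts$y[k], pts$z[k], obs, case$th, case$i,
                    case$zb, case$norm), c(u = 0, v = 0)))
    expect_lt(max(abs(prj$u - ref[, "u"])), 1e-9)
    expect_lt(max(abs(prj$v - ref[, "v"])), 1e-9)
  }
})

test_that("projected coordinates are invariant under rotation about the vertical", {
  set.seed(9)
  n <- 300
  x <- runif(n, -10, 10); y <- runif(n, -10, 10); z <- runif(n, 0, 3)
  obs <- observer(1, 2, 0)
  theta <- 25; i <- 8
  tg <- target_position(obs, theta, i, w = 2, h = 3)
  base <- project_points(point_cloud(x, y, z), obs, tg, normalized = TRUE)
  for (phi in c(30, 117, 301)) {
    a <- phi * pi / 180
    rot <- function(px, py) cbind(px * cos(a) - py * sin(a),
                                  px * sin(a) + py * cos(a))
    rp <- rot(x, y); ro <- rot(obs$x0, obs$y0)
    obs2 <- observer(ro[1], ro[2], 0)
    tg2 <- target_position(obs2, theta + phi, i, w = 2, h = 3)
    prj <- project_points(point_cloud(rp[, 1], rp[, 2], z), obs2, tg2,
                          normalized = TRUE)
    expect_lt(max(abs(prj$u - base$u)), 1e-9)
    expect_lt(max(abs(prj$v - base$v)), 1e-9)
  }
})

test_that("normalized candidate sets are nested in distance with stable (u, v)", {
  set.seed(10)
  pts <- point_cloud(runif(400, -1, 21), runif(400, -2, 2), runif(400, 0, 2))
  obs <- observer(0, 0, 0)
  prev <- integer(0)
  for (i in c(5, 10, 15, 20)) {
    tg <- target_position(obs, 0, i, w = 2, h = 2)
    cand <- select_candidates(pts, build_slab(obs, tg, TRUE), obs)
    expect_true(all(prev %in% cand))
    prev <- cand
  }
  # (u, v) of a fixed point does not depend on the target distance
  p5 <- project_points(pts, obs, target_position(obs, 0, 5, 2, 2), TRUE)
  p20 <- project_points(pts, obs, target_position(obs, 0, 20, 2, 2), TRUE)
  expect_identical(p5$u, p20$u)
  expect_identical(p5$v, p20$v)
})

test_that("level terrain reduces the tilted framework to the normalized one", {
  set.seed(12)
  z0 <- 3.2                               # constant terrain elevation
  pts <- point_cloud(runif(300, 0, 15), runif(300, -2, 2),
                     z0 + runif(300, 0, 2))
  obs <- observer(0, 0, z0)
  tg <- structure(list(theta = 0, i = 12, w = 2, h = 2,
                       base_x = 12, base_y = 0, z_base = z0),
                  class = "target_rectangle")
  expect_equal(elevation_angle(obs, tg), 0)
  nn <- project_points(pts, obs, tg, normalized = FALSE)
  shifted <- point_cloud(pts$x, pts$y, pts$z - z0)
  nz <- project_points(shifted, obs, tg, normalized = TRUE)
  expect_equal(nn$v, nz$v, tolerance = 1e-12)
  expect_identical(nn$u, nz$u)
})
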