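# Independent brute-force oracles for the projection geometry and the
# visibility index. These deliberately re-derive everything from first
# principles (rotation matrices, explicit perpendicular feet, linear scans
# over pixel intervals) rather than reusing the package's vectorized
# arithmetic.

# World position of a sight-frame coordinate (s along sight, u left of sight).
sight_to_world <- function(obs, theta, s, u) {
  a <- theta * pi / 180
  c(obs$x0 + s * cos(a) - u * sin(a),
    obs$y0 + s * sin(a) + u * cos(a))
}

# Brute-force candidate test for a single point, following the slab
# definition: corridor AABB (+-1e-6), inclusive vertical band, 0 < s < i.
brute_in_slab <- function(px, py, pz, obs, theta, i, w, h, z_base, normalized) {
  corners <- rbind(sight_to_world(obs, theta, 0, w / 2),
                   sight_to_world(obs, theta, 0, -w / 2),
                   sight_to_world(obs, theta, i, w / 2),
                   sight_to_world(obs, theta, i, -w / 2))
  if (px < min(corners[, 1]) - 1e-6 || px > max(corners[, 1]) + 1e-6 ||
      py < min(corners[, 2]) - 1e-6 || py > max(corners[, 2]) + 1e-6)
    return(FALSE)
  a <- theta * pi / 180
  s <- (px - obs$x0) * cos(a) + (py - obs$y0) * sin(a)
  if (!(s > 0 && s < i)) return(FALSE)
  if (normalized) return(pz >= 0 && pz <= h)
  omega <- atan2(z_base - obs$z0, i)
  zl <- obs$z0 + tan(omega) * s
  pz >= zl && pz <= zl + h
}

# Brute-force projection of one point: drop the perpendicular from the point
# onto the target base line, take the signed offset along the line as u, and
# apply the elevation-angle height correction for the terrain-preserving case.
brute_project <- function(px, py, pz, obs, theta, i, z_base, normalized) {
  a <- theta * pi / 180
  bx <- obs$x0 + i * cos(a); by <- obs$y0 + i * sin(a)
  lv <- c(-sin(a), cos(a))                 # base-line direction (left of sight)
  u <- (px - bx) * lv[1] + (py - by) * lv[2]
  if (normalized) {
    v <- pz
  } else {
    omega <- atan2(z_base - obs$z0, i)
    foot <- c(bx + u * lv[1], by + u * lv[2])
    d <- sqrt((px - foot[1])^2 + (py - foot[2])^2)  # horizontal point-line distance
    v <- pz + tan(omega) * d - z_base
  }
  c(u = u, v = v)
}

# Naive per-point visibility: each projected point is assigned to a pixel by
# scanning the half-open column/band intervals.
brute_visibility <- function(cloud, obs, theta, i, w, h, res, z_base, normalized) {
  wp <- ncol(sightshed::rasterize(data.frame(u = numeric(), v = numeric()), w, h, res))
  hp <- nrow(sightshed::rasterize(data.frame(u = numeric(), v = numeric()), w, h, res))
  occupied <- matrix(FALSE, hp, wp)
  for (k in seq_along(cloud$x)) {
    if (!brute_in_slab(cloud$x[k], cloud$y[k], cloud$z[k],
                       obs, theta, i, w, h, z_base, normalized)) next
    uv <- brute_project(cloud$x[k], cloud$y[k], cloud$z[k],
                        obs, theta, i, z_base, normalized)
    if (abs(uv["u"]) > w / 2 || uv["v"] < 0 || uv["v"] >= h) next
    col <- NA
    for (c0 in seq_len(wp)) {
      lo <- -w / 2 + (c0 - 1) * res
      if (uv["u"] >= lo && uv["u"] < lo + res) { col <- c0; break }
    }
    band <- NA
    for (b0 in seq_len(hp)) {
      if (uv["v"] >= (b0 - 1) * res && uv["v"] < b0 * res) { band <- b0; break }
    }
    if (!is.na(col) && !is.na(band)) occupied[hp - band + 1, col] <- TRUE
  }
  (length(occupied) - sum(occupied)) / length(occupied) * 100
}

# Package pipeline, operation by operation, for one sample.
op_path_visibility <- function(cloud, obs, theta, i, w, h, res, normalized,
                               ground = NULL) {
  tg <- target_position(obs, theta, i, w = w, h = h, ground = ground)
  slab <- build_slab(obs, tg, normalized = normalized)
  cand <- select_candidates(cloud, slab, obs)
  prj <- project_points(cloud, obs, tg, normalized = normalized,
                        candidates = cand)
  visibility(rasterize(prj, w, h, res, theta = theta, i = i))$visibility
}
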