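# Brute-force oracles and small fixture builders shared across the suite.
# The oracles deliberately re-state the definitions with plain loops so they
# stay independent of the package's k-d tree / vectorized implementations.

# Plain re-statement of the hole footprint, independent of the generator.
inside_hole_oracle <- function(spec, x, y) {
  ctr <- hole_centers(spec)
  out <- logical(length(x))
  for (i in seq_len(nrow(ctr)))
    out <- out | (abs(x - ctr$x[i]) < spec$hole_size / 2 &
                    abs(y - ctr$y[i]) < spec$hole_size / 2)
  out
}

# Per-pixel rasterization rule: pixel = 1 iff no 2D point within `res` of
# its center (plain double loop over pixels and points).
bf_rasterize <- function(coords2d, origin2d, ny, nx, res) {
  grid <- matrix(NA, ny, nx)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      cx <- origin2d[1] + (ix - 1) * res
      cy <- origin2d[2] + (iy - 1) * res
      d2 <- (coords2d[, 1] - cx)^2 + (coords2d[, 2] - cy)^2
      grid[iy, ix] <- min(d2) > res^2
    }
  }
  grid
}

# Coordinate-wise median of a component's pixel centers.
bf_component_median <- function(px, raster) {
  xs <- raster$origin2d[1] + (px[, "ix"] - 1) * raster$resolution
  ys <- raster$origin2d[2] + (px[, "iy"] - 1) * raster$resolution
  c(median(xs), median(ys))
}

# Overlap criterion and Euclidean nearest neighbor, all-pairs double loop.
bf_overlap <- function(p1, n1, p2, rho) {
  n <- nrow(p1)
  mask <- logical(n)
  nn_dist <- numeric(n)
  min_orth <- numeric(n)
  for (i in seq_len(n)) {
    d <- sweep(p2, 2, p1[i, ])
    cr <- cbind(n1[i, 2] * d[, 3] - n1[i, 3] * d[, 2],
                n1[i, 3] * d[, 1] - n1[i, 1] * d[, 3],
                n1[i, 1] * d[, 2] - n1[i, 2] * d[, 1])
    orth <- sqrt(rowSums(cr^2))
    mask[i] <- any(orth < rho)
    nn_dist[i] <- sqrt(min(rowSums(d^2)))
    min_orth[i] <- min(orth)
  }
  list(mask = mask, nn_dist = nn_dist, min_orth = min_orth)
}

# Greedy nominal-center assignment used as the sorting oracle: each nominal
# hole center claims its nearest detected median.
bf_assign_to_nominal <- function(medians2d, spec) {
  ctr <- hole_centers(spec)
  out <- matrix(NA_real_, nrow(ctr), 2)
  for (i in seq_len(nrow(ctr))) {
    d2 <- (medians2d[, 1] - ctr$x[i])^2 + (medians2d[, 2] - ctr$y[i])^2
    out[i, ] <- medians2d[which.min(d2), ]
  }
  out
}

# Capture of the default board, posed at ~1 m.
board_capture <- function(spec = board_spec(), pose = NULL, pitch = 2,
                          noise_sd = 0, dropout = 0, seed = 1L) {
  if (is.null(pose)) pose <- rigid_transform(diag(3), c(0, 0, 1000))
  generate_board_cloud(spec, capture_scenario(pose = pose,
                                              sampling_pitch = pitch,
                                              noise_sd = noise_sd,
                                              dropout = dropout, seed = seed))
}

# Distance of each board-frame median to its nearest nominal hole center,
# requiring the matching to be one-to-one (detected labels may be related
# to the board's by a pattern symmetry, so sets are compared, not indices).
match_to_nominal <- function(medians3d, pose, spec) {
  local_med <- apply_transform(medians3d, rt_inverse(pose))
  nominal <- hole_centers(spec)
  d2 <- outer(seq_len(nrow(local_med)), seq_len(nrow(nominal)),
              Vectorize(function(i, j)
                (local_med[i, 1] - nominal$x[j])^2 +
                  (local_med[i, 2] - nominal$y[j])^2 + local_med[i, 3]^2))
  j <- apply(d2, 1, which.min)
  stopifnot(!anyDuplicated(j))
  list(dist = sqrt(d2[cbind(seq_along(j), j)]), index = j)
}

rot_err_deg <- function(T_est, T_true) {
  rt_angle(rt_compose(rt_inverse(T_est), T_true)) * 180 / pi
}

trans_err_mm <- function(T_est, T_true) {
  sqrt(sum((T_est$translation - T_true$translation)^2))
}
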