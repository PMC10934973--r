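#' Simulated capture conditions for the synthetic depth camera
#'
#' Describes one simulated capture: the board pose in camera coordinates, the
#' lattice spacing of the simulated samples, Gaussian depth noise along the
#' camera ray, and random point dropout. The emulated sensor errors bracket
#' the depth cameras this board targets (sub-millimetre for industrial
#' structured light, up to ~3 mm at 1 m for consumer sensors).
#'
#' @param pose `rigid_transform` placing the board (local frame) in camera
#'   coordinates; should put the board in front of the camera (z > 0).
#' @param sampling_pitch lattice spacing, mm (> 0).
#' @param noise_sd Gaussian depth-noise standard deviation, mm (>= 0);
#'   applied along the local +z axis before posing.
#' @param dropout probability in `[0, 1)` that a sample is dropped.
#' @param seed integer RNG seed; captures are deterministic given the seed.
#' @return An object of class `capture_scenario`.
#' @export
capture_scenario <- function(pose = rt_identity(), sampling_pitch = 2,
                             noise_sd = 0, dropout = 0, seed = 1L) {
  if (!inherits(pose, "rigid_transform"))
    abort_parameter("pose must be a rigid_transform")
  if (!is_scalar_number(sampling_pitch) || sampling_pitch <= 0)
    abort_parameter("sampling_pitch must be > 0")
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    abort_parameter("noise_sd must be >= 0")
  if (!is_scalar_number(dropout) || dropout < 0 || dropout >= 1)
    abort_parameter("dropout must be in [0, 1)")
  structure(list(pose = pose, sampling_pitch = sampling_pitch,
                 noise_sd = noise_sd, dropout = dropout,
                 seed = as.integer(seed)),
            class = "capture_scenario")
}

# Lattice coordinates 0, pitch, 2*pitch, ... over [-extent/2, extent/2]
lattice_axis <- function(extent, pitch) {
  -extent / 2 + pitch * (0:floor(extent / pitch))
}

#' Generate a synthetic depth capture of the calibration board
#'
#' Samples the board's front plane on a regular lattice (excluding points
#' strictly inside hole footprints), optionally adds the solid back plane
#' across the full board footprint, applies dropout and Gaussian depth noise
#' in the board's local frame, then poses the result in camera coordinates.
#' The per-point plane of origin is recorded in `meta$plane`
#' (`"front"`/`"back"`).
#'
#' @param spec a `board_spec`.
#' @param scenario a `capture_scenario`.
#' @return A `point_cloud` in camera coordinates (mm).
#' @examples
#' cl <- generate_board_cloud(board_spec(),
#'                            capture_scenario(sampling_pitch = 5))
#' @export
generate_board_cloud <- function(spec, scenario) {
  stopifnot(inherits(spec, "board_spec"))
  if (!inherits(scenario, "capture_scenario"))
    abort_parameter("scenario must be a capture_scenario")
  xs <- lattice_axis(spec$width, scenario$sampling_pitch)
  ys <- lattice_axis(spec$height, scenario$sampling_pitch)
  g <- expand.grid(x = xs, y = ys)
  keep <- !inside_hole(spec, g$x, g$y)
  front <- cbind(g$x[keep], g$y[keep], 0)
  pts <- front
  plane <- rep("front", nrow(front))
  if (spec$back_plane_present) {
    back <- cbind(g$x, g$y, spec$back_offset)
    pts <- rbind(pts, back)
    plane <- c(plane, rep("back", nrow(back)))
  }
  with_seed(scenario$seed, {
    if (scenario$dropout > 0) {
      kept <- runif(nrow(pts)) >= scenario$dropout
      pts <- pts[kept, , drop = FALSE]
      plane <- plane[kept]
    }
    if (scenario$noise_sd > 0)
      pts[, 3] <- pts[, 3] + rnorm(nrow(pts), 0, scenario$noise_sd)
  })
  point_cloud(transform_points(pts, scenario$pose),
              label = "synthetic board capture",
              meta = list(plane = plane))
}

#' Generate a pair of board captures with ground truth
#'
#' Simulates two cameras capturing the same physical board. The returned
#' ground-truth transform maps camera-2 coordinates into camera-1
#' coordinates: `pose1 o pose2^-1`.
#'
#' @param spec a `board_spec`.
#' @param scenario1,scenario2 `capture_scenario` for each camera.
#' @return list with `cloud1`, `cloud2` (`point_cloud`) and `transform`
#'   (`rigid_transform`, camera 2 -> camera 1).
#' @export
generate_capture_pair <- function(spec, scenario1, scenario2) {
  list(cloud1 = generate_board_cloud(spec, scenario1),
       cloud2 = generate_board_cloud(spec, scenario2),
       transform = rt_compose(scenario1$pose, rt_inverse(scenario2$pose)))
}

#' Generate a smooth synthetic test surface
#'
#' Lattice-sampled parametric surface used to exercise the overlap metric and
#' ICP on curved geometry (a stand-in at desk scale for scanned anatomical
#' surfaces). `"plane"` is a square planar patch at local z = 0;
#' `"cylinder-patch"` is a patch of a cylinder of radius `radius` whose axis
#' is parallel to local y at `(0, ., radius)`, tangent to z = 0, sampled
#' uniformly in arc length.
#'
#' @param kind `"plane"` or `"cylinder-patch"`.
#' @param extent patch side length (plane) / arc and axial extent
#'   (cylinder), mm.
#' @param pitch lattice spacing, mm.
#' @param pose `rigid_transform` posing the surface in camera coordinates.
#' @param noise_sd Gaussian depth noise along local +z, mm.
#' @param seed integer RNG seed.
#' @param radius cylinder radius, mm (cylinder-patch only).
#' @return A `point_cloud`.
#' @export
generate_surface_cloud <- function(kind = c("plane", "cylinder-patch"),
                                   extent = 200, pitch = 4,
                                   pose = rt_identity(), noise_sd = 0,
                                   seed = 1L, radius = 150) {
  kind <- match.arg(kind)
  if (!is_scalar_number(extent) || extent <= 0 ||
      !is_scalar_number(pitch) || pitch <= 0)
    abort_parameter("extent and pitch must be > 0")
  u <- lattice_axis(extent, pitch)
  v <- lattice_axis(extent, pitch)
  g <- expand.grid(u = u, v = v)
  pts <- switch(kind,
    "plane" = cbind(g$u, g$v, 0),
    "cylinder-patch" = {
      if (!is_scalar_number(radius) || radius <= 0)
        abort_parameter("radius must be > 0")
      th <- g$u / radius
      cbind(radius * sin(th), g$v, radius * (1 - cos(th)))
    })
  with_seed(seed, {
    if (noise_sd > 0) pts[, 3] <- pts[, 3] + rnorm(nrow(pts), 0, noise_sd)
  })
  point_cloud(transform_points(pts, pose),
              label = sprintf("synthetic %s surface", kind))
}

#' Random moderate camera pose for a board capture
#'
#' Draws a pose of the kind a desk/clinic rig produces: an in-plane rotation
#' about the viewing axis, a small out-of-plane tilt, a lateral shift, and a
#' stand-off distance along +z. With the default bounds, any two such poses
#' differ by a relative rotation below 90 degrees, which is the working
#' assumption under which the board's 180-degree pattern symmetry can be
#' resolved (see [resolve_symmetry()]).
#'
#' @param seed integer RNG seed.
#' @param distance stand-off distance along +z, mm.
#' @param max_inplane_deg bound on the in-plane rotation magnitude, degrees.
#' @param max_tilt_deg bound on the out-of-plane tilt magnitude, degrees.
#' @param max_shift bound on |x| and |y| translation, mm.
#' @return A `rigid_transform` posing the board in camera coordinates.
#' @export
random_capture_pose <- function(seed, distance = 1000, max_inplane_deg = 30,
                                max_tilt_deg = 10, max_shift = 50) {
  with_seed(seed, {
    phi <- runif(1, -max_inplane_deg, max_inplane_deg) * pi / 180
    psi <- runif(1, 0, max_tilt_deg) * pi / 180
    tilt_dir <- runif(1, 0, 2 * pi)
    shift <- runif(2, -max_shift, max_shift)
    R <- rotation_axis_angle(c(cos(tilt_dir), sin(tilt_dir), 0), psi) %*%
      rotation_axis_angle(c(0, 0, 1), phi)
    rigid_transform(R, c(shift, distance))
  })
}
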