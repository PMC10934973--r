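# Board detection: from one depth capture of the hole-pattern target to the
# hole-median 3D landmarks in canonical (row, col) order. Pipeline stages:
# crop -> RANSAC plane fit -> PCA projection -> rasterization -> connected
# components -> per-hole medians -> grid sorting -> back-projection to 3D.

#' Detection parameters
#'
#' @param dist_estimate rough board-to-camera distance along z, mm; `NULL`
#'   uses the median z of the input cloud.
#' @param eps half-width of the kept depth slab, mm; `NULL` uses half the
#'   board's back-plane offset, so the solid back plane falls outside the
#'   slab.
#' @param plane_threshold RANSAC plane inlier distance, mm.
#' @param raster_resolution raster pixel size, mm (default 3).
#' @param min_component_px minimum hole component size in pixels; `NULL`
#'   uses `(floor(hole_size / (2 * raster_resolution)))^2` for the board in
#'   use (9 at the defaults), which rejects speckle while keeping partially
#'   seen holes.
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @param ransac_iterations number of RANSAC hypotheses.
#' @param seed integer seed making the RANSAC stage deterministic.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(dist_estimate = NULL, eps = NULL,
                             plane_threshold = 2, raster_resolution = 3,
                             min_component_px = NULL, connectivity = 8,
                             ransac_iterations = 1000, seed = 1L) {
  if (!is.null(dist_estimate) &&
      (!is_scalar_number(dist_estimate) || dist_estimate <= 0))
    abort_parameter("dist_estimate must be a positive number or NULL")
  if (!is.null(eps) && (!is_scalar_number(eps) || eps <= 0))
    abort_parameter("eps must be a positive number or NULL")
  if (!is_scalar_number(plane_threshold) || plane_threshold <= 0)
    abort_parameter("plane_threshold must be > 0")
  if (!is_scalar_number(raster_resolution) || raster_resolution <= 0)
    abort_parameter("raster_resolution must be > 0")
  if (!is.null(min_component_px) &&
      (!is_scalar_number(min_component_px) || min_component_px < 1))
    abort_parameter("min_component_px must be >= 1 or NULL")
  if (!connectivity %in% c(4, 8))
    abort_parameter("connectivity must be 4 or 8")
  if (!is_scalar_number(ransac_iterations) || ransac_iterations < 1)
    abort_parameter("ransac_iterations must be >= 1")
  structure(list(dist_estimate = dist_estimate, eps = eps,
                 plane_threshold = plane_threshold,
                 raster_resolution = raster_resolution,
                 min_component_px = min_component_px,
                 connectivity = as.integer(connectivity),
                 ransac_iterations = as.integer(ransac_iterations),
                 seed = as.integer(seed)),
            class = "detection_config")
}

#' Crop the background by a depth slab
#'
#' Keeps exactly the points whose z coordinate satisfies
#' `|z - dist_estimate| <= eps`.
#'
#' @param cloud a `point_cloud` in camera coordinates.
#' @param dist_estimate rough board distance, mm.
#' @param eps slab half-width, mm.
#' @return The cropped `point_cloud`.
#' @export
crop_background <- function(cloud, dist_estimate, eps) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is_scalar_number(eps) || eps <= 0)
    abort_parameter("eps must be > 0")
  keep <- abs(cloud$points[, 3] - dist_estimate) <= eps
  if (!any(keep))
    abort_detection("no points in depth slab", stage = "crop_background")
  subset_cloud(cloud, keep)
}

#' Fit the board plane with RANSAC
#'
#' Random-sample-consensus plane fit: repeatedly fits a plane to three random
#' points, counts points within `threshold`, then refits the best model by
#' least squares on its inliers (centroid + smallest principal axis) and
#' recomputes the inlier set. Deterministic given `seed`.
#'
#' @param cloud a `point_cloud` (>= 3 non-collinear points).
#' @param threshold inlier distance, mm.
#' @param seed integer RNG seed.
#' @param iterations number of hypotheses.
#' @return list with `model` (class `plane_model`: unit `normal`, `offset`
#'   with the plane `n . p = offset`, `inlier_indices`, `threshold`) and
#'   `inliers` (the inlier-only `point_cloud`).
#' @export
fit_board_plane <- function(cloud, threshold = 2, seed = 1L,
                            iterations = 1000L) {
  stopifnot(inherits(cloud, "point_cloud"))
  P <- cloud$points
  n <- nrow(P)
  if (n < 3L)
    abort_detection("need at least 3 points to fit a plane",
                    stage = "fit_board_plane")
  best_count <- 0L
  best_normal <- NULL
  best_offset <- NULL
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      s <- sample.int(n, 3L)
      v1 <- P[s[2], ] - P[s[1], ]
      v2 <- P[s[3], ] - P[s[1], ]
      nv <- cross3(v1, v2)
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-12) next
      nv <- nv / nn
      d0 <- sum(nv * P[s[1], ])
      cnt <- sum(abs(P %*% nv - d0) <= threshold)
      if (cnt > best_count) {
        best_count <- cnt
        best_normal <- nv
        best_offset <- d0
      }
    }
  })
  if (is.null(best_normal) || best_count < 3L)
    abort_detection("degenerate input: no plane hypothesis found (collinear points?)",
                    stage = "fit_board_plane")
  # least-squares refit on the consensus set, then final inlier set
  inl <- which(abs(P %*% best_normal - best_offset) <= threshold)
  Q <- P[inl, , drop = FALSE]
  mu <- colMeans(Q)
  e <- eigen(crossprod(sweep(Q, 2, mu)), symmetric = TRUE)
  if (e$values[2] <= 1e-10 * max(e$values[1], .Machine$double.eps))
    abort_detection("degenerate input: inliers are collinear",
                    stage = "fit_board_plane")
  normal <- e$vectors[, 3]
  # orient the normal toward the camera (sensor at the origin)
  if (sum(normal * mu) > 0) normal <- -normal
  offset <- sum(normal * mu)
  inl <- which(abs(P %*% normal - offset) <= threshold)
  model <- structure(list(normal = normal, offset = offset,
                          inlier_indices = inl, threshold = threshold),
                     class = "plane_model")
  list(model = model, inliers = subset_cloud(cloud, inl))
}

#' Project plane inliers into 2D board coordinates
#'
#' PCA of the inlier points: the first in-plane axis carries the larger
#' board dimension, the second completes a right-handed frame with the plane
#' normal. Signs are pinned for reproducibility: the normal points toward
#' the camera (`n . centroid < 0`), and the first axis has a non-negative
#' dot product with the camera x axis (falling back to y, then z, on ties).
#' The residual 180-degree labeling ambiguity is resolved later, during
#' registration.
#'
#' @param inliers a `point_cloud` of plane inliers (must span 2 dimensions).
#' @return An object of class `planar_projection`: `coords2d` (N x 2, mm),
#'   `basis` (3 x 2 orthonormal in-plane axes), `origin` (inlier centroid),
#'   `normal`, `offset`.
#' @export
project_to_plane_2d <- function(inliers) {
  stopifnot(inherits(inliers, "point_cloud"))
  P <- inliers$points
  if (nrow(P) < 3L)
    abort_detection("need at least 3 points to project",
                    stage = "project_to_plane_2d")
  mu <- colMeans(P)
  e <- eigen(crossprod(sweep(P, 2, mu)), symmetric = TRUE)
  if (e$values[2] <= 1e-10 * max(e$values[1], .Machine$double.eps))
    abort_detection("rank-deficient spread: points do not span a plane",
                    stage = "project_to_plane_2d")
  axis1 <- e$vectors[, 1]
  normal <- e$vectors[, 3]
  if (sum(normal * mu) > 0) normal <- -normal
  s <- axis1[1]
  if (abs(s) < 1e-9) s <- axis1[2]
  if (abs(s) < 1e-9) s <- axis1[3]
  if (s < 0) axis1 <- -axis1
  axis2 <- cross3(normal, axis1)
  basis <- cbind(axis1, axis2, deparse.level = 0)
  structure(list(coords2d = sweep(P, 2, mu) %*% basis, basis = basis,
                 origin = mu, normal = normal, offset = sum(normal * mu)),
            class = "planar_projection")
}

#' Rasterize the 2D projection into a binary hole image
#'
#' The grid spans the 2D bounding box of the projection with pixel size
#' `resolution`; pixel `[0, 0]` is centered at the bounding-box minimum. A
#' pixel is labeled 1 (hole) iff no projected point lies within `resolution`
#' (2D Euclidean) of its center, 0 (board) otherwise.
#'
#' @param proj a `planar_projection`.
#' @param resolution pixel size, mm.
#' @return An object of class `hole_raster`: `grid` (logical n_y x n_x
#'   matrix, `TRUE` = hole; rows index y, columns x), `resolution`,
#'   `origin2d` (center of pixel `[0, 0]`).
#' @export
rasterize_holes <- function(proj, resolution = 3) {
  stopifnot(inherits(proj, "planar_projection"))
  if (!is_scalar_number(resolution) || resolution <= 0)
    abort_parameter("resolution must be > 0")
  xy <- proj$coords2d
  x0 <- min(xy[, 1]); y0 <- min(xy[, 2])
  nx <- floor((max(xy[, 1]) - x0) / resolution) + 1L
  ny <- floor((max(xy[, 2]) - y0) / resolution) + 1L
  centers <- cbind(x0 + rep(0:(nx - 1L), each = ny) * resolution,
                   y0 + rep(0:(ny - 1L), times = nx) * resolution)
  nn <- cpp_nn(xy, centers)
  grid <- matrix(nn$dist > resolution, nrow = ny, ncol = nx)
  structure(list(grid = grid, resolution = resolution,
                 origin2d = c(x0, y0)),
            class = "hole_raster")
}

# 2D coordinates of raster pixel centers for (iy, ix) index pairs (1-based)
raster_pixel_centers <- function(raster, iy, ix) {
  cbind(raster$origin2d[1] + (ix - 1L) * raster$resolution,
        raster$origin2d[2] + (iy - 1L) * raster$resolution)
}

#' Connected hole components of a binary raster
#'
#' Labels connected components of hole pixels, then discards components that
#' touch the raster border (the margin outside the physical board, not
#' holes) and components smaller than `min_component_px` (sensor speckle).
#'
#' @param raster a `hole_raster`.
#' @param min_component_px minimum component size in pixels.
#' @param connectivity 4 or 8.
#' @return list of components, each an integer matrix with columns
#'   `iy`, `ix` (1-based pixel indices). Zero components is a valid outcome.
#' @export
find_hole_components <- function(raster, min_component_px = 9,
                                 connectivity = 8) {
  stopifnot(inherits(raster, "hole_raster"))
  if (!connectivity %in% c(4, 8))
    abort_parameter("connectivity must be 4 or 8")
  g <- raster$grid
  ny <- nrow(g); nx <- ncol(g)
  lab <- label_components(g, connectivity)
  if (max(lab) == 0L) return(list())
  comps <- split(which(lab > 0L), lab[lab > 0L])
  keep <- lapply(comps, function(lin) {
    iy <- ((lin - 1L) %% ny) + 1L
    ix <- ((lin - 1L) %/% ny) + 1L
    if (any(iy == 1L | iy == ny | ix == 1L | ix == nx)) return(NULL)
    if (length(lin) < min_component_px) return(NULL)
    cbind(iy = iy, ix = ix)
  })
  unname(keep[!vapply(keep, is.null, logical(1))])
}

# Breadth-first connected-component labeling of a logical matrix.
label_components <- function(g, connectivity) {
  ny <- nrow(g); nx <- ncol(g)
  lab <- matrix(0L, ny, nx)
  if (connectivity == 4) {
    dy <- c(-1L, 1L, 0L, 0L)
    dx <- c(0L, 0L, -1L, 1L)
  } else {
    dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  }
  cur <- 0L
  todo <- which(g)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      lin <- stack[length(stack)]
      stack <- stack[-length(stack)]
      iy <- ((lin - 1L) %% ny) + 1L
      ix <- ((lin - 1L) %/% ny) + 1L
      for (k in seq_along(dy)) {
        jy <- iy + dy[k]; jx <- ix + dx[k]
        if (jy < 1L || jy > ny || jx < 1L || jx > nx) next
        jl <- (jx - 1L) * ny + jy
        if (g[jl] && lab[jl] == 0L) {
          lab[jl] <- cur
          stack <- c(stack, jl)
        }
      }
    }
  }
  lab
}

#' Per-component hole medians in 2D
#'
#' For each component, the coordinate-wise median of its pixel-center 2D
#' coordinates.
#'
#' @param components list of pixel-index matrices from
#'   [find_hole_components()].
#' @param raster the `hole_raster` the components were found in.
#' @return numeric M x 2 matrix of 2D medians, mm.
#' @export
compute_hole_medians <- function(components, raster) {
  if (length(components) == 0L)
    abort_detection("no hole components", stage = "compute_hole_medians")
  med <- t(vapply(components, function(px) {
    ctr <- raster_pixel_centers(raster, px[, "iy"], px[, "ix"])
    c(median(ctr[, 1]), median(ctr[, 2]))
  }, numeric(2)))
  dimnames(med) <- NULL
  med
}

#' Sort hole medians into the board's (row, col) grid
#'
#' Clusters the median y coordinates into rows (split at gaps larger than
#' half the nominal row pitch), sorts by x within each row, and assigns
#' canonical grid indices row-major. The 180-degree in-plane labeling
#' ambiguity of the checkerboard-parity pattern is not resolved here; see
#' [resolve_symmetry()].
#'
#' @param medians2d numeric M x 2 matrix of 2D hole medians.
#' @param spec the `board_spec` in use.
#' @return An object of class `hole_set` with `medians2d` in canonical
#'   row-major order and `grid_index` (M x 2 integer matrix of (row, col)).
#' @export
sort_hole_medians <- function(medians2d, spec) {
  stopifnot(inherits(spec, "board_spec"))
  medians2d <- as.matrix(medians2d)
  nominal <- hole_centers(spec)
  if (nrow(medians2d) != nrow(nominal))
    abort_detection(sprintf("found %d hole medians, expected %d",
                            nrow(medians2d), nrow(nominal)),
                    stage = "sort_hole_medians")
  row_pitch <- spec$height / spec$n_rows
  ord <- order(medians2d[, 2])
  ys <- medians2d[ord, 2]
  breaks <- which(diff(ys) > row_pitch / 2)
  row_id_sorted <- cumsum(c(1L, as.integer(seq_along(ys)[-1] %in% (breaks + 1L))))
  row_id <- integer(nrow(medians2d))
  row_id[ord] <- row_id_sorted
  n_found_rows <- max(row_id)
  if (n_found_rows != spec$n_rows)
    abort_detection(sprintf("clustered %d rows of medians, expected %d",
                            n_found_rows, spec$n_rows),
                    stage = "sort_hole_medians")
  counts_found <- tabulate(row_id, spec$n_rows)
  counts_expected <- tabulate(nominal$row, spec$n_rows)
  if (!all(counts_found == counts_expected))
    abort_detection("per-row hole counts do not match the board's parity pattern",
                    stage = "sort_hole_medians")
  out <- matrix(NA_real_, nrow(medians2d), 2L)
  grid_index <- matrix(NA_integer_, nrow(medians2d), 2L)
  pos <- 0L
  for (r in seq_len(spec$n_rows)) {
    in_row <- which(row_id == r)
    in_row <- in_row[order(medians2d[in_row, 1])]
    cols <- sort(nominal$col[nominal$row == r])
    for (j in seq_along(in_row)) {
      pos <- pos + 1L
      out[pos, ] <- medians2d[in_row[j], ]
      grid_index[pos, ] <- c(r, cols[j])
    }
  }
  structure(list(medians2d = out, grid_index = grid_index, spec = spec),
            class = "hole_set")
}

#' Back-project sorted hole medians into 3D
#'
#' `medians3d = origin + coords2d %*% t(basis)`; the medians lie exactly on
#' the fitted plane.
#'
#' @param holeset a `hole_set` with 2D medians.
#' @param proj the `planar_projection` the medians came from.
#' @return The `hole_set` with `medians3d` added.
#' @export
backproject_medians <- function(holeset, proj) {
  stopifnot(inherits(holeset, "hole_set"), inherits(proj, "planar_projection"))
  holeset$medians3d <- sweep(holeset$medians2d %*% t(proj$basis), 2,
                             proj$origin, "+")
  holeset
}

#' @export
print.hole_set <- function(x, ...) {
  cat(sprintf("<hole_set> %d hole medians (%s)\n", nrow(x$grid_index),
              if (is.null(x$medians3d)) "2D" else "3D"))
  invisible(x)
}

#' Detect the calibration board in one capture
#'
#' Runs the full per-camera detection pipeline: depth-slab crop, RANSAC
#' plane fit, PCA projection to 2D, rasterization, connected-component hole
#' detection, per-hole medians, grid sorting, and back-projection to 3D.
#' Per-stage diagnostics (point and component counts) are attached as the
#' `"diagnostics"` attribute of the result.
#'
#' @param cloud a `point_cloud` capture of the board.
#' @param spec the `board_spec`.
#' @param config a `detection_config`.
#' @return A `hole_set` with `medians3d` in canonical row-major order.
#' @examples
#' spec <- board_spec()
#' cl <- generate_board_cloud(spec, capture_scenario(
#'   pose = rigid_transform(diag(3), c(0, 0, 1000)), sampling_pitch = 2))
#' hs <- detect_board(cl, spec, detection_config())
#' @export
detect_board <- function(cloud, spec, config = detection_config()) {
  stopifnot(inherits(spec, "board_spec"),
            inherits(config, "detection_config"))
  if (!inherits(cloud, "point_cloud") || n_points(cloud) == 0L)
    abort_detection("input cloud is empty", stage = "input")
  dist_estimate <- config$dist_estimate %||% median(cloud$points[, 3])
  eps <- config$eps %||% (spec$back_offset / 2)
  min_px <- config$min_component_px %||%
    max(1, floor(spec$hole_size / (2 * config$raster_resolution))^2)
  diag_ <- list(n_input = n_points(cloud), dist_estimate = dist_estimate,
                eps = eps)
  cropped <- crop_background(cloud, dist_estimate, eps)
  diag_$n_cropped <- n_points(cropped)
  fit <- fit_board_plane(cropped, threshold = config$plane_threshold,
                         seed = config$seed,
                         iterations = config$ransac_iterations)
  diag_$n_plane_inliers <- n_points(fit$inliers)
  proj <- project_to_plane_2d(fit$inliers)
  raster <- rasterize_holes(proj, config$raster_resolution)
  diag_$raster_dim <- dim(raster$grid)
  comps <- find_hole_components(raster, min_component_px = min_px,
                                connectivity = config$connectivity)
  diag_$n_components <- length(comps)
  medians2d <- compute_hole_medians(comps, raster)
  holeset <- sort_hole_medians(medians2d, spec)
  holeset <- backproject_medians(holeset, proj)
  attr(holeset, "diagnostics") <- diag_
  attr(holeset, "plane") <- fit$model
  attr(holeset, "projection") <- proj
  holeset
}
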