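#' Point cloud container
#'
#' An unordered set of 3D points in millimetres, with optional per-point unit
#' normals and a free-text provenance label (system name, pose tag). Extra
#' per-point annotations (e.g. the synthetic generator's plane-of-origin
#' labels) travel in `meta`, a list of length-N vectors that is subset
#' alongside the points.
#'
#' @param points numeric N x 3 matrix (mm).
#' @param normals optional numeric N x 3 matrix of unit vectors.
#' @param label free-text provenance string.
#' @param meta optional named list of length-N per-point vectors.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL, label = "", meta = list()) {
  points <- as_points_matrix(points, "points")
  if (!all(is.finite(points)))
    abort_parameter("point coordinates must all be finite")
  if (!is.null(normals)) {
    normals <- as_points_matrix(normals, "normals")
    if (nrow(normals) != nrow(points))
      abort_parameter("normals must match points row-for-row")
    len <- sqrt(rowSums(normals^2))
    if (nrow(normals) > 0 && max(abs(len - 1)) > 1e-6)
      abort_parameter("normals must have unit length within 1e-6")
  }
  if (length(meta)) {
    bad <- vapply(meta, function(v) length(v) != nrow(points), logical(1))
    if (any(bad))
      abort_parameter("meta vectors must have one entry per point")
  }
  structure(list(points = points, normals = normals,
                 label = as.character(label)[1], meta = meta),
            class = "point_cloud")
}

as_points_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x))
    abort_parameter(sprintf("%s must be a numeric N x 3 matrix", what))
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s%s\n", n_points(x),
              if (is.null(x$normals)) "" else " with normals",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

# Subset a cloud by row index, carrying normals and meta along.
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              normals = if (!is.null(cloud$normals))
                cloud$normals[idx, , drop = FALSE],
              label = cloud$label,
              meta = lapply(cloud$meta, function(v) v[idx]))
}
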