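# Registration-quality metrics: per-point surface normals, the
# overlap-region criterion ||n1 x (p2 - p1)|| < rho, RMSE/SD of
# nearest-neighbor distances over the overlap, and median aggregation
# across capture pairs.

#' Estimate per-point surface normals
#'
#' Each point's normal is the smallest principal axis of its k nearest
#' neighbors, oriented toward the sensor origin (`n . p < 0`). Degenerate
#' neighborhoods (rank below 2) fall back to the cloud's global plane
#' normal; their count is recorded in the `"n_degenerate"` attribute of the
#' returned normals.
#'
#' @param cloud a `point_cloud` with at least `k` points.
#' @param k neighborhood size (>= 3; default 30).
#' @param recompute logical; recompute even if the cloud already has
#'   normals (existing normals are preserved by default).
#' @return The `point_cloud` with `normals` filled.
#' @export
estimate_normals <- function(cloud, k = 30L, recompute = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.null(cloud$normals) && !recompute) return(cloud)
  k <- as.integer(k)
  if (k < 3L) abort_parameter("k must be >= 3")
  if (n_points(cloud) < k)
    abort_parameter("cloud has fewer points than the neighborhood size k")
  res <- cpp_normals(cloud$points, k)
  normals <- res$normals
  if (any(res$degenerate)) {
    mu <- colMeans(cloud$points)
    e <- eigen(crossprod(sweep(cloud$points, 2, mu)), symmetric = TRUE)
    normals[res$degenerate, ] <- matrix(e$vectors[, 3],
                                        sum(res$degenerate), 3, byrow = TRUE)
  }
  # orient toward the sensor at the origin
  flip <- rowSums(normals * cloud$points) > 0
  normals[flip, ] <- -normals[flip, ]
  attr(normals, "n_degenerate") <- sum(res$degenerate)
  cloud$normals <- normals
  cloud
}

#' Overlap region between two registered captures
#'
#' A point `p1` of cloud 1 (with surface normal `n1`) overlaps cloud 2 if
#' some point `p2` of cloud 2 lies within radius `rho` of the line through
#' `p1` along `n1`, i.e. `||n1 x (p2 - p1)|| < rho`. Note the criterion's
#' literal property: points of cloud 2 displaced purely along `n1` satisfy
#' it at any distance; this is faithful to the printed membership rule, and
#' the separately reported nearest-neighbor distances expose such cases.
#'
#' The per-point distance reported alongside the mask depends on
#' `distance_mode`:
#' * `"euclidean"` (default): full Euclidean distance to the nearest
#'   neighbor in cloud 2;
#' * `"orthogonal-to-normal"`: the minimum of `||n1 x (p2 - p1)||` over
#'   cloud 2 (the quantity the membership rule thresholds);
#' * `"point-to-plane"`: signed component along `n1` of the vector to the
#'   Euclidean nearest neighbor.
#'
#' @param cloud1 a `point_cloud` with normals (see [estimate_normals()]).
#' @param cloud2 a `point_cloud`.
#' @param rho overlap radius, mm (default 6).
#' @param distance_mode distance definition, see above.
#' @return An object of class `overlap_result`: `mask` (per-point logical
#'   over cloud 1), `nn_distance` (per-point distance, mm; defined for
#'   masked points), `nn_index` (nearest neighbor in cloud 2), `rho`,
#'   `distance_mode`.
#' @export
overlap_region <- function(cloud1, cloud2, rho = 6,
                           distance_mode = c("euclidean",
                                             "orthogonal-to-normal",
                                             "point-to-plane")) {
  stopifnot(inherits(cloud1, "point_cloud"), inherits(cloud2, "point_cloud"))
  distance_mode <- match.arg(distance_mode)
  if (is.null(cloud1$normals))
    abort_parameter("cloud1 has no normals; run estimate_normals() first")
  if (!is_scalar_number(rho) || rho <= 0)
    abort_parameter("rho must be > 0")
  if (n_points(cloud2) == 0L)
    abort_metric("cloud2 is empty")
  full <- distance_mode == "orthogonal-to-normal"
  res <- cpp_overlap(cloud1$points, cloud1$normals, cloud2$points, rho, full)
  nn_distance <- switch(distance_mode,
    "euclidean" = res$nn_dist,
    "orthogonal-to-normal" = res$min_orth,
    "point-to-plane" = rowSums(
      (cloud2$points[res$nn_index, , drop = FALSE] - cloud1$points) *
        cloud1$normals))
  structure(list(mask = res$mask, nn_distance = nn_distance,
                 nn_index = res$nn_index, rho = rho,
                 distance_mode = distance_mode),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %d / %d points overlap (rho = %g mm, %s)\n",
              sum(x$mask), length(x$mask), x$rho, x$distance_mode))
  invisible(x)
}

#' Registration error over the overlap region
#'
#' Root-mean-square and standard deviation (n - 1 denominator) of the
#' per-point nearest-neighbor distances over the overlapping points.
#'
#' @param overlap an `overlap_result`.
#' @return named numeric vector `c(rmse, sd)` in mm (`sd` is 0 for a single
#'   overlapping point).
#' @export
registration_error <- function(overlap) {
  stopifnot(inherits(overlap, "overlap_result"))
  d <- overlap$nn_distance[overlap$mask]
  if (length(d) == 0L)
    abort_metric("empty overlap region: no distances to aggregate")
  c(rmse = sqrt(mean(d^2)),
    sd = if (length(d) > 1L) sd(d) else 0)
}

#' Median registration error across capture pairs
#'
#' Coordinate-wise median of per-pair (RMSE, SD) metrics; even-length
#' inputs use the mean of the two central values.
#'
#' @param metrics a list of length-2 numeric vectors `c(rmse, sd)`, or a
#'   data.frame/matrix with columns `rmse` and `sd`.
#' @return named numeric vector `c(median_rmse, median_sd)` in mm.
#' @export
aggregate_median <- function(metrics) {
  if (is.data.frame(metrics) || is.matrix(metrics)) {
    m <- as.matrix(metrics)
    if (!all(c("rmse", "sd") %in% colnames(m)))
      abort_parameter("metrics must have rmse and sd columns")
    m <- m[, c("rmse", "sd"), drop = FALSE]
  } else if (is.list(metrics) && length(metrics) > 0L) {
    m <- do.call(rbind, lapply(metrics, function(v) as.numeric(v)[1:2]))
  } else {
    abort_parameter("metrics must be a non-empty list or table of (rmse, sd)")
  }
  if (nrow(m) == 0L || anyNA(m))
    abort_parameter("metrics must be non-empty and complete")
  c(median_rmse = median(m[, 1]), median_sd = median(m[, 2]))
}
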