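# Rigid-transform estimation between two cameras from their detected hole
# sets: least-squares (Kabsch) fit, board-symmetry resolution, transform
# application, ICP refinement, and chaining through a reference camera.

# Coerce hole_set / point_cloud / matrix to an N x 3 point matrix.
as_points3 <- function(x) {
  if (inherits(x, "hole_set")) {
    if (is.null(x$medians3d))
      abort_parameter("hole_set has no 3D medians (run backproject_medians)")
    x$medians3d
  } else if (inherits(x, "point_cloud")) {
    x$points
  } else {
    as_points_matrix(x, "points")
  }
}

#' Least-squares rigid transform between matched point sets
#'
#' Kabsch fit: centroid alignment plus SVD of the cross-covariance, with the
#' reflection-corrected determinant (the sign of the last singular vector is
#' flipped when needed so the result is a proper rotation, never a mirror).
#' Point i of `source` must correspond to point i of `target`.
#'
#' @param source,target matched point sets (`hole_set`, `point_cloud`, or
#'   N x 3 matrix), N >= 3.
#' @return list with `transform` (a `rigid_transform` mapping source
#'   coordinates into target coordinates) and `residual` (post-fit RMS of
#'   corresponding-point distances, mm).
#' @examples
#' src <- matrix(rnorm(30), 10, 3)
#' T0 <- rigid_transform(rotation_axis_angle(c(1, 1, 0), 0.4), c(10, -20, 5))
#' fit <- estimate_rigid(src, transform_points(src, T0))
#' fit$residual  # ~ 0
#' @export
estimate_rigid <- function(source, target) {
  X <- as_points3(source)
  Y <- as_points3(target)
  if (nrow(X) != nrow(Y))
    abort_estimation("source and target must have equal point counts")
  if (nrow(X) < 3L)
    abort_estimation("need at least 3 corresponding points")
  mx <- colMeans(X)
  my <- colMeans(Y)
  H <- crossprod(sweep(X, 2, mx), sweep(Y, 2, my))
  s <- svd(H)
  if (s$d[2] <= 1e-12 * max(s$d[1], .Machine$double.eps))
    abort_estimation("rank-deficient point configuration (collinear points)")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_ <- my - as.numeric(R %*% mx)
  transform <- rigid_transform(R, t_)
  resid <- sqrt(mean(rowSums((Y - transform_points(X, transform))^2)))
  list(transform = transform, residual = resid)
}

# Dihedral symmetry operations of the hole grid that map hole cells onto
# hole cells (and, for rotations by 90/270 degrees, require a square board
# with a square grid). Each returns the mapped (row, col).
board_symmetry_ops <- function(spec) {
  R <- spec$n_rows; C <- spec$n_cols
  square <- abs(spec$width - spec$height) < 1e-9 && R == C
  ops <- list(
    identity = function(r, c) cbind(r, c),
    rot180 = function(r, c) cbind(R + 1L - r, C + 1L - c),
    flip_rows = function(r, c) cbind(R + 1L - r, c),
    flip_cols = function(r, c) cbind(r, C + 1L - c))
  if (square) {
    ops$rot90 <- function(r, c) cbind(c, R + 1L - r)
    ops$rot270 <- function(r, c) cbind(C + 1L - c, r)
    ops$flip_diag <- function(r, c) cbind(c, r)
    ops$flip_anti <- function(r, c) cbind(R + 1L - c, C + 1L - r)
  }
  holes <- hole_centers(spec)
  key <- function(r, c) paste(r, c)
  hole_pos <- stats::setNames(seq_len(nrow(holes)), key(holes$row, holes$col))
  out <- list()
  for (nm in names(ops)) {
    mapped <- ops[[nm]](holes$row, holes$col)
    pos <- hole_pos[key(mapped[, 1], mapped[, 2])]
    if (anyNA(pos)) next  # symmetry not consistent with the hole parity
    out[[nm]] <- as.integer(pos)  # permutation: source slot i -> target slot pos[i]
  }
  out
}

#' Resolve the board's symmetry ambiguity and estimate the transform
#'
#' The checkerboard-parity hole pattern is invariant under a 180-degree
#' in-plane rotation (and, for square boards with a symmetric grid, under
#' 90-degree rotations too), so the canonical grid labels produced
#' independently by each camera's detection can disagree by such a symmetry
#' and the hole medians alone cannot distinguish the candidates: every true
#' pattern symmetry yields a near-zero residual. This routine fits
#' [estimate_rigid()] under every pattern-consistent index permutation,
#' discards candidates whose residual is more than `margin` above the best
#' (these are genuine misfits, e.g. reflections), and breaks the remaining
#' tie by minimal rotation angle. That tie-break is provably correct when
#' the true relative camera rotation is below 90 degrees (the wrong
#' 180-degree-composed candidate then always exceeds 90 degrees); rigs that
#' this target is designed for keep camera pairs within 90 degrees. If the
#' smallest two candidate angles are within `angle_margin_deg`, the geometry
#' is genuinely ambiguous and an error is raised.
#'
#' @param source,target `hole_set` objects with 3D medians (complete).
#' @param spec the `board_spec`.
#' @param margin residual slack (mm) within which candidates are treated as
#'   tied with the best.
#' @param angle_margin_deg minimal rotation-angle separation (degrees)
#'   required to call the tie resolved.
#' @return list with `transform` (source -> target), `residual` (mm),
#'   `symmetry` (name of the chosen permutation) and `candidates` (a
#'   data.frame of all evaluated permutations with residuals and angles).
#' @export
resolve_symmetry <- function(source, target, spec, margin = 1,
                             angle_margin_deg = 1) {
  stopifnot(inherits(source, "hole_set"), inherits(target, "hole_set"),
            inherits(spec, "board_spec"))
  src <- as_points3(source)
  tgt <- as_points3(target)
  perms <- board_symmetry_ops(spec)
  cand <- lapply(names(perms), function(nm) {
    perm <- perms[[nm]]
    # source slot i corresponds to target slot perm[i]
    tgt_perm <- tgt[perm, , drop = FALSE]
    fit <- estimate_rigid(src, tgt_perm)
    list(name = nm, perm = perm, fit = fit,
         angle = rt_angle(fit$transform))
  })
  resid <- vapply(cand, function(c_) c_$fit$residual, numeric(1))
  angle <- vapply(cand, function(c_) c_$angle, numeric(1))
  tied <- which(resid <= min(resid) + margin)
  if (length(tied) > 1L) {
    ang_sorted <- sort(angle[tied])
    if ((ang_sorted[2] - ang_sorted[1]) * 180 / pi < angle_margin_deg)
      abort_ambiguity(sprintf(
        paste("board symmetry is ambiguous: %d candidate correspondences fit",
              "equally well and their rotation angles are within %.2f deg"),
        length(tied), angle_margin_deg))
    best <- tied[which.min(angle[tied])]
  } else {
    best <- tied
  }
  chosen <- cand[[best]]
  list(transform = chosen$fit$transform, residual = chosen$fit$residual,
       symmetry = chosen$name,
       candidates = data.frame(
         symmetry = vapply(cand, function(c_) c_$name, character(1)),
         residual = resid, angle_deg = angle * 180 / pi))
}

#' Apply a rigid transform to a point cloud
#'
#' `p' = R p + t` per point; normals, when present, are rotated by `R` only.
#'
#' @param cloud a `point_cloud` (or N x 3 matrix).
#' @param transform a `rigid_transform`.
#' @return The transformed `point_cloud`.
#' @export
apply_transform <- function(cloud, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.matrix(cloud)) return(transform_points(cloud, transform))
  stopifnot(inherits(cloud, "point_cloud"))
  point_cloud(transform_points(cloud$points, transform),
              normals = if (!is.null(cloud$normals))
                cloud$normals %*% t(transform$rotation),
              label = cloud$label, meta = cloud$meta)
}

#' Refine an alignment with iterative closest point
#'
#' Point-to-point ICP restricted to the overlap region under the initial
#' transform: source points overlapping the target (per
#' [overlap_region()] with radius `rho`) are iteratively matched to their
#' Euclidean nearest neighbors in the target and re-fitted with the
#' least-squares rigid solver. Iteration stops when the correspondence RMS
#' changes by less than `tol` or after `max_iter` iterations. The
#' correspondence RMS is non-increasing across iterations; the returned
#' transform incorporates (and replaces) `T_init`.
#'
#' @param source a `point_cloud` in its own frame.
#' @param target a `point_cloud` in the target frame.
#' @param T_init initial `rigid_transform` (source -> target).
#' @param max_iter maximum iterations.
#' @param tol RMS-change stopping tolerance, mm.
#' @param rho overlap radius, mm (see [overlap_region()]).
#' @param normals_k neighborhood size for normal estimation when the source
#'   has no normals.
#' @return A `rigid_transform` (source -> target) with attribute
#'   `"rms_history"` (correspondence RMS per iteration, mm).
#' @export
refine_icp <- function(source, target, T_init = rt_identity(),
                       max_iter = 50L, tol = 1e-3, rho = 6,
                       normals_k = 30L) {
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"))
  if (n_points(source) == 0L || n_points(target) == 0L)
    abort_estimation("ICP requires non-empty clouds")
  src_init <- apply_transform(source, T_init)
  if (is.null(src_init$normals))
    src_init <- estimate_normals(src_init, k = min(normals_k, n_points(src_init)))
  ov <- overlap_region(src_init, target, rho = rho)
  if (!any(ov$mask))
    abort_estimation("empty overlap under the initial transform; cannot refine")
  S <- source$points[ov$mask, , drop = FALSE]
  Tgt <- target$points
  T_cur <- T_init
  rms_prev <- Inf
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    St <- transform_points(S, T_cur)
    nn <- cpp_nn(Tgt, St)
    rms <- sqrt(mean(nn$dist^2))
    history <- c(history, rms)
    if (abs(rms_prev - rms) < tol) break
    rms_prev <- rms
    fit <- estimate_rigid(S, Tgt[nn$index, , drop = FALSE])
    T_cur <- fit$transform
  }
  attr(T_cur, "rms_history") <- history
  T_cur
}

#' Chain two camera-to-reference transforms
#'
#' Given transforms mapping cameras a and b into a shared reference frame,
#' returns the transform mapping b directly into a:
#' `T_a_to_ref^-1 o T_b_to_ref`.
#'
#' @param T_a_to_ref,T_b_to_ref `rigid_transform` objects into the common
#'   reference frame.
#' @return The b -> a `rigid_transform`.
#' @export
chain_transforms <- function(T_a_to_ref, T_b_to_ref) {
  rt_compose(rt_inverse(T_a_to_ref), T_b_to_ref)
}
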