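# Rigid estimation, symmetry resolution, transform application, ICP.

test_that("rigid fit recovers constructed transforms exactly", {
  set.seed(1)
  src <- matrix(runif(54, -150, 150), 18, 3)
  fit0 <- estimate_rigid(src, src)
  expect_lt(max(abs(fit0$transform$rotation - diag(3))), 1e-12)
  expect_lt(fit0$residual, 1e-12)

  T_true <- rigid_transform(
    rotation_axis_angle(c(1, 1, 0) / sqrt(2), 25 * pi / 180),
    c(10, -20, 5))
  fit <- estimate_rigid(src, apply_transform(src, T_true))
  expect_lt(max(abs(fit$transform$rotation - T_true$rotation)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - T_true$translation)), 1e-9)
  expect_lt(fit$residual, 1e-9)
})

test_that("rigid fit degrades gracefully under landmark noise", {
  # thresholds sized by a quick Monte-Carlo of the same construction:
  # sigma 0.5 mm over 18 landmarks with ~110 mm lever arm gives rotation
  # errors of a few hundredths of a degree
  nominal <- hole_centers(board_spec())
  src <- cbind(nominal$x, nominal$y, 0)
  T_true <- rigid_transform(rotation_axis_angle(c(0, 1, 0), 0.4),
                            c(30, 10, -20))
  set.seed(7)
  noisy <- apply_transform(src, T_true) + matrix(rnorm(54, 0, 0.5), 18, 3)
  fit <- estimate_rigid(src, noisy)
  expect_lt(rot_err_deg(fit$transform, T_true), 0.5)
  expect_lt(trans_err_mm(fit$transform, T_true), 1)
})

test_that("rigid fit rejects degenerate configurations", {
  expect_error(estimate_rigid(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "cb3d_estimation_error")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(estimate_rigid(line, line), class = "cb3d_estimation_error")
  expect_error(estimate_rigid(matrix(0, 4, 3), matrix(0, 5, 3)),
               class = "cb3d_estimation_error")
})

test_that("symmetry resolution picks the ground-truth correspondence", {
  spec <- board_spec()
  p1 <- random_capture_pose(seed = 21L)
  p2 <- random_capture_pose(seed = 22L)
  pair <- generate_capture_pair(
    spec,
    capture_scenario(pose = p1, sampling_pitch = 2, noise_sd = 0.5, seed = 1L),
    capture_scenario(pose = p2, sampling_pitch = 2, noise_sd = 0.5, seed = 2L))
  hs1 <- detect_board(pair$cloud1, spec, detection_config())
  hs2 <- detect_board(pair$cloud2, spec, detection_config())
  res <- resolve_symmetry(hs2, hs1, spec)
  expect_lt(rot_err_deg(res$transform, pair$transform), 0.5)
  expect_lt(trans_err_mm(res$transform, pair$transform), 2)
  # the hole pattern itself is 180-degree symmetric: the alternative is
  # residual-tied but its rotation angle exceeds 90 degrees
  cand <- res$candidates
  expect_setequal(cand$symmetry, c("identity", "rot180"))
  expect_gt(cand$angle_deg[cand$symmetry != res$symmetry], 90)
})

test_that("unambiguous ordered hole sets reduce to the plain rigid fit", {
  spec <- board_spec()
  nominal <- hole_centers(spec)
  T_true <- rigid_transform(rotation_axis_angle(c(0, 0, 1), 0.3),
                            c(5, -5, 10))
  mk <- function(pts) structure(
    list(medians3d = pts, grid_index = cbind(nominal$row, nominal$col),
         spec = spec), class = "hole_set")
  src <- mk(cbind(nominal$x, nominal$y, 0))
  tgt <- mk(apply_transform(src$medians3d, T_true))
  res <- resolve_symmetry(src, tgt, spec)
  fit <- estimate_rigid(src, tgt)
  expect_identical(res$symmetry, "identity")
  expect_lt(max(abs(res$transform$rotation - fit$transform$rotation)), 1e-12)
})

test_that("a square symmetric board at 45 degrees is reported as ambiguous", {
  spec <- board_spec(width = 240, height = 240, n_rows = 5, n_cols = 5)
  nominal <- hole_centers(spec)
  mk <- function(pts) structure(
    list(medians3d = pts, grid_index = cbind(nominal$row, nominal$col),
         spec = spec), class = "hole_set")
  src <- mk(cbind(nominal$x, nominal$y, 0))
  T45 <- rigid_transform(rotation_axis_angle(c(0, 0, 1), pi / 4), c(0, 0, 0))
  tgt <- mk(apply_transform(src$medians3d, T45))
  expect_error(resolve_symmetry(src, tgt, spec),
               class = "cb3d_ambiguity_error")
})

test_that("applying transforms preserves geometry and composes", {
  cl <- generate_surface_cloud("cylinder-patch", extent = 80, pitch = 8)
  cl <- estimate_normals(cl, k = 10)
  T1 <- rigid_transform(rotation_axis_angle(c(1, 0, 1), 0.7), c(5, 6, 7))
  T2 <- rigid_transform(rotation_axis_angle(c(0, 1, 0), -0.3), c(-2, 0, 4))

  expect_equal(apply_transform(cl, rt_identity())$points, cl$points)

  back <- apply_transform(apply_transform(cl, T1), rt_inverse(T1))
  expect_lt(max(abs(back$points - cl$points)), 1e-9)

  a <- apply_transform(apply_transform(cl, T1), T2)
  b <- apply_transform(cl, rt_compose(T2, T1))
  expect_lt(max(abs(a$points - b$points)), 1e-9)

  # isometry: pairwise distances unchanged; normals stay unit
  idx <- seq(1, n_points(cl), by = 7)
  expect_lt(max(abs(dist(a$points[idx, ]) - dist(cl$points[idx, ]))), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(a$normals^2)) - 1)), 1e-9)
})

test_that("ICP removes a small injected misalignment", {
  target <- generate_surface_cloud("cylinder-patch", extent = 160, pitch = 4)
  target <- apply_transform(target, rigid_transform(diag(3), c(0, 0, 800)))
  miss <- rt_compose(
    rigid_transform(rotation_axis_angle(c(0, 0, 1), 1 * pi / 180),
                    c(2, 0, 0)),
    rt_identity())
  # source in its own frame = target points; true source->target transform
  # is the identity; start ICP from the injected misalignment
  refined <- refine_icp(target, target, T_init = miss)
  expect_lt(rt_angle(refined) * 180 / pi, 0.1)
  expect_lt(sqrt(sum(refined$translation^2)), 0.1)
  rms <- attr(refined, "rms_history")
  expect_true(all(diff(rms) <= 1e-9))
  expect_lt(rms[length(rms)], rms[1])
})

test_that("ICP is a no-op for aligned clouds and fails with no overlap", {
  cl <- generate_surface_cloud("plane", extent = 100, pitch = 5)
  refined <- refine_icp(cl, cl, T_init = rt_identity(), tol = 1e-3)
  expect_lt(rt_angle(refined), 1e-9)
  expect_lt(sqrt(sum(refined$translation^2)), 1e-9)

  far <- apply_transform(cl, rigid_transform(diag(3), c(1e5, 1e5, 0)))
  expect_error(refine_icp(cl, far, T_init = rt_identity()),
               class = "cb3d_estimation_error")
})

test_that("chaining through a reference matches the direct transform", {
  Ta <- rigid_transform(rotation_axis_angle(c(1, 2, 0), 0.5), c(10, 0, -5))
  Tb <- rigid_transform(rotation_axis_angle(c(0, 1, 1), -0.8), c(0, 20, 5))
  expect_equal(chain_transforms(rt_identity(), rt_identity())$rotation,
               diag(3))
  Tba <- chain_transforms(Ta, Tb)
  set.seed(4)
  probe <- matrix(runif(30, -50, 50), 10, 3)
  direct <- apply_transform(apply_transform(probe, Tb), rt_inverse(Ta))
  expect_lt(max(abs(apply_transform(probe, Tba) - direct)), 1e-9)
  # chain then chain back gives the identity
  back <- rt_compose(rt_inverse(Tba), chain_transforms(Ta, Tb))
  expect_lt(rt_angle(back), 1e-9)
})
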