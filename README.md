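# cb3d — single-capture extrinsic calibration for 3D scanning systems

Multi-camera 3D scanning rigs (clinical back-shape platforms, multi-sensor
quality-validation setups) need the rigid transform between every pair of
camera frames, and need it re-estimated quickly whenever the rig is
adjusted. `cb3d` calibrates a camera pair from **one depth capture each**
of a planar target with through-holes in a checkerboard-parity grid — an
A4 board (297 × 210 mm) with 18 holes of 20 × 20 mm by default. Because
the holes are visible in depth data alone, the method works identically
for structured-light, active-stereo and time-of-flight sensors, texture or
not.

## Method

Per camera, the capture is reduced to 18 landmarks:
depth-slab crop → RANSAC plane fit → PCA projection to 2D → 3 mm
rasterization (pixel = hole iff no point within 3 mm of its center) →
connected components → per-hole coordinate-wise medians → grid sorting →
back-projection to 3D.

Between the two landmark sets the rigid transform `p′ = R p + t` is the
least-squares (Kabsch/SVD) fit; the hole pattern's 180° in-plane symmetry
is resolved by fitting all pattern-consistent correspondences and keeping
the candidate with minimal rotation angle (exact whenever the true
relative camera rotation is below 90°, which such rigs satisfy). An
optional point-to-point ICP refinement absorbs residual motion between
sequentially triggered captures.

Registration quality is scored on the overlap region: point `p1` with
normal `n1` overlaps the other cloud if some `p2` satisfies
`‖n1 × (p2 − p1)‖ < ρ` (ρ = 6 mm); over the overlapping points the RMSE
and SD of nearest-neighbor distances are reported, with medians across
capture pairs. A synthetic depth-capture generator (lattice sampling,
Gaussian depth noise, dropout, ground-truth poses) makes the whole
pipeline testable without hardware.

## Worked example

```r
library(cb3d)
spec <- board_spec()                       # A4 board, 6 x 6 grid, 18 holes
pair <- generate_capture_pair(spec,
  capture_scenario(pose = random_capture_pose(seed = 1), sampling_pitch = 2,
                   noise_sd = 0.5, seed = 11),
  capture_scenario(pose = random_capture_pose(seed = 2), sampling_pitch = 2,
                   noise_sd = 0.5, seed = 12))
hs1 <- detect_board(pair$cloud1, spec, detection_config())
hs2 <- detect_board(pair$cloud2, spec, detection_config())
res <- resolve_symmetry(hs2, hs1, spec)    # camera 2 -> camera 1
res$transform

aligned <- apply_transform(pair$cloud2, res$transform)
ov <- overlap_region(estimate_normals(pair$cloud1), aligned, rho = 6)
registration_error(ov)
```

Output:

```
<rigid_transform> rotation 5.8535 deg, translation (42.724, -24.700, -1.516) mm
<overlap_result> 13994 / 13994 points overlap (rho = 6 mm, euclidean)
  rmse     sd
0.7096 0.4222
```

The estimated transform maps camera-2 coordinates into camera-1
coordinates; here it recovers the simulated ground truth to 0.005° and
0.05 mm despite 0.5 mm depth noise, and the re-aligned captures agree to a
0.71 mm overlap RMSE — the scale of the injected sensor noise, as it
should be.

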