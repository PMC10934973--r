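---
title: "Single-capture extrinsic calibration with a hole-pattern checkerboard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-capture extrinsic calibration with a hole-pattern checkerboard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-camera 3D scanning rigs — for instance platforms that capture the
human back simultaneously from behind and from above while the patient
bends — need the rigid transform between every pair of camera coordinate
frames. When the rig is re-adjusted per patient, this extrinsic calibration
must be redone in seconds, from a single capture, and it must work for
structured-light, active-stereo and time-of-flight sensors alike, including
consumer devices with millimetre-level depth noise and no usable texture
channel.

`cb3d` implements a calibration target and pipeline built for exactly this
setting: a planar board with square through-holes in a checkerboard-parity
grid. Holes are directly visible in depth data, so no texture or intensity
information is needed. An optional solid plane mounted behind the board
gives pattern-projecting stereo sensors something to see through the holes,
which makes hole boundaries much more reliable on such devices.

The default geometry is an A4 board: 297 mm x 210 mm, a 6 x 6 grid of
20 mm x 20 mm holes in the cells where (row + col) is even (0-based),
giving 18 holes, with the solid plane 100 mm behind. All distances in the
package are millimetres, end to end.

## Detection: from one depth capture to 18 landmarks

Per camera, `detect_board()` runs:

1. **Depth-slab crop** — keep points with `|z - dist_estimate| <= eps`.
   `dist_estimate` is the user's rough board distance (defaulting to the
   cloud's median z); `eps` defaults to half the back-plane offset (50 mm)
   so the back plane falls outside the slab.
2. **RANSAC plane fit** — 1000 three-point hypotheses, inlier threshold
   2 mm, fixed seed, followed by a least-squares refit (centroid plus
   smallest principal axis) on the consensus set. The slab may still
   contain clutter; the plane fit keeps only the board's front plane.
3. **PCA projection to 2D** — the inliers' first principal axis carries
   the board's long side; coordinates are expressed in the in-plane frame
   `(axis1, axis2)` about the inlier centroid. Signs are pinned so runs
   are reproducible: the plane normal points toward the sensor
   (`n . centroid < 0`) and `axis1 . camera_x >= 0` (falling back to the
   y then z components on ties); `axis2 = n x axis1` completes a
   right-handed frame. Two prints worth knowing: the principal axes are
   rotated slightly (well under a degree at the default geometry) relative
   to the physical board edges, because the hole pattern's xy cross-moment
   is not zero; and depending on the viewing side convention the projected
   pattern can be a mirror image of the board's front-face labeling. Both
   effects are absorbed downstream (row clustering tolerates the rotation;
   the symmetry resolver absorbs the relabeling).
4. **Rasterization** — a grid of 3 mm pixels spanning the projection's
   bounding box; a pixel is a *hole* pixel iff no projected point lies
   within 3 mm (2D Euclidean) of its center.
5. **Connected components** — 8-connected components of hole pixels.
   Components touching the raster border are the margin outside the board,
   not holes, and are discarded; components smaller than
   `(floor(hole_size / (2 * resolution)))^2` pixels (9 at the defaults)
   are sensor speckle and are discarded too.
6. **Hole medians** — per component, the coordinate-wise median of its
   pixel centers: a robust, quantized estimate of the hole center.
7. **Grid sorting** — median y values are clustered into rows by splitting
   at gaps larger than half the nominal row pitch, rows are ordered by y
   and holes by x within each row, and each median receives a canonical
   (row, col) label. A count mismatch at any level is a hard error: a
   partially seen board yields a detection failure, never a silent result.
8. **Back-projection** — `medians3d = origin + coords2d %*% t(basis)`;
   the landmarks lie exactly on the fitted plane.

## Registration and the pattern's symmetry

With 18 matched landmark pairs, `estimate_rigid()` computes the
least-squares rigid transform (Kabsch: centroid alignment, SVD of the
cross-covariance, determinant correction so the result is never a
reflection) together with the RMS landmark residual.

The subtle point is correspondence. The hole-center set of the default
board is *exactly invariant* under a 180-degree in-plane rotation: cell
(r, c) maps to (5 - r, 5 - c) (0-based), which preserves (row + col)
parity, and hole centers map onto hole centers. Two cameras therefore
cannot agree on the board's orientation from the hole medians alone — the
candidate correspondence obtained by rotating the labels 180 degrees fits
with the same near-zero residual as the true one, and the two resulting
camera-to-camera transforms differ by a 180-degree rotation about the
board normal. Reflected label candidates, by contrast, map holes onto
blank cells on grids with even dimensions and misfit by tens of
millimetres, so the residual rejects them.

`resolve_symmetry()` therefore fits every pattern-consistent label
permutation, discards candidates more than `margin` (1 mm) above the best
residual, and breaks the remaining tie by **minimal rotation angle**. This
is valid under one explicit assumption: the true relative rotation between
the two cameras is below 90 degrees. A quaternion argument makes the
tie-break exact rather than heuristic: if `angle(T) < 90` degrees then for
the 180-degree symmetry `S`, `|cos(angle(T S)/2)| = |sin(angle(T)/2) (u . a)|
< cos(angle(T)/2)`, so `angle(T S) > 90` degrees — the wrong candidate
always loses. Rigs of the kind this target serves keep camera pairs within
90 degrees; beyond that, the orientation is genuinely unidentifiable from
a single capture of a 180-degree-symmetric target, and a capture of an
asymmetric target (or a second pose) would be required. When even the
angles cannot separate candidates — e.g. a square board with a
90-degree-symmetric hole pattern seen at 45 degrees — the resolver raises
an explicit ambiguity error instead of guessing.

`refine_icp()` optionally polishes the result for dynamic scenes:
point-to-point ICP restricted to the overlap region under the initial
transform, nearest-neighbor correspondences from a k-d tree, rigid updates
by the same Kabsch solver, stopping when the correspondence RMS changes by
less than 1e-3 mm or after 50 iterations. The RMS is non-increasing across
iterations by the usual two-step argument. ICP exists to absorb small
*residual* motion (e.g. capture delay between sequentially triggered
cameras); it is not a substitute for the board-based initialization.

## The overlap metric

Registration quality is scored on the region where the two captures
actually see the same surface. A point `p1` of cloud 1 with unit normal
`n1` overlaps cloud 2 if some `p2` satisfies `||n1 x (p2 - p1)|| < rho`
with `rho = 6` mm — i.e. `p2` lies within a 6 mm radius of the *line*
through `p1` along its normal. Taken literally, the rule accepts points
displaced arbitrarily far purely along the normal (the cross product is
then zero); the implementation is faithful to the rule and reports the
nearest-neighbor distances alongside, which exposes such cases rather than
hiding them.

Normals are estimated as the smallest principal axis of each point's 30
nearest neighbors, oriented toward the sensor origin; degenerate
neighborhoods fall back to the cloud's global plane normal and are
counted.

Over the overlapping points, `registration_error()` reports the RMSE and
the standard deviation (n - 1 denominator) of the per-point distances, and
`aggregate_median()` takes coordinate-wise medians across capture pairs.
Because communities differ in which distance they report, the per-point
distance is configurable: full Euclidean nearest-neighbor distance (the
default), the minimum normal-orthogonal component (the quantity the
membership rule thresholds), or the signed point-to-plane component along
`n1`. Note the algebraic identity `rmse^2 = mean^2 + population variance`:
for any one set of nonnegative distances, the RMSE can never be smaller
than the population SD of those same distances, so an "RMSE much smaller
than SD" report necessarily mixes definitions (for instance signed
distances); exposing the modes makes such choices explicit.

## The synthetic generator: what it does and does not emulate

`generate_board_cloud()` samples the board's front plane on a regular
lattice (default pitch 2 mm, comparable to the lateral resolution of the
emulated sensors at 1 m), removes points strictly inside hole footprints,
optionally adds the full back plane, applies Bernoulli dropout and
Gaussian depth noise *along the camera ray* (depth sensors err mostly in
range, not laterally), and poses the result rigidly. Noise SDs of 0-1 mm
and dropout up to 20% bracket the emulated device class, from
sub-millimetre industrial structured light to ~3 mm consumer sensors.
`random_capture_pose()` draws rig-plausible poses: about 1 m stand-off,
in-plane rotation within +/-30 degrees, tilt within 10 degrees, lateral
shift within +/-50 mm — bounds that also guarantee any two poses differ by
less than 90 degrees, the symmetry resolver's working assumption, and that
the tilted board stays inside the default +/-50 mm crop slab.

Deliberately *not* modeled: perspective projection and self-occlusion
(the lattice covers the full board whatever the pose), sensor-specific
artifacts such as stereo sensors smoothing over unbacked holes, projector
shadows and multi-path. One consequence matters for interpreting tests:
two noise-free captures of the same board contain the *same physical
sample points*, so end-to-end noise-free recovery is exact rather than
raster-limited, and the meaningful accuracy statements come from the noisy
conditions (1 mm depth noise, 20% dropout), where median translation
recovery error at the default geometry is well under 1 mm. Passing tests
on this generator demonstrate the pipeline's correctness and its noise
behavior, not the artifact spectrum of any particular physical sensor.

## Numerical and design choices

| parameter | default | unit | why |
|---|---|---|---|
| board width x height | 297 x 210 | mm | A4 target, desk/clinic scale |
| grid, hole size | 6 x 6, 20 | -, mm | 18 holes; hole comfortably spans several raster pixels |
| back-plane offset | 100 | mm | separable from the front plane by a 50 mm slab |
| crop `eps` | back_offset / 2 = 50 | mm | excludes the back plane before the fit |
| RANSAC threshold / iterations | 2 / 1000 | mm / - | tolerates 1 mm depth noise; deterministic via seed |
| raster resolution | 3 | mm | coarse enough that the lattice never leaves false holes, fine enough for ~1.5 mm median quantization |
| min component size | 9 | px | `(floor(20 / 6))^2`; rejects speckle, keeps partial holes |
| connectivity | 8 | - | holes survive single-pixel diagonal nicks |
| overlap radius `rho` | 6 | mm | twice the raster resolution |
| normals k | 30 | - | stable plane estimates at 2 mm pitch |
| symmetry margin / angle margin | 1 / 1 | mm / deg | residual tie band; minimum angle separation |
| ICP max_iter / tol | 50 / 1e-3 | - / mm | converges in a handful of iterations on lattice data |

Other conventions: transforms use column vectors, `p' = R p + t`, stated
explicitly in the JSON files to prevent silent transpose bugs; clouds are
written as float64 so round-trips are bit-exact; raster pixel `[0, 0]` is
centered on the projection bounding-box minimum; hole parity, hole
centering in cells, and the full-footprint back plane are conventions of
this implementation (physical targets vary in details the detection does
not depend on).

The test suite exercises the pipeline at 2 mm sampling pitch (about
14,000 points per capture) with 50-pose recovery sweeps, and brute-force
oracle comparisons (rasterization, medians, overlap, RMSE/SD) on fixtures
of a few hundred points — sizes at which the oracles are exact re-statements
of the definitions, not approximations.

## Known limitations

* A single capture of a 180-degree-symmetric pattern cannot identify the
  relative orientation beyond the <90-degree assumption discussed above.
* Detection requires the full hole count; occluded or clipped boards fail
  loudly rather than degrade.
* The overlap rule's acceptance of arbitrarily distant points along the
  normal is kept as specified; use the reported distances to audit it.
* Sorting assumes the row structure survives projection; extreme
  perspective-free tilts are fine, but a physically foreshortened capture
  from a real camera at grazing angles is outside the generator's model.
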