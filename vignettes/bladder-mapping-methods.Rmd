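---
title: "Methods: feature-based bladder map stitching, drift correction and revisit localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-based bladder map stitching, drift correction and revisit localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`cystomap` treats the bladder wall, as seen through a cystoscope, as a
locally planar surface viewed under translation, in-plane rotation and
zoom. The inter-frame motion model is therefore a 4-DOF similarity

$$x' = s\,R(\theta)\,x + t,$$

with a full 6-DOF affine available via
`feature_config(model = "affine")`. This is an approximation: a bladder is
curved, so a similarity chain cannot be exact over long sweeps, and the
compositing of a curved surface into one plane necessarily distorts at
the periphery. The approximation is the same one the 2D-map formulation
itself makes, and the synthetic test substrate (below) realizes it
exactly, which is what makes ground-truth pose recovery a fair oracle for
the *algorithm* as opposed to the model.

Pixel coordinates are 0-based, x rightward, y downward; 2×3 transforms act
on homogeneous columns. Global poses map frame pixels to canvas pixels;
the map's orientation is initialized by the first frame, whose pose equals
the cumulative canvas offset at all times.

## The estimation pipeline and its parameters

*Detection.* A difference-of-Gaussian blob detector over
`n_scales = 6` layers starting at `sigma0 = 1.6` px, with quadratic
sub-pixel localisation, an edge-response test on the local Hessian and a
36-bin gradient-orientation assignment. The response threshold
(`dog_thresh = 0.004` on unit-intensity images) and keypoint cap
(`max_keypoints = 600`) were chosen once for 256×256 endoscope frames:
vessel-textured frames yield a few hundred keypoints, two orders of
magnitude above the six-feature gate.

*Description.* 128-d gradient-orientation histograms (4×4 spatial cells ×
8 bins, trilinear soft binning, 0.2 clamping) over a rotated,
scale-normalized 16×16 sample grid. A normalized raw-patch descriptor is
kept as `descriptor = "patch"`; it proved under-discriminative on
self-similar vessel textures (near-duplicate curvilinear structures), so
the histogram descriptor is the default.

*Matching.* Brute-force nearest neighbour with a Lowe ratio test at
`ratio = 0.75`; mutual-nearest cross-checking is optional and off by
default. The ratio value is standard practice; the matcher itself makes no
geometric decision.

*Robust estimation.* RANSAC with minimal samples (2 points for similarity,
3 for affine), inlier threshold 3 px, confidence 0.995, at most 2000
iterations with the usual adaptive stopping rule, a seeded RNG
(`ransac$seed`, default 42) so that identical inputs give bit-identical
transforms, and a minimum of 6 accepted inliers mirroring the six-feature
gate (6 points is also the algebraic minimum with redundancy for a stable
similarity fit). Two acceptance gates follow:

- the **feature gate**: at least 6 detected features in each frame *and*
  6 final inliers — the printed rule is ambiguous about which count it
  refers to, so both are enforced; either failing produces a typed
  failure value that triggers the fallback;
- a **scale-plausibility gate** (`scale_range = c(0.75, 1.33)`): a
  similarity whose zoom falls outside these bounds is rejected. Every
  spurious registration observed between unrelated textures in
  Monte-Carlo testing carried a wildly implausible scale (0.01–0.7),
  while genuine inter-frame zoom in this application stays within a few
  percent of unity; the gate encodes that physical prior.

*Refinement.* Three refinements were added after chained accuracy proved
insufficient with a plain RANSAC + least-squares refit (approximately
0.1 px of systematic error per pair, i.e. ~3 px over a 25-frame chain):

1. staged re-selection of inliers at decreasing thresholds
   (`refine_thresholds = c(1.5, 0.8)` px) with a refit at each stage;
2. symmetric estimation (`symmetric = TRUE`): the pair is estimated in
   both directions and the two transforms averaged parameter-wise in
   $(t_x, t_y, \theta, \log s)$, cancelling direction-dependent
   localisation bias;
3. photometric sub-pixel refinement (`lk_refine = TRUE`): inlier
   correspondences are re-localised by warp-compensated, translation-only
   Lucas–Kanade on 13×13 patches before the final fit; points whose
   alignment diverges or keeps a high residual are dropped.

All three are conventional components of accurate mosaicking systems and
leave the algorithmic contract (detect → match → RANSAC → fallback)
unchanged.

## Stitching and fallback bookkeeping

The registration reference is the most recent *successfully registered*
frame, not blindly the previous frame. When a frame fails the gates, it
inherits the last accepted step transform (constant-velocity assumption)
and is counted as "no transformation found"; the next frame then attempts
registration against the last good frame. This detail is forced by the
reporting convention: inserting `k` featureless frames must produce
exactly `k` inherited transforms and a success fraction of `(n−k)/n` —
if the reference were always the previous frame, the frame *after* a
featureless stretch would fail too and the count would be `k+1`.

Compositing is last-writer-wins under the frame validity mask: the map
shows the most recent view of each region, is deterministic, and keeps
poses — the source of truth — independent of any blending choice. The
canvas grows minimally (integer pixels) as projected corners leave it;
growth toward negative coordinates shifts a cumulative offset and all
stored poses consistently.

Frame ingestion subsamples by a fixed stride (reproducible and simple);
a keyframe rule based on estimated displacement would also fit the
interface but is not the default.

## Drift correction

Candidate loop closures are frame pairs at least `min_gap = 10` frames
apart whose projected centers lie within 1.5 frame diagonals and whose
footprints overlap by at least 25% (overlap is measured by pulling a point
grid of one frame back into the other); at most one closure — the
highest-overlap one — is kept per closing frame. Each closure stores the
*direct* feature-based measurement between its two frames.

The source material describes drift correction in a single sentence and
leaves the correction mechanism open. The design chosen here: closures
are processed in increasing closing-index order; each closure's residual
is re-derived from the **current** (partially corrected) poses using its
stored direct measurement, and distributed over the not-yet-anchored part
of the intervening chain by linear interpolation in
$(t_x, t_y, \theta, \log s)$ — frames up to the previous closure's end
are treated as already anchored. Re-deriving the residual is what keeps
overlapping chains from double-counting: a naive application of each
pre-measured residual over its full span over-corrects badly when many
closures share their early frames (observed directly during development).
Frame 0 is never moved, so the map keeps its initial-frame orientation; a
global pose-graph or bundle adjustment is explicitly out of scope. The
canvas is re-rendered from corrected poses afterwards.

## Revisit localization

Map-canvas features are detected once (up to 4000 keypoints, restricted to
covered pixels) and cached. The first revisit frame is matched globally
with no position prior. Later frames are matched against the cached map
features inside the previous footprint dilated by one frame size — the
locality prior bounds cost on large maps and suppresses far-away false
matches — falling back to frame-to-frame chaining, and finally to
constant-velocity inheritance for featureless frames (both fallbacks are
reported as `tracked_from_previous`; the reported matched fraction counts
only `matched_to_map` frames, exactly). Rotation is reported in degrees
relative to the map's initial frame, wrapped to (−180, 180]. The overlay
draws the revisit path as a red polyline, per-frame positions as green
dots and per-frame orientation as blue arrows.

## Camera calibration

Planar (homography-based) calibration: DLT homographies per view with
Hartley normalization, closed-form intrinsics from the image of the
absolute conic, extrinsics from the decomposed homographies, then a joint
Levenberg–Marquardt refinement of intrinsics, distortion and per-view
extrinsics minimizing total squared reprojection error. The numeric
Jacobian exploits block sparsity (an extrinsic parameter touches only its
own view), which keeps refinement under a second for 20 views.

The distortion model is the standard 5-coefficient
$(k_1, k_2, p_1, p_2, k_3)$ vector, but $k_3$ is *fixed at zero by
default* (`free_dist`): the sixth-order term is unidentifiable from
checkerboard views at ordinary field coverage and only absorbs corner
noise — with it free, all other parameters recover almost exactly while
$k_3$ wanders by ±0.05. Fixing it is classic planar-calibration practice.
Checkerboard corners are found as Hessian-saddle points, refined to
sub-pixel by the gradient-orthogonality iteration, and ordered row-major
along the board axes via a max-area-quadrilateral homography with an
orientation-preservation check (mirrored labelings are rejected; the
180° symmetry of the board is resolved by first detection, which
calibration is invariant to). Undistortion maps each output pixel through
the forward distortion model and samples bilinearly; out-of-source pixels
are zeroed and excluded from the validity mask.

## The synthetic world

The generator emulates the things the algorithm actually relies on:

- a planar, vessel-textured surface (branching random-walk strokes,
  1.2–3 px wide, on a smoothly shaded mucosa-toned background,
  50 curves/megapixel by default — enough that any frame-sized crop
  passes the six-feature gate, a property the tests verify rather than
  assume);
- smooth scripted sweeps (serpentine, longitudinal, rotational) with
  bounded inter-frame motion (≤25% frame-width translation, ≤5°
  rotation, scale within [0.9, 1.1]) and ground-truth similarity poses;
- degradations on demand: circular vignette masks, Gaussian noise,
  lens distortion, featureless gray frames;
- checkerboard views rendered through a known camera (inverse-mapped
  through the lens model with 2×2 supersampling), with exact projected
  corner positions as the oracle. View poses deliberately cover the full
  image field: clustering boards near the center makes the radial
  coefficients mutually unidentifiable, a property of calibration
  geometry, not of the implementation.

What it does **not** emulate: surface curvature and perspective
foreshortening, specular highlights, fluid turbidity, illumination
falloff coupled to pose, non-rigid deformation of the bladder wall, or
sensor noise statistics of a real endoscope. A green test suite therefore
establishes that the pipeline recovers the motion model it assumes, on
textures with realistic feature statistics — not that it would survive
every artifact of clinical video.

All randomness descends from explicit integer seeds (scene seed,
trajectory seed, RANSAC seed); identical seeds give byte-identical
textures, frames and transforms.

## Numerical choices and degenerate inputs

- Bilinear interpolation everywhere (rendering, warping, undistortion,
  descriptor sampling); out-of-source samples are filled with 0 and
  marked invalid.
- RANSAC minimal samples closer than 2 px are rejected; singular or
  non-finite fits are skipped; a final non-singularity check guards the
  refit.
- Recoverable conditions (board not visible, feature gate, too few
  inliers, implausible scale) are typed values (`cm_failure`), not
  exceptions; genuine contract violations (empty sequences, size
  mismatches, singular transforms, identical calibration poses) are
  errors.
- Poses serialize as row-major 6-element arrays with an explicit
  convention string and schema version; JSON round trips agree to 15
  significant digits, canvas PNG bytes exactly.

## Known limitations

- The 2D similarity chain cannot represent a curved bladder exactly;
  long sweeps over strongly curved regions will show seams that no drift
  correction removes (elastic registration is out of scope).
- Drift correction is sequential per-closure relaxation, not a joint
  optimum; it provably reduces the injected-bias scenario but is not a
  pose-graph solver.
- The revisit matched-fraction depends on the revisit sweep staying
  inside the mapped region; frames beyond it are tracked, not matched.
- Video container decoding is not included (no decoder in the target
  environment); ingestion is from ordered image directories.
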