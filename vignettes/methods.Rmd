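---
title: "Calibration-free stereo pose reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration-free stereo pose reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereopose)
```

This vignette is the package's own account of its science: the geometric
model, the estimators and their numerical details, what every tunable
parameter means and why its default is what it is, what the synthetic test
bed does and does not emulate, and the design decisions that were genuinely
open.

## 1. Geometry

**Camera model.** Each camera is a pinhole with calibration matrix
$K = \begin{pmatrix} f_x & 0 & c_x \\ 0 & f_y & c_y \\ 0 & 0 & 1 \end{pmatrix}$
(pixels) and Brown–Conrady distortion $d = (k_1, k_2, p_1, p_2, k_3)$.
Projection of a world point: transform to the camera frame
($p_\mathrm{cam} = R\,p_\mathrm{world} + t$), perspective-divide, distort,
apply $K$. Pixel origin is the upper-left image corner, x right, y down.
Undistortion inverts the distortion polynomial by fixed-point iteration
(at most 20 iterations, tolerance $10^{-10}$ in normalized units). For
phone-lens-scale coefficients ($|k_1| \le 0.3$ over the portrait field of
view used here) the iteration contracts quickly; non-convergence is a
warning, not an error, and returns the best iterate. With zero distortion
the map reduces exactly to $((u-c_x)/f_x,\,(v-c_y)/f_y)$. Intrinsics are
supplied as configuration (per-camera YAML/JSON): estimating them from a
calibration pattern is standard practice and out of this package's scope,
and the virtual rig supplies exact ones.

**Epipolar constraint.** Normalized points of the two views obey
$\tilde{x}_1^\top E_{21}\, \tilde{x}_2 = 0$ with
$E_{21} = [t_{21}]_\times R_{21}$, where $p_{c1} = R_{21} p_{c2} + t_{21}$.
All geometry lives on normalized coordinates, so the essential (not
fundamental) matrix is estimated; the scale of $t_{21}$ is unobservable and
fixed to $\lVert t_{21}\rVert = 1$, which sets the arbitrary global scale of
the reconstruction. That scale is recovered later by the similarity
alignment, which is why the alignment must include a scale factor.

## 2. Robust self-calibration

`estimate_essential_lms()` estimates $E$ **once per recording** from
correspondences pooled over all frames and all 12 joints. The cameras are
static within a trial, so pooling maximizes the constraint set; per-frame
estimation would be both underdetermined (12 points) and needlessly
variable.

The solver is the 8-point algorithm with Hartley's isotropic conditioning
(translate each point set to its centroid, scale the mean distance to
$\sqrt{2}$), solved by SVD, followed by projection onto the essential
manifold: singular values replaced by $(\sigma, \sigma, 0)$ with $\sigma$
the mean of the two largest. Estimated matrices are Frobenius-normalized
with the sign fixed so the largest-magnitude entry is positive, making
estimates comparable across runs. A 7-point fundamental-matrix solver would
also be possible, but on normalized coordinates the 8-point solve plus
constraint projection is the simplest standard choice.

Robustness comes from **least median of squares**: `n_subsets` (default
2000) seeded random 8-point samples are solved, each candidate is scored by
the *median* Sampson residual over all correspondences, and the minimizer
wins. With the default subset count the probability that no all-inlier
sample is drawn at 20% contamination is about
$(1 - 0.8^8)^{2000} \approx 10^{-135}$ — effectively zero. The Sampson
residual (first-order geometric distance to the constraint manifold, in
squared normalized units) is used because the plain algebraic residual
weights points unevenly across the image. The winner is refit once on its
inliers: residuals within $2.5\,\hat\sigma$ of zero, with the robust scale
$\hat\sigma = 1.4826 \sqrt{\mathrm{med}\, r}$ — the standard
median-to-Gaussian-scale conversion. Degenerate 8-point samples
(rank-deficient design) are simply resampled.

Correspondences enter estimation only if **both** joints' visibility scores
are at least 0.5 (configurable). Detector visibility is reported in $[0,1]$
but no operating threshold comes with it; 0.5 splits the score range and, in
the synthetic model where dropouts draw visibility in $[0, 0.3]$ and valid
detections in $[0.9, 1]$, any threshold in $(0.3, 0.9)$ is equivalent. The
deliberately hard case — a gross mis-detection with *high* visibility, e.g.
background clothing confidently mistaken for a limb — passes this gate by
construction and is exactly what the LMS loop absorbs.

**Decomposition.** The SVD factorization yields four $(R, \pm t)$
candidates; every inlier is triangulated under each, and the candidate with
the most points in front of *both* cameras wins (cheirality). A tie signals
degenerate geometry and is an error rather than a silent guess.

## 3. Triangulation and the reference methods

`triangulate_dlt()` builds the standard $4 \times 4$ DLT system from the two
cross-product row pairs under $P_1 = [I\,|\,0]$,
$P_2 = [R_{21}^\top\,|\,-R_{21}^\top t_{21}]$ and takes the right singular
vector of the smallest singular value. A homogeneous $w$ below $10^{-12}$
marks the point invalid (at infinity) instead of producing a huge
coordinate. The reconstruction frame is the frontal camera's frame — the
frontal camera is the natural reference of the rig.

The **orthogonal combination** baseline assumes the cameras are exactly
perpendicular and simply takes $(x_\mathrm{front}, y_\mathrm{front},
x_\mathrm{lateral})$ per joint in normalized units. Only the x↔depth
exchange is defined by that construction; for the y-coordinate the frontal
camera's value is used rather than an average of the two views — the
simplest faithful reading, recorded here as an assumption. The construction
is exact in the orthographic limit and degrades under perspective, which is
precisely why it serves as the reference to beat.

The **monocular baseline** is emulated, not computed from a real single-view
3D estimator: ground truth expressed in one camera's frame, in-plane
coordinates perturbed at pixel-equivalent noise, and the depth coordinate
perturbed `mono_depth_sigma_scale` (default 5) times more strongly. It is a
stand-in with the one property that matters for the comparison — depth noise
dominating in-plane noise — and no claim to emulate any specific estimator's
error structure.

No temporal smoothing happens inside reconstruction; filtering is a separate
optional stage so filtered and unfiltered variants can be compared on
otherwise identical computations.

## 4. Filtering

Three smoothers are available per scalar channel, with invalid gaps linearly
bridged before filtering and re-masked after (the validity mask is never
altered by filtering):

* **Butterworth low-pass** (default: order 4, cutoff 2 Hz at 30 fps),
  applied forward–backward. The two passes square the magnitude response —
  amplitude $\approx 0.5$ at the design cutoff — and cancel the phase, so
  repetition peaks are not shifted in time. The implementation uses
  direct-form-II-transposed filtering with steady-state initial conditions
  (the state a constant input would produce) plus odd-reflection end
  padding, giving unit DC gain to machine precision without edge
  transients. A 2 Hz cutoff sits comfortably above the squat cadence
  (~0.3 Hz and its first few harmonics) while removing frame-rate detector
  jitter.
* **Moving average** (trailing window, default 5 samples). Implemented
  causal on purpose: one-pass averaging delays the signal by about half the
  window, visibly shifting the two sharp direction changes of each squat
  repetition — the delay artifact that motivates preferring the zero-phase
  Butterworth.
* **Savitzky–Golay** (default window 9, polynomial order 3), via
  `signal::sgolayfilt`.

`grid_search_filter()` scores each candidate by mean aligned RMSE against
ground truth and breaks ties toward `none`, then toward less smoothing; the
default grid is Butterworth orders {2, 4} × cutoffs {1, 2, 3, 4} Hz, windows
{5, 9, 15} for the moving average, and windows {5, 9, 15} × orders {2, 3}
for Savitzky–Golay. The exact grid is a package choice; it brackets the
useful cutoff range for movements with sub-Hz cadence.

## 5. Ground truth handling

Motion-capture markers sit on the skin surface while detector joints sit
inside the joint, so markers are harmonized to the 12-joint set by fixed
rules: single-marker passthrough (shoulders, wrists), the mean of a marker
pair (elbows, knees, ankles), or an axis composite (hips: x from the
anterior iliac marker, y and z from the trochanter marker). The right-ankle
pair is A27 + A29, mirroring the left side's A26 + A28. Trajectory gaps
strictly shorter than 100 samples with anchors on both sides are linearly
interpolated; longer gaps and edge gaps stay invalid — "strictly" is the
implemented reading of the threshold. Ground truth at 100 fps is resampled
to the 30 fps camera rate by linear interpolation at target timestamps
starting at $t = 0$; a resampled frame is valid only if both bracketing
source frames are. Streams are assumed to start simultaneously; an integer
`frame_offset` is available in the run configuration because hardware
synchronization details vary.

## 6. Evaluation metrics

`similarity_align()` is the closed-form least-squares similarity fit
(Umeyama's method) over all joint-frame pairs valid in both sequences,
pooled into one transform per recording. Reflections are forbidden
($\det R = +1$): a mirror-image "fit" would be geometrically meaningless
for a reconstruction that is already in a right-handed frame. The residual
RMSE — root of the mean squared Euclidean joint error — is the position
metric, directly comparable to MPJPE. Alignments with fewer than 3
non-collinear shared points are errors.

Joint angles are interior 3D angles at the vertex (arccos of the clamped
normalized dot product), invariant under any similarity transform — so angle
metrics are computed on the raw, unaligned reconstruction. Angle RMSE is
computed over frames valid in both trajectories.

`peak_summary()` reports the mean of the first $n$ repetition extremes
(default 3), found as local extrema with minimum prominence 10° and minimum
separation 1 s. For interior knee/hip angles the bottom of each squat is a
local *minimum* (the angle dips from ~175° standing to the bottom value), so
variant discrimination uses `troughs = TRUE`; the maxima convention is kept
for flexion-style signals. The prominence and separation defaults isolate
~10 repetitions per trial from detector noise: squat cycles are several
seconds long and tens of degrees deep, so 10°/1 s sits an order of magnitude
above noise while far below the signal.

`compare_methods()` is a two-sided **paired** t-test on per-recording scores
at $\alpha = 0.05$ — recordings are the natural pairing unit since every
method is evaluated on the same recordings. All-zero differences return
$p = 1$ by convention; a constant nonzero difference underflows to $p = 0$.

## 7. The synthetic test bed

`squat_scenario()` + `generate_squat()` produce deterministic ground truth:
each body side is a planar kinematic chain (ankle→knee→hip→shoulder, arms
hanging with a fixed 165° elbow), driven by a raised-cosine cycle between
standing and bottom-of-squat interior angles. Defaults (units: degrees, mm,
s):

| parameter | default | meaning |
|---|---|---|
| `reps` / `duration_s` | 10 / 30 | ten repetitions per trial; cadence = reps/duration |
| `fps` | 30 | camera frame rate |
| `standing_knee_deg` | 175 | interior knee angle at the top of the cycle |
| `peak_knee_flexion` | 40 (E1), 60 (E2/E3) | bottom knee = 180 − flexion: 140° vs 120°, a 20° variant gap |
| `trunk_lean_extra` | 15 (E2) | extra bottom hip flexion from the excessive forward lean |
| `lateral_shift` | 120 (E3) | peak lateral pelvis displacement, realised as a rigid frontal-plane lean about the feet centre |
| `knee_asymmetry` | 10 (E3) | extra right-knee flexion under the weight shift |
| `e3_hip_extra` | 10 | E3's bottom hip angle sits 10° below E2's |
| segments | trunk 500, thigh 420, shank 410, upper arm 280, forearm 250, shoulder width 380, hip width 320, ankle height 80 | adult-scale skeleton |

Driving the *interior angles* directly (rather than simulating dynamics)
makes the variant gaps exact in ground truth: the bottom-of-squat knee gap
between correct (E1) and incorrect (E2/E3) execution is exactly 20°, and the
hip gap between E2 and E3 exactly 10° — the configured discrimination
margins the evaluation must recover. The rigid frontal-plane lean for E3
preserves all interior angles, so the lateral-shift variant perturbs the
*geometry seen by the cameras* without perturbing the angle targets. One
knowing simplification: the shoulders sit 30 mm wider than the hips, which
tilts the trunk vector ~3° out of the sagittal plane and shifts all hip
interior angles by ~0.12° — identically across variants, so gaps are
unaffected.

The virtual rig defaults to the recording geometry the method is meant for:
portrait 1080×1920 at 30 fps, $f_x = f_y = 1400$ px, both cameras level at
1300 mm height, 2500 mm from the subject, 90° apart (frontal on the world
+z axis, lateral on the subject's right); generation fails if any joint
leaves either image. The noise model adds Gaussian pixel noise (default
σ = 2 px, a realistic detector jitter at this image scale), dropout
(probability 0.02; visibility drawn below the gate) and, optionally,
confident outliers (replaced position, visibility kept high). The outlier
probability defaults to **zero**: confident gross mis-detections come from
exceptional scene clutter rather than from ordinary detector noise, and
because they pass the visibility gate by design they dominate any per-frame
error metric; analyses of robustness switch them on explicitly (the
essential-estimation tests use 20% contamination).

**What the test bed does not emulate.** Real squat trajectories are not
raised cosines; real detector noise is temporally correlated, joint- and
pose-dependent and heavier-tailed than Gaussian; self-occlusion makes
lateral-view visibility systematically asymmetric; marker soft-tissue
artifact is absent; and the monocular baseline is a noise model, not an
estimator. Passing tests therefore demonstrate the correctness and the
relative behaviour of the geometric pipeline under controlled conditions —
not the absolute millimetre accuracy achievable on real recordings.

## 8. Numerical choices and degenerate inputs

* Conditioning: Hartley rescaling before every linear essential solve;
  rank-deficient sample designs are resampled; the final refit falls back to
  the LMS winner if its inlier design degenerates.
* Triangulation: homogeneous $|w| < 10^{-12}$ → invalid, not infinite.
* Angles: the dot product is clamped to $[-1, 1]$ before arccos; zero-length
  limb vectors give masked samples, not errors.
* Alignment: collinear point sets and sub-3-point overlaps are hard errors;
  the fitted scale must be positive.
* Undistortion: fixed-point tolerance $10^{-10}$ normalized units ≈
  $10^{-7}$ px at the default focal length — far below all evaluation
  tolerances.
* Determinism: every stochastic stage takes an explicit seed, uses it
  locally, and restores the caller's RNG state; equal seeds give
  byte-identical outputs.
* Problem sizes in the shipped tests and acceptance script: 300-frame
  (10 s, 3-repetition) trials, 500–2000 robust subsets, 10–20 Monte-Carlo
  seeds per comparison — sizes at which every statistical check is stable
  yet a full run stays fast on one CPU.

## 9. Known limitations

* One essential matrix per recording assumes static cameras; a bumped tripod
  mid-trial violates the model.
* The similarity alignment uses ground truth; absolute (metric) scale is not
  recoverable from the two uncalibrated views alone.
* Angle metrics inherit detector bias near repetition extremes, where
  overestimation concentrates.
* The CLI and pipeline process one recording at a time; multi-recording
  statistics (`compare_methods`) are assembled by the caller.
* Only two views are supported — no multi-view fusion, no bundle adjustment,
  no biomechanical constraints.
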