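---
title: "Automated 2D-3D vertebral image fusion: models, algorithm and design choices"
author: "autofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated 2D-3D vertebral image fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(autofuse)
```

## The problem

During endovascular aortic repair (EVAR), a preoperative CT angiogram can be
fused with live fluoroscopy so that the aorta and its branches are overlaid
on the X-ray image as a 3D roadmap. The registration that aligns the two
modalities is conventionally done by hand, by matching the vertebral column.
`autofuse` implements an image-based alternative: the lumbar column is
segmented from CT, converted to a digital X-ray projection (DRR), and an
affine pose — translations $T_x, T_y, T_z$ (mm), rotations
$R_x, R_y, R_z$ (degrees, applied as $R_z R_y R_x$ about the structure
centre), and an isotropic scale $s$ — is estimated per vertebra pair
(T12–L1, L2–L3, L4–L5) by maximising an edge-based similarity score in a
hierarchical global-then-local search. Alongside the registration the
package implements the accompanying measurement protocol (pigtail-marker
calibrated bone offsets $D_b$ and the vascular offset $D_v$ at the lowest
renal artery orifice) and the study statistics (median/min–max summaries,
Mann–Whitney U, two-way absolute-agreement single-measure ICC).

All coordinates are millimetres in patient LPS axes; the isocenter is the
world origin; the C-arm is a cone-beam model with source–isocenter distance
SID and source–detector distance SDD (magnification at isocenter
$= \mathrm{SDD}/\mathrm{SID}$); the primary angle is positive for LAO; the
detector $u$ axis is lateral and $v$ increases caudally. One rotation-centre
convention — the geometric centre of the CT volume, a fixed proxy for the
column centroid — is used by the simulator, the search, the feasibility
check and the measurement alike, so poses are comparable across all stages.

## The similarity score

The reported registration score is the Pearson correlation of the
mm-normalised gradient-magnitude (edge-strength) images of the DRR and the
fluoroscopy frame over the union of their edge masks (pixels above the
q-th percentile of nonzero strengths, default $q = 85$) within the region
of interest; it lies in $[-1, 1]$ and returns 0 on an empty union or a
constant strength field. Edge strength is used because the outer vertebral
edges are the most reliable structures in fluoroscopy, and correlation of
strengths is invariant to intensity offset and gain between the modalities.

Internally the search evaluates this score with two practical adjustments,
both symmetric in the two images so the maximum stays at the true pose:

* both images receive a light binomial smoothing before the gradient
  (1 pass at full resolution, 2–3 at the pyramid levels); without it the
  correlation basin of sharp cortical edges is narrower than the search
  lattice;
* at the pyramid levels (2x and 4x decimation), where the percentile masks
  contain only a handful of pixels, poses are *ranked* by the gradient
  correlation over a wide context window around the projected pair instead
  of the union-restricted correlation. All *reported* scores (global and
  local) are the union-based score at full resolution.

The pyramid uses grid-aligned decimation, not block averaging: retained
pixels sit exactly on the fine grid, so a DRR rendered on the coarse
template samples the same detector positions as the retained fluoroscopy
pixels; block averaging would smear one side of the correlation only.

## Global phase: column anchor, lattice, mirror starts

A lattice over the full seven-parameter default bounds at the default
coarse steps (8 mm, 4 degrees, 0.05) has on the order of $10^7$ nodes, and a
two-vertebra DRR is periodic in the craniocaudal direction at the vertebra
pitch, so a naive per-pair lattice both overruns any budget and aliases by
whole vertebrae. The global phase therefore:

1. anchors the *whole column* (the union of the pair masks, whose envelope
   is aperiodic — lumbar bodies widen caudally) on the coarse pyramid
   level with separable sweeps: the in-plane translation factorial at the
   nominal rotation, then the depth axis alone (depth mostly rescales the
   projection and is weakly observable from one view), capped by
   `maxEvaluations`;
2. scores the rotation lattice at the mid pyramid level (the heavily
   smoothed coarse level cannot separate mirror-image out-of-plane tilts)
   and, because an out-of-plane tilt and a translation error compensate
   each other, descends by coordinate descent from the sweep winner *and*
   from its out-of-plane mirror images, keeping the two best descended
   anchors;
3. refines each vertebra pair from each anchor at the mid level and keeps
   the candidate with the better full-resolution score.

Pairs are ranked by that score, ties broken by the fixed pair order
T12–L1 < L2–L3 < L4–L5 (and lexicographic parameter order inside the
lattice, which enumerates deterministically with $T_x$ most significant).
When the acquisition angulation is unknown, an optional primary-angle sweep
(e.g. RAO 30 to LAO 30) repeats the column anchor per angle and keeps the
best; with known geometry, as in all phantom experiments here, the sweep is
off.

## Local phase: variable step-size coordinate descent

From the selected global pose the seven parameters are cycled
($T_x, T_y, T_z, R_x, R_y, R_z, s$); each is probed at plus/minus the
current step, walking while the score strictly improves; after a full cycle
without improvement all steps shrink by the factor 0.5, stopping at the
minimum steps (0.1 mm, 0.1 degree, 0.001) or the evaluation budget. The
local phase runs two V-cycles, each a smoothed full-resolution gradient
correlation descent followed by a sharp union-score descent — the smoothed
pass is well-conditioned and wide, the sharp pass does the final
sub-millimetre centring, and the second cycle un-sticks plateau stalls. The
reported local score never falls below the global score it refines; every
accepted move of the final sharpening stage is logged (parameter, step,
value, score) so the monotone ascent is checkable.

## Feasibility: the visibility check

Clinically, automatic fusion fails when the vertebral edges run off the
image border. The package's programmatic analogue projects the selected
pair's mask silhouette at the selected global pose and requires every
silhouette boundary pixel to lie at least 2 px inside the frame. On
failure the result is flagged "manual adjustment needed" (CLI exit code 2)
and the local phase runs only from a user-supplied initial pose — the
analogue of the operator dragging the column to a rough match.

## The phantom: what it emulates and what it does not

`buildSpinePhantom()` emulates a lumbar T12–L5 CT at clinical resolution
(1 x 1 x 0.9 mm voxels, bone 700 HU on soft tissue 40 HU, segmentation
threshold 200 HU): each vertebra is an elliptic-cylinder body (lateral
semi-axis 17 mm growing 5% per level caudally, as lumbar bodies do — this
also breaks the pitch periodicity that otherwise makes vertebra counting
ambiguous), two posterior pedicle cylinders joined to the body, and a
posterior spinous-process fin whose lever arm gives the out-of-plane pose
components a projected signature, as posterior elements do clinically.
Sub-millimetre seeded lateral jitter desymmetrises the column. Ground-truth
lateral edge landmarks (left/right extremes of each body) feed the bone
caliper protocol.

`buildVesselTree()` supplies a gently curved aorta centreline with renal
orifice points on the wall; `simulateCase()` renders the fluoroscopy frame
at a known pose (so zero noise and zero truncation give a frame identical
to the DRR), adds Gaussian noise on the projected image (registration
consumes the 2D image, so noise belongs there), displaces the DSA position
of the lowest renal orifice by exactly the requested offset in a random
in-plane direction (vascular deformation by stiff devices), places pigtail
markers every 10 mm world distance along a catheter line at isocenter
depth, and can crop the *lateral* field-of-view border so a stated fraction
of the column silhouette falls outside the frame — the failure mode in
which vertebrae sit at the edge of the screen. Markers are carried as a
point list (and in the JSON sidecar), not burned into the image: they serve
the caliper-calibration arithmetic, and rendering them would add synthetic
edges unrelated to the method.

The phantom does not model soft-tissue clutter, scatter, detector blur,
scoliosis, or contrast dynamics; passing the recovery tests shows the
search machinery is correct and well-conditioned on clean anatomy, not that
the score is robust to every clinical confounder.

## Measurement protocol

`calibrateScale()` converts pixels to millimetres from the 10 mm pigtail
markers (least squares of cumulative distance against marker index for
three or more markers). Bone alignment is the per-side Euclidean offset
between corresponding lateral vertebral edge points, averaged left/right
per vertebra; correspondence comes from phantom ground truth or a user
annotation file — the package implements the caliper arithmetic, not edge
perception. Vascular alignment $D_v$ is the offset at the most caudal
projected point (distal edge) of the lowest renal orifice ring against its
DSA position; offsets are point-to-point distances in one image plane.

## Statistics

`medianMinMax()` reports order statistics with exact-decimal half-up
roundings (computed in tenths so 0.25 rounds to 0.3 and 4.85 to 4.9, the
arithmetic used in clinical tables; binary floating point `round()` would
give 0.2 and 4.8). `mannWhitneyU()` uses midranks, exact enumeration of all
arrangements when both groups have at most 7 observations, and otherwise
the tie-corrected normal approximation with continuity correction.
`iccAgreementSingle()` is the two-way absolute-agreement single-measure
ICC, $(MS_R - MS_E) / (MS_R + (k-1)MS_E + k(MS_C - MS_E)/n)$, with the
interpretation bands (> 0.85 excellent, 0.75–0.85 good, 0.40–0.75 fair,
below poor). `medianDifference()` is the absolute difference of the two
one-decimal-rounded group medians (the convention under which the packaged
tables' comparisons, 0.3 − 0.2 = 0.1 and 5.5 − 4.9 = 0.6, are exact); the
median of paired differences is available via `paired = TRUE`.

The packaged per-patient fixtures carry the printed cells verbatim. The
loader validates that each manual total equals the half-up rounded mean of
the two physician values and *reports* discrepancies rather than repairing
them: one bone-column cell is internally inconsistent in the printed table
(patient 4: physician values 0.9 and 0.2 against a printed total of 0.1),
which propagates to the physician-1 bone median and the bone ICC.
`reproduceSummaries()` marks the affected rows as known-inconsistent and
excludes them from its pass flag; all other summaries must match within the
rounding tolerance (0.05 mm; 0.005 for the ICC).

## Numerical choices and degenerate inputs

* DRR: trapezoid line integrals of $\max(\mathrm{HU} - 150, 0)/1000$ with
  trilinear interpolation; ray step 0.45 mm (half the finest clinical slice
  dimension) for rendering, twice that inside the search evaluator; a
  binary-mask mode integrates the interpolated indicator for silhouettes.
* Empty masks give empty silhouettes, not errors; constant images give
  zero edge strength and score 0; empty measurement lists and zero-variance
  ICC inputs are errors.
* Accuracy is stated in-plane: the in-plane translation error is the
  projected displacement of a reference point divided by the isocenter
  magnification, and the in-plane rotation error is the component of the
  relative rotation about the ray axis. Depth ($T_y$ in the AP view) and
  scale trade off almost exactly in a cone beam, and the out-of-plane tilt
  of a short two-vertebra segment is weakly observable from one view, so
  single-view claims about those components would be hollow.
* Determinism: all random draws are seeded explicitly (spec seeds, case
  seeds derived from the experiment seed); the search itself is
  deterministic, with lexicographic tie-breaking.

## Experiment sizes

The recovery experiment registers 20 noiseless, untruncated cases with true
poses sampled inside the default search bounds but within a field-of-view
preserving sub-range ($T_x \in [-15, 25]$, $T_y \in [-40, 40]$,
$T_z \in [-25, 25]$ mm, tilts within 8 degrees, $R_z \in [-1, 6.5]$,
scale within 3%): the printed clinical extremes (e.g. $T_z$ near −230 mm)
reflect table/scanner offsets that would place the column entirely outside
a 384 mm detector, where single-view registration is structurally
impossible and the visibility check (correctly) refuses. The cohort
experiment simulates 10 cases, 3 of them with a 20% lateral silhouette
crop, and reproduces the 7/10 feasibility pattern structurally. Simulated
frames are 384 x 384 px at 1 mm/px with SID 800 mm and SDD 1200 mm —
detector parameters are configurable, none of the claims depend on them.

## Known limitations

* The score definition (edge-strength correlation) is a reconstruction:
  the original system's score is proprietary and undocumented.
* Landmark correspondence for the bone caliper is ground truth or user
  annotation, never detected automatically.
* Only axis-aligned LPS volumes are read; DICOM, multi-frame DSA and
  deformable correction of the vascular overlay are out of scope.
* The three-times-faster server-side timings of the clinical deployment
  are not modelled; this package optimises for reproducibility on one CPU.
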