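---
title: "Planning vertebral implant corridors from 3D landmark points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning vertebral implant corridors from 3D landmark points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osic)
```

## The problem

Ventral stabilization of the canine atlantoaxial (C1–C2) joint requires
placing implants through extremely narrow bone corridors in very small dogs.
Most of these corridors run obliquely, so the classical single-plane
("transverse angle") description of a screw trajectory does not apply. This
package implements a semi-automated 3D planning method: each corridor is
simplified to a geometric solid with a well-defined centered axis, the
optimal implant is the segment of that axis between the ventral bone surface
and the far corridor boundary, and its 3D direction is summarized by two
projected angles measured in a per-vertebra anatomical coordinate frame.
Safety margins around the implant are summarized by four safety angles and
two corridor widths. All quantities are computed from labelled 3D
region-of-interest (ROI) points exported from a DICOM viewer — no image
processing is involved.

## Anatomical frames and projected angles

Each vertebra's frame is built from three ROI points placed in its sagittal
plane: an origin `O` and two points `A`, `B` spanning the in-plane reference
axis (`build_frame()`). The axes are

* `X = unit(A - B)` — the in-plane reference axis (for C2, the craniocaudal
  axis along the ventral border of the vertebral foramen, `A` cranial to `B`;
  for C1, the axis derived from the cranial border of the dorsal and ventral
  arches);
* `Y = unit((A - O) x (B - O))` — the sagittal-plane normal (mediolateral);
* `Z = X x Y` — completing the right-handed triad (ventrodorsal, pointing
  ventrally under the documented landmark placement).

The literature fixes the axis *line* but not its *sense*, so the two sign
conventions above are this package's documented choice; flipping a convention
flips the sign of the affected angles but not their magnitude, and magnitudes
are what the planning tables report.

An implant from insertion point `I` to exit point `E` is re-expressed in the
frame (`to_anatomical()`), giving components `(x, y, z)`. The three projected
angles are two-argument arctangents:

* sagittal ProjA = `atan2(z, x)`,
* dorsal ProjA = `atan2(y, x)`,
* transverse ProjA = `atan2(y, z)`.

Any two of them determine the direction; oblique sites are reported by the
(sagittal, dorsal) pair and strictly sagittal sites by the sagittal angle
alone. Transarticular C1–C2 implants are projected in the C1 frame. Internally
angles are signed; reports take magnitudes, matching the tabulated convention
in which left- and right-sided implants have equal-magnitude dorsal angles.

```{r}
frame <- build_frame(O = c(0, 0, 4), A = c(15, 0, 0), B = c(-15, 0, 0))
v <- to_anatomical(frame, start = c(2, 3, -4), end = c(9.2, 8.1, 1.5))
projected_angles(v)[c("sagittal", "dorsal")]
```

## Safety angles and corridor widths

A safety-margin point `S` marks where rotating the implant axis about `I`
becomes unsafe. The safety angle is measured in the plane spanned by
`E - I` and `S - I`:

```
SafA = alpha - beta,   alpha = angle(E - I, S - I),   beta = asin(r / |S - I|)
```

where `r` is the implant radius: `beta` is the half-angle subtended by a
circle of implant radius drawn around `S`, so `alpha - beta` is the rotation
available before the implant *surface* (not its axis) reaches the margin.
Negative values mean the corridor is locally narrower than the implant; they
are returned unclamped and flagged rather than truncated, because a clamped
zero would hide how infeasible a site is. The four safety points come in two
pairs lying in two orthogonal planes through the axis; `safety_angles()`
warns when the planes deviate from orthogonality by more than 5 degrees.

The corridor width in each plane is the sum of the perpendicular distances of
the pair's two points to the implant axis (measured along the common
in-plane perpendicular). The implant radius enters only the safety angles,
never the width. For strictly sagittal implants directed toward the vertebral
canal, safety points are placed at 75% of corridor length — a data-collection
rule enforced by the synthetic generator and documented for users, not
recomputed from images.

## Centered axes of simplified corridors

`centered_axis()` supports the three shape kinds used for the 13 catalog
sites: pyramids (axis through apex and base centroid), prisms (axis through
the two end-face centroids) and hemi-ellipsoids (principal axis of an
algebraic least-squares quadric fit, taken through the base-plane centroid
and oriented toward the dome). `simulate_optimal_implant()` then intersects
the axis with the ventral-surface and far-boundary point sets by
nearest-point projection. Degenerate inputs (collinear landmarks, zero-area
bases, rank-deficient fits, equal projections) raise typed errors rather than
returning unusable geometry. The per-site construction details of the
original workflow are not published, so the shipped catalog records the shape
kind, laterality, projection frame and reported angle pair per site as the
package's own convention; the constructors are generic and take whatever
labelled points the user supplies.

## Validation statistics

The packaged measurement table (`load_validation_table()`) holds the
gold-standard (mathematically calculated) and manually measured values of 2
ProjA and 4 SafA for 12 implants, measured by 2 observers twice. The
transcription was checked by recomputing every derived statistic the original
analysis reports. `validation_report()` reproduces them:

```{r}
rep <- validation_report(load_validation_table())
rep$concordance[, c("family", "value1", "value2", "n", "rho_c",
                    "tl_low", "tl_high", "bias", "p_value")]
```

Three methodological choices deserve explanation:

* **Concordance.** `lin_ccc()` uses the original population-moment (1/n)
  form of the concordance correlation; a sample-moment variant is an option.
* **Tolerance intervals.** The "95% tolerance interval" here is the
  two-sided normal tolerance interval with 95% content and 95% confidence,
  `mean(d) ± k·sd(d)` with Howe's factor
  `k = sqrt(nu (1 + 1/n) z² / chisq(0.05, nu))`. This is the only variant of
  the three implemented in `tolerance_limits()` that reproduces the published
  ProjA limits `[-1.23, 1.20]` and SafA limits `[-0.65, 0.70]` from the raw
  table; the prediction-style `t·sd·sqrt(1 + 1/n)` and plain `1.96·sd`
  variants remain available.
* **Difference orientation.** Gold-standard rows use `d = manual -
  calculated`; the repeat-vs-repeat and observer-vs-observer rows use
  `d = value1 - value2`, matching the signs of the published biases.

The paired location test is a two-sided paired t-test, consistent with the
normal-theory tolerance limits. Absolute-error summaries use the sample
standard deviation, which reproduces the published error grid. No
multiple-testing correction is applied (per-comparison p-values are
reported).

## The synthetic scene generator

`generate_scene()` builds scenes with exactly known ground truth, standing in
for the CT cohort that cannot be redistributed. The defaults *are* the study
conditions wherever those are stated, and otherwise a fixed realistic choice:

| parameter | default | why |
|---|---|---|
| `n_cases` | 12 | size of the validation sample |
| `implant_radius` | 0.75 mm | the 1.5 mm implant diameter used for SafA |
| `landmark_noise_sd` | 0.3125 mm | half the 0.625 mm CT slice thickness, the stated bound on placement error |
| `implant_length` | 10 mm | plausible Toy-breed corridor length (no coordinates are published) |
| `safety_offsets` | 2 mm | gives SafA ≈ 22°, mid-range of the validated sites |
| template size | landmarks within a 30 mm box | Toy-breed scale |
| pose | uniform rotations (quaternion method), translations ±100 mm | exercises rigid invariance, not realism |

Exit points are constructed as `E = I + L · dir(sagittal, dorsal)` where
`dir` realizes the prescribed projected angles, so recomputing angles from
noise-free points reproduces the prescription to 1e-9 degrees — the identity
the whole geometric pipeline is tested against. Safety points are placed at
prescribed perpendicular offsets in two orthogonal planes at mid-corridor
(75% for canal-directed sagittal sites), making true SafA and widths
available in closed form.

`perturb_landmarks()` adds isotropic Gaussian noise to the six frame
landmarks only, emulating operator variability in axis placement;
`landmark_error_experiment()` recomputes every site's ProjA under 4 replicate
landmark sets (2 virtual observers × 2 repeats) and analyses the quadruples
with `landmark_proja_analysis()`, whose per-item gold standard is the mean of
the 4 values — the same design as the original landmark-reproducibility
study. The raw data behind the original landmark study are not published, so
those printed values are reproduced qualitatively (orderings, collapse at
zero noise, monotone growth with noise), not numerically.

What the generator does *not* emulate: anisotropic (in-plane vs
through-plane) placement error, slice quantization of ROI coordinates,
anatomical variation between dogs, or subluxation displacement between C1 and
C2. Passing tests therefore demonstrate the correctness of the geometry and
statistics, and the qualitative error structure of landmark noise — not
clinical accuracy on real CT data.

## Numerical choices

* Collinearity of O/A/B is rejected below a triangle area of 1e-6 mm²,
  far below landmark-placement precision (~0.3 mm).
* Angles between vectors use `atan2(|u × v|, u·v)`, stable near 0° and 180°.
* The ellipsoid fit conditions the design matrix by centring and scaling
  before the SVD; rank deficiency is declared at a relative singular-value
  threshold of 1e-9.
* `safety_angle()` with `S` exactly on the axis returns `-beta` with a
  collinearity warning (the tangent construction is still defined; the planar
  angle is 0).
* Test problem sizes: the geometry oracles run on ≥ 1000 random
  configurations; the landmark-noise monotonicity check averages 200 cases
  per noise level (13 sites, 4 replicates each), which keeps the full suite
  under a minute on one CPU.

## Limitations

* The ROI points themselves are placed manually in the DICOM viewer; the
  package starts where the viewer's export ends. Automatic ROI placement and
  bone segmentation are out of scope.
* The sign conventions for the frame axes (and hence signed angles) are
  package conventions; only angle magnitudes are comparable to published
  planning tables.
* The transcription of the packaged validation table resolved a few cells
  that render ambiguously in electronic versions of the source table; the
  resolution was validated by reproducing all derived statistics, but those
  individual cells carry that caveat.
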