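---
title: "Left atrial 4D-flow biomarkers: models, corrections, and reproducibility statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left atrial 4D-flow biomarkers: models, corrections, and reproducibility statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laflow4d)
```

## The problem

ECG-gated phase-contrast CMR with three-directional velocity encoding
("4D flow") measures the blood velocity vector in every voxel of the left
atrium (LA) across the cardiac cycle. Several global hemodynamic biomarkers
derived from such data — peak and mean velocity, stasis, vorticity, vortex
volume, and the qualitative flow pattern — are candidates for stratifying
cardioembolic risk, because slow and disorganised atrial flow promotes
thrombus formation. Before such biomarkers can be used in studies or
clinics, two questions must be answerable with code: *are the biomarker
definitions implemented correctly*, and *how reproducible are the resulting
measurements across contours, observers, rescans, and time*?

laflow4d addresses both. It implements the biomarker definitions and the
velocity-data corrections they need, and pairs them with (a) analytic
phantom generators whose ground truth is known in closed form, and (b) the
statistical machinery of repeatability studies: the root-mean-square (RMS)
within-subject coefficient of variation (CV) with bootstrap inference,
Bland–Altman agreement, the two-way mixed intraclass correlation, McNemar's
test, and an agreement-based power calculation. Clinical acquisitions are
not distributable, so all validation runs against synthetic fields and
simulated measurement tables; what that does and does not demonstrate is
discussed at the end.

## Biomarker definitions

All biomarkers operate on a preprocessed velocity field `v(x, t)` (m/s) on
a voxel grid with spacing `h` (mm) and `T` cardiac frames of duration
`dt` seconds, within a boolean LA mask.

* **Speed** is the per-voxel Euclidean norm `|v|`.
* **Peak / mean velocity.** Per voxel, the temporal maximum and mean of the
  speed are computed first. The global mean velocity is the spatial average
  of per-voxel means. For the global peak the package defaults to the
  spatial average of per-voxel temporal peaks — a deliberate choice: the
  field convention computes per-voxel peaks but leaves the spatial
  reduction unstated, and averaging is robust to single-voxel noise. The
  single global maximum is available via `peak_reduction = "max"`.
* **Stasis** of a voxel is `n_stasis / n_tot`: the fraction of frames with
  speed *strictly* below a threshold (default 0.1 m/s). Global stasis is
  the mask average of the per-voxel proportions, in [0, 1]. The strict
  comparison makes the counts integer-exact and bit-reproducible.
* **Vorticity** is the curl magnitude `|curl v|` (rad/s), computed by
  central differences (one-sided at grid edges, spacing converted to
  metres), volume-averaged over the mask per frame. The scalar summary is
  the area under this vorticity–time curve over one cycle (rad), by the
  rectangle rule — frames are uniform-width bins of the cycle, so no
  higher-order quadrature is warranted.
* **Lambda2 vortex volumes.** Per voxel and frame the velocity-gradient
  tensor `J` is split into strain `S = (J + J')/2` and rotation
  `W = (J - J')/2`; lambda2 is the middle eigenvalue of `S^2 + W^2`
  (computed with the closed-form trigonometric eigenvalue formula for
  symmetric 3×3 matrices, vectorised over voxels). Vortex cores have
  lambda2 < 0. The vortex threshold is **half the mean of the negative
  lambda2 values** over all mask voxels and frames; a vortex voxel must be
  *more negative* than the threshold. Averaging only negative values is a
  declared resolution of an ambiguity: including non-negative lambda2
  values would dilute the mean toward zero and make the threshold
  trivially permissive. Per frame, vortex voxels form connected components
  under 26-connectivity (a stated determinism choice), and the largest
  component's volume (ml) is reported, with the cycle mean and the peaks
  within the systolic and diastolic frame blocks.
* **Flow patterns.** Pathlines are integrated from seed planes with classic
  RK4 (trilinear spatial, linear cyclic temporal interpolation) from their
  release frame to the end of the averaged cycle, terminating on grid exit
  or on crossing the mitral-valve plane. Clinical reading classifies the
  patterns visually; this package replaces the visual call with a declared
  quantitative proxy so contingency analyses are computable: per phase, the
  median absolute winding angle about the vertical axis through the mask
  centroid and the fraction of pathlines that reached the MV plane.
  `vortex` requires winding ≥ π and reach ≥ 0.5; winding without reach is
  `short_range_vortex`; anything else is `other`. Both thresholds are
  configurable; the winding-angle criterion itself is a package decision,
  not a published definition.

Units and coordinates are fixed package-wide: 0-based voxel indices, world
position = index × spacing (mm) at voxel centres, velocities in m/s,
frame `f` covering `[(f-1) dt, f dt)`, frames `1..mv_open_frame` systolic.

## Velocity corrections

* **VENC unwrap.** Velocities beyond ±VENC alias into `(-venc, +venc]`
  (the half-open convention is stated so wrap/unwrap round trips are
  exact). The unwrap scans frames in order per voxel and component and adds
  the multiple of `2*venc` that minimises the jump to the previous,
  already-corrected frame. This temporal scheme recovers any aliasing whose
  true inter-frame jumps stay below VENC and whose first frame is in range;
  spatial unwrapping is out of scope.
* **Eddy-current correction.** Background phase offsets vary smoothly in
  space; the standard stationary-tissue correction fits a low-order
  polynomial (order 1 by default, order 2 available) to the *temporally
  averaged* velocity over declared static voxels and subtracts the surface
  from all frames. Static-voxel selection on clinical data is an
  acquisition-specific problem and is an explicit input here.
* **Divergence-free denoising.** Blood is incompressible; measurement noise
  is not constrained to be. The package projects each frame onto its
  discretely divergence-free component in Fourier space using *modified
  wavenumbers* `sin(k h)/h`, which correspond exactly to the
  central-difference operators used everywhere else. The design was chosen
  over a mirror-padded projection after analysis showed that no reflection
  convention can make a padded projector simultaneously idempotent and
  transparent to rigid rotations: a vector-reflecting (sign-flipping)
  extension commutes with the projector but makes a rotation's extension
  discontinuous; a plain reflection preserves the rotation but breaks
  idempotence on crop-and-re-extend. The periodic modified-wavenumber
  projector has the properties the pipeline actually relies on, exactly:
  it is idempotent to machine precision, it passes any field with zero
  discrete divergence through unchanged (a rigid rotation is such a field,
  since each velocity component is constant along its own axis), the
  output's central-difference divergence vanishes at interior voxels, and
  per-frame mean flow is preserved. The trade-off is periodic wrap-around:
  for non-periodic fields the correction near the outermost voxel layers
  absorbs the seam mismatch, so guarantees are stated for interior voxels.
  Note what this step does *not* do: it removes only the curl-free third
  of white noise power, so it cannot reduce noise in the *vorticity* —
  only genuine smoothing (e.g. the wavelet shrinkage used by commercial
  tools) could, at the price of biasing the signal. The phantom conditions
  below are therefore designed so the vorticity noise floor is small
  relative to the signal, rather than pretending the projection denoises
  the curl.

## The phantom: what it emulates, and why these defaults

`make_phantom()` builds fields from closed-form primitives — uniform flow,
rigid rotation (curl magnitude exactly `2*omega`), and a Lamb–Oseen vortex
(tangential speed `Gamma/(2 pi r) (1 - exp(-r^2/r_c^2))`) — windowed by a
smooth cos² envelope that is 1 inside the ellipsoidal "LA" mask and decays
to exactly 0 at a configurable ellipsoid level (default 1.3). The envelope
gives the phantom what the eddy correction needs: genuinely static
background tissue. Ground-truth biomarkers are computed on the clean field
before corruption; `corrupt_field()` then applies the inverse of the
correction chain — i.i.d. Gaussian noise, a time-invariant affine eddy
offset, and VENC wrapping.

Default conditions (chosen once, from the physics, and documented rather
than revisited):

* grid 20³ at 6 mm isotropic, 20 frames × 50 ms (1 s cycle), MV opening
  after frame 8 — the temporal envelope of clinical atrial 4D-flow
  protocols. The spatial sampling is deliberately coarser than clinical
  (≈2.5 mm): noise `sigma` enters the finite-difference curl as
  `sigma/h`, so the voxel size controls the vorticity noise floor. With
  `sigma = 0.05` m/s and `h = 6` mm the folded-noise bias of the
  volume-averaged |curl| is `(sigma/h)^2 / (2*omega)` ≈ 2% of the signal
  at the default rotation rate.
* rotation rate 28 rad/s (volume-averaged vorticity 56 rad/s, within the
  range seen in atrial flow), VENC 1.2 m/s: fast enough for the noise
  floor argument above, slow enough that clean speeds plus the eddy offset
  stay inside the VENC envelope, which keeps any noise-induced aliasing
  isolated in time and hence recoverable by the temporal unwrap.
* noise SD 0.05 m/s and a few-cm/s affine eddy offset: plausible
  magnitudes for phase-contrast data; the true values are free parameters
  of the generator since acquisition noise is not printed in protocol
  descriptions.
* ellipsoid semi-axes 28 × 24 × 20 mm: a normal-sized LA; anatomic realism
  is deliberately not attempted (see Limitations).

The temporal profile multiplies the whole spatial field per frame
(separable space–time). That is adequate for biomarker oracles — it makes
AUC ground truth a closed form — but it cannot represent phase-dependent
flow reorganisation.

## The simulated reproducibility study

`simulate_study()` emits the long-format table of a scan1a/scan1b/scan2
design with a re-contour (intra-observer), a second observer
(inter-observer), a same-day rescan, and an interval scan: 64 SR and 22 AF
subjects by default, with group-specific biomarker population means.

Errors are multiplicative (`value = truth * (1 + e)`) because the RMS
within-subject CV is a proportional-error statistic. A single "error per
source" model cannot make all four contrast CVs hold simultaneously —
every measurement participates in several contrasts — so `e` sums four
independent zero-mean components: contour (SD `cv_intra`), observer
(`sqrt(cv_inter^2 - cv_intra^2)`), acquisition
(`sqrt(cv_rescan^2 - cv_intra^2)`), and visit
(`sqrt(cv_interval^2 - cv_rescan^2)`). Under this decomposition the RMS-CV
estimand of each named contrast equals its configured value exactly; the
decomposition requires `intra ≤ inter` and `intra ≤ rescan ≤ interval`,
which is validated and matches the ordering such studies report. Default
CVs (3%, 7%, 10%, 14%) are those of LA stasis, the least reproducible
biomarker, making the defaults the hard case. Interval-scan values are
additionally scaled by `1 + hr_effect * dHR` (default −0.005 per bpm:
a heart-rate drop raises stasis, the direction seen clinically).
Non-positive draws are resampled with a warning counter.

## Statistical definitions and choices

* **RMS within-subject CV** for pairs:
  `CV = sqrt( mean_i[ (d_i^2 / 2) / m_i^2 ] )` with `d_i` the pair
  difference and `m_i` the pair mean; reported as a proportion. Sessions
  with more than two replicates are out of scope. Confidence intervals are
  **percentile bootstrap** over subjects (1000 resamples by default) —
  percentile rather than BCa because the method is specified only as
  "non-parametric"; the choice is declared, and calibration is *tested*
  (95% CI coverage within [92%, 97%] at n = 74 over 200 replicates).
* **CV comparisons** bootstrap the difference of CVs: independently per
  group for independent contrasts, jointly over subjects (each draw carries
  both pair sets) for dependent ones, preserving dependence. 1000 and
  10000 resamples by default, respectively. The two-tailed p-value uses the
  add-one rule `2*min(#{Δ*≤0}+1, #{Δ*≥0}+1)/(B+1)`, capped at 1. Type-I
  behaviour of the dependent test is verified by simulation (rejection
  rate at the 5% level within [2%, 8%] over 500 replicates).
* **Bland–Altman**: bias ± 1.96 × sample SD (n−1) of differences.
* **ICC(A,1)**: two-way model, absolute agreement, single measures,
  `(MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE))`, with the F test
  `MSR/MSE` for p. On exchangeable (double-entered) tables it approaches
  Pearson's r with an O(1/n) gap — exact equality holds only
  asymptotically, and the tests assert exactly that.
* **McNemar**: exact two-tailed binomial on the discordant counts when
  `b + c < 25`, chi-square with continuity correction above; the switch
  point is a declared convention.
* **Stratified bootstrap Pearson**: the point estimate is pooled; resamples
  draw within strata (e.g. rhythm groups), preserving stratum sizes.
* **Spearman** uses average ranks and the t approximation for p.
* **Bonferroni** delegates to `stats::p.adjust`.
* **Agreement power** (`ba_agreement_power`) follows the
  normal-approximation framework of Lu et al. (2016): with expected bias
  `mu`, SD of differences `sigma`, and clinical agreement limit `delta`,
  the standard error of an estimated 95% limit of agreement is
  `sigma * sqrt(1/n + 1.96^2/(2(n−1)))`, and the power that both limits
  fall inside ±delta is `Phi(tau1) + Phi(tau2) − 1` with
  `tau_{1,2} = (delta ∓ mu − 1.96 sigma)/SE − z_{1−alpha/2}`. The
  commercial tool originally used for such calculations does not print its
  formula; this package asserts only the one-sided claim that n = 74
  reaches 90% power at the stated inputs (it computes ≈98.8%), not a
  specific minimum n. `ba_sample_size()` inverts the formula by search.

All seeded procedures save and restore the caller's RNG state, so
`seed = NULL` uses the ambient stream and an explicit seed is purely local.

## Problem sizes used in the tests

The suite exercises: 48³ voxels for the analytic oracle grid; the 20³ × 20
frame default phantom for round trips; n = 200 subjects for CV point
recovery; 200 replicates × 1000 bootstraps at n = 74 for CI coverage; 500
replicates × 1000 bootstraps for the dependent-test size; pathline
convergence at dt = 1/50 and 1/100 of a cycle. These sizes make every
stochastic criterion's Monte-Carlo error small relative to its acceptance
band while the whole suite stays desk-scale.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
library(laflow4d)

ph <- make_phantom(corruption = default_corruption())
pre <- preprocess_field(ph$field, ph$static_mask)
biomarkers <- extract_biomarkers(pre$field, ph$mask, patterns = FALSE)

rbind(truth = as.data.frame(ph$truth)[1:5],
      recovered = as.data.frame(biomarkers)[1:5])

tab <- simulate_study(study_design(seed = 1))
tab |>
  cv_pairs("stasis", "rescan") |>
  within_subject_cv(seed = 1) |>
  tidy()
```

## Known limitations

* The phantom establishes *correctness under the stated error model*, not
  clinical performance: it has no anatomic atrial geometry, no pulmonary
  vein jets, no flow-pattern variety beyond what its primitives compose,
  and its corruptions are Gaussian noise, affine offsets and wrapping —
  not k-space artifacts, segmentation error, or motion.
* The study simulator draws i.i.d. subjects with a fixed variance
  decomposition; it cannot express observer-by-subject interactions,
  drift between sessions, or non-Gaussian error tails. CV recovery there
  validates the estimators, not the biology.
* The flow-pattern proxy is a rule, not a radiologist; agreement with
  visual classification is untested by construction.
* The divergence-free projection enforces incompressibility but does not
  smooth; vorticity accuracy under noise therefore depends on the
  signal-to-noise conditions discussed above.
* Regional analyses (e.g. the atrial appendage), spatial unwrapping,
  Maxwell-term correction, and DICOM ingestion are out of scope.
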