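---
title: "Methods: quality, reliability and multi-site variability of diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality, reliability and multi-site variability of diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwivar)
```

## The problem

Diffusion-weighted MRI (DWI) studies that pool data from several scanners
face three entangled questions: is each acquisition of usable quality
(signal-to-noise, tissue contrast), are repeated measurements of the same
subject reproducible, and how much of the spread seen across a pooled cohort
is scanner- or vendor-induced rather than biological? `dwivar` implements
the computational core of such an assessment — configurable signal
operations, an adaptive model planner, a weighted-least-squares tensor fit
with validation maps, and the quality/reliability/variability statistics —
together with a synthetic multi-site generator with known ground truth, so
every stage can be verified end to end without any acquisition.

## Signal operations

**b0 drift normalization.** Long scans drift in intensity as gradients and
RF coils heat up. `normalize_b0_drift()` models the drift multiplicatively:
every volume is rescaled by `T / R(t)`, where `T` is the scalar mean of the
first contiguous group of b0 (unweighted) volumes and `R(t)` is
piecewise-linear in volume index between the scalar means of the b0 groups
bracketing volume `t`. Inside a b0 group the reference is that group's own
mean, so after normalization every b0 group lands exactly on the target and
a second application is the identity. Scalar (whole-volume or masked) group
means are used rather than voxelwise maps because they are robust to noise;
the price is that spatially non-uniform drift is not corrected. `before` and
`after` modes replace the interpolation by a single bracketing group for
acquisitions where b0s and diffusion blocks are far apart. For an exactly
linear drift and b0s anchoring both ends of the series, the round trip to
the drift-free signal is exact to floating-point precision — this is
asserted in the test suite.

**Powder averaging.** `powder_average()` is the voxelwise mean over all
diffusion-weighted volumes. Averaging over gradient orientations removes the
directional dependence of the signal and yields a WM/GM contrast that is a
more stable registration target than the b0. b0 volumes are excluded: they
carry no orientation, and including them would dilute precisely the contrast
the powder average exists to provide. For isotropic tissue the powder
average equals `S0 * exp(-b * MD)` in closed form, which the tests use as an
oracle.

**Shells.** `detect_shells()` clusters non-b0 b-values in one dimension,
splitting sorted values at gaps larger than a tolerance (default 50 s/mm²,
since scanners jitter nominal b-values by a few s/mm²). A volume is "b0"
when its b-value is below 50 s/mm² (scanner-reported residual values), also
configurable. Direction counts fold antipodal vectors together, because `g`
and `-g` probe the same diffusion direction; whether antipodal pairs should
ever count twice is debatable, and the folded reading is the conservative
one for model budgeting. `filter_shells_for_dti()` drops shells above
1300 s/mm² (configurable), where non-Gaussian diffusion invalidates the
tensor model.

**Transform composition.** Registration to diffusion space goes through a
template: `compose_anat_to_dwi()` returns `solve(T_dwi) %*% T_mid %*% T_t1w`
for affine transforms. Non-linear mid-space corrections belong to external
registration tools and are out of scope.

## Adaptive model configuration

**Spherical-harmonic orders.** A symmetric (even-order) real SH basis of
order `L` has `(L+1)(L+2)/2` coefficients, a full basis `(L+1)^2`. The
usable order is the largest `L` whose coefficient count does not exceed the
number of independent gradient directions; symmetric orders are additionally
floored to even, since the symmetric basis contains only even degrees. For
multi-shell samplings the order is computed per shell and the minimum is
selected (`sh_order_multishell()`), so the weakest shell bounds the basis.
Both closed forms are verified against brute-force maximization for
`n = 1..500` in the tests.

**Multi-compartment budgeting.** The full starting model for the
multi-compartment (DIAMOND-style) fit is 3 fascicle compartments, each a
6-parameter tensor plus a fraction, plus a 2-parameter free-water
compartment — 23 parameters, and hence a 23-direction minimum. When fewer
directions are available, `plan_diamond()` reduces complexity one step at a
time in priority order — lower the fascicle model (tensor → cylinder →
stick), drop to 2 fascicles, remove free water, drop to 1 fascicle —
re-checking the budget after each step and cycling back to the first
priority while still over budget. This one-step-per-priority cycling (rather
than exhausting each priority before moving on) is a deliberate reading of
the priority list: it sheds the cheapest complexity first at every level and
reproduces the intended worked cases (22 directions → 3 cylinders + free
water, 17 parameters; 6 directions → 1 cylinder, 5 parameters). The reduced
per-fascicle counts are declared constants: cylinder 4 (axial + radial
diffusivity + 2 orientation angles), stick 3 (1 diffusivity + 2 angles).

Above 23 directions, complexity is increased greedily in priority order —
raise the fascicle model, add restriction/hindrance estimation, add
fascicles — stopping before any step would exceed the direction count.
Because the starting model already uses the top fascicle model and the
maximum of 3 fascicles, the only increase available from the default start
is restriction/hindrance, budgeted at +1 parameter per fascicle (a declared,
config-exposed placeholder; the true increment depends on the downstream
fitting implementation), giving 26 parameters at ≥26 directions. Users can
force any configuration; forced plans are flagged, since the fitted model's
uniqueness is then no longer guaranteed. The minimal reachable model is one
stick fascicle (4 parameters); below 4 directions the plan carries an
infeasibility flag rather than erroring, so callers can decide.

**Resolution adaptivity.** Spatial parameters (smoothing windows, knot
spacings) are declared as dimensionless ratios and multiplied by the voxel
size at run time (`scale_parameter()`). For anisotropic voxels the default
is the per-axis vector; when the consumer needs a scalar, the minimum axis
is the declared reduction — the conservative choice for anything resembling
a smoothing extent.

## Tensor fit and validation maps

`fit_dti_wls()` fits `log S = log S0 - b g' D g` by ordinary least squares
on the log-signal, followed by one reweighting pass (configurable) with
weights equal to the squared predicted signal — the canonical
weighted-least-squares scheme, which undoes the noise amplification the log
transform causes at low signal. The fit is unconstrained; negative
eigenvalues are preserved in the coefficients but clamped to zero for the
scalar metrics (`FA`, `MD = mean(λ)`, `AD = λ1`, `RD = (λ2+λ3)/2`),
trading a guaranteed-SPD fit for transparency about where the data violate
the model. All-zero voxels are excluded and flagged rather than fitted.
Validation maps comprise the RMS fit residual, the per-voxel SD across
diffusion-weighted volumes (pulsation/misalignment artifacts), and the
physically-implausible mask: voxels where any diffusion-weighted intensity
exceeds the mean b0, which attenuation alone cannot produce.

## Quality statistics

**Noise.** With ≥2 b0 volumes, `estimate_noise_b0_pairs()` pools all
pairwise b0 difference maps within a mask and halves the pooled variance
(`Var(X−Y) = 2σ²` for i.i.d. images). Averaging the difference maps
themselves would cancel to zero by symmetry, so the pooled-variance reading
is the implementable interpretation; the factor-of-two correction is
config-exposed (default on). With a single b0, the noise SD is measured in
a background mask (`background_mask()`): an automatic Otsu
(between-class-variance) histogram threshold finds the foreground, which is
dilated by 3 voxels (configurable), complemented, and trimmed of a 1-voxel
field-of-view edge band; backgrounds under 100 voxels are refused. This
threshold is a declared surrogate for more elaborate background-extraction
techniques and is labelled as such in its output. Magnitude-image
backgrounds are Rayleigh-distributed, whose SD understates the Gaussian σ by
`sqrt(2 − π/2) ≈ 0.655`; an optional flag applies the correction, and the
raw SD remains the default.

**SNR and CNR.** `snr()` is the mean b0 intensity in a tissue mask over the
noise SD; `cnr()` is `|μ_WM − μ_GM| / sqrt(σ²_WM + σ²_GM)` on the b0. The
denominators are standard deviations — the only dimensionally consistent
choice for a ratio to a mean intensity. A documented behavioral difference:
the pair-difference SNR is invariant to a constant intensity offset inside
the mask (offsets cancel in differences), while the background SNR is not.

## Reliability and variability statistics

**I2C2.** The image intraclass correlation coefficient is
`1 − MS_within / MS_total`, with
`MS_within = Σ_s Σ_j Σ_v (I_sj(v) − Ī_s(v))² / Σ_s (N_s − 1)` over subjects
with ≥2 sessions and `MS_total = Σ (I_sj(v) − Ī(v))² / (N − 1)` over all
images. This trace-ratio estimator with degrees-of-freedom normalization
reduces to the classic intraclass correlation for a single voxel; for the
generator's additive model it converges to `σ²_subject / (σ²_subject +
σ²_within)`, which the tests verify at 20 subjects × 3 sessions × 1000
voxels over 20 seeds (absolute error ≤ 0.05 at targets 0.8, 0.5 and 0.0).
Evaluation is mask-restricted when the stack carries a mask. When all
images are identical the ratio is 0/0 and the value is defined as 1 with a
warning.

**Coefficients of variation.** Each session image is summarized by its mean
within the tissue mask; `cv()` is the sample SD over the mean of a group of
summaries. `cv_report()` evaluates four nested groupings: intra-subject
(IS, per subject over its sessions; MIS is their mean), between-subject per
site (BS), intra-vendor (IV) and between-vendor (BV) — the latter three over
session-averaged subjects, so repetition noise does not inflate
subject-level spread. Whether the CV should be voxelwise or over per-image
summaries is genuinely open; per-image mask means are the default (robust,
and matching the per-tissue reporting granularity), with a voxelwise mode
(`mode = "voxelwise"`) behind a flag for sensitivity analysis. Groups with
fewer than two members are skipped with a message, never silently averaged.

**Session separation.** When repeated sessions cluster by acquisition time
point rather than subject, a shared session effect dominates.
`session_separation()` computes a one-way variance ratio (between-session
over within-session mean square) on the per-image summaries, dropping
subjects that lack the full session set. Its null expectation is about 1
for i.i.d. summaries; with strong subject effects the repeated-measures
structure deflates it below 1, so it is a diagnostic for *session-dominated*
variance, not a calibrated test statistic.

## The synthetic generator: what it does and does not emulate

`simulate_dwi()` produces `S = S0_tissue * exp(-b g' D_tissue g)` on nested
ellipsoids (WM core, GM shell, CSF rim), scales each volume by a linear
multiplicative drift factor, and applies Rician corruption
`sqrt((S+ε1)² + ε2²)`. Default tissue constants are canonical literature
values — WM tensor diag(1.7, 0.3, 0.3)×10⁻³ mm²/s, GM isotropic 0.8×10⁻³,
CSF isotropic 3.0×10⁻³; S0 0.7 / 1.0 / 2.0 — giving realistic FA/MD/b0
contrast. Directions come from a seeded-rotated Fibonacci sphere lattice,
whose minimum angular separation beats uniform-random sampling.
`simulate_metric_study()` draws the hierarchical model
`I = μ + β_site + b_subject + e_session + ε_voxel` with independent Gaussian
effects and returns the drawn effects for recovery tests. The default
multi-site layout uses three sites on two vendors (4/6/4 subjects, 3/2/2
sessions) with a two-shell 250/1000 scheme, a single shell at 1600 s/mm²
(above the DTI ceiling, exercising the applicability logic) and a dense
single shell at 1000 s/mm².

Deliberately not emulated: susceptibility, eddy-current and motion
artifacts, multi-coil (chi-squared) noise, partial-volume boundaries,
realistic anatomy, and spatially correlated noise. Passing tests therefore
demonstrate correctness of the statistics and operations under their stated
models — not robustness to the full artifact spectrum of in-vivo data,
whose correction belongs to the wrapped external tools upstream of this
package.

## Numerical choices and problem sizes

Log-fits clamp the signal at `max(S) * 1e-12` to avoid `log(0)`; a
reweighting solve that turns singular falls back to the previous iterate for
that voxel. Eigenvalues are computed per voxel by symmetric
eigendecomposition and reported in descending order. All randomness is
seeded explicitly, and `set.seed` calls restore the caller's RNG state, so
two identical runs produce bit-identical reports — asserted end to end.
Test problem sizes are deliberately modest so the full suite runs
interactively: 16³–48³ phantoms, 20 subjects × 3 sessions × 10³ voxels for
reliability recovery, 100 seeded replicates for the CV ordering property,
and a 24³ default grid for `run_study()`.
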