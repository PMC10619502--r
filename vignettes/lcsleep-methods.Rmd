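---
title: "Methods: locus coeruleus imaging, sleep EEG energies, and the association pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus coeruleus imaging, sleep EEG energies, and the association pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsleep)
```

`lcsleep` implements a quantitative chain that links a structural/functional
measure of the locus coeruleus (LC) — a small noradrenergic brainstem
nucleus visible as a hyperintense tube on magnetization-transfer-weighted
7T MRI — to habitual sleep quality. The chain has three computational
stages (LC contrast extraction, overnight EEG energy metrics, moderated
association statistics) plus a synthetic-data module that provides ground
truth for every stage. This vignette records the models, the tunable
parameters, and the design decisions taken where the underlying procedure
left genuine freedom.

## 1. LC contrast from a neuromelanin-sensitive volume

**Model.** Given a 3D intensity volume and a binary LC mask per side, the
mask is *skeletonized*: on each axial slice intersecting the mask only the
in-mask voxel with the highest intensity is kept. For skeleton slice $i$,
with $LC_i$ the intensity of that voxel and
$\overline{\mathrm{pons}}_i$ the mean intensity of a 15 × 15-voxel square
reference region placed anteriorly and centrally in the pontine tegmentum
of the same slice, the per-slice contrast is

$$ C_i = \frac{LC_i - \overline{\mathrm{pons}}_i}{\overline{\mathrm{pons}}_i}, $$

the side contrast is the arithmetic mean of $C_i$ over skeleton slices,
and the participant-level LC contrast is the mean of the left and right
side contrasts. The contrast is dimensionless, invariant to global
intensity rescaling, and may legitimately be negative.

**Design decisions.**

* *Per-slice normalization, then averaging.* The alternative — a ratio of
  slice-averaged numerator and denominator — is not equivalent under
  slice-to-slice coil-sensitivity variation. The per-slice form follows
  directly from defining the contrast slice-wise and is what the slice
  subscript $i$ implies; it is the implemented and tested behaviour.
* *Argmax ties* break to the smallest in-plane coordinate pair in
  row-major order, which is deterministic and platform independent.
* *Reference centers are user input* (per-slice coordinates). Anatomical
  placement of the pontine square is a judgment call that we do not
  automate; an automatic placement heuristic would silently encode
  anatomy the caller should control.
* *No partial squares, no silent slice dropping.* A reference square
  clipped by the grid, or a mapped slice without a center, aborts the
  computation: dropping slices would bias the slice mean, and a partial
  square would change the estimator.
* *A non-positive reference mean is an error* — the normalization is
  undefined there, and real MT-weighted intensities are positive.
* Inputs are assumed co-registered on a common grid; registration and
  up-sampling belong to upstream preprocessing tools and are out of
  scope. Voxel coordinates are 1-based grid indices (R convention).

`contrast_density()` summarizes a cohort's contrasts with a Gaussian
kernel density (Silverman bandwidth unless fixed), for distributional
inspection.

## 2. Sleep metrics and cumulative band energies

**Architecture metrics** come from a 30-s epoch hypnogram restricted to
epochs fully inside the lights-off window: total sleep time (TST, minutes
of non-wake), sleep onset latency (lights-off to the first non-wake
epoch), sleep efficiency (100·TST/time-in-bed) and REM percentage of TST.
Sleep onset is defined as the *first epoch of any non-wake stage*; no
stage-specific (e.g. first-N2) rule is imposed, and the choice is
documented in the run manifest. REM metrics add REM onset latency (first
sleep epoch to first REM epoch), the number of arousal *events*
overlapping REM epochs (events, not epochs, are counted), and REM episode
durations, where an episode is a maximal run of REM epochs optionally
merging gaps up to a configurable window (default 0 = strict runs).

**Spectral estimator.** Band powers use Welch's overlapped-segment
estimator with the sleep-lab convention: 4-s Hamming-windowed segments
with 2-s overlap, on a 200 Hz frontal EEG channel. The one-sided density
scaling makes the integral of the PSD over the full band an estimate of
the signal variance; a unit-amplitude sinusoid integrates to
$A^2/2 = 0.5\ \mu V^2$. Both properties are asserted in the test suite,
together with agreement against an independent full-length periodogram
oracle.

**Cumulative energies.** Slow wave energy (SWE) is the cumulated
overnight 0.5–4 Hz power during slow wave sleep; REM theta energy is the
cumulated 4–8 Hz power during REM. The record is cut into 30-min bins
anchored at lights-off. Within a bin, band power is the mean over *clean*
4-s segments (aligned to epoch starts, 2-s step) of the target-stage
epochs; a segment is clean only if it overlaps no arousal or artifact
annotation at all (strict exclusion). The bin contributes

$$ \text{clean mean} \times \frac{\#\,\text{stage epochs in bin}}{\#\,\text{epochs per bin}} $$

and the energy is the sum over bins. The stage-time weighting is the
"adjustment for the proportion of rejected data": rejected spans neither
inflate nor deflate the sum, which the tests verify by comparing a
half-artifact record against its clean twin (within 5%). A config flag
(`adjust = FALSE`) gives the simpler unadjusted clean-mean sum for
comparison. Bins that contain stage epochs but no clean segment are
flagged and excluded with a warning rather than imputed. A record with no
target-stage epoch yields an explicitly undefined (NA) energy.

**Choices worth naming:** SWS defaults to stage N3 only (`swe_stages`
accepts `c("N2","N3")` for a broader NREM definition); bins are anchored
to lights-off, not to sleep onset; epochs partially outside the
lights-off window are excluded entirely; the caller selects one EEG
channel (averaging frontal derivations is upstream of this package).

## 3. Association statistics

**Moderated regression.** Each sleep outcome is regressed on LC activity,
a binary age-group moderator, their interaction, and covariates (sex,
BMI; TST additionally for the two cumulative-energy outcomes, whose value
grows mechanically with time in stage). One observation per participant
makes a participant random intercept unidentifiable — it is confounded
with the residual — so the model is a fixed-effects `lm`/`glm`; this
replaces the mixed-model phrasing a repeated-measures design would
warrant, and is recorded prominently here. The family defaults to
gaussian with an optional log-link Gamma for right-skewed positive
outcomes; the family in effect is recorded in the report.

Internally the moderator is coded $-\tfrac12/+\tfrac12$ so that the
predictor main effect is the average of the group slopes and the
interaction coefficient is their difference; per-group *simple slopes*
are linear contrasts $\hat\beta_x \pm \tfrac12\hat\beta_{x\times g}$ with
t statistics from the contrast variance, and are invariant to the
moderator's reference level. Effect sizes use the partial
$R^2 = F \cdot df_1 / (F \cdot df_1 + df_2)$ convention so results are
comparable across models; with 1-df terms $F = t^2$.

**Multiplicity.** The six primary models (subjective sleep quality, sleep
onset latency, efficiency, REM%, SWE, REM theta energy) contribute one
p-value each to a Benjamini–Hochberg step-up at $q = 0.05$. The FDR
family defaults to the six *interaction* p-values — the moderation is the
primary claim — and can be switched to the predictor main effects
(`fdr_on = "predictor"`). `bh_fdr()` is tested against an exhaustive
brute-force evaluation of the step-up rule and `stats::p.adjust`.

**Mediation.** `mediation_analysis()` implements the counterfactual
decomposition for linear mediator and outcome models, the outcome model
optionally containing an exposure-by-mediator interaction:
controlled direct effect $\mathrm{CDE}(m^\*) = (\theta_1 + \theta_3 m^\*)\Delta$,
pure indirect effect $\mathrm{PIE} = (\theta_2 + \theta_3 x_0)\beta_1\Delta$,
total effect $= \mathrm{PNDE} + \mathrm{TNIE}$. Choices: the CDE
reference $m^\*$ is the covariate-adjusted mediator mean; the exposure
contrast is $x_0 = \bar X$, $x_1 = \bar X + s_X$ (percent-of-total
figures are invariant to the contrast width when the interaction is
absent); inference is nonparametric case-resampling bootstrap with
percentile CIs and a mandatory seed, with at least 200 replicates.
Cumulative-energy mediators are analysed on the square-root scale
(`transform = "sqrt"`) to meet the linearity assumption. A near-zero
total effect flags the percentages as unstable instead of returning them
silently. Without interaction the PIE reduces exactly to the
product-of-coefficients $a\cdot b\cdot\Delta$, which the tests assert to
$10^{-6}$; when testing recovery of a planted no-interaction mediation
the analysis model is fitted without the interaction term, matching the
generating model.

**Sensitivity.** `sensitivity_min_effect()` inverts the noncentral-t
power function of the test of one predictor in multiple regression
(ncp $\sqrt{n f^2}$ with $f^2 = r^2/(1-r^2)$, residual
df $= n - k - 2$ for $k$ covariates) with `uniroot` at tolerance
$10^{-12}$; the achieved power at the solution equals the target to
$10^{-6}$. One-sided tests use the one-tailed critical value; two-sided
tests use $|t|$. Both the 3- and 4-covariate df conventions are
supported via `n_covariates`; the default is 4 (group, sex, BMI, TST).

## 4. The synthetic-data module: a stated world

The generators are pure functions of (spec, seed) — identical inputs give
bit-identical outputs — and every generator returns a ground-truth record
sufficient to predict each downstream result without rerunning it.

* **Phantom volumes** emulate the geometry of a high-resolution LC slab
  (0.4 × 0.4 × 0.5 mm voxels): two one-voxel-per-slice centerlines at a
  planted intensity on a uniform pontine background, a partial-volume
  ring at 60% of the step, optional additive Gaussian noise, and masks
  built by in-plane dilation of the centerline (radius 1, which
  guarantees the centerline is the in-mask maximum at small noise). With
  zero noise the analytic contrast
  $(I_{LC} - I_{bg})/I_{bg}$ holds exactly on every slice.
* **Hypnograms** fix stage counts from target proportions by
  largest-remainder rounding (realized proportions within one epoch per
  stage), lay REM out in bouts, and place 10-s arousal and 4-s artifact
  intervals uniformly. Default proportions (10% W, 5% N1, 45% N2, 20% N3,
  20% REM over 480 min in bed) describe a healthy adult night.
* **EEG** is synthesized per contiguous stage run as a sum of band-limited
  Gaussian noise components with *sample-exact* band variances plus a
  white floor — chosen over AR fits to real EEG because the band powers
  are then analytically known. Artifact spans are multiplied by 10: an
  unambiguous signature whose content is irrelevant, because artifacts
  are excluded by annotation, not detected. The default per-stage band
  powers (e.g. 200 µV² delta in N3, 20 µV² theta in REM) are plausible
  frontal-scalp placeholders, *not* calibrated to any cohort — no
  per-stage spectral levels are available to calibrate against. The
  generator makes no attempt at real EEG morphology (spindles,
  K-complexes, 1/f slopes): a green spectral test establishes correct
  energy accounting, not realism.
* **Cohorts** default to the emulated study design: 33 younger and 19
  older participants, ~80% women, BMI within screening bounds, TST
  around 7 h. The outcome is a continuous PSQI-like score — the integer
  questionnaire score is deliberately not rounded, so that zero-noise
  recovery of planted coefficients is exact. The mediator (REM theta
  energy) is generated on the squared scale so the square-root transform
  is exercised downstream. The exposure-to-mediator path `a` applies in
  the older group only: a single coefficient then plants both the
  group-specific interaction on REM theta energy and a mediation
  structure confined to the older subsample, where the mediation analysis
  is performed. All planted effects default to zero, making the null
  cohort the type-I-error reference world (calibration is tested over
  1000 replicates against the 99% binomial band of $\alpha = 0.05$).

## 5. Pipeline, formats, determinism

`run_pipeline()` executes contrast → sleep metrics → cohort → statistics
from a single config (an R list or JSON file; JSON stands in for YAML
because no YAML parser is available in the target environment). Exactly
one source — generator spec or file path — is allowed per input block,
and a seed is mandatory whenever a generator is used. Volumes and masks
travel as NIfTI-1 (a minimal float32 reader/writer is built in, verified
against an independent implementation); hypnograms, annotations, EEG
traces and cohort tables travel as documented CSV dialects (EEG carries
its sampling rate in a header comment; EDF input is not supported in
this environment). Every output file is stamped with a config hash and
the seed, no timestamps are written, and a rerun with an identical
config reproduces all outputs byte for byte — asserted in the test
suite. The exported functions are the interface; there is no separate
shell binary.

## 6. Known limitations

* The fixed-effects stand-in for the mixed-model phrasing is exact only
  for the cross-sectional one-row-per-participant design.
* The partial $R^2$ convention and the FDR-family choice (interaction
  p-values) are assumptions where the emulated analysis was
  underspecified; both are recorded in the run manifest and
  configurable.
* The rejected-data adjustment is the stage-time weighting described
  above; other published adjustment variants exist and can be
  approximated with `adjust = FALSE`.
* Synthetic EEG band levels are placeholders; absolute energy values are
  not comparable to any real cohort, only their accounting properties
  are.
* Mediation p-values are bootstrap-percentile based; with 19 older
  participants (the emulated subsample size) they are exploratory, as
  the wide planted-world bootstrap intervals in the tests illustrate.
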