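---
title: "Methods: traffic-light acceptance of predicted joint moments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: traffic-light acceptance of predicted joint moments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momentqc)
```

## Scope and data model

`momentqc` judges whether model-predicted lower-extremity joint moments from
clinical gait analysis are clinically usable, and whether that judgement can
be anticipated from kinematics alone. The unit of analysis is one side of
one subject during the stance phase of gait, time-normalised to 60 samples
spanning foot strike to foot off (0-indexed grid 0..59 in the interchange
files). Left and right sides are independent records throughout: clinical
stance events are identified per side, and treating sides separately keeps
every downstream statistic a plain i.i.d. computation. Whether both sides of
a patient should enter a given analysis is a cohort-assembly decision left to
the caller (the synthetic generator has a `paired_sides` switch).

Angles are degrees, moments Nm/kg. Only the sagittal plane is modelled:
pelvic tilt, hip flexion/extension, knee flexion/extension and ankle
dorsi/plantarflexion, plus hip/knee/ankle flexion-extension
(dorsi-plantarflexion) moments. The interchange format is a long CSV
(`subject_id, side, variable, sample_index, value`) with a JSON mirror;
measured and predicted moments are distinguished by the `_meas`/`_pred`
suffix on the variable name. Raw traces of any length are brought onto the
canonical grid by `resample_stance()`, linear interpolation on a uniform
parameterisation — the standard time-normalisation of gait curves, exact at
the endpoints and shape-preserving (no overshoot, unlike spline schemes).
No motion-capture ingestion (C3D, marker trajectories, event detection) is
implemented; analysis starts from time-normalised curves.

## Step 1 — thresholds and labels

Prediction error per joint is the normalised root-mean-square error

$$\mathrm{nRMSE} = \frac{\sqrt{\tfrac{1}{60}\sum_t (m_t - \hat m_t)^2}}
                        {\max_t m_t - \min_t m_t},$$

with $m$ the lab-measured and $\hat m$ the predicted moment. Normalising by
the *measured* curve's peak-to-peak amplitude (not the combined range of both
curves) keeps the denominator independent of the prediction being judged;
this choice is configurable in principle but deliberately not exposed, since
a prediction-dependent denominator would let a bad prediction shrink its own
error.

The acceptance band is anchored on the standardised peak moment

$$\mathrm{MaxMom}^* = \frac{\max_t m_t - \overline{m}}{s_m},$$

the within-trace z-score of the peak ($s_m$ = sample sd over the 60
samples), computed from the measured trace of each record and joint. Two
readings of this definition are possible — a within-trace z-score, or a
cohort-level standardisation of peak moments — and the definition alone does
not disambiguate. The per-trace reading is adopted because (a) it makes the
statistic a property of a single trace, defined without reference to any
cohort, so a single new patient can be labelled; and (b) it accounts both
for the peak load and for how the moment is distributed across stance
(a peaky trace tolerates proportionally more absolute error than a flat
one). It is dimensionless and invariant under constant shifts and positive
rescaling of the moment, so the resulting thresholds inherit the
unit-free character of nRMSE.

The lower and upper kinetic limits are fixed fractions of it:
$\mathrm{LKL} = 0.10\,\mathrm{MaxMom}^*$,
$\mathrm{UKL} = 0.20\,\mathrm{MaxMom}^*$. The 10%/20% defaults reflect the
reported range of joint-moment measurement error in test-retest reliability
studies (SEMs of roughly 12-25% of peak moment) and are configurable
(`lkl_fraction`, `ukl_fraction`, with `lkl_fraction < ukl_fraction`
enforced).

Labels: **Green** strictly below LKL, **Red** strictly above UKL, **Yellow**
otherwise. Boundary ties go to Yellow — "smaller than LKL" and "bigger than
UKL" are read as strict inequalities, and the cautious middle class absorbs
the measure-zero boundary cases. A constant measured trace makes both
MaxMom* and nRMSE undefined; such records are excluded and logged rather
than imputed, because a flat physiological moment cannot occur and signals
corrupt input.

## Step 2 — kinematic profiling

Per record, each kinematic curve is summarised by MAX, ROM (max − min) and
MEAN (MIN is computed internally for ROM but not reported), and the Gait
Profile Score is the RMS over variables of the per-variable gait variable
scores (RMS deviation from a typically-developed reference mean curve over
the 60 samples). The GPS variable set defaults to the four sagittal
variables — the package's canonical inputs — but the functions are
set-agnostic: the conventional wider set (nine variables minus foot
progression, which is customarily excluded) can be supplied when the curves
and the reference cover it. With one of $k$ variables offset by a constant
$d$, GPS $= d/\sqrt{k}$, which is the closed form the tests pin.

The stance is split into five equal 12-sample bins for the subphase error
profile, standing in for initial contact, loading response, mid stance,
terminal stance and pre-swing. Named clinical subphases have no canonical
boundaries on a normalised stance axis, so the equal partition is the only
reproducible choice; the bin count is configurable. Subphase nRMSE keeps the
*full-stance* peak-to-peak denominator: per-bin ranges can be near zero in
mid stance and would explode the statistic. This makes the decomposition
exactly conservative: the width-weighted mean of squared bin values equals
the squared full-curve nRMSE (asserted at 1e-10 relative tolerance).

Label validity is tested with classic equal-variance one-way ANOVA over the
per-label nRMSE groups plus pooled-variance pairwise t-tests, Bonferroni
corrected: for three labels the corrected threshold is 0.05/3, reported at
three decimals as 0.017 per clinical convention. Welch variants are
available by flag but are not the default, matching the named tests.
The comparison is run per joint (each joint's labelling is a separate
experiment with its own groups).

## Step 3 — feasibility classification

The feature vector is {MAX, ROM, MEAN} × 4 sagittal variables plus GPS
(13 features; GPS inclusion is a flag). The classifier is linear
discriminant analysis implemented in the package (class means, pooled
within-class covariance with $n-k$ divisor, empirical priors, discriminant
$\delta_c(x) = x^\top\Sigma^{-1}\mu_c - \tfrac12\mu_c^\top\Sigma^{-1}\mu_c +
\log\pi_c$); `MASS::lda` serves only as an independent oracle in the test
suite. Empirical rather than uniform priors are deliberate: under the heavy
Green dominance typical of this problem, prior-weighted LDA predicting
almost everything Green is the behaviour the confusion tables show, and
uniform priors would misstate the deployment base rates. Exact score ties
break to the earlier class in factor order (Green before Yellow before Red).
A ridge of $10^{-8}\times$ the mean diagonal is added to the pooled
covariance only when it is numerically singular (e.g. duplicated features);
this is deterministic and leaves predictions on well-posed problems
untouched. One LDA is fitted per joint on the same kinematic inputs, and a
single 80/20 split (uniform by default, stratified by flag, explicit
`train_count` supported) is shared across joints.

Reports give the confusion table, accuracy, and one-vs-rest precision,
recall and F1 per class, with zero-denominator metrics reported absent
(printed "-") rather than zero. `prf_from_counts()` exposes the same
arithmetic directly on printed marginals so published tables can be
re-derived without a full confusion matrix. The Green+Yellow merge rescores
the pooled relabelling — clinically, "not unacceptable" — and is where
imbalanced per-class metrics consolidate.

## The synthetic cohort: a stated world

The generator exists so that every stage is testable without clinical data.
Its defaults state the world it emulates and are not tuned to test outcomes:

* **Severity** $\in [0,1]$, uniform by default (beta optional): an abstract
  crouch-severity axis.
* **Kinematics**: fixed low-order Fourier templates (harmonics of period 2
  over the stance parameter, so curves need not be periodic across stance)
  whose severity-0 MAX/ROM/MEAN sit in ranges plausible for a mildly
  involved CP cohort; coefficients were chosen once, by hand, on that
  criterion. Severity deforms them by construction: knee MEAN +15°, hip ROM
  −10°, ankle MAX −10° (an equinus-like downward shift) at severity 1, plus
  smooth subject noise (random 3-harmonic Fourier series scaled to a 4°
  pointwise sd — between-subject spread, intentionally below the 6-8°
  clinical feature sds since severity itself contributes the rest).
* **Moments**: a biphasic extensor-to-flexor hip template, a knee
  flexion-extension wave, and an ankle moment rising to a plantarflexor
  peak ≈1.4 Nm/kg near 70% stance, with multiplicative amplitude jitter
  (sd 0.1, ankle peak clamped to [1.0, 1.8] Nm/kg).
* **Prediction error**: smooth random Fourier noise added to the measured
  moment and rescaled so nRMSE hits the drawn target exactly (machine
  precision; the 1e-6 acceptance tolerance is slack). Optional subphase
  weights concentrate error in chosen bins.
* **Tiers**: drawn per record × joint from per-joint base probabilities
  (defaults 0.84/0.15/0.01 hip, 0.60/0.33/0.07 knee, 0.50/0.40/0.10 ankle —
  the label populations reported for CP cohorts). Severity coupling is a
  mean-zero probability transfer in the severity quantile (mass moves from
  Green to Yellow/Red in proportion to their base shares), so for coupling
  ≤ 1 the marginal tier frequencies equal the base probabilities exactly
  while P(Red) rises monotonically with severity — letting one stated world
  satisfy both the frequency checks and the severity-Red association.
* **Targets**: by default drawn *relative* to the record's own limits
  (Green in [0.30, 0.90]·LKL, Yellow in LKL + [0.15, 0.85]·(UKL−LKL), Red in
  [1.20, 2.50]·UKL), making tier recovery by the labeller exact and never
  flagged. In `absolute` mode targets come from fixed nRMSE bands
  (0.05-0.12 / 0.15-0.25 / 0.30-0.50) and records whose per-trace thresholds
  contradict the drawn tier are flagged in the ground truth; recovery is
  asserted at 100% off the flags.
* **Reproducibility**: the master seed draws one per-record seed vector;
  each record is generated under its own seed, so cohorts are
  bit-reproducible and a record does not depend on how many precede it.

What the generator does *not* emulate: correlation structure between
kinematic variables beyond the shared severity factor, asymmetry between
sides, real CP gait subtypes (jump, stiff-knee, equinus proper),
non-Gaussian measurement artefacts, or any behaviour of an actual
moment-predicting network. A green end-to-end test therefore establishes
that the pipeline's statistics behave as designed under the stated world —
not that any particular model's clinical accuracy is reproduced. Published
per-label feature values and GPS magnitudes from clinical cohorts are out of
reach by construction (the reference here is the severity-0 template, not a
lab's typically-developed cohort); only monotone trends are meaningful.

## Numerical choices and degenerate inputs

* Sample (n−1) standard deviations throughout.
* Quartiles use R's default (type 7) quantile.
* CSV round trips write 17 significant digits and canonicalise record and
  variable order, so write∘read is the identity and repeated writes are
  byte-identical.
* Degenerate (constant) measured traces error at the point of computation
  and are excluded-and-logged at cohort level.
* `split_cohort` restores the caller's RNG state; all generator randomness
  is derived from explicit seeds.

## Known limitations

Frontal/transverse kinetics, GDI/MAP summaries, cross-validated classifier
tuning and non-parametric label comparisons are out of scope. The
per-trace reading of the standardised peak and the measured-only nRMSE
denominator are documented defaults where the underlying definitions admit
alternatives. The LDA assumes a shared covariance across labels, which the
per-label feature sds suggest is only approximately true; it is kept for its
interpretability and small-sample robustness.
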