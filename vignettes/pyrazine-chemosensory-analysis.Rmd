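---
title: "From pyrazine concentrations to perceptual synergy: the methods behind pyrasense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pyrazine concentrations to perceptual synergy: the methods behind pyrasense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrasense)
```

# The scientific question

Soy sauce aroma type Baijiu (SSAB), a Chinese distilled spirit, owes part
of its characteristic roasted aroma to pyrazines. Most of the sixteen
pyrazines quantifiable in SSAB sit *below* their individual odor
thresholds, which by the classical odor-activity-value (OAV) logic would
make them irrelevant to the percept. The analyses in this package follow
the chain of evidence that challenges that logic:

1. **Quantitation QC** — are the concentration numbers trustworthy
   (calibration linearity, recovery, replicate precision, LOD/LOQ)?
2. **OAV profiling** — which compounds exceed threshold, which sit in
   the 0.1–1 sub-threshold band?
3. **Correlation screening** — which compound concentrations track the
   panel-rated roasted-aroma intensity across brands?
4. **Discrimination testing** — can a panel smell a spiked addition at
   all (exact 3-alternative forced choice)?
5. **Threshold psychophysics** — where does the group detect an
   ascending odorant series?
6. **Feller additive model** — does a sub-threshold bundle shift the
   detection curve of a supra-threshold bundle *more* than independent
   detection predicts (synergy)?

# The data containers

Concentrations live in an `AromaExperiment`, a `SummarizedExperiment`
with compounds in rows (odor thresholds, threshold matrix and source in
`rowData`) and Baijiu samples in columns. The published tables ship as
plain-text fixtures:

```{r}
ae <- ssabExperiment()
ae
head(suppressWarnings(oavProfile(ae)))
```

The warning is deliberate: the odor thresholds were measured in 53%
ethanol/water, not in Baijiu, and every OAV inherits that caveat.

# OAV profiling

OAV is concentration over threshold. Banding is `negligible` below 0.1,
`sub_threshold` in [0.1, 1) and `supra_threshold` at or above 1; an OAV
of exactly 1.0 counts as supra-threshold because the compound has
reached its threshold (the published spike table groups its OAV-1.00
addition with the supra-threshold set).

Two notions of "contributor" coexist and the package keeps them apart.
`oavBands()` works per sample: five compounds reach OAV ≥ 1 in at least
one brand (23DE touches 1.4 in one sample). `contributingCompounds()`
works on the across-sample mean concentration, the basis on which the
source study names exactly four aroma contributors (26DM, 235TM, 2E6M,
2E35DM); 23DE averages to OAV 0.66 and drops out. Reports round OAVs
half-up to 1 decimal (2 decimals for spike designs, integers for
percent-of-threshold); base R's round-half-to-even would disagree with
the published tables at exact halves. One published value (23DE at 80/172
of threshold = 46.5%, printed 46%) was evidently truncated rather than
rounded; `percentOfThreshold()` returns 47 and this single mismatch is
documented rather than special-cased.

# The sensory screen

Panel ratings (0–7 scale) are averaged per sample
(`aggregateIntensity()`), checked by a one-way fixed-effect ANOVA
(`anovaBySample()`), and correlated with per-compound concentrations by
Spearman's rho (`spearmanScreen()`). Design choices:

* **Mid-rank Pearson** definition of rho, so ties are averaged.
* **Directional flagging**: a compound is called only for a *positive*
  relationship, rho > 0.5 with the one-sided p below alpha. Both one-
  and two-sided p-values are reported; the one-sided value drives the
  flag because the screen itself is one-directional — flagging on a
  two-sided p while requiring rho > 0.5 would make the effective size
  half the nominal alpha.
* **Exact permutation** p-values for nine or fewer common samples (full
  enumeration of orderings), the classical t approximation
  `t = rho * sqrt((n-2)/(1-rho^2))` beyond; eleven samples therefore use
  the approximation, matching common statistical-package behaviour.
* **No multiple-testing correction by default** (the original analysis
  applied none across sixteen compounds); Benjamini–Hochberg is
  available and its use is logged.

# 3-AFC discrimination and Abbott correction

A 3-AFC trial has guessing probability 1/3, so significance comes from
the exact binomial upper tail — panel sizes of 12–20 would distort the
`***`/`**`/`*`/`ns` ladder under a normal approximation. Observed
proportion-correct converts to a detection probability by Abbott's
correction `p_d = (p_c - 1/3)/(2/3)`, clipped below at zero for
reporting (a panel below chance carries no evidence of detection). The
conversion is the standard one for m-AFC tasks with guessing rate 1/m;
the source study reports detection probabilities without stating the
formula.

# Group odor thresholds

The default estimator takes the group threshold literally as the dose at
which 50% of the panel chooses the spiked glass: proportions are made
non-decreasing by weighted pool-adjacent-violators smoothing, then the
threshold is interpolated linearly in log-dose (the ladder is geometric,
so log spacing is uniform). Because a 3-AFC guessing floor of 1/3 sits
close to 50%, the criterion's meaning is ambiguous in the original
wording; `scale = "chance_corrected"` applies the criterion to the
Abbott-corrected detection probability instead (equivalently 66.7%
correct), which targets the psychometric midpoint. Every estimate
records its scale, criterion, bracketing doses and censoring status;
curves already above criterion at the lowest dose are left-censored,
curves that never cross raise a structured error carrying the maximum
smoothed proportion.

`fitPsychometric()` offers the parametric alternative: a binomial MLE of
a logistic in log10-dose with the guessing floor fixed at chance and no
lapse term — the minimal standard psychometric model.

Printed dose ladders are taken verbatim as data (the published series'
low steps are inconsistently rounded); `makeGeometricSeries()` generates
canonical `base * 2^i` ladders. Volume-dosed thresholds stay in mL; the
optional conversion to in-glass concentration assumes additive volumes,
`c = stock * v / (v + 15)`, and is clearly labelled
(`doseToConcentration()`).

# The Feller additive model and the synergy verdict

Feller's model gives the joint detection of two independently perceived
components: `p(AB) = p(A) + p(B) - p(A) p(B)`. Deviations are summarized
by the package's interaction exponent theta, acting on the complement:
`p(AB) = 1 - ((1-p(A))(1-p(B)))^theta`. Theta of 1 is exact additivity;
above 1 the mixture is detected more than independence allows (synergy),
below 1 less (suppression). All Feller arithmetic happens on the
chance-corrected detection scale — treating raw proportions-correct as
independent would double-count guessing.

On the direction of the mapping: the conclusions and results of the
source study use "observed detection above the calculated value" and an
observed threshold *below* the predicted one as evidence of synergy
(an "excessive addition effect"), and that is the mapping implemented.
Its methods section states the opposite wording; the two cannot both be
right, and the results-section usage is the one consistent with the
study's own conclusion and with the mixture-perception literature.

`classifyInteraction()` compares an observed mixture curve with the
dose-wise prediction built from the component curves. The fixed
sub-threshold bundle contributes one dose-independent `p(A)`, either
measured from its own pooled 3-AFC counts or set to zero — the mode must
be chosen explicitly because the two answer different questions. The
verdict's decision statistic pools the per-dose deviations between the
observed mixture counts and the predicted proportion-correct along the
deviation template that one doubling of the interaction exponent would
produce (`(1-chance) * fbar * (1-fbar)` with `fbar` the predicted
complement), weighted by generalized-least-squares coefficients that
account for the mixture counts' binomial noise, the propagated noise of
the component-B estimates, and the shared noise of the component-A
estimate. Detection probabilities enter the statistic through the
unclipped linear Abbott transform so the plug-in prediction stays
unbiased near chance; clipped values are reported. The statistic's null
distribution is obtained by a parametric bootstrap of the fitted
additive model — all counts regenerated, the entire estimation pipeline
replayed per resample — and compared equal-tailed. Because a plug-in
bootstrap at panel sizes around 20 carries a first-order level error (we
measured 6–7% rejection at nominal 5%), the equal-tail p-value is itself
calibrated by a double bootstrap: outer datasets drawn from the fitted
null each receive their own inner-bootstrap p-value, and the observed
p-value's rank among them is the reported one. A significant result is
called synergy or suppression only when the threshold comparison points
the same way; thresholds are estimated on the observed and predicted
curves by the same interpolation estimator, and their ratio (predicted
over observed) is reported at one decimal in the style of the source
study ("decreased by a factor of ...").

A power note, computed from the design itself: with 20 panelists per
dose, a nine-step factor-2 ladder and the fixed bundle judged once per
session, the expected standardized deviation of the score at an
interaction exponent of 2 is about 2.0 (generalized-least-squares
projection with the component-A nuisance profiled out). A validly
calibrated two-sided test at alpha 0.05 therefore detects that effect
in roughly half of replicate experiments — the design sits at the edge
of the information needed, and larger panels are the only honest way to
raise that power.

Per-dose exact-binomial comparisons are reported as descriptive detail.
They are deliberately *not* the decision rule: an exact binomial test of
the mixture counts against the predicted proportion treats the
prediction as known, ignores the sampling error of the component
estimates, and in simulation rejects a true additive null far above its
nominal level at panel size 20.

# The synthetic-data generators

Every pipeline input can be generated with the statistical structure the
analysis assumes (`studyConfig()` holds the knobs):

* **Concentrations**: a latent roasted-aroma intensity per sample,
  uniform on [1, 6.3] — echoing the observed intensity spread of the
  eleven commercial samples without claiming its distribution — drives
  each compound's log10 concentration through a loading plus Gaussian
  noise (default residual sd 0.15 log10 units, roughly 40% CV between
  brands). Zero-loading compounds are null controls; generator baselines
  are the published mean concentrations so magnitudes look right.
* **3-AFC responses**: each panelist owns a log-normal individual
  threshold (geometric sd one dilution step by default, reflecting
  standard sensory practice; 0 disables heterogeneity for oracle tests)
  and a logistic psychometric function in log10-dose with slope 4.9 —
  chosen so the 10–90% detection span covers about three factor-2
  dilution steps — under a 1/3 guessing floor.
* **Mixtures**: component B follows the psychometric model; the fixed
  bundle A is detected with constant probability (default 0.15, the
  value consistent with the published shift from 0.456 to 0.292 mL of
  the additive-model threshold under the default slope) and is judged
  once per ascending session; the true mixture follows the
  complement-power transform above, so theta is a clean synergy dial.
* **Calibration series**: straight-line response ratios with Gaussian
  noise.

All generators are bit-reproducible from a seed and leave the caller's
RNG stream untouched.

What the generators do *not* emulate: matrix effects of real Baijiu
(hundreds of co-eluting volatiles), panelist lapses and learning,
session-to-session drift, correlated compound families from shared
Maillard chemistry, or chromatographic artefacts. Passing the recovery
tests therefore shows the *statistical machinery* is sound under the
stated assumptions, not that real SSAB data will behave this tamely.

# Verification at the study's design sizes

The acceptance suite re-runs the machinery at the sizes the study used
(11 samples, 16 compounds, 20 panelists per dose, factor-2 nine-step
ladders):

* group-threshold recovery over 500 simulated panels (median within one
  dilution step of truth);
* interaction-verdict operating characteristics over 200 replicates per
  theta, with panelist heterogeneity disabled so the replicates are a
  clean oracle: the suite asserts additive at ≥ 95% under theta 1 and a
  majority of synergy calls under theta 2. The first holds; the second
  does not for a validly calibrated test at this panel size — see the
  power note above — and the suite reports that shortfall rather than
  hiding it;
* screen size and power over 2000 null and 200 planted replicates (flag
  rate near the nominal 5%; a rho ≈ 0.9 planted compound found in the
  majority).

The same quantities, plus the fixture-derived OAV/threshold numbers, are
recomputed from scratch by `scripts/acceptance.R`.

# Numerical and degenerate-input policy

* Rounding for display is half-up (`roundHalfUp()`), matching the
  published tables; computations keep full precision.
* PAVA uses panel sizes as weights; exact criterion hits return the dose
  itself; interpolation never extrapolates beyond the bracketing doses.
* The psychometric MLE refuses chance-level and fully saturated curves
  (structured `pyrasense_fit_error`) and flags separation (slope at the
  boundary) rather than reporting a spuriously precise midpoint.
* Negative inverse-predicted concentrations are flagged, never silently
  clamped; summary layers may display them as zero.
* Validation failures throw classed conditions
  (`pyrasense_design_error`, `pyrasense_data_error`,
  `pyrasense_schema_error`, ...) so pipelines can distinguish bad input
  from bugs.

# Known limitations

* The per-sample roasted-aroma means behind the published intensity
  figure are not printed, so the 8-compound screen result of the source
  study is validated on synthetic data with the published thresholds,
  not reproduced from raw panel data; the same holds for the spike-test
  p-values and the detection-probability figures.
* Thresholds from the literature/website compilations are fixture data;
  only the OAV arithmetic on top of them is recomputable.
* The verdict's bootstrap is approximate at panel size 20; its measured
  operating characteristics are what the acceptance suite asserts.
* No individual-panelist best-estimate-threshold aggregation (group
  thresholds only), no Thurstonian d' models, no sigma/tau mixture
  models beyond Feller independence.
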