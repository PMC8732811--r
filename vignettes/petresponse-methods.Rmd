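---
title: "Quantitative PET response assessment: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative PET response assessment: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petresponse)
```

# The problem

Serial FDG-PET is the standard tool for judging whether a solid tumor is
responding to systemic therapy. Under immune checkpoint inhibitors (ICIs)
this judgement is harder than under cytotoxic therapy: immune infiltration
can mimic progression, and multicenter cohorts mix scanners whose
reconstructions yield systematically different standardized uptake values
(SUV). `petresponse` implements the full quantitative chain for this
setting: per-lesion metric extraction from voxel grids, cross-scanner
harmonization by Gaussian filtering, classification of each patient's
baseline-to-follow-up change under three rule sets (EORTC, PERCIST,
imPERCIST), and the comparison statistics — weighted Cohen's $\kappa$,
percent agreement, Kaplan–Meier survival and log-rank tests.

Because clinical PET images cannot be redistributed, the package ships a
synthetic phantom and cohort generator with the statistical structure the
analysis assumes, so every stage is testable end to end.

# Lesion metrics

All metrics operate on a `voxel_grid`: a 3-D SUV array with anisotropic
voxel spacing in mm. Volume-of-interest membership is
*voxel-center-in-region* with no partial-volume weighting — a deliberate
simplification that makes every metric exactly reproducible by exhaustive
enumeration, which the test suite exploits.

* **SUV~max~** — hottest voxel in the lesion VOI.
* **SUV~peak~** — mean over a 1.2-cm-diameter sphere placed at the hottest
  site. "Hottest site" is operationalized as an exhaustive search over all
  candidate sphere centers (every voxel center in the lesion VOI),
  maximizing the sphere mean; centering on the hottest voxel is available
  as a cheaper fallback (`placement = "max"`).
* **SUL~peak~** — SUV~peak~ scaled by lean body mass over total body mass.
  LBM uses the sex-specific James formula (weight in kg, height in cm),
  the formulation associated with the original SUL definition, clamped to
  at most total body weight so SUL $\le$ SUV always.
* **MTV** — volume of VOI voxels at or above 40% of the lesion SUV~max~,
  restricted to the 26-connected component containing the hottest voxel.
  The connectivity restriction prevents background speckle inside a
  generous VOI from inflating the volume.
* **TLG** — SUV~mean~ $\times$ MTV, with SUV~mean~ taken over the MTV
  voxels (the 40% isocontour). Whether the mean should run over the
  isocontour or the whole VOI is genuinely ambiguous in the field; the
  isocontour is the default because it makes the recorded worked-example
  product (MTV 2.22 mL $\times$ SUV~mean~ 4.50 $\approx$ TLG 10.0) come
  out within input rounding, and the whole-VOI variant adds nothing the
  threshold fraction parameter cannot express.
* **Liver reference** — per-voxel SUL mean and SD over a 3-cm sphere on
  the normal right lobe. Two derived thresholds matter downstream: the
  complete-response comparator `mean + 2 SD` and the measurability floor
  `1.5 * mean + 2 SD`.

# Harmonization

Cross-scanner harmonization is modeled as post-reconstruction Gaussian
filtering at a scanner-specific FWHM (`scanner_profiles()` carries the
built-in table; scanners without an entry pass through unchanged). The
proprietary phantom-calibration software used in practice summarizes its
output as exactly such a per-scanner FWHM, so direct filtering is the
faithful desk-scale emulation.

The filter is a separable convolution with **Lindeberg's discrete
Gaussian kernel** $T(n, t) = e^{-t} I_n(t)$, $t = \sigma^2$ in voxel
units, rather than a sampled continuous Gaussian. The discrete Gaussian
forms an exact semigroup: filtering at $f_1$ then $f_2$ equals one pass at
$\sqrt{f_1^2 + f_2^2}$ up to kernel truncation (observed error
$\sim 10^{-12}$, against a tolerance of $10^{-4}$), which a sampled kernel
only approximates at these sigma-to-voxel ratios. Boundaries are
mirror-extended (half-sample symmetric), which conserves the global voxel
sum exactly for a symmetric kernel. Consequences used as invariants: the
global maximum never increases, uniform fields are fixed points, and FWHM
0 is the identity.

One property deserves care: **MTV stability under filtering**. For a 3-cm
uniform sphere on a *cold* surround — the standard sphere-phantom
configuration — the 40%-of-max adaptive threshold recovers the sphere
volume to within 10% at every built-in FWHM (0–5.5% in simulation). On a
*warm* background (SUV 1 around a contrast of 7) the absolute threshold
sits below the blurred edge value and the isocontour inflates by up to
roughly 20% at FWHM 8.6 mm. The stability tests therefore use the
cold-surround configuration; users thresholding lesions embedded in high
background should expect MTV to grow under smoothing.

# Response criteria

Each patient is a `scan_pair`: baseline and follow-up lesion tables, an
injective lesion identity map (follow-up lesions without a counterpart are
new-lesion candidates), the follow-up liver reference and a background
activity level. All three classifiers return one of the ordinal categories
CMR < PMR < SMD < PMD plus the rule that fired and the percent change
$100 (f - b)/b$ of the relevant sum.

**Target selection.** At most five lesions, at most two per organ, ranked
by the criterion's metric (baseline SUV~max~ for EORTC, per-scan SUL~peak~
for PERCIST), ties broken by lesion id. These caps form a truncated
partition matroid, so the greedy ranking provably attains the same sum as
exhaustive enumeration — the suite checks this directly against a
brute-force oracle.

**EORTC** sums SUV~max~ of the *same* lesions across scans
($\pm 25\%$ thresholds). A resolved mapped lesion contributes its
*measured residual* value, never an imputed zero — the worked nodal case
(43.95 $\to$ 7.36, $-83.3\%$) depends on this. A baseline target with no
follow-up row falls back to the follow-up background mean. Complete
response requires *every* follow-up lesion at or below
`background mean + 2 SD` (the stricter reading that includes non-target
lesions).

**PERCIST** sums SUL~peak~ of the hottest lesions selected independently
per scan ($\pm 30\%$), with two extra PMD triggers: any measurable new
lesion, and a $\ge 75\%$ increase in whole-body TLG. Complete response
requires every follow-up lesion below the liver comparator, taken as
`liver mean + 2 SD`: the plain-mean variant would contradict the worked
nodal case (residuals 1.96/1.62/1.67 against a recorded comparator of
2.33) whenever the liver SD is non-negligible. Both comparators are
exposed via `criteria_params(percist_cmr_comparator=)`.

**imPERCIST** removes the new-lesion trigger: new lesions instead *join*
the follow-up sum when they are hotter than the persisting disease or when
the baseline held fewer than five targets, and PMD requires the sum to
rise $\ge 30\%$. The TLG trigger is not part of imPERCIST here; with no
new lesions and TLG change below 75%, PERCIST and imPERCIST coincide by
construction (a tested invariant).

**Rule precedence** is fixed as: new lesions (where applicable), then
complete response, then the signed thresholds, else SMD. The criteria are
stated in the literature as unordered rule lists; this order reproduces
both packaged worked cases and keeps the classifiers total and
deterministic. Threshold boundaries are inclusive ("$\ge$"), exactly as
worded.

# Concordance statistics

`cohen_kappa()` computes weighted $\kappa = (p_o - p_e)/(1 - p_e)$ with
weights $w_{ij} = 1 - (|i-j|/3)^q$. **Quadratic weights ($q = 2$) are the
default**: recomputing $\kappa$ from the packaged reference
cross-classification tables yields 0.9703, 0.9394 and 0.9714 — matching
the recorded 0.970, 0.939 and 0.972 (the third to last-digit rounding) —
whereas unweighted $\kappa$ on the same tables gives roughly 0.88 and is
incompatible with them. Verbal agreement bands (slight/fair/moderate/
substantial/nearly perfect) are applied to $\kappa$ rounded half-up to two
decimals, so the printed band edges 0.21/0.41/0.61/0.80 behave as printed;
"nearly perfect" is strictly above 0.80.

# Survival

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package (`survfit`/`survdiff`) behind `km_estimate()` and
`logrank_test()`; the suite pins their behavior to hand-computed oracles
(a product-limit configuration giving $S(24) = 7/8$, and a four-subject
log-rank toy with $\chi^2 = 2.882$). `survival_by_response()` dichotomizes
a classified cohort — responders (CMR/PMR) vs non-responders, or disease
control (CMR/PMR/SMD) vs PMD — and runs both.

# The synthetic cohort generator

`cohort_spec()` fixes the study conditions; its defaults are the
conditions the analysis is designed around, not tuning knobs:

* **27 patients**, baseline SUV~max~ log-normal with arithmetic mean 7.3
  and SD 5.0 (parameters derived by moment inversion in
  `lognormal_params()`).
* **Scenario mix** `resolution 3 : strong_response 5 : stable 4 : growth 3
  : growth_plus_new 10 : new_lesion_only 2`, allocated deterministically
  by largest remainder and shuffled. This reproduces the qualitative
  structure of a melanoma ICI cohort in which most progression presents as
  new-lesion appearance, part of which the imPERCIST sum rule downgrades
  to SMD.
* **1–4 lesions per patient**, at most two per organ from a 14-organ pool,
  so the selection caps never bind and the intended class per criterion is
  exact arithmetic on the construction.
* **Derived metrics** use fixed ratios (SUV~mean~ = 0.62, SUV~peak~ = 0.85
  of SUV~max~; SUL factor 0.79 $\approx$ LBM/weight for a 70 kg / 170 cm
  male), which keeps every measurement invariant true by construction.
* **Noise** is a single multiplicative log-normal factor per lesion and
  time point (CV 10% by default, mean-one), applied jointly to all metrics
  so ratio invariants survive; the voxel path instead adds Gaussian voxel
  noise before measurement. Truth labels are computed from the noise-free
  construction, so exact label recovery is guaranteed only at
  `noise_cv = 0` — a property the suite tests.
* **Survival**: progression times are exponential with hazards inverted
  from 2-year PFS of 85% (responders) and 10% (non-responders); overall
  survival adds an exponential post-progression time (median 10 months),
  guaranteeing OS $\ge$ PFS; both endpoints share one administrative
  censoring time uniform on 24–68 months, mirroring a follow-up range of a
  few years.

What the generator does *not* emulate: reconstruction physics
(attenuation, scatter, OSEM noise texture), pseudoprogression kinetics,
correlated per-patient lesion biology, or organ-specific uptake patterns.
Passing tests therefore demonstrate the correctness of the measurement and
classification chain under the stated statistical assumptions, not
robustness to real-image artifacts.

Phantom lesions are spheres with Gaussian radial falloff
($\mathrm{bg} + (\mathrm{peak} - \mathrm{bg}) e^{-4.5 (r/R)^2}$, truncated
at $R$ where the profile has decayed to about 1% of its contrast) — simple
enough that the rendered maximum is known exactly when the center
coincides with a voxel center.

# Numerical choices and degenerate inputs

* Problem sizes: property simulations use grids up to $44^3$ voxels,
  cohorts of 27–4000 patients, 500 log-rank replicates at $n = 200$, and
  500-patient KM recovery — sizes chosen so the whole suite completes in
  well under a minute per file while keeping Monte-Carlo error far from
  the asserted tolerances.
* Kernel truncation at relative tail $10^{-12}$; composition tolerance
  $10^{-4}$ (observed $10^{-12}$).
* A lesion with SUV~max~ = 0 yields MTV = TLG = 0 with a warning rather
  than an error.
* Degenerate $\kappa$ margins ($p_e = 1$) raise an error naming the
  degeneracy; a log-rank comparison with zero events returns statistic 0,
  $p = 1$, with a warning.
* Ties in target hotness break by lesion id; events precede censorings at
  tied survival times (the `survival` package convention).
* Baseline disease is mandatory: classification of a patient with no
  baseline lesions is an error, since an avid baseline lesion is an
  inclusion requirement of this study design.

# Known limitations

* The EORTC background test needs a background level; in lesion-table mode
  this is a per-scan scalar, not a measured VOI.
* The per-scan hottest-lesion selection can compare partially
  non-overlapping lesion sets across time points; this is inherent to the
  criterion, not a defect, but can surprise users of the identity map.
* Harmonization emulates only the resolution component of cross-scanner
  differences; count-rate and reconstruction-bias effects are out of
  scope.
* `suv_peak_in_voi()` averages over the full peak sphere even where it
  protrudes beyond the lesion VOI; on adversarial fields (a hotter
  structure immediately adjacent) the sphere mean can exceed the VOI
  maximum. In phantom-realistic settings the invariant
  SUV~peak~ $\le$ SUV~max~ holds and is tested there.
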