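---
title: "Classifying Parkinson's disease versus essential tremor from wrist accelerometry and polygenic risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Parkinson's disease versus essential tremor from wrist accelerometry and polygenic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tremordx)
```

## The problem

Parkinson's disease (PD) and essential tremor (ET) are the two most
common adult-onset tremor disorders, and they are misdiagnosed for one
another in roughly 15–35% of cases. The classical PD presentation is a
4–6 Hz *resting* limb tremor; the classical ET presentation is a 4–8 Hz
*postural or kinetic* tremor — but both tremor types occur in both
diseases, and in the early stages the clinical signs overlap heavily.
`tremordx` implements an inexpensive, at-home screening pipeline: a
smart-watch worn on the tremor-dominant hand records triaxial
acceleration while the patient performs a short seated attention task
(the watch hand rests in the lap, supported against gravity, so any
movement there is involuntary), a two-question prompt afterwards asks
whether a tremor was felt and in which hand, and a consumer-grade
genotyping panel supplies a polygenic risk score (PRS) for PD.

## Pipeline

### Session reconstruction

Raw watch data arrive as a timestamped stream (nominally one sample
every 20 ms, i.e. 50 Hz) in milli-G (1 G = 9.8 m/s²). Recordings are
anchored to the questionnaire responses: the span of a gameplay session
is the run of consecutive samples — inter-sample gaps of at most 1 s
(`max_gap_ms`, configurable) — inside the 5-minute window
(`lookback_s`) ending at the response time. Device connectivity drops
and late questionnaire answers fragment this window; when several
qualifying runs exist we keep the longest (tie broken toward the most
recent), on the grounds that the gameplay itself is the dominant
contiguous block. Runs shorter than `min_samples = 250` (about 5 s at
50 Hz) are discarded because spectral features on shorter windows are
unstable; the source analysis states no floor, so this is exposed as a
parameter. No duration truncation is applied: sessions may run well
past the nominal 2 minutes. Only sessions where the subject reported a
tremor on *either* hand enter the analysis.

### Tremor features

Each session's triaxial samples are collapsed to the root-sum-of-squares
magnitude, which is invariant to watch orientation. The magnitude
series is band-passed to 3–7 Hz — the band shared by PD and ET tremor —
with a Butterworth filter (prototype order 4) run forward and backward,
so the output is zero-phase and the effective gain is the squared
one-pass magnitude response. Three numbers summarise each filtered
session `f_t`:

* total energy `E = sum(f_t^2)` (entering models as `log2 E`),
* average amplitude `mean(|f_t|)` in mG,
* maximum amplitude `max(|f_t|)` in mG.

Numerical choices worth knowing about:

* **Sampling regularity.** The filter is designed at the rate implied
  by the median inter-sample interval; if that deviates more than 20%
  from the nominal 20 ms the session is first resampled to a uniform
  50 Hz grid by linear interpolation (an IIR filter requires uniform
  sampling). A series whose effective rate puts the 7 Hz band edge at
  or above Nyquist is an error, not silently resampled.
* **Edge handling.** `signal::filtfilt` applies no padding, and the
  ~1000 mG static gravity offset would otherwise ring through the
  filter at the session boundaries. We subtract the session mean and
  extend both ends with a Burg (maximum-entropy) linear prediction
  (AR order 8 fitted to the nearest 100 samples, 2 s of padding,
  discarded after filtering). An autoregressive continuation carries
  in-band oscillations smoothly past the record ends: measured
  pass-band and stop-band tone gains agree with the analytic
  Butterworth response to better than 0.1%, where zero padding or
  reflection padding mis-measure the maximum amplitude by up to 7% and
  ~50% respectively in the worst phase alignments. The price is that
  the padding adapts to the data, so the end-to-end filter is exactly
  linear only away from the record ends (the pad's influence decays
  with the filter's settling time; the test suite checks linearity to
  1e-9 on the record interior).
* **Energy convention.** Total energy is the raw sum of squares, not a
  time average, so session length enters the model implicitly through
  `E`; a `energy = "mean"` option is provided since published summary
  statistics do not disambiguate the convention.
* **Degenerate sessions.** An all-zero filtered series has `E = 0` and
  an undefined `log2 E`; such sessions are flagged and excluded from
  models that use the log.

### Polygenic risk score

The PRS is a weighted allele count over 22 PD susceptibility SNPs:
`S_i = sum_j g_ij * ln(OR_j)`, with `g_ij` the dosage (0/1/2) of the
effect allele and `OR_j` the published odds ratio. Natural-log weights
are the standard convention for weighted allele counting. Missing
dosages are imputed as `2 * effect_allele_freq` when a frequency is
available (Hardy–Weinberg expectation), as the cohort mean dosage
otherwise, or dropped without rescaling (`missing = "drop"`). Scores
are not standardized by default — a raw weighted sum over 22 SNPs with
odds ratios around 1.2 and allele frequencies around 0.25 gives means
near 2, the scale on which results are reported — and `normalize =
TRUE` divides by the maximum attainable score. Proxy-SNP selection is
upstream of this package: the weight table is consumed as given.

### Classification and evaluation

The classifier is intentionally plain: an ordinary-least-squares
*linear probability model* of diagnosis (PD coded 1, ET coded 0) on the
three session features, every session treated as an independent
observation. OLS rather than logistic regression is used because the
reported artefacts of the analysis this package reproduces — adjusted
R², per-coefficient betas with t-test p-values — are OLS quantities;
predictions are unbounded scores, which is harmless since they are
used only for ranking (ROC) and thresholding. Each subject's sessions
are then summarised by the *median* of their per-session predictions,
and the combined genetics model regresses diagnosis on that frozen
median prediction plus the PRS (the movement model is not refitted).

Discrimination is evaluated by ROC curves swept over all distinct
score thresholds; tied scores collapse to a single step, making the
trapezoidal AUC exactly `U / (n1 * n0)` with half-credit for ties. The
reported operating point maximises Youden's `J = sensitivity +
specificity − 1` (tie toward higher sensitivity); the source analysis
never states its threshold rule, so this choice is ours. Evaluation is
in-sample, matching the pilot-scale analysis being reproduced;
`loocv_subject_auc()` provides a leave-one-subject-out variant for
users who want an out-of-sample estimate.

### Descriptive statistics

Group comparisons of the session features and the PRS use a
Mann–Whitney U test with the convention `U = #{x > y} + 0.5 #{x = y}`.
For `n1 * n2 <= 400` the p-value comes from the exact permutation null
of the midrank sum, computed by dynamic programming over the observed
rank multiset — this stays exact under ties, which enumeration-free
closed forms do not. Larger samples use the normal approximation with
tie-corrected variance and continuity correction. Feature comparisons
pool sessions (one observation per session) because subject-level
sample sizes cannot produce the very small p-values these comparisons
are known to reach; a per-subject aggregation is available via the
report-rate utilities. Tremor-report proportions are compared by a
Welch t-test after a natural-log transform (the t statistic is
invariant to the log base); zero proportions cannot be logged and are
excluded with a warning.

## The synthetic cohort generator

No patient-level data ship with this package; `simulate_cohort()`
draws a complete synthetic study so the whole pipeline can be run and
calibration-tested. Its defaults are the study conditions:

| parameter | PD | ET | source |
|---|---|---|---|
| subjects | 40 | 27 | recruited cohort |
| schedule | 3/day × 14 days | same | protocol |
| sampling | 50 Hz, 120 s sessions | same | protocol |
| tremor-report rate (mean ± SD) | 0.52 ± 0.31 | 0.63 ± 0.34 | reported |
| filtered max amplitude (mG) | 280 ± 123 | 328 ± 158 | reported |
| tremor frequency band (Hz) | 4–6 | 4–8 | clinical |
| PRS group difference | 0 (null) | — | reported |

Structure of the generative model, and why each piece is there:

* **Subject-level latents.** Each subject draws one amplitude
  (truncated normal), one tremor frequency (uniform in the group
  band), one report rate (Beta, moment-matched to the group mean/SD,
  truncated to (0.02, 1) matching the observed 2–100% range), and one
  duty cycle. Sessions add multiplicative log-normal noise (CV 0.2)
  around the subject amplitude. Between-subject variance dominating
  within-subject variance is what makes median aggregation beat
  per-session classification; the within-subject CV is a free
  parameter because no published value constrains it.
* **Burst structure.** Tremor is active only for a duty-cycle fraction
  of each session (PD 0.10, ET 0.07 on average, log-normal variation
  across subjects and sessions). The published feature means force
  this: average amplitude (~18 mG) is an order of magnitude below
  maximum amplitude (~300 mG), which a sustained sinusoid cannot
  produce (it pins `mean|f| = (2/π) max|f|`), and PD shows *higher*
  average but *lower* maximum amplitude than ET — a sustained rest
  tremor against shorter, larger kinetic bursts. The duty means are
  set once from the printed average/maximum ratios. This also keeps
  the two amplitude features from being collinear, without which the
  opposite-signed model coefficients would be unrecoverable.
* **Amplitude calibration.** The configured amplitude distributions
  describe the *filtered* maximum amplitude — the scale on which
  results are reported. The generator therefore divides the raw
  sinusoid amplitude by the analytic zero-phase band gain at the
  subject's tremor frequency, so an ET subject with a 7.5 Hz tremor
  (outside the 3–7 Hz analysis band) still lands on the configured
  filtered scale.
* **Signal assembly.** Each session's magnitude is `gravity (1000 mG)
  + amp · envelope · sin(2π f t + φ) + white noise (SD 10 mG)`; the
  vector is rotated to a random wrist orientation, which partitions
  the signal across axes while leaving the magnitude invariant (the
  pipeline's first step undoes exactly this). The gravity offset is
  included deliberately so tests prove the band-pass removes it.
* **Messiness.** Scheduled sessions drop out at a configurable rate,
  recordings lose a 5 s mid-session stretch with probability
  `gap_rate` (the ground truth records the resulting run lengths, so
  the extractor's output can be checked exactly), and questionnaire
  responses lag the recording end by 5–60 s.
* **Genetics.** 22 synthetic SNPs with odds ratios uniform in
  (1.05, 1.4) and effect-allele frequencies uniform in (0.05, 0.45) —
  an unstandardized weighted sum over these lands near the reported
  mean score of ~2. Dosages are binomial(2, freq); `prs_effect`
  tilts case-group frequencies in proportion to `w·f·(1−f)` to hit a
  target standardized score difference, with 0 (the study's null
  finding) as default.

What the generator does **not** emulate: biomechanically realistic
tremor waveforms (real tremor is neither a pure tone nor
rectangular-burst modulated), medication on/off dynamics across the
three daily sessions, phone-hand tremor, re-emergent tremor latency,
or any genetic overlap between PD and ET risk. Passing the end-to-end
tests therefore shows that the pipeline recovers the study's findings
*under its own stated statistical structure*, not that it would attain
any particular accuracy on real recordings.

## Problem sizes used in the checks

The packaged tests run the full pipeline 100 times at the final-cohort
size (33 PD / 24 ET) with sessions shortened to 10 s to keep the suite
fast, checking that (a) the maximum-amplitude coefficient is negative
in ≥90% of replicates, (b) median aggregation improves the AUC in a
majority of replicates, and (c) the null PRS term stays nonsignificant
in ≥85%. Statistical calibration checks use 500 null replicates at
n = 30 per group. `scripts/acceptance.R` runs one full-scale study
(120 s sessions) and writes every headline quantity to JSON.

## Known limitations

* In-sample evaluation overstates accuracy relative to held-out data;
  use `loocv_subject_auc()` for an honest subject-level estimate.
* The linear probability model's predictions are not probabilities;
  only their ranking is meaningful.
* Maximum amplitude is sensitive to any residual edge transient and to
  single outlying samples; the Burg padding controls the former, but a
  robust quantile (e.g. 99th percentile) would be a natural hardening
  not implemented here because the reproduced analysis used the raw
  maximum.
* The exact Mann–Whitney null is enumerated only up to `n1 * n2 = 400`;
  beyond that the tie-corrected normal approximation is used.
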