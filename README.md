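# tremordx

Differential screening of **Parkinson's disease (PD) versus essential
tremor (ET)** from at-home smart-watch accelerometry, optionally
combined with a polygenic risk score — for movement-disorder
researchers and digital-biomarker engineers who need the full pipeline
(raw stream → sessions → tremor features → classifier → ROC) in one
auditable R package.

PD and ET are the two most common adult tremor disorders and are
misdiagnosed for one another in 15–35% of cases. The classical PD
tremor is a 4–6 Hz *rest* tremor; the classical ET tremor is a 4–8 Hz
*postural/kinetic* tremor, but the presentations overlap. The package
implements:

1. **Session reconstruction** — a gameplay recording is the run of
   consecutive samples (gaps ≤ 1 s) in the 5-minute window ending at
   the tremor-questionnaire response; only sessions with a reported
   tremor on either hand are analysed.
2. **Tremor features** — the triaxial signal is collapsed to its
   root-sum-of-squares magnitude `m_t = sqrt(ax² + ay² + az²)` (mG),
   band-passed to 3–7 Hz with a zero-phase order-4 Butterworth filter,
   and summarised per session as total energy `E = Σ f_t²`, average
   amplitude `mean|f_t|`, and maximum amplitude `max|f_t|`.
3. **Polygenic risk score** — a weighted allele count over 22 PD
   susceptibility SNPs, `S_i = Σ_j g_ij · ln(OR_j)`, from a dosage CSV
   or a small VCF plus a published weight table.
4. **Classification** — an OLS linear probability model (PD = 1) of
   diagnosis on `(log₂E, mean|f|, max|f|)` per session; per-subject
   scores are the **median** of that subject's session predictions; a
   combined model adds the PRS to the frozen median prediction.
5. **Evaluation** — ROC curves with tie-grouped thresholds (so the
   trapezoidal AUC equals the Mann–Whitney `U/(n₁n₀)` identity) and
   Youden-optimal operating points; descriptive Mann–Whitney U tests
   (exact, tie-aware null for small samples) and a Welch t-test on
   log-transformed tremor-report proportions.
6. **Synthetic cohorts** — `simulate_cohort()` draws a complete study
   (accelerometer streams, questionnaire logs, roster, SNP weights,
   genotypes, plus ground truth) under the documented group conditions,
   so everything above runs with no external data.

## Worked example

```r
library(tremordx)

cfg    <- sim_config(n_pd = 12, n_et = 9, days = 7, session_length_s = 30)
cohort <- simulate_cohort(cfg, seed = 42)
res    <- suppressWarnings(run_pipeline(cohort))
res$analysis
#> PD vs ET discrimination analysis
#>   sessions: 247 from 18 subjects
#>   session-level AUC:  0.752
#>   subject-level AUC:  0.875 (median aggregation)
#>   combined AUC:       0.863 (movement + PRS)
#>   subject operating point: sensitivity 0.80, specificity 0.88

summary(res$analysis$session_model)
#>                Estimate  Std. Error t value  Pr(>|t|)
#> (Intercept) -0.43112213  0.57057245 -0.7556   0.45062
#> log2_energy  0.05786434  0.02997172  1.9306   0.05469 .
#> avg_amp_mg   0.01269408  0.00275394  4.6094 6.527e-06 ***
#> max_amp_mg  -0.00183682  0.00033984 -5.4049 1.547e-07 ***
#> Adjusted R-squared: 0.1685  (model p-value 2.2e-10, n = 247)
```

Reading the output: each gameplay session gets a linear score; the
session-level AUC (0.75) is the probability a random PD session
outscores a random ET session. Taking each subject's median session
score sharpens discrimination (subject AUC 0.88). The
maximum-amplitude coefficient is *negative* — ET tremor bursts reach
higher peak amplitude than PD rest tremor, so a large `max|f|` pulls
the prediction toward ET — while the more sustained PD tremor gives a
*positive* average-amplitude coefficient. Adding the (null) polygenic
score does not improve the subject-level AUC. Group descriptives are
in `res$comparisons`, per-subject report rates in `res$report_rates`,
and `plot(res$analysis)` overlays the three ROC curves.

File-based workflows use the same pieces: `read_accel_csv()`,
`read_events_csv()`, `tremor_sessions()`, `session_features()`,
`read_snp_weights()`, `read_dosage_csv()` / `read_genotypes_vcf()`,
`compute_prs()`, then `classify_cohort()`.

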