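# crtscore

Visual scoring systems on baseline rectal MRI for predicting response to
neoadjuvant chemoradiotherapy (CRT), with the complete multireader
evaluation toolkit: Krippendorff's alpha interobserver agreement,
reader-averaged ROC/AUC with bootstrap confidence intervals, optimal
cutoffs and confusion-matrix metrics, and regression models for reader
experience and the CRT-to-surgery interval. A calibrated synthetic
multireader study generator makes the whole pipeline runnable end to end
without patient data.

## Who this is for

Radiology and biostatistics groups running (or planning) multireader,
multicase studies of structured MRI response prediction in rectal cancer —
and anyone who needs a tested, reproducible implementation of the
underlying statistics: chance-corrected agreement for many raters with
missing data, reader-averaged diagnostic accuracy, and variance-component
models for repeated measurements of the same patients.

## The methods in brief

Three scores are computed from a structured staging profile (T-stage, size,
signal, shape, N-stage, EMVI, MRF):

| Score | Construction | Predicts nCR when |
|---|---|---|
| 5-point confidence | count of high-/low-risk criteria among the 7 features; rules applied extremes-first (1, 2, 5, 4, else 3) | score 4–5 |
| 4-point risk | one point per *obvious* high-risk feature (MRF invasion, T3c–4 stage, nodal involvement, EMVI) | score 0–1 |
| 2-point | 1 if high-risk T-stage or obvious MRF invasion, else 0 | score 0 |

The positive outcome throughout is a (near-)complete response, nCR —
Mandard TRG 1–2 on histopathology, or a ≥ 2-year sustained clinical
complete response under watch-and-wait.

Agreement is Krippendorff's alpha, `alpha = 1 − D_o/D_e` from the
coincidence matrix, with ordinal and nominal metrics and missing-data
support. Diagnostic accuracy uses the Mann–Whitney AUC (equal to the
trapezoidal ROC area) on reader-mean oriented scores with a stratified
percentile bootstrap, plus per-reader sensitivity/specificity/PPV/NPV/
accuracy at each score's fixed dichotomisation, macro-averaged by reader
stratum. Reader experience is modelled as a linear probability model with
a patient-level random intercept fitted by profile REML; the interval
effect is a binomial logistic regression fitted by IRLS. See the vignette
(`vignettes/multireader-response-scoring.Rmd`) for formulas, defaults, and
design decisions.

## Worked example

Simulate a 90-patient study read by 5 expert and 17 non-expert radiologists
and evaluate all three scores:

```r
library(crtscore)

study <- simulate_study(sim_config(n_patients = 90, seed = 1))
outcomes <- study$truth[c("patient_id", "ncr", "interval_weeks")]

performance_table(study$scores, outcomes, study$panel,
                  n_boot = 1000, seed = 1)
#>   method     stratum   sensitivity specificity accuracy   auc  ...
#> 1 five_point all             0.849       0.275    0.575 0.659
#> 4 four_point all             0.625       0.610    0.618 0.695
#> 7 two_point  all             0.600       0.691    0.643 0.688
```

Each row gives the reader-averaged confusion metrics at the score's fixed
cutoff and the AUC of the stratum-mean score with its 95% bootstrap CI —
here the 4-point score discriminates best (AUC 0.695, CI 0.589–0.805), and
all three sit in the moderate range typical of purely visual baseline
prediction.

```r
agreement_table(study$scores, study$panel, assessments = study$assessments)
#>    item        stratum   metric  alpha
#>  1 five_point  all       ordinal 0.496
#>  2 five_point  expert    ordinal 0.690
#>  3 five_point  nonexpert ordinal 0.458
#>  ...
```

Expert agreement (alpha 0.69) clearly exceeds non-expert agreement (0.46)
for the 5-point score, reproducing the expected experience gradient of the
simulated error model.

```r
records <- correctness_records(study$scores, outcomes, study$panel)
fit_interval_model(interval_correctness(
  records[records$method == "four_point", ], outcomes))
#> Binomial regression of reader correctness on CRT-to-surgery interval
#>   slope: -0.0062 log-odds per week (95% CI -0.0474 to 0.0351), p = 0.77
```

The whole bundle — truth, assessments, scores, cohort summary, performance,
agreement, effects, interval model, manifest with config hash — is written
by one call, bitwise reproducible under a fixed seed:

```r
run_pipeline(sim_config(), output_dir = "study_out", seed = 1)
```

A thin command-line wrapper with `simulate`, `score`, `agreement`,
`performance`, `effects`, and `run-all` subcommands lives at
`inst/scripts/crtscore-cli.R`.

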