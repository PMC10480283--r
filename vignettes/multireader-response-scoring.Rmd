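---
title: "Multireader evaluation of baseline-MRI response scores in rectal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multireader evaluation of baseline-MRI response scores in rectal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(crtscore)
library(dplyr)
```

## The problem

Patients with locally advanced rectal cancer receive long-course
chemoradiotherapy (CRT) before surgery. A substantial fraction respond so
well — a complete or near-complete response (nCR), operationalised as
Mandard tumor regression grade (TRG) 1–2, or a sustained clinical complete
response of at least two years under watch-and-wait surveillance — that
organ-preserving management becomes possible. Being able to anticipate, on
the *baseline* staging MRI, which tumors are likely to melt away under CRT
would help select candidates for organ preservation and spare anticipated
non-responders unnecessary toxicity.

Radiologists can attempt this prediction with nothing more than structured
visual assessment. `crtscore` implements three such scoring systems and the
complete statistical machinery of a multireader, multicase evaluation of
them, together with a calibrated synthetic study generator so the whole
pipeline can be exercised, tested, and taught without access to patient
data.

## The three scoring systems

All three work from a structured baseline staging profile with seven
features: T-stage (T1, T2, T3a–d, T4), craniocaudal tumor size (cm), signal
(homogeneous/heterogeneous), shape (regular/irregular), N-stage (N0–N2),
extramural vascular invasion (EMVI), and mesorectal fascia (MRF) invasion.

**5-point confidence score.** Each feature is classified high risk, low
risk, or neutral: T-stage is high risk at T3c/T3d/T4 and low risk at
T1–T3b; size is high risk above 5 cm, low risk below 3 cm, neutral in
between; heterogeneous signal, irregular shape, N+, EMVI+ and MRF+ are high
risk, their complements low risk. The score is then 1 (highly unlikely to
achieve nCR) with all 7 criteria high risk, 2 with ≥ 5 high-risk criteria,
5 (highly likely) with ≥ 5 low-risk criteria, 4 with ≥ 3 low-risk criteria,
and 3 (equivocal) otherwise. Because a profile can satisfy several clauses
(7 high-risk criteria also satisfies "≥ 5"), the rules are evaluated
extremes first — 1, 2, 5, 4, else 3 — so a profile always receives its most
extreme applicable category. This precedence is a design decision of the
package; a confidence scale would be incoherent otherwise.

**4-point risk score.** One point for each of four *obvious* high-risk
features: macroscopic MRF invasion, high-risk (bulky, T3c–4) T-stage, nodal
involvement, EMVI. Readers are instructed to mark a feature present only
when confident — when in doubt, the answer is "no". The score is simply the
count (0–4); 0–1 predicts nCR.

**2-point score.** A single dichotomy: tumors with high-risk T-stage
(T3c/T3d/T4, with or without MRF involvement), or with obvious MRF invasion
at lower T-stage, are "unlikely" (1); the "likely" branch (0) requires a
low-risk T-stage *and* a free (or at most borderline) MRF. The morphologic
"bulky semicircular or circular" wording of the rubric has no quantitative
definition, so T-stage and MRF status are the operative criteria here; this
is documented behaviour, not an omission.

Boundary conventions: size classification takes ">5" and "<3" strictly, so
3.0 cm and 5.0 cm are neutral. Scores are integers; no half-points.

The four booleans of the 4-point score are recorded independently of the
staging features in real case report forms — a reader may stage a tumor
T3c yet hesitate to call the T-stage "obviously" high risk.
`score_assessments()` therefore uses the booleans as given when present
(deriving them from the staging features only as a fallback), and
`check_four_point_consistency()` audits divergences without enforcing
anything.

```{r}
staging <- tibble::tibble(
  patient_id = c("P1", "P2"),
  t_stage = c("t4", "t2"), size_cm = c(6.2, 2.0),
  signal = c("heterogeneous", "homogeneous"),
  shape = c("irregular", "regular"),
  n_stage = c("n2", "n0"), emvi = c(TRUE, FALSE), mrf = c(TRUE, FALSE)
)
score_assessments(staging)
```

## Interobserver agreement

Group agreement uses Krippendorff's alpha, which handles any number of
raters and missing cells. Within each patient rated by `m_u ≥ 2` readers,
every ordered pair of ratings contributes `1/(m_u − 1)` to a coincidence
matrix `o`; with marginals `n_c` (total pairable values `n`),

* observed disagreement `D_o = Σ o[c,k] δ²(c,k) / n`,
* expected disagreement `D_e = Σ n_c n_k δ²(c,k) / (n(n−1))`,
* `alpha = 1 − D_o / D_e`.

The nominal metric sets `δ² = 1` off the diagonal; the ordinal metric sets
`δ²(c,k)` to the squared number of pairable values lying between the two
categories, counting half of each endpoint's marginal. The package uses the
ordinal metric for the 5- and 4-point scores and the nominal metric for the
2-point score and the four binary features — the rubrics are ordered scales
where they have more than two levels — and both metrics are always
available via the `metric` argument. On a two-value domain the metrics
coincide (the single off-diagonal distance cancels in `D_o/D_e`), which the
test suite asserts.

Conventions worth knowing: patients with a single rating are excluded from
pairing (and counted in `n_pairable`'s complement); a table in which every
pairable rating is identical has `D_e = 0` and raises an explicit error
rather than returning 1, because such data carry no chance-corrected
information; the bootstrap CI resamples *patients*, not readers, matching a
design with a fixed reader panel, and redraws degenerate resamples. The
implementation is verified against a brute-force oracle that enumerates
every rating pair directly.

## Diagnostic performance

For ROC analysis the scores of a reader stratum are averaged per patient
and oriented so that larger values mean a higher predicted probability of
nCR: the 5-point score as-is, the 4- and 2-point risk scores negated. The
orientation is recorded in the output metadata; AUC is rank-invariant, so
whether the mean is further rescaled to [0, 1] is cosmetic and the report
keeps raw means.

The AUC is computed in Mann–Whitney form (fraction of
positive–negative patient pairs ranked correctly, ties at ½) and equals the
trapezoidal area under the empirical ROC curve; both forms are implemented
and their identity is asserted to 10⁻¹² in the tests. Confidence intervals
use a stratified percentile bootstrap (resampling patients within outcome
class, default 2000 resamples, seeded). Differences between methods' AUCs
are tested with a paired bootstrap of the AUC difference rather than
DeLong's variance formula, keeping one resampling mechanism throughout.

Cutoff-based metrics (sensitivity, specificity, PPV, NPV, accuracy, with
nCR the positive class) are computed per reader at each method's fixed
dichotomisation — 5-point 4–5 vs 1–3, 4-point 0–1 vs 2–4, 2-point 0 vs 1 —
then macro-averaged within the reader stratum, matching the "average over
readers" reading of a multireader report; `optimal_cutoff()` separately
provides the Youden-optimal threshold (midpoints between distinct observed
values; ties broken by higher specificity, then higher threshold; scores
equal to a threshold are called negative). Ratios with empty denominators
are reported `NA`, never 0.

## Reader-experience and interval models

Two regressions probe the correctness records (one record per reader ×
patient × method; correct means the dichotomised prediction equals the nCR
label):

**Experience effect.** `correct ~ expert` as a *linear probability model*
with a patient-level random intercept, so effects are differences on the
probability scale (e.g. +0.03 accuracy), and the repeated measurement of
each patient by 22 readers is absorbed by the random intercept. The
variance components are estimated by REML: the criterion is profiled over
the variance ratio `λ = σ²_patient/σ²_resid`, for which the block structure
of `(I + λJ)` gives a closed-form GLS step per candidate `λ`, and a
one-dimensional optimisation over `log λ` (with the `λ = 0` boundary
checked explicitly) finishes the job. Wald CIs and p-values are used
throughout; no Satterthwaite correction is applied, a documented
limitation. The fit is verified against `lme4::lmer` in the test suite.
Per-metric effect rows condition on outcome subsets: sensitivity effects
use responders only, specificity effects non-responders only, accuracy all
patients — a convention of this package, recorded as such.

**Interval confounder.** The number of readers correct per patient (out of
the panel) is regressed on the CRT-to-surgery interval in weeks by binomial
logistic regression, fitted by iteratively reweighted least squares to a
score-norm tolerance of 10⁻⁸ (verified against `stats::glm`). Complete
separation — all per-patient proportions 0 or 1 — raises an explicit error
with a diagnostic rather than returning divergent estimates.

## The synthetic study generator

No per-reader ratings are publicly deposited for studies of this design, so
the package ships a generator that emulates the statistical structure the
analysis assumes, not any physiological mechanism:

* **Patient truth.** T-stage group probabilities default to the cohort
  margins of a 90-patient multicenter study (cT1-2 : cT3 : cT4 counts
  3 : 68 : 18, normalised; the printed counts sum to 89, so the
  normalisation is over 89), N-stage to 12 : 19 : 59 of 90. Size is
  log-normal (median 4.5 cm, log-SD 0.4 — a typical rectal tumor length
  distribution); heterogeneous signal, irregular shape, EMVI and MRF are
  Bernoulli with log-odds linear in the (centred, scaled) T-stage rank, so
  advanced tumors carry correlated high-risk features.
* **Outcome.** nCR is Bernoulli with logistic link on the seven high-risk
  indicators (default coefficient −0.5 each); the intercept is
  auto-calibrated by monotone bisection on a fixed Monte-Carlo draw of the
  feature space (20 000 profiles, tolerance 10⁻³) so the marginal nCR
  probability hits the target prevalence of 0.49. TRG is drawn
  conditionally on nCR with margins 30/19/32/17/2%; 6/27 of complete
  responders follow the watch-and-wait pathway (sustained clinical complete
  response instead of histopathology). The CRT-to-surgery interval is
  normal (11 ± 2.5 weeks) truncated below at 6 weeks to exclude
  non-physiologic values.
* **Readers.** 5 experts and 17 non-experts by default. Each reader
  perceives each true feature through a stratum-specific error channel:
  binary features flip present→absent with `p_miss` and absent→present with
  `p_false_call`, with `p_miss > p_false_call` to encode the
  doubt-means-no instruction (defaults 0.15/0.05 expert, 0.30/0.10
  non-expert); T-stage moves to an adjacent category with probability 0.15
  (expert) or 0.30 (non-expert); size carries multiplicative log-normal
  noise. The per-feature error rates of real reader panels are unknown;
  these defaults were chosen once as plausible perception-error magnitudes
  with experts roughly twice as reliable, and they are all surfaced in
  `sim_config()`. The 4-point booleans are derived from the same perceived
  features, so each simulated reader is internally consistent by
  construction.

One master seed drives everything; per-stage sub-seeds are derived from it
deterministically, so a stage can be regenerated in isolation and the full
bundle is bitwise reproducible.

What the generator does *not* emulate: reader-specific bias or drift,
per-case difficulty, correlated errors between readers looking at the same
ambiguous image, reader drop-out, or any dependence of response on
treatment beyond the interval covariate. Passing tests on simulated data
therefore demonstrate that the *machinery* is correct under the assumed
structure — they say nothing about how well the scores predict response in
real patients.

```{r}
study <- simulate_study(sim_config(n_patients = 90, seed = 1))
summarize_cohort(study$truth)
```

## Numerical and design choices, in one place

* Rubric precedence 1, 2, 5, 4, else 3; strict size boundaries; integer
  scores.
* 2-point score: MRF invasion at low T-stage scores 1 (the "likely" branch
  requires a free MRF).
* Ordinal alpha for 5-/4-point scores, nominal for 2-point and binary
  features; `D_e = 0` errors; single-rating units excluded; unit (patient)
  bootstrap.
* Score orientation for ROC: risk counts negated; ties at a threshold
  classified negative; Youden ties broken by specificity then threshold.
* Stratified percentile bootstrap everywhere (AUC CI, AUC comparison,
  alpha CI); default 2000 resamples; all seeded.
* Linear probability model (not a logistic mixed model) for the experience
  effect, matching probability-scale effect reporting; REML, profile over
  `log λ`, `λ = 0` boundary checked; Wald inference.
* IRLS to gradient norm 10⁻⁸, iteration cap 100, separation guarded.
* Degenerate inputs raise errors: single-class outcomes, all-zero confusion
  counts, constant correctness, all-boundary proportions, no pairable unit.
* Problem sizes in the test suite: the oracle sweeps use 1000 random rating
  matrices (≤ 4 raters × 6 units × 3 values) and 500 random AUC instances;
  calibration checks use 10 000 simulated patients; parameter-recovery
  checks use 200 replicates at the study design size of 90 patients × 22
  readers — sizes chosen so each suite runs in about a minute while keeping
  Monte-Carlo error well inside the asserted bounds.

## Limitations

The generator's defaults are calibrated to one study's cohort margins, not
to any universal case mix. Wald intervals are anti-conservative in small
strata. The linear probability model can fit values outside [0, 1] for
extreme covariate patterns — accepted here because effects near 0.5 are the
use case. Krippendorff's alpha is reported without small-sample bias
correction. None of the diagnostic machinery models correlation between
scoring methods evaluated on the same patients beyond the paired bootstrap.
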