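---
title: "Methods: diagnostic accuracy evaluation and triage simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic accuracy evaluation and triage simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovatriage)
```

## The problem

Ovarian lesions are common, and expert gynecological ultrasound
examiners are scarce. A classifier that estimates the risk of
malignancy from ultrasound images can be evaluated in two
complementary ways: as a *stand-alone reader*, compared against panels
of expert and non-expert human examiners on matched case sets, and as a
*second reader* inside a triage workflow, where it filters which
patients must be escalated to an expert. `ovatriage` implements both
evaluations — the metric suite, the multi-reader comparison statistics
and the workflow simulation — together with a synthetic cohort
generator that reproduces the data *structure* such studies share, so
the whole pipeline is testable without clinical data.

## Case-level scoring

The classifier emits, per image, a probability vector over ten
histological categories — five benign (endometrioma, dermoid, other
common benign, solid benign, cystadeno(fibro)ma) and five malignant
(serous borderline, mucinous intestinal borderline, epithelial ovarian
cancer, non-epithelial ovarian cancer, metastasis); borderline tumors
count as malignant. The image malignancy score is the sum of the five
malignant entries; the case score is the unweighted mean over the
case's images; and a case is called malignant when its score *strictly
exceeds* the cutoff (default 0.5). Ties at the cutoff therefore
classify benign — "exceeds" is read as a strict inequality, and the
choice only matters on a measure-zero set of scores.

## The metric suite

`metric_set()` reports sensitivity, specificity, accuracy, PPV, F1
(the harmonic mean of PPV and sensitivity), Cohen's kappa with
marginal-product chance agreement, the Matthews correlation
coefficient, the diagnostic odds ratio, Youden's J, and — when
continuous scores are available — the Brier score and the AUC computed
as the Mann–Whitney concordance (ties count one half). Conventions for
degenerate input, chosen where the field's software disagrees:

* 0/0 proportions are **explicit `NA`**, flagged in `undefined`, never
  silently 0.
* DOR with an empty error cell is `+Inf` when `tp * tn > 0`; an
  optional Haldane–Anscombe 0.5 correction (`haldane = TRUE`) is off by
  default.
* An MCC denominator with a zero factor yields 0 (the standard
  convention).
* `jeffreys_ci()` uses the Beta(x+1/2, n−x+1/2) posterior with the
  boundary convention lower = 0 at x = 0 and upper = 1 at x = n.

`reconstruct_confusion()` inverts printed sensitivity/specificity
percentages into integer cell counts (nearest achievable count; exact
halfway targets are reported via a warning). It exists so that printed
result tables can be audited: the counts it returns reproduce every
other metric of the printed row.

## Reader-versus-AI comparison

The pairing unit is the **examiner**: for each of the 66 readers the
chosen metric is computed on exactly the case set that reader assessed,
for the reader and for the AI (`paired_scores()`), and the per-reader
differences go into a two-sided Wilcoxon signed-rank test. Zeros are
discarded before ranking; for up to 25 non-zero differences the p-value
comes from the exact null distribution, computed by convolution over
doubled midranks (integer-valued even under ties, and identical to
enumerating all 2^n sign assignments); beyond that, a normal
approximation with tie correction and a 0.5 continuity correction is
used. Per-case pairing is deliberately not offered: readers saw
different case sets, so the examiner is the exchangeable unit.

Pooled tier-level operating points use **inverse-workload sampling**:
each replicate draws one examiner per case with probability
proportional to 1/(cases assessed), which equalizes examiner
representation when workloads differ. Confidence intervals are
percentile bootstrap intervals with the **case** as the resampling
unit (default 2,000 replicates in the pipeline; reduced sizes are used
in examples and tests). The reported point estimate is the mean over
replicates — a replicate-averaged estimator that is *more* precise
than any single draw. For this reason the package's coverage property
is validated on a single-reader-per-case design, where the interval's
implied design coincides with the estimator; with many readers per
case the percentile interval is conservative (it also carries the
examiner-draw variance), which we regard as the safe direction.

The ROC curve is the empirical curve over all distinct thresholds
(strict-inequality rule, so it is exactly consistent with `classify()`
and its trapezoidal area equals the concordance AUC on every input).
The confidence band bootstraps cases, interpolates each bootstrap curve
onto a fixed specificity grid (1,001 points by default) and takes the
2.5th/97.5th percentile of sensitivity at each level of specificity;
degenerate single-class resamples are redrawn and counted.
`matched_cutoff()` scans the achievable operating points for the cutoff
whose constrained coordinate is closest to the target without falling
below it, breaking ties toward the higher free coordinate.

The panel summary is a **bivariate random-effects model on the logit
scale**, fitted by method of moments: per-examiner logit (sensitivity,
specificity) with delta-method within-examiner variances, a
between-examiner covariance estimated as the sample covariance minus
the mean within-examiner covariance (eigenvalue-floored at zero), and
an elliptical confidence region for the mean from the covariance of
the mean. Method of moments is deterministic and directly testable by
parameter recovery; full maximum likelihood (as in dedicated
meta-analysis software) is a possible extension, not the default. A
0.5 continuity correction is applied to the cells of any examiner with
a zero cell. At study scale (33 examiners, hundreds of cases each) the
moment estimator's bias is below one percentage point, which the test
suite verifies by simulation.

Calibration uses 10 equal-frequency bins by default (per-bin mean
score against observed malignant proportion, with a bin-weighted mean
absolute calibration error); smoothing-based curves are a deliberate
non-default because binned curves are directly testable.

## Triage simulation

Two workflow families are simulated (`simulate_triage()`):

* **Current practice** — a non-expert examines first; cases with an
  uncertain diagnosis or a presumed malignancy are referred to an
  expert whose call is final. The referral trigger uses the recorded
  call and confidence only.
* **AI-assisted** — the AI and a human (non-expert or expert) each
  assess; on agreement the shared call is final after one human
  examination, on disagreement a *different* expert arbitrates.

Reference strategies `single_expert`, `single_nonexpert` and
`ai_alone` complete the comparison. Human resources are the expected
number of *human* examinations per management decision, so
`human_resources = 1 + referral fraction` holds on every replicate by
construction, and the AI's own assessment is never counted as an
examination (the floor is the single acquiring examination). The
relative referral reduction between two workflows is
`100 * (1 − (hr_new − 1)/(hr_baseline − 1))`.

Initial examiners and arbiters are drawn with inverse-workload
weights, the arbiter among that case's experts excluding the initial
examiner where the initial examiner is an expert (by rejection
sampling, which is exact for the renormalized weights). How the
original study drew its arbiters — with or without exclusion of the
initial expert — is not documented; exclusion matches the phrase
"referral to (second) expert" and is our documented choice. Default
`n_reps` is 1,000, with percentile intervals over replicates that also
bootstrap cases.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the
study conditions the downstream analyses assume:

* **Cohort**: 19 centers × 140 cases = 2,660, with the ten-category
  histology mix of a surgical referral population (40.8% malignant;
  the small "rare benign" group is folded into "other common benign").
  Conservatively managed cases (ultrasound follow-up as the reference
  standard) are benign by construction and controlled by
  `conservative_fraction` (0 in the surgical cohort; 1 reproduces a
  follow-up-only cohort).
* **Image counts**: `1 + NegBin(size = 3, mu = 3.8)`, giving exactly
  median 4 and IQR 3–6. Only the summary statistics are knowable, so a
  mid-dispersion member of the matching parameter family was fixed
  once.
* **Latent difficulty**: one standard-normal scalar per case shared by
  every simulator. This is the simplest mechanism that makes reader
  errors, reader confidence and AI errors correlate on the same cases,
  which the confidence-stratified analyses require.
* **Examiner panels**: 33 experts and 33 non-experts; latent
  (sensitivity, specificity) drawn per tier from a bivariate
  logit-normal centered on tier means of 82.40%/82.67% (expert) and
  78.71%/77.27% (non-expert). Between-examiner heterogeneity is not
  identifiable from pooled operating points, so the defaults — SD 0.35
  on the logit scale with correlation −0.3 — encode a realistic
  reader-to-reader spread with the usual threshold trade-off; they are
  stated, not estimated.
* **Correctness link**: probability of a correct call is
  `pnorm(qnorm(latent) * sqrt(1 + beta^2) − beta * d)` with difficulty
  weight `beta = 1`. The probit form is chosen because its Gaussian
  mixture integrates exactly back to `latent`, so pooled empirical
  accuracy recovers the configured tier means with no approximation
  error (the logit-normal part of the model lives between examiners,
  not within the link).
* **Confidence**: thresholds 0.3 and 1.2 on the examiner's noisy
  perception of difficulty (jitter SD 0.3) split assessments into
  certain/probable/uncertain at roughly 60/27/13%, and accuracy is
  monotone decreasing across those levels by construction.
* **Review design**: every case reviewed by at least 7 experts and 6
  non-experts (Poisson extras with mean 3 give median panels of 10 and
  9), never by an examiner from the case's own center; examiner
  availability weights are Gamma-distributed so workloads vary and
  inverse-workload weighting is non-trivial.
* **AI predictions**: per image, evidence
  `x = s(delta/2 − w d) + eps` with class sign `s`, separation
  `delta = 2.4`, shared-difficulty weight `w = 0.95` and image noise
  `eps ~ N(0, 0.3)`; the malignancy mass is the exact Bayes posterior
  given `x` and the cohort prevalence, so calibrated-mode scores are
  calibrated at the image level *by construction*. Averaging over a
  case's images perturbs this only mildly (the test suite bounds the
  decile deviation). The constants were fixed at design time so the
  cutoff-0.5 operating point dominates the expert tier, as the
  evaluated setting requires; `overconfident`/`underconfident` modes
  rescale the posterior log-odds by 2 and 0.5 for calibration-analysis
  stress tests. Within-class mass is spread over the five categories
  of each class proportionally to the cohort mix with the true
  category boosted sixfold, plus per-image Dirichlet jitter
  (concentration 20), so rows are exact probability vectors.

### What the generator does and does not emulate

It reproduces the *structure* the statistics consume: class and
category composition, per-case image counts, panel design with
own-center exclusion, unequal workloads, tier-separated accuracy, the
confidence–accuracy link, correlated reader/AI errors, and a
calibrated AI with a dominant operating point. It does **not** emulate
center-level case-mix differences, ultrasound-system effects on
difficulty, reader learning or fatigue, label noise in the reference
standard, or any image content. Passing tests therefore certify the
statistical machinery under the stated generative assumptions — not
the clinical performance of any model on real data.

## Numerical and reproducibility choices

* All randomness flows from one master seed through named substreams
  (`stage_seed()`), so every stage is independently reproducible and
  identical seeds give bit-identical cohorts and results.
* Probability rows must sum to 1 within 1e−6; the generator's own
  output is exact to 1e−9.
* Percentile intervals use type-7 quantiles of the replicate values;
  degenerate bootstrap resamples are redrawn and counted rather than
  dropped silently.
* Problem sizes in examples and tests (hundreds of cases, hundreds of
  replicates) are deliberately modest; the same code paths scale to
  the full study size, and the acceptance material runs the full
  2,660-case configuration where the property under test needs it.

## Known limitations

* The bivariate summary is method-of-moments, not restricted maximum
  likelihood; with very small panels (< 10 examiners) its between-
  examiner covariance is noisy and the zero floor binds often.
* The exact Wilcoxon path is limited to 25 non-zero differences; the
  66-reader comparisons always use it (per tier, n = 33 > 25) only via
  the corrected normal approximation, which at that n is accurate to
  well under the decision threshold.
* Conservative management is modelled as benign-by-construction; no
  follow-up misclassification mechanism is provided.
* The triage simulation assumes every case has whatever examiner tiers
  its strategy needs; infeasible designs fail loudly rather than being
  imputed.
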