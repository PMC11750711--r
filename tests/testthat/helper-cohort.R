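# Shared fixtures, generated in code.

# A small but non-degenerate cohort configuration used across tests.
small_config <- function(...) {
  cohort_config(n_centers = 4L, cases_per_center = 30L,
                n_experts = 12L, n_nonexperts = 10L, ...)
}

# One cached small cohort (deterministic; built once per test run).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(small_config(), seed = 402L)
    cache
  }
})

# Random valid 10-category probability vector.
random_prob_vector <- function() {
  x <- stats::rgamma(10, shape = 1)
  x / sum(x)
}

# Independent first-principles metric implementation used as the oracle
# against metric_set(): recomputes every metric by explicit counting over
# expanded per-case vectors, sharing no code with the package.
oracle_metrics <- function(tp, fp, tn, fn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  ref <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  n <- length(ref)
  sens <- if (sum(ref) == 0) NA_real_ else
    sum(pred == 1 & ref == 1) / sum(ref == 1)
  spec <- if (sum(ref == 0) == 0) NA_real_ else
    sum(pred == 0 & ref == 0) / sum(ref == 0)
  ppv <- if (sum(pred) == 0) NA_real_ else
    sum(pred == 1 & ref == 1) / sum(pred == 1)
  acc <- mean(pred == ref)
  f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  p_yes <- mean(pred == 1) * mean(ref == 1)
  p_no <- mean(pred == 0) * mean(ref == 0)
  pe <- p_yes + p_no
  kappa <- if (pe == 1) NA_real_ else (acc - pe) / (1 - pe)
  den <- sqrt(sum(pred == 1)) * sqrt(sum(ref == 1)) *
    sqrt(sum(pred == 0)) * sqrt(sum(ref == 0))
  mcc <- if (den == 0) 0 else
    (sum(pred == 1 & ref == 1) * sum(pred == 0 & ref == 0) -
       sum(pred == 1 & ref == 0) * sum(pred == 0 & ref == 1)) / den
  dor <- if (fp * fn == 0) {
    if (tp * tn > 0) Inf else NA_real_
  } else (tp / fn) / (fp / tn)
  j <- if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1
  list(sensitivity = sens, specificity = spec, accuracy = acc, ppv = ppv,
       f1 = f1, kappa = kappa, mcc = mcc, dor = dor, youden_j = j)
}

# Exhaustive pairwise concordance AUC (positive-negative pair
# enumeration), the oracle for auc().
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Exact two-sided signed-rank p-value by full 2^n sign enumeration,
# the oracle for wilcoxon_signed_rank() at small n.
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Closed-form expected human resources for a triage strategy on a toy
# cohort, by exhaustive expectation over the initial-examiner draw
# (the oracle for simulate_triage's Monte-Carlo aggregate).
oracle_expected_hr <- function(cases, assessments, examiners, ai_call = NULL,
                               strategy) {
  init_tier <- if (strategy %in% c("current_practice",
                                   "ai_assisted_nonexpert"))
    "nonexpert" else "expert"
  design <- unique(assessments[c("case_id", "examiner_id")])
  w <- examiner_sampling_weights(design, examiners, init_tier)
  p_refer <- vapply(cases$case_id, function(cid) {
    rows <- w[w$case_id == cid, ]
    key <- paste(rows$examiner_id, cid)
    akey <- paste(assessments$examiner_id, assessments$case_id)
    i <- match(key, akey)
    refer <- if (strategy == "current_practice") {
      assessments$confidence[i] == "uncertain" |
        assessments$call[i] == "malignant"
    } else {
      assessments$call[i] != ai_call[match(cid, cases$case_id)]
    }
    sum(rows$weight * refer)
  }, numeric(1))
  1 + mean(p_refer)
}
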