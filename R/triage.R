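# Triage workflow simulation: current practice and AI-assisted variants.

TRIAGE_STRATEGIES <- c("current_practice", "ai_assisted_nonexpert",
                       "ai_assisted_expert", "single_expert",
                       "single_nonexpert", "ai_alone")

#' Current-practice triage decision
#'
#' A non-expert examiner makes the initial assessment; the patient is
#' referred to an expert when the initial diagnosis is uncertain or
#' presumed malignant, and the expert's call is then final. Otherwise the
#' initial call stands after a single examination.
#'
#' @param initial_call Initial non-expert call(s),
#'   `"benign"`/`"malignant"`.
#' @param initial_confidence Confidence rating(s): `"certain"`,
#'   `"probable"` or `"uncertain"`.
#' @param expert_call Expert call(s); may be `NA` for cases that are not
#'   referred, but a referred case with a missing expert call is an
#'   error.
#' @return A data.frame with `final_call`, `examinations` (1 or 2) and
#'   `referred`.
#' @export
#' @examples
#' decide_current_practice("benign", "certain", NA)      # kept, 1 exam
#' decide_current_practice("malignant", "certain", "benign")  # referred
decide_current_practice <- function(initial_call, initial_confidence,
                                    expert_call) {
  bad <- !initial_confidence %in% c("certain", "probable", "uncertain")
  if (any(bad)) stop("unknown confidence rating")
  init_mal <- as_malignant(initial_call, "initial calls")
  referred <- initial_confidence == "uncertain" | init_mal
  if (any(referred & is.na(expert_call))) {
    stop("missing expert assessment for a referred case")
  }
  final <- ifelse(referred, expert_call, initial_call)
  data.frame(final_call = final,
             examinations = 1L + referred,
             referred = referred,
             stringsAsFactors = FALSE)
}

#' AI-assisted triage decision
#'
#' The AI model and a human examiner each make an initial assessment; when
#' they agree, the shared call is final after one human examination. On
#' disagreement an expert arbiter (distinct from the initial examiner)
#' makes the final decision, adding a second examination. The arbiter is
#' never consulted on agreement.
#'
#' @param ai_call AI call(s), `"benign"`/`"malignant"`.
#' @param initial_call Initial human call(s).
#' @param arbiter_call Expert arbiter call(s); may be `NA` when the AI and
#'   the initial examiner agree.
#' @return A data.frame with `final_call`, `examinations` and `referred`.
#' @export
decide_ai_assisted <- function(ai_call, initial_call, arbiter_call) {
  ai_mal <- as_malignant(ai_call, "AI calls")
  init_mal <- as_malignant(initial_call, "initial calls")
  referred <- ai_mal != init_mal
  if (any(referred & is.na(arbiter_call))) {
    stop("missing arbiter assessment for a disagreement")
  }
  final <- ifelse(referred, arbiter_call, initial_call)
  data.frame(final_call = final,
             examinations = 1L + referred,
             referred = referred,
             stringsAsFactors = FALSE)
}

# Calls of a weight table's rows, looked up once from the assessments.
lookup_calls <- function(weights, assessments) {
  key <- paste(weights$examiner_id, weights$case_id)
  akey <- paste(assessments$examiner_id, assessments$case_id)
  i <- match(key, akey)
  if (anyNA(i)) stop("review design pair without an assessment")
  list(call = assessments$call[i], confidence = assessments$confidence[i],
       row_examiner = weights$examiner_id)
}

#' Simulate a triage strategy over a cohort
#'
#' Monte-Carlo simulation of one triage workflow. In each replicate, the
#' initial examiner of the required tier is drawn per case with
#' inverse-workload probability ([examiner_sampling_weights()]); where the
#' workflow refers the case, the expert arbiter is drawn the same way
#' among that case's experts, excluding the initial examiner when the
#' initial examiner is an expert. Diagnostic metrics, the expected number
#' of human examinations per management decision (human resources) and
#' the referral fraction are averaged over replicates with percentile
#' confidence intervals; cases are bootstrapped per replicate so the
#' intervals reflect case sampling as well.
#'
#' The AI examination is not counted as a human resource: strategies
#' without referral, including `ai_alone`, cost exactly 1 examination
#' per case. On every replicate `human_resources = 1 + referral
#' fraction`.
#'
#' @param cases Case table with `case_id`, `label`.
#' @param assessments Assessment table (`examiner_id`, `case_id`, `call`,
#'   `confidence`).
#' @param examiners Examiner table (`examiner_id`, `tier`).
#' @param ai_scores Data.frame with `case_id`, `malignancy_score`
#'   (required for AI arms).
#' @param strategy One of `"current_practice"`,
#'   `"ai_assisted_nonexpert"`, `"ai_assisted_expert"`,
#'   `"single_expert"`, `"single_nonexpert"`, `"ai_alone"`.
#' @param cutoff AI classification cutoff (default 0.5).
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @param resample_cases Bootstrap cases within each replicate (default
#'   `TRUE`).
#' @param metrics Metric names to report.
#' @return An object of class `triage_result`: a list with `strategy`,
#'   `metrics` (data.frame metric/estimate/lower/upper),
#'   `human_resources` (estimate + interval), `referral_fraction`,
#'   `n_reps`, `seed`, and `decisions` (per-case decisions of the first
#'   replicate, without case bootstrap).
#' @export
simulate_triage <- function(cases, assessments, examiners,
                            ai_scores = NULL,
                            strategy = TRIAGE_STRATEGIES,
                            cutoff = 0.5, n_reps = 1000L, seed = 1L,
                            level = 0.95, resample_cases = TRUE,
                            metrics = c("sensitivity", "specificity",
                                        "accuracy", "f1", "kappa", "mcc",
                                        "dor", "youden_j")) {
  strategy <- match.arg(strategy)
  design <- unique(assessments[c("case_id", "examiner_id")])

  initial_tier <- switch(strategy,
                         current_practice = "nonexpert",
                         ai_assisted_nonexpert = "nonexpert",
                         single_nonexpert = "nonexpert",
                         ai_assisted_expert = "expert",
                         single_expert = "expert",
                         ai_alone = NA_character_)
  needs_arbiter <- strategy %in% c("current_practice",
                                   "ai_assisted_nonexpert",
                                   "ai_assisted_expert")
  uses_ai <- strategy %in% c("ai_assisted_nonexpert",
                             "ai_assisted_expert", "ai_alone")

  if (uses_ai) {
    if (is.null(ai_scores)) stop("AI scores required for this strategy")
    si <- match(cases$case_id, ai_scores$case_id)
    if (anyNA(si)) stop("case without an AI score")
    ai_call_mal <- ai_scores$malignancy_score[si] > cutoff
  }

  # Per-tier weight tables, grouped by case in cases$case_id order.
  case_order <- cases$case_id
  tier_weights <- function(tier) {
    w <- examiner_sampling_weights(design, examiners, tier)
    w[order(match(w$case_id, case_order)), , drop = FALSE]
  }
  if (!is.na(initial_tier)) {
    w_init <- tier_weights(initial_tier)
    init_info <- lookup_calls(w_init, assessments)
    draw_init <- case_sampler(w_init)
  }
  if (needs_arbiter) {
    w_exp <- tier_weights("expert")
    exp_info <- lookup_calls(w_exp, assessments)
    draw_exp <- case_sampler(w_exp)
    n_experts_per_case <- tabulate(factor(w_exp$case_id,
                                          levels = case_order))
  }

  y <- as_malignant(cases$label, "labels")
  n_cases <- nrow(cases)

  one_replicate <- function() {
    if (!is.na(initial_tier)) {
      pick <- draw_init()
      init_call <- init_info$call[pick]
      init_conf <- init_info$confidence[pick]
      init_examiner <- init_info$row_examiner[pick]
      init_mal <- init_call == "malignant"
    }
    if (strategy == "ai_alone") {
      return(data.frame(case_id = cases$case_id,
                        final_call = malignant_label(ai_call_mal),
                        examinations = 1L, referred = FALSE,
                        stringsAsFactors = FALSE))
    }
    referred <- switch(strategy,
      current_practice = init_conf == "uncertain" | init_mal,
      ai_assisted_nonexpert = ai_call_mal != init_mal,
      ai_assisted_expert = ai_call_mal != init_mal,
      single_expert = rep(FALSE, n_cases),
      single_nonexpert = rep(FALSE, n_cases))
    final <- init_call
    if (needs_arbiter && any(referred)) {
      arb_pick <- draw_exp()
      if (strategy == "ai_assisted_expert") {
        # the arbiter must be a different expert than the initial one
        conflict <- referred & exp_info$row_examiner[arb_pick] ==
          init_examiner
        if (any(conflict & n_experts_per_case < 2L)) {
          stop("a case lacks any eligible arbiter")
        }
        guard <- 0L
        while (any(conflict)) {
          guard <- guard + 1L
          if (guard > 10000L) stop("arbiter redraw did not converge")
          sub <- which(conflict)
          redraw <- sample_one_per_case(
            w_exp[w_exp$case_id %in% cases$case_id[sub], , drop = FALSE])
          arb_pick[sub] <- which(w_exp$case_id %in%
                                   cases$case_id[sub])[redraw]
          conflict[sub] <- exp_info$row_examiner[arb_pick[sub]] ==
            init_examiner[sub]
        }
      }
      final[referred] <- exp_info$call[arb_pick][referred]
    }
    data.frame(case_id = cases$case_id, final_call = final,
               examinations = 1L + referred, referred = referred,
               stringsAsFactors = FALSE)
  }

  metric_cols <- c(metrics, "human_resources", "referral_fraction")
  vals <- matrix(NA_real_, n_reps, length(metric_cols),
                 dimnames = list(NULL, metric_cols))
  decisions <- NULL
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      dec <- one_replicate()
      if (r == 1L) decisions <- dec
      i <- if (resample_cases) sample.int(n_cases, n_cases,
                                          replace = TRUE)
           else seq_len(n_cases)
      ms <- metric_set(confusion(dec$final_call[i], cases$label[i]))
      vals[r, metrics] <- vapply(metrics,
                                 function(m) metric_value(ms, m),
                                 numeric(1))
      vals[r, "referral_fraction"] <- mean(dec$referred[i])
      vals[r, "human_resources"] <- mean(dec$examinations[i])
    }
  })
  a <- (1 - level) / 2
  summ <- data.frame(
    metric = metric_cols,
    estimate = colMeans(vals, na.rm = TRUE),
    lower = apply(vals, 2, stats::quantile, probs = a, na.rm = TRUE,
                  names = FALSE),
    upper = apply(vals, 2, stats::quantile, probs = 1 - a, na.rm = TRUE,
                  names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  hr <- summ[summ$metric == "human_resources", ]
  out <- list(strategy = strategy, cutoff = if (uses_ai) cutoff else NA,
              metrics = summ[!summ$metric %in%
                               c("human_resources",
                                 "referral_fraction"), ],
              human_resources = c(estimate = hr$estimate,
                                  lower = hr$lower, upper = hr$upper),
              referral_fraction =
                summ$estimate[summ$metric == "referral_fraction"],
              n_reps = n_reps, seed = seed, decisions = decisions,
              replicates = vals)
  class(out) <- "triage_result"
  out
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result> %s (%d replicates)\n", x$strategy,
              x$n_reps))
  cat(sprintf("  human resources %.2f (%.2f-%.2f), referral fraction %.3f\n",
              x$human_resources["estimate"], x$human_resources["lower"],
              x$human_resources["upper"], x$referral_fraction))
  f1 <- x$metrics[x$metrics$metric == "f1", ]
  if (nrow(f1)) {
    cat(sprintf("  F1 %.2f%% (%.2f-%.2f)\n", 100 * f1$estimate,
                100 * f1$lower, 100 * f1$upper))
  }
  invisible(x)
}

#' Reduction in expert referrals between two workflows
#'
#' Human resources are `1 + referral fraction`, so the relative reduction
#' in referrals from a baseline workflow to a new one is
#' `100 * (1 - (hr_new - 1) / (hr_baseline - 1))` percent.
#'
#' @param hr_baseline Baseline human resources (> 1).
#' @param hr_new New human resources (>= 1).
#' @return The reduction in percent.
#' @export
#' @examples
#' referral_reduction(1.52, 1.19)  # about 63
referral_reduction <- function(hr_baseline, hr_new) {
  if (hr_baseline <= 1) stop("hr_baseline must exceed 1")
  if (hr_new < 1) stop("hr_new cannot be below 1")
  100 * (1 - (hr_new - 1) / (hr_baseline - 1))
}
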