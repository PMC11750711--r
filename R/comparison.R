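# Reader-versus-AI comparison statistics.

# Extract one named metric from a metric_set.
metric_value <- function(ms, metric) {
  if (!metric %in% names(ms)) stop(sprintf("unknown metric '%s'", metric))
  ms[[metric]]
}

#' Paired examiner-versus-AI metrics on matched case sets
#'
#' For every examiner, computes the chosen metric once from the
#' examiner's own calls and once from the AI predictions restricted to
#' exactly the case set that examiner assessed, so the two numbers in a
#' row are always computed on identical cases.
#'
#' @param assessments Data.frame with `examiner_id`, `case_id`, `call`.
#' @param ai_scores Data.frame with `case_id`, `malignancy_score` (e.g.
#'   from [case_scores()]).
#' @param labels Data.frame with `case_id`, `label`.
#' @param metric Metric name from [metric_set()] (default `"f1"`).
#' @param cutoff AI classification cutoff (default 0.5).
#' @param examiners Optional examiner table supplying `tier`.
#' @return A data.frame with columns `examiner_id`, `tier`, `n_cases`,
#'   `examiner_metric`, `ai_metric`, `undefined` (logical: the metric
#'   could not be computed on that case set for either reader).
#' @export
paired_scores <- function(assessments, ai_scores, labels, metric = "f1",
                          cutoff = 0.5, examiners = NULL) {
  li <- match(assessments$case_id, labels$case_id)
  ai <- match(assessments$case_id, ai_scores$case_id)
  if (anyNA(li)) stop("assessed case without a reference label")
  if (anyNA(ai)) stop("assessed case without an AI prediction")
  lab <- labels$label[li]
  ai_call <- classify(ai_scores$malignancy_score[ai], cutoff)
  ids <- split(seq_len(nrow(assessments)), assessments$examiner_id)
  rows <- lapply(names(ids), function(e) {
    i <- ids[[e]]
    em <- metric_value(metric_set(confusion(assessments$call[i], lab[i])),
                       metric)
    am <- metric_value(metric_set(confusion(ai_call[i], lab[i])), metric)
    tier <- if (is.null(examiners)) NA_character_ else
      examiners$tier[match(e, examiners$examiner_id)]
    data.frame(examiner_id = e, tier = tier, n_cases = length(i),
               examiner_metric = em, ai_metric = am,
               undefined = is.na(em) || is.na(am),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Exact null distribution of the signed-rank statistic W+ over doubled
# midranks (integers even under ties), by convolution. Returns the
# probability vector over W+ in steps of 1/2 (index k = doubled sum k-1).
signed_rank_null <- function(doubled_ranks) {
  dist <- 1
  for (m in doubled_ranks) {
    new <- numeric(length(dist) + m)
    new[seq_along(dist)] <- dist / 2
    new[seq_along(dist) + m] <- new[seq_along(dist) + m] + dist / 2
    dist <- new
  }
  dist
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test on a vector of paired
#' differences. Zero differences are discarded before ranking (the
#' common software convention). For `n <= exact_max` non-zero
#' differences the p-value comes from the exact null distribution of the
#' statistic, computed by convolution over the (midrank-tied) ranks --
#' identical to enumerating all 2^n sign assignments. For larger n, a
#' normal approximation with tie correction and a 0.5 continuity
#' correction is used. All-zero input returns p = 1 by convention.
#'
#' @param differences Numeric vector of paired differences.
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return A list with `statistic` (W+, the sum of positive ranks),
#'   `p_value`, `n` (after zero removal) and `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))$p_value  # 2/2^6 = 0.03125
wilcoxon_signed_rank <- function(differences, exact_max = 25L) {
  if (length(differences) == 0L) stop("need at least one difference")
  if (anyNA(differences)) stop("missing differences")
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n = 0L,
                method = "all zero differences"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    dbl <- as.integer(round(2 * r))
    dist <- signed_rank_null(dbl)
    k <- as.integer(round(2 * w)) + 1L  # index of W+ in the support
    p_le <- sum(dist[seq_len(k)])
    p_ge <- sum(dist[k:length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-z)
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

#' Inverse-workload examiner sampling weights
#'
#' For every case, a selection distribution over the examiners of the
#' requested tier who assessed it, with probability inversely
#' proportional to each examiner's total number of cases assessed. This
#' equalizes examiner representation when one examiner per case is drawn
#' repeatedly, so heavy-workload examiners do not dominate pooled
#' estimates.
#'
#' @param design Data.frame with `case_id`, `examiner_id` (the review
#'   design; workloads are counted from it).
#' @param examiners Examiner table with `examiner_id`, `tier`.
#' @param tier `"expert"` or `"nonexpert"`.
#' @return A data.frame with `case_id`, `examiner_id`, `weight`, where
#'   weights sum to 1 within each case.
#' @export
examiner_sampling_weights <- function(design, examiners, tier) {
  keep_ids <- examiners$examiner_id[examiners$tier == tier]
  sub <- design[design$examiner_id %in% keep_ids, , drop = FALSE]
  missing_cases <- setdiff(design$case_id, sub$case_id)
  if (length(missing_cases) > 0) {
    stop(sprintf("case %s has no eligible %s examiner",
                 missing_cases[1], tier))
  }
  workload <- table(sub$examiner_id)
  w <- 1 / as.numeric(workload[sub$examiner_id])
  tot <- stats::ave(w, sub$case_id, FUN = sum)
  data.frame(case_id = sub$case_id, examiner_id = sub$examiner_id,
             weight = w / tot, stringsAsFactors = FALSE)
}

# Precompiled weighted per-case sampler over a weight table. Returns a
# function that draws one row index per case (first-appearance order of
# case_id) each time it is called; the block structure and cumulative
# weights are computed once. Rows are regrouped by case internally if
# needed.
case_sampler <- function(weights) {
  ids <- factor(weights$case_id, levels = unique(weights$case_id))
  ord <- NULL
  if (is.unsorted(as.integer(ids))) {
    ord <- order(as.integer(ids))
    weights <- weights[ord, , drop = FALSE]
    ids <- factor(weights$case_id, levels = levels(ids))
  }
  sizes <- tabulate(ids)
  first <- cumsum(sizes) - sizes + 1L
  # within-block cumulative weights, normalized so each block ends at 1
  cum <- cumsum(weights$weight)
  block_base <- rep(c(0, cum[first[-1] - 1L]), times = sizes)
  block_tot <- rep(cum[first + sizes - 1L], times = sizes) - block_base
  cum <- (cum - block_base) / block_tot
  id_int <- as.integer(ids)
  n_blocks <- nlevels(ids)
  function(u = NULL) {
    if (is.null(u)) u <- stats::runif(n_blocks)
    below <- cum < rep(u, sizes)
    off <- tabulate(id_int[below], nbins = n_blocks)
    pick <- pmin(first + off, first + sizes - 1L)
    if (!is.null(ord)) pick <- ord[pick]
    pick
  }
}

# One-shot convenience wrapper around case_sampler().
sample_one_per_case <- function(weights, u = NULL) {
  case_sampler(weights)(u)
}

#' Pooled examiner metrics with percentile bootstrap interval
#'
#' Estimates tier-level pooled diagnostic performance by repeated
#' sampling: in each replicate the cases are resampled with replacement
#' (the bootstrap unit is the case) and for every sampled case one
#' examiner of the tier is drawn with inverse-workload probability; the
#' metric suite is computed on those calls. The point estimate is the
#' mean over replicates and the confidence interval the percentile
#' interval of the replicate values.
#'
#' @param assessments Data.frame with `examiner_id`, `case_id`, `call`.
#' @param labels Data.frame with `case_id`, `label`.
#' @param examiners Examiner table with `examiner_id`, `tier`.
#' @param tier `"expert"` or `"nonexpert"`.
#' @param n_reps Number of replicates (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed Integer seed.
#' @param level Confidence level for the percentile interval.
#' @param resample_cases Resample cases with replacement per replicate
#'   (default `TRUE`; `FALSE` isolates the examiner-sampling variation
#'   only).
#' @param metrics Metric names to aggregate.
#' @return A data.frame with one row per metric: `metric`, `estimate`,
#'   `lower`, `upper`, plus attributes `n_reps` and `seed`.
#' @export
pooled_examiner_metrics <- function(assessments, labels, examiners, tier,
                                    n_reps = 1000L, seed = 1L,
                                    level = 0.95, resample_cases = TRUE,
                                    metrics = c("sensitivity",
                                                "specificity", "accuracy",
                                                "f1", "kappa", "mcc",
                                                "youden_j")) {
  if (n_reps < 100) warning("n_reps < 100: intervals will be unstable")
  w <- examiner_sampling_weights(assessments[c("case_id", "examiner_id")],
                                 examiners, tier)
  ord <- order(w$case_id)
  w <- w[ord, , drop = FALSE]
  key <- paste(w$examiner_id, w$case_id)
  akey <- paste(assessments$examiner_id, assessments$case_id)
  call_mal <- as_malignant(assessments$call[match(key, akey)], "calls")
  case_lvls <- unique(w$case_id)
  y <- as_malignant(labels$label[match(case_lvls, labels$case_id)],
                    "labels")
  if (anyNA(y)) stop("assessed case without a reference label")
  n_cases <- length(case_lvls)
  vals <- matrix(NA_real_, n_reps, length(metrics),
                 dimnames = list(NULL, metrics))
  draw <- case_sampler(w)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      pick <- draw()
      calls_r <- call_mal[pick]
      if (resample_cases) {
        i <- sample.int(n_cases, n_cases, replace = TRUE)
      } else {
        i <- seq_len(n_cases)
      }
      ms <- metric_set(confusion(calls_r[i], y[i]))
      vals[r, ] <- vapply(metrics, function(m) metric_value(ms, m),
                          numeric(1))
    }
  })
  a <- (1 - level) / 2
  out <- data.frame(
    metric = metrics,
    estimate = colMeans(vals, na.rm = TRUE),
    lower = apply(vals, 2, stats::quantile, probs = a, na.rm = TRUE,
                  names = FALSE),
    upper = apply(vals, 2, stats::quantile, probs = 1 - a, na.rm = TRUE,
                  names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  out
}

#' Calibration curve and mean absolute calibration error
#'
#' Bins cases into equal-frequency score bins and contrasts the mean
#' predicted malignancy score with the observed malignant proportion per
#' bin. The mean absolute calibration error (MACE) is the bin-count
#' weighted mean of the absolute bin deviations.
#'
#' @param scores Predicted malignancy scores.
#' @param labels Binary labels.
#' @param n_bins Number of equal-frequency bins (default 10).
#' @return An object of class `calibration_curve`: a data.frame with
#'   `bin`, `n`, `mean_score`, `obs_prop`, and attributes `mace` and
#'   `max_dev`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10L) {
  y <- as_malignant(labels, "labels")
  if (length(scores) != length(y)) stop("length mismatch")
  if (length(scores) < n_bins) stop("fewer cases than bins")
  check_prob(scores, "scores")
  br <- unique(stats::quantile(scores, probs = seq(0, 1,
                                                   length.out = n_bins + 1),
                               names = FALSE))
  if (length(br) < 2L) {
    bins <- factor(rep(1L, length(scores)))
  } else {
    bins <- cut(scores, br, include.lowest = TRUE, labels = FALSE)
    bins <- factor(bins)
  }
  out <- data.frame(
    bin = as.integer(levels(bins)),
    n = as.integer(tabulate(bins)),
    mean_score = as.numeric(tapply(scores, bins, mean)),
    obs_prop = as.numeric(tapply(as.numeric(y), bins, mean)),
    row.names = NULL
  )
  dev <- abs(out$mean_score - out$obs_prop)
  attr(out, "mace") <- sum(dev * out$n) / sum(out$n)
  attr(out, "max_dev") <- max(dev)
  class(out) <- c("calibration_curve", "data.frame")
  out
}
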