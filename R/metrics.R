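# Case-level diagnostic-performance metrics.

#' Build a 2x2 confusion matrix from predictions and labels
#'
#' @param predictions Binary predictions: logical, 0/1 or
#'   `"benign"`/`"malignant"`.
#' @param labels Binary reference labels, same encodings.
#' @param ids Optional case identifiers; if given for both vectors they
#'   must match element-wise (mismatched ids are an error, not silently
#'   reordered).
#' @return An object of class `confusion`: a list with integer counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion <- function(predictions, labels, ids = NULL) {
  p <- as_malignant(predictions, "predictions")
  y <- as_malignant(labels, "labels")
  if (length(p) != length(y)) {
    stop("predictions and labels must have equal length")
  }
  if (length(p) == 0L) stop("empty input")
  if (!is.null(ids)) {
    if (anyDuplicated(ids)) stop("duplicated case ids")
  }
  if (anyNA(p) || anyNA(y)) stop("missing values in predictions or labels")
  out <- list(tp = sum(p & y), fp = sum(p & !y),
              tn = sum(!p & !y), fn = sum(!p & y))
  out <- lapply(out, as.integer)
  class(out) <- "confusion"
  out
}

new_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("confusion matrix is empty")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(reference = c("malignant", "benign"),
                              predicted = c("malignant", "benign")))
  print(m)
  invisible(x)
}

# 0/0 proportions are explicit missing values, never coerced to 0.
safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic metric suite from a confusion matrix
#'
#' Computes sensitivity, specificity, accuracy, positive predictive
#' value, F1 (harmonic mean of PPV and sensitivity), Cohen's kappa (with
#' marginal-product chance agreement), the Matthews correlation
#' coefficient, the diagnostic odds ratio, and Youden's J. Optionally the
#' Brier score and AUC when continuous `scores` are supplied.
#'
#' Undefined metrics (e.g. sensitivity with no positive cases) are
#' returned as `NA` and listed in the `undefined` element. The DOR is
#' `+Inf` when `fp * fn == 0` while `tp * tn > 0`; with
#' `haldane = TRUE` a 0.5 continuity correction is added to every cell
#' instead. An MCC denominator with a zero factor yields 0 by the usual
#' convention.
#'
#' @param cm A `confusion` object (or a list with `tp`, `fp`, `tn`, `fn`).
#' @param scores Optional per-case malignancy scores (for Brier/AUC).
#' @param labels Labels matching `scores`.
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to the DOR
#'   when a cell is zero (default `FALSE`: zero-cell DOR is `+Inf` or
#'   `NA`).
#' @return An object of class `metric_set`: a list of the metrics above
#'   plus the counts and an `undefined` character vector.
#' @export
#' @examples
#' metric_set(confusion(c(1, 1, 0, 0), c(1, 0, 0, 1)))
metric_set <- function(cm, scores = NULL, labels = NULL, haldane = FALSE) {
  if (!inherits(cm, "confusion")) {
    cm <- new_confusion(cm$tp, cm$fp, cm$tn, cm$fn)
  }
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  n <- tp + fp + tn + fn
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  ppv <- safe_ratio(tp, tp + fp)
  acc <- (tp + tn) / n
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) NA_real_ else (acc - pe) / (1 - pe)
  mcc_den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else
    (as.double(tp) * tn - as.double(fp) * fn) / mcc_den
  dor <- if (haldane && (tp == 0 || tn == 0 || fp == 0 || fn == 0)) {
    ((tp + 0.5) * (tn + 0.5)) / ((fp + 0.5) * (fn + 0.5))
  } else if (fp * fn == 0) {
    if (tp * tn > 0) Inf else NA_real_
  } else {
    (as.double(tp) * tn) / (as.double(fp) * fn)
  }
  j <- if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
              sensitivity = sens, specificity = spec, accuracy = acc,
              ppv = ppv, f1 = f1, kappa = kappa, mcc = mcc, dor = dor,
              youden_j = j, brier = NA_real_, auc = NA_real_)
  if (!is.null(scores)) {
    if (is.null(labels)) stop("labels required with scores")
    out$brier <- brier(scores, labels)
    y <- as_malignant(labels, "labels")
    out$auc <- if (length(unique(y)) == 2L) auc(scores, labels) else
      NA_real_
  }
  metric_names <- c("sensitivity", "specificity", "accuracy", "ppv", "f1",
                    "kappa", "mcc", "dor", "youden_j")
  out$undefined <- metric_names[vapply(out[metric_names],
                                       function(v) is.na(v), logical(1))]
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, digits = 2, ...) {
  cat(sprintf("<metric_set> n = %d (tp %d, fp %d, tn %d, fn %d)\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  pct <- function(v) if (is.na(v)) "NA" else
    sprintf(paste0("%.", digits, "f%%"), 100 * v)
  cat(sprintf("  sens %s  spec %s  acc %s  F1 %s  J %s\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$accuracy),
              pct(x$f1), pct(x$youden_j)))
  cat(sprintf("  kappa %.3f  MCC %.3f  DOR %s\n", x$kappa, x$mcc,
              if (is.na(x$dor)) "NA" else format(round(x$dor, 2))))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.4f  Brier %.4f\n", x$auc,
                                 x$brier))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Brier score
#'
#' Mean squared difference between the predicted malignancy score and the
#' 0/1 reference label.
#'
#' @param scores Numeric vector of probabilities.
#' @param labels Binary labels.
#' @return A number in `[0, 1]`.
#' @export
brier <- function(scores, labels) {
  y <- as_malignant(labels, "labels")
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(y)) stop("length mismatch")
  check_prob(scores, "scores")
  mean((scores - as.numeric(y))^2)
}

#' Area under the ROC curve (concordance probability)
#'
#' The AUC equals the Mann-Whitney concordance
#' `P(score+ > score-) + 0.5 P(tie)` over all positive-negative pairs,
#' computed from midranks so ties contribute one half.
#'
#' @inheritParams brier
#' @return A number in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as_malignant(labels, "labels")
  if (length(scores) != length(y)) stop("length mismatch")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (as.double(n1) * n0)
}

#' Jeffreys interval for a binomial proportion
#'
#' Equal-tailed credible interval from the Jeffreys posterior
#' `Beta(successes + 1/2, n - successes + 1/2)`, with the usual boundary
#' conventions: the lower bound is 0 when `successes == 0` and the upper
#' bound is 1 when `successes == n`.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` on the probability
#'   scale.
#' @export
#' @examples
#' round(100 * jeffreys_ci(216, 233), 2)  # 88.83 95.53
jeffreys_ci <- function(successes, n, level = 0.95) {
  if (length(successes) != 1L || length(n) != 1L ||
      successes < 0 || n <= 0 || successes > n ||
      successes != round(successes) || n != round(n)) {
    stop("need integer counts with 0 <= successes <= n, n > 0")
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  a <- (1 - level) / 2
  lo <- if (successes == 0) 0 else
    stats::qbeta(a, successes + 0.5, n - successes + 0.5)
  hi <- if (successes == n) 1 else
    stats::qbeta(1 - a, successes + 0.5, n - successes + 0.5)
  c(lower = lo, upper = hi)
}

#' Reconstruct a confusion matrix from printed sensitivity/specificity
#'
#' Given a sensitivity and specificity printed as percentages plus the
#' class sizes, finds the integer cell counts: `tp` minimizes
#' `|tp / n_pos - sensitivity|` and `tn` minimizes
#' `|tn / n_neg - specificity|`. An exact rounding tie (the target
#' fraction falls exactly halfway between two achievable counts) is
#' reported via a warning and resolved upward.
#'
#' @param sensitivity,specificity Percentages (e.g. `84.88`).
#' @param n_pos,n_neg Numbers of positive and negative cases.
#' @return A `confusion` object.
#' @export
#' @examples
#' reconstruct_confusion(84.88, 87.30, 1085, 1575)
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg) {
  if (sensitivity < 0 || sensitivity > 100 ||
      specificity < 0 || specificity > 100) {
    stop("sensitivity and specificity must be percentages in [0, 100]")
  }
  if (n_pos < 1 || n_neg < 1) stop("class sizes must be positive")
  nearest_count <- function(target_pct, n, what) {
    x <- target_pct / 100 * n
    if (abs(x - floor(x) - 0.5) < 1e-9) {
      warning(sprintf("%s count is exactly halfway between %d and %d; using %d",
                      what, floor(x), ceiling(x), ceiling(x)))
      return(as.integer(ceiling(x)))
    }
    as.integer(round(x))
  }
  tp <- nearest_count(sensitivity, n_pos, "tp")
  tn <- nearest_count(specificity, n_neg, "tn")
  new_confusion(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Per-subgroup diagnostic metrics
#'
#' Splits the cases by a grouping factor and computes a [metric_set()]
#' within each subgroup. Subgroups where a metric is undefined (e.g. a
#' single-class subgroup) carry `NA` for that metric and are flagged.
#'
#' @inheritParams confusion
#' @param groups Vector mapping each case to exactly one subgroup.
#' @param scores Optional scores for Brier/AUC per subgroup.
#' @return A data.frame with one row per subgroup: `group`, `n`, the
#'   confusion counts, every metric, and `undefined` (comma-separated
#'   flagged metrics).
#' @export
grouped_metrics <- function(predictions, labels, groups, scores = NULL) {
  if (length(groups) != length(labels)) stop("groups must map every case")
  if (anyNA(groups)) stop("every case must belong to exactly one subgroup")
  idx <- split(seq_along(groups), groups)
  rows <- lapply(names(idx), function(g) {
    i <- idx[[g]]
    ms <- metric_set(confusion(predictions[i], labels[i]),
                     scores = if (is.null(scores)) NULL else scores[i],
                     labels = if (is.null(scores)) NULL else labels[i])
    data.frame(group = g, n = ms$n, tp = ms$tp, fp = ms$fp, tn = ms$tn,
               fn = ms$fn, sensitivity = ms$sensitivity,
               specificity = ms$specificity, accuracy = ms$accuracy,
               ppv = ms$ppv, f1 = ms$f1, kappa = ms$kappa, mcc = ms$mcc,
               dor = ms$dor, youden_j = ms$youden_j, brier = ms$brier,
               auc = ms$auc,
               undefined = paste(ms$undefined, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
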