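# Empirical ROC curves, bootstrap confidence bands, matched cutoffs.

#' Empirical ROC curve
#'
#' Computes the empirical ROC over all distinct score thresholds, using
#' the same decision rule as [classify()] (malignant when the score
#' strictly exceeds the threshold). The curve starts at (0, 0)
#' (threshold above every score) and ends at (1, 1); both coordinates are
#' non-decreasing, and its trapezoidal area equals [auc()] exactly.
#'
#' @param scores Numeric malignancy scores.
#' @param labels Binary labels (both classes required).
#' @return An object of class `roc_curve`: a data.frame with columns
#'   `threshold`, `fpr`, `tpr` ordered from (0, 0) to (1, 1).
#' @export
roc_curve <- function(scores, labels) {
  y <- as_malignant(labels, "labels")
  if (length(scores) != length(y)) stop("length mismatch")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; ys <- y[o]
  last <- !duplicated(s, fromLast = TRUE)  # block ends of tied scores
  tpr <- cumsum(ys)[last] / n1
  fpr <- cumsum(!ys)[last] / n0
  out <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc A `roc_curve`.
#' @return The area, equal to [auc()] on the same data.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                         utils::tail(roc$tpr, -1)) / 2)
}

# Sensitivity of an empirical ROC at given specificity values, by linear
# interpolation along the curve (max sensitivity among duplicated
# specificities, which keeps the upper envelope).
sens_at_spec <- function(roc, spec_grid) {
  spec <- 1 - roc$fpr
  sens <- roc$tpr
  keep_max <- tapply(sens, spec, max)
  xs <- as.numeric(names(keep_max))
  stats::approx(xs, as.numeric(keep_max), xout = spec_grid, rule = 2,
                ties = max)$y
}

#' Bootstrap confidence band around a ROC curve
#'
#' Case-level bootstrap: in each replicate the cases are resampled with
#' replacement, the empirical ROC recomputed and its sensitivity read off
#' on a fixed specificity grid by linear interpolation. The band holds
#' the 2.5th and 97.5th percentiles (for `level = 0.95`) of the bootstrap
#' sensitivities at each level of specificity. Degenerate resamples
#' containing a single class are redrawn and counted.
#'
#' @inheritParams roc_curve
#' @param n_boot Number of bootstrap replicates (at least 200).
#' @param grid Specificity grid (default 1001 equally spaced points).
#' @param seed Integer seed.
#' @param level Band level.
#' @return An object of class `roc_band`: a data.frame with
#'   `specificity`, `sensitivity` (point estimate), `lower`, `upper`,
#'   plus attributes `n_boot` and `n_degenerate`.
#' @export
roc_confidence_band <- function(scores, labels, n_boot = 2000L,
                                grid = seq(0, 1, length.out = 1001L),
                                seed = 1L, level = 0.95) {
  if (n_boot < 200) stop("n_boot must be at least 200")
  y <- as_malignant(labels, "labels")
  point <- sens_at_spec(roc_curve(scores, labels), grid)
  n <- length(scores)
  boot <- matrix(NA_real_, n_boot, length(grid))
  n_degenerate <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        i <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[i])) == 2L) break
        n_degenerate <- n_degenerate + 1L
      }
      boot[b, ] <- sens_at_spec(roc_curve(scores[i], y[i]), grid)
    }
  })
  a <- (1 - level) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(a, 1 - a),
              names = FALSE)
  out <- data.frame(specificity = grid, sensitivity = point,
                    lower = qs[1, ], upper = qs[2, ])
  attr(out, "n_boot") <- n_boot
  attr(out, "n_degenerate") <- n_degenerate
  class(out) <- c("roc_band", "data.frame")
  out
}

#' Cutoff matching a target specificity or sensitivity
#'
#' Finds the score cutoff whose achieved constrained coordinate is
#' closest to the target without falling below it; ties are broken toward
#' the higher unconstrained coordinate. Classification uses the strict
#' rule of [classify()].
#'
#' @inheritParams roc_curve
#' @param target_specificity,target_sensitivity Exactly one of the two,
#'   in (0, 1].
#' @return A list with `cutoff`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' matched_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1),
#'                target_specificity = 0.5)
matched_cutoff <- function(scores, labels, target_specificity = NULL,
                           target_sensitivity = NULL) {
  if (is.null(target_specificity) == is.null(target_sensitivity)) {
    stop("supply exactly one of target_specificity / target_sensitivity")
  }
  target <- target_specificity %||% target_sensitivity
  if (target <= 0 || target > 1) stop("target must lie in (0, 1]")
  y <- as_malignant(labels, "labels")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  cand <- c(-Inf, sort(unique(scores)))
  sens <- vapply(cand, function(c) sum(y & scores > c) / n1, numeric(1))
  spec <- vapply(cand, function(c) sum(!y & scores <= c) / n0, numeric(1))
  if (!is.null(target_specificity)) {
    ok <- spec >= target - 1e-12
    if (!any(ok)) stop("unattainable specificity target")
    best <- which(ok)[order(spec[ok], -sens[ok])][1]
  } else {
    ok <- sens >= target - 1e-12
    if (!any(ok)) stop("unattainable sensitivity target")
    best <- which(ok)[order(sens[ok], -spec[ok])][1]
  }
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best])
}
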