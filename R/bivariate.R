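# Bivariate random-effects summary of a reader panel.

#' Bivariate random-effects summary of per-examiner accuracy
#'
#' Summarizes a panel of examiners by the mean of their logit
#' (sensitivity, specificity) pairs under a bivariate random-effects
#' model fitted by method of moments: per-examiner logits carry
#' delta-method within-examiner variances `1/tp + 1/fn` and
#' `1/tn + 1/fp`; the between-examiner covariance is the sample
#' covariance of the logits minus the mean within-examiner covariance,
#' floored at positive semi-definite; and the 95% confidence region for
#' the mean is the ellipse of the estimated covariance of the mean. This
#' respects the negative sensitivity-specificity correlation typical of
#' reader panels. A continuity correction is added to every cell of an
#' examiner with a zero cell before the logit transformation.
#'
#' @param counts Data.frame with one row per examiner and columns `tp`,
#'   `fn`, `tn`, `fp` (an `examiner_id` column is carried through if
#'   present). Examiners lacking one of the classes entirely are dropped
#'   with a warning; at least 3 usable examiners are required.
#' @param level Confidence level of the region (default 0.95).
#' @param correction Continuity correction for zero cells (default 0.5).
#' @return An object of class `bivariate_summary`: a list with
#'   `mean_logit` (length 2: sens, spec), `between_cov` (2x2),
#'   `within_cov` (mean within-examiner covariance), `mean_cov`
#'   (covariance of the mean), `center` (back-transformed mean on the
#'   probability scale), `n_examiners`, `level`.
#' @export
bivariate_summary <- function(counts, level = 0.95, correction = 0.5) {
  need <- c("tp", "fn", "tn", "fp")
  if (!all(need %in% names(counts))) {
    stop("counts needs columns tp, fn, tn, fp")
  }
  has_both <- (counts$tp + counts$fn) > 0 & (counts$tn + counts$fp) > 0
  if (any(!has_both)) {
    warning(sprintf("%d examiner(s) without both classes dropped",
                    sum(!has_both)))
    counts <- counts[has_both, , drop = FALSE]
  }
  m <- nrow(counts)
  if (m < 3L) stop("need at least 3 examiners with both classes assessed")
  cc <- function(a, b) {
    zero <- a == 0 | b == 0
    list(a = a + correction * zero, b = b + correction * zero)
  }
  pos <- cc(counts$tp, counts$fn)
  neg <- cc(counts$tn, counts$fp)
  y <- cbind(sens = log(pos$a / pos$b), spec = log(neg$a / neg$b))
  w_sens <- 1 / pos$a + 1 / pos$b
  w_spec <- 1 / neg$a + 1 / neg$b
  within <- diag(c(mean(w_sens), mean(w_spec)))
  total <- stats::cov(y)
  between <- total - within
  # floor at positive semi-definite
  e <- eigen(between, symmetric = TRUE)
  between <- e$vectors %*% diag(pmax(e$values, 0), 2L) %*% t(e$vectors)
  dimnames(between) <- dimnames(total)
  mean_cov <- (between + within) / m
  mu <- colMeans(y)
  out <- list(mean_logit = mu, between_cov = between,
              within_cov = within, mean_cov = mean_cov,
              center = stats::plogis(mu), n_examiners = m, level = level)
  class(out) <- "bivariate_summary"
  out
}

#' @export
print.bivariate_summary <- function(x, ...) {
  cat(sprintf("<bivariate_summary> %d examiners\n", x$n_examiners))
  cat(sprintf("  mean sens %.2f%%, mean spec %.2f%% (logit means %.3f, %.3f)\n",
              100 * x$center["sens"], 100 * x$center["spec"],
              x$mean_logit["sens"], x$mean_logit["spec"]))
  cat(sprintf("  between-examiner logit cov: var %.4f / %.4f, cov %.4f\n",
              x$between_cov[1, 1], x$between_cov[2, 2],
              x$between_cov[1, 2]))
  invisible(x)
}

#' Boundary of the confidence region for the panel mean
#'
#' Points of the elliptical confidence region of a
#' [bivariate_summary()], back-transformed to the
#' (sensitivity, specificity) probability scale.
#'
#' @param summary A `bivariate_summary`.
#' @param n Number of boundary points.
#' @return A data.frame with columns `sensitivity`, `specificity`.
#' @export
ellipse_points <- function(summary, n = 200L) {
  stopifnot(inherits(summary, "bivariate_summary"))
  r <- sqrt(stats::qchisq(summary$level, df = 2))
  theta <- seq(0, 2 * pi, length.out = n)
  circle <- r * cbind(cos(theta), sin(theta))
  # guard the degenerate (point) region
  S <- summary$mean_cov + diag(1e-12, 2L)
  pts <- circle %*% chol(S)
  pts <- sweep(pts, 2L, summary$mean_logit, `+`)
  data.frame(sensitivity = stats::plogis(pts[, 1]),
             specificity = stats::plogis(pts[, 2]))
}
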