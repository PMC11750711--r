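# Case-level malignancy scoring from multi-class image predictions.

#' Malignancy score of one image
#'
#' The risk of malignancy for an image is the sum of the predicted
#' probabilities of the five malignant histological categories.
#'
#' @param probs Numeric vector of length 10 over the categories of
#'   [histology_categories()]: non-negative entries summing to 1 (within
#'   `tol`).
#' @param tol Tolerance on the probability sum.
#' @return A single probability in `[0, 1]`.
#' @export
#' @examples
#' image_malignancy(c(0.5, 0.1, 0.1, 0.1, 0.2, 0, 0, 0, 0, 0))  # 0
#' image_malignancy(rep(0.1, 10))                               # 0.5
image_malignancy <- function(probs, tol = 1e-6) {
  if (length(probs) != 10L) stop("probs must have length 10")
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop("probs must be finite and non-negative")
  }
  if (abs(sum(probs) - 1) > tol) {
    stop(sprintf("probs sum to %.8f, deviating from 1 beyond tolerance %g",
                 sum(probs), tol))
  }
  sum(probs[malignant_idx()])
}

#' Case-level malignancy score
#'
#' The malignancy score of a case is the unweighted arithmetic mean of
#' the malignancy scores of its images.
#'
#' @param image_scores Numeric vector of per-image malignancy scores
#'   (at least one).
#' @return A single probability.
#' @export
case_score <- function(image_scores) {
  if (length(image_scores) == 0L) stop("a case needs at least one image")
  check_prob(image_scores, "image_scores")
  mean(image_scores)
}

#' Score all cases of an image-prediction table
#'
#' Applies [image_malignancy()] to every row of an image-prediction table
#' and averages within case.
#'
#' @param image_preds Data.frame with columns `case_id`, `image_id`, and
#'   `p_1` ... `p_10`.
#' @param tol Tolerance on each row's probability sum.
#' @return A data.frame with columns `case_id`, `malignancy_score`,
#'   `n_images`, one row per case, in first-appearance order.
#' @export
case_scores <- function(image_preds, tol = 1e-6) {
  pcols <- paste0("p_", 1:10)
  if (!all(pcols %in% names(image_preds))) {
    stop("image_preds must contain columns p_1 ... p_10")
  }
  pm <- as.matrix(image_preds[pcols])
  if (any(!is.finite(pm)) || any(pm < 0)) {
    stop("probability entries must be finite and non-negative")
  }
  bad <- abs(rowSums(pm) - 1) > tol
  if (any(bad)) {
    stop(sprintf("probability row %d (image %s) sums to %.8f",
                 which(bad)[1], image_preds$image_id[which(bad)[1]],
                 rowSums(pm)[which(bad)[1]]))
  }
  img_score <- rowSums(pm[, malignant_idx(), drop = FALSE])
  ids <- factor(image_preds$case_id, levels = unique(image_preds$case_id))
  data.frame(
    case_id = levels(ids),
    malignancy_score = as.numeric(tapply(img_score, ids, mean)),
    n_images = as.integer(tapply(img_score, ids, length)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Classify a malignancy score at a cutoff
#'
#' A case is called malignant when its malignancy score strictly exceeds
#' the cutoff; ties at the cutoff classify benign.
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @param cutoff Cutoff in `[0, 1]` (default 0.5).
#' @return Character vector, `"benign"` or `"malignant"`.
#' @export
#' @examples
#' classify(c(0.5, 0.51), cutoff = 0.5)  # "benign" "malignant"
classify <- function(score, cutoff = 0.5) {
  check_prob(score, "score")
  check_prob(cutoff, "cutoff")
  malignant_label(score > cutoff)
}
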