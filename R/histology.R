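#' Histological categories of ovarian lesions
#'
#' The ten-level histology scheme used throughout the package: five benign
#' categories (endometrioma, dermoid, other common benign, solid benign,
#' cystadeno(fibro)ma) and five malignant ones (serous borderline, mucinous
#' intestinal borderline, epithelial ovarian cancer, non-epithelial ovarian
#' cancer, metastasis). Borderline tumors count as malignant. The binary
#' class is a pure function of the category code.
#'
#' @return A data.frame with columns `code`, `label` and `class`
#'   (`"benign"` or `"malignant"`), one row per category, in the fixed
#'   order used by probability-vector columns `p_1` ... `p_10`.
#' @export
#' @examples
#' histology_categories()
histology_categories <- function() {
  data.frame(
    code = c("endometrioma", "dermoid", "other_benign", "solid_benign",
             "cystadenofibroma", "borderline_serous", "borderline_mucinous",
             "epithelial_cancer", "nonepithelial_cancer", "metastasis"),
    label = c("Endometrioma", "Dermoid", "Other common benign",
              "Solid benign", "Cystadeno(fibro)ma", "Borderline (serous)",
              "Borderline (mucinous intestinal)",
              "Ovarian cancer (epithelial)",
              "Ovarian cancer (nonepithelial)", "Metastasis"),
    class = rep(c("benign", "malignant"), each = 5L),
    stringsAsFactors = FALSE
  )
}

#' Binary class of a histological category
#'
#' @param code Character vector of category codes
#'   (see [histology_categories()]).
#' @return Character vector, `"benign"` or `"malignant"`.
#' @export
histology_class <- function(code) {
  cats <- histology_categories()
  i <- match(code, cats$code)
  if (anyNA(i)) {
    stop(sprintf("unknown histology code '%s'", code[which(is.na(i))[1]]))
  }
  cats$class[i]
}

# Indices of the malignant categories within the canonical 10-vector order.
malignant_idx <- function() 6:10
benign_idx <- function() 1:5
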