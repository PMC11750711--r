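#' Configuration for the synthetic multi-center cohort generator
#'
#' Bundles and validates every parameter of the synthetic cohort: cohort
#' layout, histology composition, per-case image counts, examiner panel
#' accuracy, review-design minimums, the confidence link and the AI
#' operating parameters. Defaults emulate the structure of a large
#' multi-center ovarian-lesion test set reviewed by expert and non-expert
#' examiner panels: 2,660 cases (40.8% malignant) across 19 centers,
#' image counts with median 4 (IQR 3-6), 33 examiners per tier with
#' tier-mean sensitivity/specificity of 82.40%/82.67% (expert) and
#' 78.71%/77.27% (non-expert), and each case reviewed by at least 7
#' experts and 6 non-experts, never from the case's own center.
#'
#' @param n_centers Number of centers.
#' @param cases_per_center Cases generated per center.
#' @param category_props Named numeric vector of length 10 over the codes
#'   of [histology_categories()], summing to 1.
#' @param conservative_fraction Fraction of cases managed conservatively
#'   with ultrasound follow-up. Such cases are always benign: their
#'   histology is drawn from the benign categories only and their
#'   reference label is benign by follow-up, not surgery.
#' @param image_size,image_mu Size and mean of the negative binomial whose
#'   1-shifted draw gives the per-case image count (defaults reproduce
#'   median 4, IQR 3-6).
#' @param n_experts,n_nonexperts Panel sizes per tier.
#' @param expert_sens,expert_spec,nonexpert_sens,nonexpert_spec Tier-mean
#'   latent sensitivity/specificity (probability scale; transformed to the
#'   logit scale internally).
#' @param sd_logit_sens,sd_logit_spec Between-examiner standard deviations
#'   of logit sensitivity/specificity within a tier.
#' @param cor_sens_spec Between-examiner correlation of logit sensitivity
#'   and logit specificity (negative values encode the usual
#'   threshold-style trade-off).
#' @param difficulty_weight Weight of the shared latent case difficulty in
#'   the examiner correctness link (0 removes difficulty sharing).
#' @param confidence_thresholds Length-2 numeric `c(certain, uncertain)`:
#'   assessments with perceived difficulty below the first threshold are
#'   rated certain, above the second uncertain, probable in between.
#' @param confidence_jitter SD of the examiner-specific noise added to the
#'   case difficulty before thresholding into a confidence rating.
#' @param min_experts,min_nonexperts Minimum panel sizes per reviewed case.
#' @param extra_experts_mean,extra_nonexperts_mean Poisson means of the
#'   per-case panel sizes in excess of the minimums (defaults reproduce
#'   median panel sizes of 10 experts and 9 non-experts).
#' @param ai_delta Class separation of the AI evidence model on the latent
#'   scale; larger values give a more discriminative AI.
#' @param ai_difficulty_weight Weight of the shared case difficulty in the
#'   AI evidence (couples AI errors to examiner errors).
#' @param ai_image_sd SD of independent per-image evidence noise.
#' @param ai_calibration One of `"calibrated"`, `"overconfident"`,
#'   `"underconfident"`. Calibrated scores satisfy
#'   P(malignant | score = s) = s at the image level by construction.
#' @param ai_category_boost Multiplicative weight placed on the case's true
#'   histological category when the within-class probability mass is
#'   allocated over the five categories of that class.
#' @param ai_dirichlet_conc Concentration of the per-image Dirichlet jitter
#'   on the within-class allocation.
#' @param age_mean,age_sd Age distribution (years, truncated to 18-90).
#' @param exam_years Calendar years sampled uniformly for the examination.
#' @param n_us_systems Number of distinct ultrasound systems; market share
#'   decays geometrically so one manufacturer dominates.
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_centers = 4, cases_per_center = 25)
#' cfg$n_cases
cohort_config <- function(n_centers = 19L,
                          cases_per_center = 140L,
                          category_props = NULL,
                          conservative_fraction = 0,
                          image_size = 3,
                          image_mu = 3.8,
                          n_experts = 33L,
                          n_nonexperts = 33L,
                          expert_sens = 0.8240,
                          expert_spec = 0.8267,
                          nonexpert_sens = 0.7871,
                          nonexpert_spec = 0.7727,
                          sd_logit_sens = 0.35,
                          sd_logit_spec = 0.35,
                          cor_sens_spec = -0.3,
                          difficulty_weight = 1,
                          confidence_thresholds = c(0.3, 1.2),
                          confidence_jitter = 0.3,
                          min_experts = 7L,
                          min_nonexperts = 6L,
                          extra_experts_mean = 3,
                          extra_nonexperts_mean = 3,
                          ai_delta = 2.4,
                          ai_difficulty_weight = 0.95,
                          ai_image_sd = 0.3,
                          ai_calibration = c("calibrated", "overconfident",
                                             "underconfident"),
                          ai_category_boost = 6,
                          ai_dirichlet_conc = 20,
                          age_mean = 45,
                          age_sd = 15,
                          exam_years = 2006:2021,
                          n_us_systems = 8L) {
  cats <- histology_categories()
  if (is.null(category_props)) {
    # Test-data composition of the emulated study; the small "rare benign"
    # group is folded into "other common benign" so that five benign and
    # five malignant categories carry the full 59.2% / 40.8% split.
    counts <- c(endometrioma = 276, dermoid = 340, other_benign = 272,
                solid_benign = 118, cystadenofibroma = 569,
                borderline_serous = 160, borderline_mucinous = 79,
                epithelial_cancer = 611, nonepithelial_cancer = 89,
                metastasis = 146)
    category_props <- counts / sum(counts)
  }
  if (is.null(names(category_props)) ||
      !setequal(names(category_props), cats$code) ||
      length(category_props) != 10L) {
    stop("category_props must be named by the 10 histology codes")
  }
  category_props <- category_props[cats$code]
  if (any(category_props < 0)) stop("category_props must be non-negative")
  if (abs(sum(category_props) - 1) > 1e-6) {
    stop("category_props must sum to 1 (tolerance 1e-6)")
  }
  ai_calibration <- match.arg(ai_calibration)

  if (n_centers < 1 || cases_per_center < 1) {
    stop("n_centers and cases_per_center must be positive")
  }
  if (n_experts < 1 || n_nonexperts < 1) {
    stop("panel sizes must be positive")
  }
  check_prob(c(expert_sens, expert_spec, nonexpert_sens, nonexpert_spec,
               conservative_fraction), "accuracy parameters")
  if (any(c(expert_sens, expert_spec, nonexpert_sens, nonexpert_spec)
          %in% c(0, 1))) {
    stop("latent tier accuracies must lie strictly inside (0, 1)")
  }
  if (sd_logit_sens < 0 || sd_logit_spec < 0 || abs(cor_sens_spec) > 1) {
    stop("between-examiner covariance is not positive semi-definite")
  }
  if (image_size <= 0 || image_mu <= 0) {
    stop("image-count parameters must be positive")
  }
  if (length(confidence_thresholds) != 2L ||
      diff(confidence_thresholds) <= 0) {
    stop("confidence_thresholds must be increasing c(certain, uncertain)")
  }

  out <- list(
    n_centers = as.integer(n_centers),
    cases_per_center = as.integer(cases_per_center),
    n_cases = as.integer(n_centers) * as.integer(cases_per_center),
    category_props = category_props,
    conservative_fraction = conservative_fraction,
    image_size = image_size, image_mu = image_mu,
    n_experts = as.integer(n_experts),
    n_nonexperts = as.integer(n_nonexperts),
    tier_means = list(
      expert = c(sens = expert_sens, spec = expert_spec),
      nonexpert = c(sens = nonexpert_sens, spec = nonexpert_spec)),
    sd_logit_sens = sd_logit_sens, sd_logit_spec = sd_logit_spec,
    cor_sens_spec = cor_sens_spec,
    difficulty_weight = difficulty_weight,
    confidence_thresholds = confidence_thresholds,
    confidence_jitter = confidence_jitter,
    min_experts = as.integer(min_experts),
    min_nonexperts = as.integer(min_nonexperts),
    extra_experts_mean = extra_experts_mean,
    extra_nonexperts_mean = extra_nonexperts_mean,
    ai_delta = ai_delta,
    ai_difficulty_weight = ai_difficulty_weight,
    ai_image_sd = ai_image_sd,
    ai_calibration = ai_calibration,
    ai_category_boost = ai_category_boost,
    ai_dirichlet_conc = ai_dirichlet_conc,
    age_mean = age_mean, age_sd = age_sd,
    exam_years = exam_years,
    n_us_systems = as.integer(n_us_systems)
  )
  class(out) <- "cohort_config"
  out
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d centers x %d cases = %d cases (%.1f%% malignant)\n",
              x$n_centers, x$cases_per_center, x$n_cases,
              100 * sum(x$category_props[malignant_idx()])))
  cat(sprintf("  examiners: %d experts, %d non-experts\n",
              x$n_experts, x$n_nonexperts))
  cat(sprintf("  review minimums: %d experts / %d non-experts per case\n",
              x$min_experts, x$min_nonexperts))
  cat(sprintf("  AI: delta = %.2f, calibration = %s\n",
              x$ai_delta, x$ai_calibration))
  invisible(x)
}
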