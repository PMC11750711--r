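# Synthetic multi-reader multi-case cohort generator.
#
# A single latent difficulty scalar per case drives both examiner errors
# and AI errors, which induces the correlated-difficulty structure that
# the downstream confidence and triage analyses rely on.

#' Generate synthetic cases with latent difficulty
#'
#' Draws one case per row: center, ten-level histology, binary reference
#' label, covariates (age, exam year, ultrasound system), management type,
#' per-case image count, and a standard-normal latent difficulty shared by
#' every downstream simulator. Conservatively managed cases are benign by
#' construction (their reference standard is ultrasound follow-up, not
#' surgery). Image counts are drawn as 1 + NegBin(`image_size`,
#' `image_mu`), whose defaults reproduce a median of 4 images per case
#' with IQR 3-6.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A data.frame with one row per case and columns `case_id`,
#'   `center_id`, `histology`, `label`, `age`, `exam_year`, `us_system`,
#'   `management`, `n_images`, `difficulty`.
#' @export
#' @examples
#' cases <- generate_cases(cohort_config(n_centers = 2,
#'                                       cases_per_center = 10), seed = 1)
#' table(cases$label)
generate_cases <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  cats <- histology_categories()
  n <- config$n_cases
  with_seed(seed, {
    center_id <- sprintf("C%02d", rep(seq_len(config$n_centers),
                                      each = config$cases_per_center))
    conservative <- stats::runif(n) < config$conservative_fraction
    histology <- character(n)
    n_cons <- sum(conservative)
    if (n_cons < n) {
      histology[!conservative] <- sample(cats$code, n - n_cons,
                                         replace = TRUE,
                                         prob = config$category_props)
    }
    if (n_cons > 0) {
      bp <- config$category_props[benign_idx()]
      if (sum(bp) <= 0) stop("conservative cases need benign mass")
      histology[conservative] <- sample(cats$code[benign_idx()], n_cons,
                                        replace = TRUE, prob = bp)
    }
    label <- histology_class(histology)
    age <- round(pmin(90, pmax(18, stats::rnorm(n, config$age_mean,
                                                config$age_sd))))
    exam_year <- sample(config$exam_years, n, replace = TRUE)
    us_w <- 0.1 ^ (seq_len(config$n_us_systems) - 1)
    us_system <- sprintf("US%02d", sample(config$n_us_systems, n,
                                          replace = TRUE, prob = us_w))
    n_images <- 1L + stats::rnbinom(n, size = config$image_size,
                                    mu = config$image_mu)
    data.frame(
      case_id = sprintf("case%05d", seq_len(n)),
      center_id = center_id,
      histology = histology,
      label = label,
      age = age,
      exam_year = exam_year,
      us_system = us_system,
      management = ifelse(conservative, "conservative", "surgery"),
      n_images = n_images,
      difficulty = stats::rnorm(n),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate an examiner panel with latent accuracy
#'
#' Latent (sensitivity, specificity) pairs are drawn per tier from a
#' bivariate logit-normal distribution centered on the tier means of the
#' configuration, with between-examiner covariance
#' `diag(sd_logit_sens, sd_logit_spec) %*% R %*% diag(...)` where `R` has
#' off-diagonal `cor_sens_spec`. With the default negative correlation,
#' examiners trade sensitivity against specificity as real readers with
#' different operating thresholds do.
#'
#' @inheritParams generate_cases
#' @return A data.frame with columns `examiner_id`, `tier`, `home_center`,
#'   `latent_sens`, `latent_spec`.
#' @export
generate_examiner_panel <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  sig <- matrix(c(config$sd_logit_sens^2,
                  rep(config$cor_sens_spec * config$sd_logit_sens *
                        config$sd_logit_spec, 2L),
                  config$sd_logit_spec^2), 2L, 2L)
  if (min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop("between-examiner covariance is not positive semi-definite")
  }
  with_seed(seed, {
    draw_tier <- function(n, prefix, tier) {
      mu <- stats::qlogis(config$tier_means[[tier]])
      y <- if (all(sig == 0)) {
        matrix(rep(mu, each = n), ncol = 2L)
      } else {
        rbvnorm(n, mu, sig)
      }
      data.frame(
        examiner_id = sprintf("%s%02d", prefix, seq_len(n)),
        tier = tier,
        home_center = sprintf("C%02d",
                              1L + (sample.int(n) - 1L) %% config$n_centers),
        latent_sens = stats::plogis(y[, 1L]),
        latent_spec = stats::plogis(y[, 2L]),
        stringsAsFactors = FALSE
      )
    }
    rbind(draw_tier(config$n_experts, "EXP", "expert"),
          draw_tier(config$n_nonexperts, "NEX", "nonexpert"))
  })
}

#' Assign examiners to cases (review design)
#'
#' Every case is reviewed by at least `min_experts` experts and
#' `min_nonexperts` non-experts (defaults 7 and 6), with per-case panel
#' sizes inflated by Poisson extras so the median panel matches a
#' realistic review (10 experts, 9 non-experts). No examiner is ever
#' assigned a case from their own center. Examiners are picked with
#' unequal availability weights so workloads vary across the panel, which
#' makes the inverse-workload sampling weights downstream non-trivial.
#'
#' @param cases Output of [generate_cases()].
#' @param examiners Output of [generate_examiner_panel()].
#' @inheritParams generate_cases
#' @return A data.frame in long format with columns `case_id`,
#'   `examiner_id`.
#' @export
assign_reviews <- function(cases, examiners, config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  mins <- c(expert = config$min_experts, nonexpert = config$min_nonexperts)
  extras <- c(expert = config$extra_experts_mean,
              nonexpert = config$extra_nonexperts_mean)
  # Feasibility: each represented center needs enough external examiners.
  for (tier in names(mins)) {
    ex <- examiners[examiners$tier == tier, ]
    for (ctr in unique(cases$center_id)) {
      if (sum(ex$home_center != ctr) < mins[[tier]]) {
        stop(sprintf(
          "infeasible review design: center %s has only %d external %s examiners (%d required)",
          ctr, sum(ex$home_center != ctr), tier, mins[[tier]]))
      }
    }
  }
  with_seed(seed, {
    avail <- stats::rgamma(nrow(examiners), shape = 4, rate = 4)
    names(avail) <- examiners$examiner_id
    out <- vector("list", 2L * nrow(cases))
    k <- 0L
    for (tier in names(mins)) {
      ex <- examiners[examiners$tier == tier, ]
      n_extra <- stats::rpois(nrow(cases), extras[[tier]])
      for (i in seq_len(nrow(cases))) {
        elig <- ex$examiner_id[ex$home_center != cases$center_id[i]]
        n_take <- min(mins[[tier]] + n_extra[i], length(elig))
        picked <- sample(elig, n_take, prob = avail[elig])
        k <- k + 1L
        out[[k]] <- data.frame(case_id = cases$case_id[i],
                               examiner_id = picked,
                               stringsAsFactors = FALSE)
      }
    }
    design <- do.call(rbind, out[seq_len(k)])
    design[order(design$case_id, design$examiner_id), , drop = FALSE]
  })
}

#' Simulate examiner assessments
#'
#' Each assigned (examiner, case) pair yields a binary call and a
#' confidence rating. The probability of a correct call follows a probit
#' link in the shared latent difficulty `d`:
#' `P(correct) = pnorm(qnorm(latent) * sqrt(1 + beta^2) - beta * d)`,
#' where `latent` is the examiner's latent sensitivity (malignant case)
#' or specificity (benign case) and `beta` is `difficulty_weight`.
#' Averaged over `d ~ N(0, 1)` this link returns exactly the configured
#' latent accuracy, so pooled empirical operating points recover the tier
#' means. Confidence is a thresholding of the examiner's noisy perception
#' of the case difficulty, which makes accuracy decrease from certain to
#' probable to uncertain by construction.
#'
#' @param cases Output of [generate_cases()] (must carry `difficulty`).
#' @param examiners Output of [generate_examiner_panel()].
#' @param design Output of [assign_reviews()].
#' @inheritParams generate_cases
#' @return A data.frame with columns `examiner_id`, `case_id`, `call`
#'   (`"benign"`/`"malignant"`) and `confidence` (`"certain"`,
#'   `"probable"`, `"uncertain"`).
#' @export
simulate_assessments <- function(cases, examiners, design, config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (anyDuplicated(design[c("case_id", "examiner_id")])) {
    stop("duplicate (case, examiner) pairs in review design")
  }
  ci <- match(design$case_id, cases$case_id)
  ei <- match(design$examiner_id, examiners$examiner_id)
  if (anyNA(ci) || anyNA(ei)) stop("design references unknown ids")
  d <- cases$difficulty[ci]
  is_mal <- cases$label[ci] == "malignant"
  latent <- ifelse(is_mal, examiners$latent_sens[ei],
                   examiners$latent_spec[ei])
  beta <- config$difficulty_weight
  alpha <- stats::qnorm(latent) * sqrt(1 + beta^2)
  p_correct <- stats::pnorm(alpha - beta * d)
  with_seed(seed, {
    correct <- stats::runif(nrow(design)) < p_correct
    call <- ifelse(correct == is_mal, "malignant", "benign")
    perceived <- d + stats::rnorm(nrow(design), 0, config$confidence_jitter)
    confidence <- cut(perceived,
                      c(-Inf, config$confidence_thresholds, Inf),
                      labels = c("certain", "probable", "uncertain"))
    data.frame(examiner_id = design$examiner_id,
               case_id = design$case_id,
               call = call,
               confidence = as.character(confidence),
               stringsAsFactors = FALSE)
  })
}

#' Simulate AI image-level predictions
#'
#' For each image of a case, a latent evidence value
#' `x = s * (delta/2 - w * d) + eps` is drawn, where `s` is +1 for
#' malignant and -1 for benign cases, `d` the shared case difficulty
#' (weight `w = ai_difficulty_weight`) and `eps ~ N(0, ai_image_sd)` is
#' independent image noise. The image malignancy mass is the exact
#' Bayes posterior `plogis(delta * x / tau^2 + qlogis(prevalence))` with
#' `tau^2 = w^2 + ai_image_sd^2`, which makes calibrated-mode scores
#' calibrated by construction; the overconfident and underconfident modes
#' re-scale the posterior log-odds by 2 and 0.5. The malignancy mass is
#' then spread over the five malignant categories (and its complement
#' over the five benign ones) proportionally to the configured category
#' mix with the case's true category boosted, plus per-image Dirichlet
#' jitter, so each row is a valid 10-category probability vector summing
#' to 1.
#'
#' @inheritParams simulate_assessments
#' @return A data.frame with columns `case_id`, `image_id`,
#'   `p_1` ... `p_10` (category order of [histology_categories()]).
#' @export
simulate_ai_predictions <- function(cases, config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!config$ai_calibration %in%
        c("calibrated", "overconfident", "underconfident")) {
    stop("unknown calibration mode")
  }
  n_img <- cases$n_images
  stopifnot(all(n_img >= 1))
  row_case <- rep(seq_len(nrow(cases)), n_img)
  total <- length(row_case)
  s <- ifelse(cases$label[row_case] == "malignant", 1, -1)
  d <- cases$difficulty[row_case]
  delta <- config$ai_delta
  w <- config$ai_difficulty_weight
  sig_e <- config$ai_image_sd
  tau2 <- w^2 + sig_e^2
  prev <- (1 - config$conservative_fraction) *
    sum(config$category_props[malignant_idx()])
  prev <- min(max(prev, 1e-12), 1 - 1e-12)

  # Within-class allocation weights per case (true category boosted).
  cats <- histology_categories()
  wmat <- matrix(rep(config$category_props, each = nrow(cases)),
                 nrow = nrow(cases))
  colnames(wmat) <- cats$code
  true_col <- match(cases$histology, cats$code)
  wmat[cbind(seq_len(nrow(cases)), true_col)] <-
    wmat[cbind(seq_len(nrow(cases)), true_col)] * config$ai_category_boost
  bi <- benign_idx(); mi <- malignant_idx()
  wmat[, bi] <- wmat[, bi] / pmax(rowSums(wmat[, bi]), 1e-300)
  wmat[, mi] <- wmat[, mi] / pmax(rowSums(wmat[, mi]), 1e-300)

  with_seed(seed, {
    x <- s * (delta / 2 - w * d) + stats::rnorm(total, 0, sig_e)
    lo <- delta * x / tau2 + stats::qlogis(prev)
    lo <- switch(config$ai_calibration,
                 calibrated = lo,
                 overconfident = 2 * lo,
                 underconfident = 0.5 * lo)
    m <- stats::plogis(lo)
    # Per-image Dirichlet jitter on the within-class allocation.
    shape <- config$ai_dirichlet_conc * wmat[row_case, , drop = FALSE]
    g <- matrix(stats::rgamma(length(shape), shape = shape),
                nrow = total)
    gb <- rowSums(g[, bi, drop = FALSE])
    gm <- rowSums(g[, mi, drop = FALSE])
    # Degenerate gamma draws (all-zero class) fall back to the mean split.
    bad_b <- gb <= 0; bad_m <- gm <= 0
    if (any(bad_b)) {
      g[bad_b, bi] <- wmat[row_case[bad_b], bi, drop = FALSE]
      gb[bad_b] <- rowSums(g[bad_b, bi, drop = FALSE])
    }
    if (any(bad_m)) {
      g[bad_m, mi] <- wmat[row_case[bad_m], mi, drop = FALSE]
      gm[bad_m] <- rowSums(g[bad_m, mi, drop = FALSE])
    }
    probs <- cbind((1 - m) * g[, bi, drop = FALSE] / gb,
                   m * g[, mi, drop = FALSE] / gm)
    colnames(probs) <- paste0("p_", 1:10)
    img_seq <- sequence(n_img)
    out <- data.frame(case_id = cases$case_id[row_case],
                      image_id = sprintf("%s_img%d",
                                         cases$case_id[row_case], img_seq),
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(probs))
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_cases()],
#' [generate_examiner_panel()], [assign_reviews()],
#' [simulate_assessments()] and [simulate_ai_predictions()] on named
#' per-stage substreams of one master seed.
#'
#' @inheritParams generate_cases
#' @return An object of class `ova_cohort`: a list with elements `cases`,
#'   `examiners`, `design`, `assessments`, `image_preds`, `config`,
#'   `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_centers = 3,
#'                                      cases_per_center = 12,
#'                                      n_experts = 10, n_nonexperts = 9),
#'                        seed = 7)
#' nrow(coh$assessments)
simulate_cohort <- function(config, seed) {
  cases <- generate_cases(config, stage_seed(seed, "cases"))
  examiners <- generate_examiner_panel(config, stage_seed(seed, "panel"))
  design <- assign_reviews(cases, examiners, config,
                           stage_seed(seed, "design"))
  assessments <- simulate_assessments(cases, examiners, design, config,
                                      stage_seed(seed, "assessments"))
  image_preds <- simulate_ai_predictions(cases, config,
                                         stage_seed(seed, "ai"))
  structure(list(cases = cases, examiners = examiners, design = design,
                 assessments = assessments, image_preds = image_preds,
                 config = config, seed = seed),
            class = "ova_cohort")
}

#' @export
print.ova_cohort <- function(x, ...) {
  cat(sprintf("<ova_cohort> %d cases, %d examiners, %d assessments, %d images (seed %d)\n",
              nrow(x$cases), nrow(x$examiners), nrow(x$assessments),
              nrow(x$image_preds), x$seed))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `cases.csv` (without the latent difficulty column),
#' `examiners.csv`, `design.csv`, `assessments.csv` and
#' `image_preds.csv` to `dir`, UTF-8 with header row and "." decimal
#' separator.
#'
#' @param cohort An `ova_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ova_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cases_pub <- cohort$cases[setdiff(names(cohort$cases), "difficulty")]
  tabs <- list(cases = cases_pub, examiners = cohort$examiners,
               design = cohort$design, assessments = cohort$assessments,
               image_preds = cohort$image_preds)
  files <- file.path(dir, paste0(names(tabs), ".csv"))
  for (i in seq_along(tabs)) {
    utils::write.csv(tabs[[i]], files[i], row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(files)
}

#' Read cohort tables from a directory of CSV files
#'
#' @param dir Directory containing the files written by [write_cohort()].
#' @return A list with the tables found (`cases`, `examiners`, `design`,
#'   `assessments`, `image_preds`); missing files are omitted.
#' @export
read_cohort <- function(dir) {
  out <- list()
  for (nm in c("cases", "examiners", "design", "assessments",
               "image_preds")) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) {
      out[[nm]] <- utils::read.csv(f, stringsAsFactors = FALSE,
                                   fileEncoding = "UTF-8")
    }
  }
  out
}
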