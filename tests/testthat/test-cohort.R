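# Synthetic cohort generator.

test_that("config validation rejects bad parameters", {
  expect_error(cohort_config(n_centers = 0), "positive")
  props <- rep(0.1, 10)
  names(props) <- histology_categories()$code
  props[1] <- 0.2  # sums to 1.1
  expect_error(cohort_config(category_props = props), "sum to 1")
  expect_error(cohort_config(cor_sens_spec = -1.5),
               "positive semi-definite")
  expect_error(cohort_config(expert_sens = 1), "strictly inside")
})

test_that("histology class is a pure function of code, five per class", {
  cats <- histology_categories()
  expect_equal(nrow(cats), 10L)
  expect_equal(sum(cats$class == "benign"), 5L)
  expect_equal(sum(cats$class == "malignant"), 5L)
  expect_equal(histology_class(cats$code), cats$class)
  expect_error(histology_class("adenoma"), "unknown")
})

test_that("case generation matches configured composition", {
  # degenerate distribution: a single category
  props <- stats::setNames(rep(0, 10), histology_categories()$code)
  props["dermoid"] <- 1
  one <- generate_cases(cohort_config(n_centers = 2, cases_per_center = 20,
                                      category_props = props), seed = 1)
  expect_true(all(one$histology == "dermoid"))
  expect_true(all(one$label == "benign"))

  # frequencies converge: within 3 binomial SE per category at n = 10,000
  cfg <- cohort_config(n_centers = 10, cases_per_center = 1000)
  cases <- generate_cases(cfg, seed = 2)
  n <- nrow(cases)
  freq <- table(factor(cases$histology,
                       levels = histology_categories()$code)) / n
  se <- sqrt(cfg$category_props * (1 - cfg$category_props) / n)
  expect_true(all(abs(freq - cfg$category_props) <= 3 * se))
  # defaults put 40.8% of mass on the malignant class
  expect_equal(sum(cfg$category_props[6:10]), 0.408, tolerance = 1e-3)

  # image counts: median 4, quartiles 3 and 6
  expect_equal(unname(stats::quantile(cases$n_images, c(.25, .5, .75))),
               c(3, 4, 6))
  expect_true(all(cases$n_images >= 1))

  # label is the histology class for surgical cases; conservative benign
  expect_equal(cases$label, histology_class(cases$histology))
  cons <- generate_cases(cohort_config(n_centers = 2,
                                       cases_per_center = 200,
                                       conservative_fraction = 1),
                         seed = 3)
  expect_true(all(cons$label == "benign"))
  expect_true(all(cons$management == "conservative"))
})

test_that("examiner panel draws from the configured logit-normal", {
  # zero covariance: all examiners in a tier identical
  cfg0 <- small_config(sd_logit_sens = 0, sd_logit_spec = 0,
                       cor_sens_spec = 0)
  p0 <- generate_examiner_panel(cfg0, seed = 4)
  expect_equal(length(unique(p0$latent_sens[p0$tier == "expert"])), 1L)
  expect_equal(p0$latent_sens[p0$tier == "expert"][1], 0.8240)
  expect_equal(p0$latent_spec[p0$tier == "expert"][1], 0.8267)

  # law of large numbers: logit-mean recovered over many draws
  cfg <- cohort_config(n_centers = 4, cases_per_center = 5,
                       n_experts = 10000, n_nonexperts = 2)
  p <- generate_examiner_panel(cfg, seed = 5)
  ls <- stats::qlogis(p$latent_sens[p$tier == "expert"])
  mc_se <- cfg$sd_logit_sens / sqrt(10000)
  expect_lt(abs(mean(ls) - stats::qlogis(0.8240)), 3 * mc_se)
  expect_lt(abs(stats::sd(ls) - 0.35), 0.02)
  # experts stochastically dominate non-experts at the defaults
  expect_gt(stats::qlogis(0.8240), stats::qlogis(0.7871))
})

test_that("review design honors minimums and own-center exclusion", {
  coh <- small_cohort()
  des <- coh$design
  tiers <- coh$examiners$tier[match(des$examiner_id,
                                    coh$examiners$examiner_id)]
  per_case <- table(des$case_id, tiers)
  expect_true(all(per_case[, "expert"] >= coh$config$min_experts))
  expect_true(all(per_case[, "nonexpert"] >= coh$config$min_nonexperts))
  hc <- coh$examiners$home_center[match(des$examiner_id,
                                        coh$examiners$examiner_id)]
  cc <- coh$cases$center_id[match(des$case_id, coh$cases$case_id)]
  expect_true(all(hc != cc))
  # workloads vary (inverse-probability weighting must be non-trivial)
  expect_gt(stats::sd(table(des$examiner_id)), 0)

  # infeasible: one center only, every examiner from it
  cfg1 <- cohort_config(n_centers = 1, cases_per_center = 5,
                        n_experts = 8, n_nonexperts = 7)
  cases1 <- generate_cases(cfg1, seed = 6)
  panel1 <- generate_examiner_panel(cfg1, seed = 6)
  panel1$home_center <- "C01"
  expect_error(assign_reviews(cases1, panel1, cfg1, seed = 6),
               "infeasible")

  # determinism
  des2 <- assign_reviews(coh$cases, coh$examiners, coh$config,
                         stage_seed(402L, "design"))
  expect_identical(des, des2)
})

test_that("assessments recover latent accuracy and confidence ordering", {
  # large cohort, zero heterogeneity: pooled accuracy within 3 MC SE
  cfg <- cohort_config(n_centers = 5, cases_per_center = 400,
                       n_experts = 10, n_nonexperts = 10,
                       sd_logit_sens = 0, sd_logit_spec = 0,
                       cor_sens_spec = 0,
                       min_experts = 3, min_nonexperts = 3,
                       extra_experts_mean = 0, extra_nonexperts_mean = 0)
  cases <- generate_cases(cfg, seed = 7)
  panel <- generate_examiner_panel(cfg, seed = 7)
  des <- assign_reviews(cases, panel, cfg, seed = 7)
  ass <- simulate_assessments(cases, panel, des, cfg, seed = 7)
  lab <- cases$label[match(ass$case_id, cases$case_id)]
  tier <- panel$tier[match(ass$examiner_id, panel$examiner_id)]
  for (tr in c("expert", "nonexpert")) {
    pos <- tier == tr & lab == "malignant"
    neg <- tier == tr & lab == "benign"
    sens_hat <- mean(ass$call[pos] == "malignant")
    spec_hat <- mean(ass$call[neg] == "benign")
    tm <- cfg$tier_means[[tr]]
    expect_lt(abs(sens_hat - tm["sens"]),
              3 * sqrt(tm["sens"] * (1 - tm["sens"]) / sum(pos)))
    expect_lt(abs(spec_hat - tm["spec"]),
              3 * sqrt(tm["spec"] * (1 - tm["spec"]) / sum(neg)))
  }
  # accuracy decreases monotonically from certain to uncertain
  correct <- (ass$call == "malignant") == (lab == "malignant")
  acc <- tapply(correct, ass$confidence, mean)
  expect_gt(acc[["certain"]], acc[["probable"]])
  expect_gt(acc[["probable"]], acc[["uncertain"]])
})

test_that("AI predictions are valid probability vectors tied to difficulty", {
  coh <- small_cohort()
  pm <- as.matrix(coh$image_preds[paste0("p_", 1:10)])
  expect_true(all(pm >= 0))
  expect_true(all(abs(rowSums(pm) - 1) < 1e-9))
  expect_equal(nrow(coh$image_preds), sum(coh$cases$n_images))

  # perfect-AI limit: huge separation, no image noise -> benign cases
  # carry essentially zero malignant mass
  cfg <- small_config(ai_delta = 50, ai_image_sd = 1e-9)
  cases <- generate_cases(cfg, seed = 8)
  preds <- simulate_ai_predictions(cases, cfg, seed = 8)
  cs <- case_scores(preds)
  ben <- cases$label[match(cs$case_id, cases$case_id)] == "benign"
  expect_lt(max(cs$malignancy_score[ben]), 1e-6)
  expect_gt(min(cs$malignancy_score[!ben]), 1 - 1e-6)

  cfg_bad <- cfg
  cfg_bad$ai_calibration <- "sharp"
  expect_error(simulate_ai_predictions(cases, cfg_bad, seed = 1),
               "calibration")
})

test_that("identical seeds give bit-identical cohorts", {
  a <- simulate_cohort(small_config(), seed = 99)
  b <- simulate_cohort(small_config(), seed = 99)
  expect_identical(a$cases, b$cases)
  expect_identical(a$design, b$design)
  expect_identical(a$assessments, b$assessments)
  expect_identical(a$image_preds, b$image_preds)
  c <- simulate_cohort(small_config(), seed = 100)
  expect_false(identical(a$assessments, c$assessments))
})

test_that("cohort round-trips through CSV files", {
  coh <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$cases$case_id, coh$cases$case_id)
  expect_equal(back$image_preds$p_4, coh$image_preds$p_4,
               tolerance = 1e-12)
  expect_false("difficulty" %in% names(back$cases))
})
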