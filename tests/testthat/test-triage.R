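# Triage workflow simulation.

test_that("current-practice rules: refer on uncertainty or presumed malignancy", {
  d1 <- decide_current_practice("benign", "certain", NA)
  expect_equal(d1$final_call, "benign")
  expect_equal(d1$examinations, 1L)
  expect_false(d1$referred)
  d2 <- decide_current_practice("malignant", "certain", "benign")
  expect_equal(d2$final_call, "benign")   # expert overrides
  expect_equal(d2$examinations, 2L)
  d3 <- decide_current_practice("benign", "uncertain", "malignant")
  expect_equal(d3$final_call, "malignant")
  expect_equal(d3$examinations, 2L)
  expect_error(decide_current_practice("malignant", "certain", NA),
               "missing expert")
  expect_error(decide_current_practice("benign", "sure", NA),
               "confidence")
})

test_that("AI-assisted rules: arbiter only on disagreement", {
  d1 <- decide_ai_assisted("malignant", "malignant", NA)
  expect_equal(d1$final_call, "malignant")
  expect_equal(d1$examinations, 1L)
  d2 <- decide_ai_assisted("malignant", "benign", "malignant")
  expect_equal(d2$final_call, "malignant")
  expect_equal(d2$examinations, 2L)
  d3 <- decide_ai_assisted("benign", "benign", NA)  # arbiter not needed
  expect_false(d3$referred)
  expect_error(decide_ai_assisted("benign", "malignant", NA),
               "missing arbiter")
})

test_that("referral reduction arithmetic", {
  expect_equal(round(referral_reduction(1.52, 1.19)), 63)
  expect_equal(referral_reduction(1.3, 1.3), 0)
  expect_equal(referral_reduction(1.50, 1.00), 100)
  expect_error(referral_reduction(1.0, 1.0), "exceed 1")
  expect_error(referral_reduction(1.5, 0.9), "below 1")
})

test_that("human resources equal 1 + referral fraction on every replicate", {
  coh <- small_cohort()
  cs <- case_scores(coh$image_preds)
  for (strat in c("current_practice", "ai_assisted_nonexpert",
                  "ai_assisted_expert")) {
    tr <- simulate_triage(coh$cases, coh$assessments, coh$examiners, cs,
                          strategy = strat, n_reps = 30, seed = 3)
    expect_true(all(abs(tr$replicates[, "human_resources"] -
                          1 - tr$replicates[, "referral_fraction"]) <
                      1e-12), label = strat)
    expect_true(all(tr$decisions$referred ==
                      (tr$decisions$examinations == 2L)))
  }
  solo <- simulate_triage(coh$cases, coh$assessments, coh$examiners,
                          strategy = "single_expert", n_reps = 10,
                          seed = 3)
  expect_equal(unname(solo$human_resources["estimate"]), 1)
  aio <- simulate_triage(coh$cases, coh$assessments, coh$examiners, cs,
                         strategy = "ai_alone", n_reps = 5, seed = 3)
  expect_equal(unname(aio$human_resources["estimate"]), 1)
  expect_error(
    simulate_triage(coh$cases, coh$assessments, coh$examiners,
                    strategy = "ai_alone", n_reps = 5, seed = 3),
    "AI scores required")
})

test_that("perfect readers: current practice refers the malignant fraction, AI arms no one", {
  # hand-built toy where every reader and the AI are always right and
  # always certain
  cases <- data.frame(case_id = sprintf("c%d", 1:10),
                      label = rep(c("malignant", "benign"), c(4, 6)),
                      stringsAsFactors = FALSE)
  examiners <- data.frame(examiner_id = c("E1", "E2", "N1", "N2"),
                          tier = c("expert", "expert", "nonexpert",
                                   "nonexpert"))
  ass <- expand.grid(examiner_id = examiners$examiner_id,
                     case_id = cases$case_id, stringsAsFactors = FALSE)
  ass$call <- cases$label[match(ass$case_id, cases$case_id)]
  ass$confidence <- "certain"
  ai <- data.frame(case_id = cases$case_id,
                   malignancy_score = ifelse(cases$label == "malignant",
                                             0.95, 0.05))
  cp <- simulate_triage(cases, ass, examiners, ai, "current_practice",
                        n_reps = 20, seed = 4, resample_cases = FALSE)
  expect_equal(cp$referral_fraction, 0.4)   # exactly the malignant share
  expect_equal(unname(cp$human_resources["estimate"]), 1.4)
  for (strat in c("ai_assisted_nonexpert", "ai_assisted_expert")) {
    tr <- simulate_triage(cases, ass, examiners, ai, strat, n_reps = 20,
                          seed = 4, resample_cases = FALSE)
    expect_equal(tr$referral_fraction, 0, label = strat)
    ms <- tr$metrics
    expect_equal(ms$estimate[ms$metric == "accuracy"], 1)
  }
})

test_that("AI-assisted accuracy dominates the solo reader with perfect arbiters", {
  # initial non-experts err; the expert arbiter pool is always right, so
  # every disagreement is resolved correctly on every replicate
  set.seed(81)
  cases <- data.frame(case_id = sprintf("c%d", 1:12),
                      label = rep(c("malignant", "benign"), 6),
                      stringsAsFactors = FALSE)
  examiners <- data.frame(examiner_id = c("E1", "E2", "N1", "N2"),
                          tier = c("expert", "expert", "nonexpert",
                                   "nonexpert"))
  ass <- expand.grid(examiner_id = examiners$examiner_id,
                     case_id = cases$case_id, stringsAsFactors = FALSE)
  truth <- cases$label[match(ass$case_id, cases$case_id)]
  is_exp <- ass$examiner_id %in% c("E1", "E2")
  flip <- !is_exp & stats::runif(nrow(ass)) < 0.35
  ass$call <- ifelse(flip, ifelse(truth == "malignant", "benign",
                                  "malignant"), truth)
  ass$confidence <- "probable"
  ai <- data.frame(case_id = cases$case_id,
                   malignancy_score = ifelse(cases$label == "malignant",
                                             0.9, 0.1))
  tr <- simulate_triage(cases, ass, examiners, ai,
                        "ai_assisted_nonexpert", n_reps = 50, seed = 5,
                        resample_cases = FALSE)
  solo <- simulate_triage(cases, ass, examiners, ai, "single_nonexpert",
                          n_reps = 50, seed = 5, resample_cases = FALSE)
  expect_true(all(tr$replicates[, "accuracy"] >=
                    solo$replicates[, "accuracy"] - 1e-12))
  # here AI and arbiters are perfect, so assisted accuracy is exactly 1
  expect_equal(unname(tr$metrics$estimate[tr$metrics$metric ==
                                            "accuracy"]), 1)
})

test_that("Monte-Carlo human resources match exhaustive enumeration on a toy", {
  coh <- simulate_cohort(cohort_config(n_centers = 3,
                                       cases_per_center = 4,
                                       n_experts = 5, n_nonexperts = 5,
                                       min_experts = 2,
                                       min_nonexperts = 2,
                                       extra_experts_mean = 1,
                                       extra_nonexperts_mean = 1),
                         seed = 12)
  cs <- case_scores(coh$image_preds)
  ai_call <- classify(cs$malignancy_score)[match(coh$cases$case_id,
                                                 cs$case_id)]
  for (strat in c("current_practice", "ai_assisted_nonexpert")) {
    hr_exact <- oracle_expected_hr(coh$cases, coh$assessments,
                                   coh$examiners, ai_call, strat)
    tr <- simulate_triage(coh$cases, coh$assessments, coh$examiners, cs,
                          strat, n_reps = 4000, seed = 6,
                          resample_cases = FALSE)
    mc_se <- stats::sd(tr$replicates[, "human_resources"]) / sqrt(4000)
    expect_lt(abs(unname(tr$human_resources["estimate"]) - hr_exact),
              3 * mc_se + 1e-9, label = strat)
  }
})

test_that("triage simulation is deterministic under a seed", {
  coh <- small_cohort()
  cs <- case_scores(coh$image_preds)
  a <- simulate_triage(coh$cases, coh$assessments, coh$examiners, cs,
                       "ai_assisted_expert", n_reps = 25, seed = 10)
  b <- simulate_triage(coh$cases, coh$assessments, coh$examiners, cs,
                       "ai_assisted_expert", n_reps = 25, seed = 10)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$decisions, b$decisions)
})
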