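# Diagnostic metric suite.

test_that("confusion matrix counts partition the cases", {
  cm <- confusion(c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(cm$fp + cm$fn, 0L)
  cm2 <- confusion(rep("malignant", 10),
                   rep(c("malignant", "benign"), each = 5))
  expect_equal(unlist(cm2[c("tp", "fp", "tn", "fn")]),
               c(tp = 5L, fp = 5L, tn = 0L, fn = 0L))
  set.seed(41)
  p <- stats::runif(200) > 0.5
  y <- stats::runif(200) > 0.6
  cm3 <- confusion(p, y)
  tally <- table(pred = p, ref = y)
  expect_equal(cm3$tp, unname(tally["TRUE", "TRUE"]))
  expect_equal(cm3$fp, unname(tally["TRUE", "FALSE"]))
  expect_equal(cm3$tn, unname(tally["FALSE", "FALSE"]))
  expect_equal(cm3$fn, unname(tally["FALSE", "TRUE"]))
  expect_equal(cm3$tp + cm3$fp + cm3$tn + cm3$fn, 200L)
  expect_error(confusion(p, y[1:100]), "equal length")
  expect_error(confusion(p, y, ids = rep("x", 200)), "duplicated")
})

test_that("metric_set matches a first-principles oracle on random matrices", {
  set.seed(42)
  for (i in 1:100) {
    cts <- stats::rmultinom(1, size = sample(20:400, 1),
                            prob = stats::rgamma(4, 1) + 0.05)[, 1]
    cm <- list(tp = cts[1], fp = cts[2], tn = cts[3], fn = cts[4])
    ms <- metric_set(cm)
    or <- oracle_metrics(cts[1], cts[2], cts[3], cts[4])
    for (m in names(or)) {
      expect_equal(ms[[m]], or[[m]], tolerance = 1e-12, label = m)
    }
    # internal identities
    if (!is.na(ms$youden_j)) {
      expect_equal(ms$youden_j, ms$sensitivity + ms$specificity - 1,
                   tolerance = 1e-12)
    }
    if (!is.na(ms$f1) && ms$f1 > 0) {
      expect_equal(2 / (1 / ms$ppv + 1 / ms$sensitivity), ms$f1,
                   tolerance = 1e-12)
    }
    if (is.finite(ms$dor) && !is.na(ms$dor)) {
      expect_equal(ms$dor,
                   (ms$sensitivity / (1 - ms$sensitivity)) *
                     (ms$specificity / (1 - ms$specificity)),
                   tolerance = 1e-9)
    }
  }
})

test_that("perfect classifier and degenerate cells behave as documented", {
  ms <- metric_set(list(tp = 7, fp = 0, tn = 13, fn = 0))
  expect_equal(ms$sensitivity, 1)
  expect_equal(ms$specificity, 1)
  expect_equal(ms$f1, 1)
  expect_equal(ms$youden_j, 1)
  expect_identical(ms$dor, Inf)
  # Haldane correction turns the infinite DOR finite
  msh <- metric_set(list(tp = 7, fp = 0, tn = 13, fn = 0), haldane = TRUE)
  expect_true(is.finite(msh$dor))
  # no positives: sensitivity undefined and flagged, never coerced to 0
  ms0 <- metric_set(list(tp = 0, fp = 3, tn = 17, fn = 0))
  expect_true(is.na(ms0$sensitivity))
  expect_true("sensitivity" %in% ms0$undefined)
})

test_that("label swap maps (sens, spec) to (spec, sens), fixes acc/kappa/|mcc|", {
  set.seed(43)
  for (i in 1:25) {
    p <- stats::runif(80) > 0.5
    y <- stats::runif(80) > 0.4
    a <- metric_set(confusion(p, y))
    b <- metric_set(confusion(!p, !y))
    expect_equal(a$sensitivity, b$specificity, tolerance = 1e-12)
    expect_equal(a$specificity, b$sensitivity, tolerance = 1e-12)
    expect_equal(a$accuracy, b$accuracy, tolerance = 1e-12)
    expect_equal(a$kappa, b$kappa, tolerance = 1e-12)
    expect_equal(abs(a$mcc), abs(b$mcc), tolerance = 1e-12)
  }
})

test_that("brier score equals the mean squared residual", {
  expect_equal(brier(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(brier(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  set.seed(44)
  s <- stats::runif(150); y <- stats::runif(150) > 0.5
  expect_equal(brier(s, y), mean((s - as.numeric(y))^2),
               tolerance = 1e-12)
  expect_error(brier(numeric(0), logical(0)), "empty")
})

test_that("auc equals exhaustive pair enumeration", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  set.seed(45)
  y_null <- stats::runif(4000) > 0.5
  expect_equal(auc(stats::runif(4000), y_null), 0.5, tolerance = 0.03)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    y <- stats::runif(n) > 0.5
    if (length(unique(y)) < 2) next
    expect_equal(auc(s, y), oracle_auc(s, as.numeric(y)),
                 tolerance = 1e-12)
  }
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("jeffreys interval matches the Beta posterior and boundaries", {
  expect_equal(unname(jeffreys_ci(216, 233)),
               c(stats::qbeta(0.025, 216.5, 17.5),
                 stats::qbeta(0.975, 216.5, 17.5)))
  expect_equal(unname(jeffreys_ci(10, 10))[2], 1)    # upper boundary
  expect_equal(unname(jeffreys_ci(0, 10))[1], 0)     # lower boundary
  # Monte-Carlo posterior quantile oracle
  set.seed(46)
  draws <- stats::rbeta(1e6, 50.5, 50.5)
  mc <- unname(stats::quantile(draws, c(0.025, 0.975)))
  expect_equal(unname(jeffreys_ci(50, 100)), mc, tolerance = 0.002)
  expect_error(jeffreys_ci(11, 10), "<= n")
  expect_error(jeffreys_ci(5, 10, level = 1.2), "level")
})

test_that("confusion reconstruction inverts printed sens/spec", {
  cm <- reconstruct_confusion(84.88, 87.30, 1085, 1575)
  # enumeration oracle: integer tp minimizing |tp/n_pos - target|
  tp_star <- which.min(abs((0:1085) / 1085 - 0.8488)) - 1L
  tn_star <- which.min(abs((0:1575) / 1575 - 0.8730)) - 1L
  expect_equal(cm$tp, tp_star)
  expect_equal(cm$tn, tn_star)
  expect_equal(unlist(cm[c("tp", "fn", "tn", "fp")]),
               c(tp = 921L, fn = 164L, tn = 1375L, fp = 200L))
  cm2 <- reconstruct_confusion(100, 100, 10, 10)
  expect_equal(unlist(cm2[c("tp", "tn", "fp", "fn")]),
               c(tp = 10L, tn = 10L, fp = 0L, fn = 0L))
  cm3 <- reconstruct_confusion(50, 50, 4, 4)
  expect_equal(c(cm3$tp, cm3$tn), c(2L, 2L))
  # exact-half ambiguity is reported
  expect_warning(reconstruct_confusion(50, 100, 5, 5), "halfway")
})

test_that("grouped metrics are consistent with the pooled analysis", {
  set.seed(47)
  p <- stats::runif(120) > 0.5
  y <- stats::runif(120) > 0.4
  g1 <- grouped_metrics(p, y, rep("all", 120))
  ms <- metric_set(confusion(p, y))
  expect_equal(g1$f1, ms$f1)
  expect_equal(g1$kappa, ms$kappa)
  # additivity: subgroup confusions sum to the pooled confusion
  g2 <- grouped_metrics(p, y, rep(c("a", "b"), each = 60))
  expect_equal(sum(g2$tp), ms$tp)
  expect_equal(sum(g2$fp), ms$fp)
  expect_equal(sum(g2$tn), ms$tn)
  expect_equal(sum(g2$fn), ms$fn)
  # single-class subgroup flags undefined metrics instead of imputing
  g3 <- grouped_metrics(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, TRUE),
                        c("x", "x", "y"))
  expect_true(grepl("specificity", g3$undefined[g3$group == "x"]))
  expect_error(grouped_metrics(p, y, rep(NA, 120)), "exactly one")
})
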