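# Pipeline orchestration: validation, staged execution, reporting.

#' Validate pipeline input tables
#'
#' Checks schemas, id referential integrity and value invariants of the
#' cohort tables. Hard errors (schema violations, orphan ids,
#' probability rows breaking the sum tolerance, invalid labels/calls) are
#' distinguished from warnings.
#'
#' @param cases,image_preds,assessments,design,examiners Data.frames as
#'   produced by the synthetic cohort module (any subset may be given;
#'   cross-checks run when both sides are present).
#' @param tol Probability-sum tolerance (default 1e-6).
#' @return A list with `errors` and `warnings` (character vectors) and
#'   `ok` (`TRUE` when there is no hard error).
#' @export
validate_inputs <- function(cases = NULL, image_preds = NULL,
                            assessments = NULL, design = NULL,
                            examiners = NULL, tol = 1e-6) {
  errors <- character()
  warnings <- character()
  need_cols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      errors <<- c(errors, sprintf("%s: missing column(s) %s", what,
                                   paste(miss, collapse = ", ")))
      FALSE
    } else TRUE
  }
  if (!is.null(cases) &&
      need_cols(cases, c("case_id", "center_id", "histology", "label",
                         "management", "n_images"), "cases")) {
    if (anyDuplicated(cases$case_id)) {
      errors <- c(errors, "cases: duplicated case_id")
    }
    bad <- !cases$label %in% c("benign", "malignant")
    if (any(bad)) {
      errors <- c(errors, sprintf("cases: invalid label in row %d",
                                  which(bad)[1]))
    }
    if (any(cases$n_images < 1)) {
      errors <- c(errors, "cases: n_images must be >= 1")
    }
    cons_mal <- cases$management == "conservative" &
      cases$label == "malignant"
    if (any(cons_mal)) {
      errors <- c(errors,
                  "cases: conservatively managed case labelled malignant")
    }
    surg <- cases$management == "surgery" &
      cases$histology %in% histology_categories()$code
    mismatch <- surg & histology_class(cases$histology) != cases$label
    if (any(mismatch)) {
      errors <- c(errors, sprintf(
        "cases: label disagrees with histology class in row %d",
        which(mismatch)[1]))
    }
  }
  if (!is.null(image_preds) &&
      need_cols(image_preds, c("case_id", "image_id", paste0("p_", 1:10)),
                "image_preds")) {
    pm <- as.matrix(image_preds[paste0("p_", 1:10)])
    if (any(pm < 0 | !is.finite(pm))) {
      errors <- c(errors, "image_preds: negative or non-finite entry")
    } else {
      bad <- abs(rowSums(pm) - 1) > tol
      if (any(bad)) {
        errors <- c(errors, sprintf(
          "image_preds: probability row %d (image %s) sums to %.6f",
          which(bad)[1], image_preds$image_id[which(bad)[1]],
          rowSums(pm)[which(bad)[1]]))
      }
    }
    if (!is.null(cases)) {
      orphan <- !image_preds$case_id %in% cases$case_id
      if (any(orphan)) {
        errors <- c(errors, sprintf(
          "image_preds: unknown case id '%s'",
          image_preds$case_id[which(orphan)[1]]))
      }
    }
  }
  if (!is.null(assessments) &&
      need_cols(assessments, c("examiner_id", "case_id", "call",
                               "confidence"), "assessments")) {
    if (anyDuplicated(assessments[c("examiner_id", "case_id")])) {
      errors <- c(errors, "assessments: duplicated (examiner, case) pair")
    }
    if (any(!assessments$call %in% c("benign", "malignant"))) {
      errors <- c(errors, "assessments: invalid call")
    }
    if (any(!assessments$confidence %in%
              c("certain", "probable", "uncertain"))) {
      errors <- c(errors, "assessments: invalid confidence")
    }
    if (!is.null(cases)) {
      orphan <- !assessments$case_id %in% cases$case_id
      if (any(orphan)) {
        errors <- c(errors, sprintf(
          "assessments: unknown case id '%s'",
          assessments$case_id[which(orphan)[1]]))
      }
    }
    if (!is.null(design)) {
      dkey <- paste(design$examiner_id, design$case_id)
      akey <- paste(assessments$examiner_id, assessments$case_id)
      if (any(!akey %in% dkey)) {
        errors <- c(errors,
                    "assessments: pair not present in the review design")
      }
    }
    if (!is.null(examiners) &&
        any(!assessments$examiner_id %in% examiners$examiner_id)) {
      errors <- c(errors, "assessments: unknown examiner id")
    }
  }
  if (!is.null(design) && !is.null(examiners) && !is.null(cases) &&
      all(c("home_center") %in% names(examiners))) {
    hc <- examiners$home_center[match(design$examiner_id,
                                      examiners$examiner_id)]
    cc <- cases$center_id[match(design$case_id, cases$case_id)]
    own <- !is.na(hc) & !is.na(cc) & hc == cc
    if (any(own)) {
      errors <- c(errors,
                  "design: examiner assigned a case from their own center")
    }
  }
  list(errors = errors, warnings = warnings, ok = length(errors) == 0L)
}

# strip non-serializable pieces from a metric_set for JSON output
metrics_json <- function(ms) {
  out <- unclass(ms)
  out$dor <- if (is.infinite(out$dor)) "Inf" else out$dor
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages simulate, score, evaluate, compare, triage and
#' report in dependency order, writing each stage's artifacts under
#' `out_dir`. Stages whose output files already exist are skipped unless
#' `force = TRUE`. All randomness derives from `seed` via named
#' per-stage substreams, so two runs with the same configuration and seed
#' produce identical outputs.
#'
#' @param config A [cohort_config()], or a path to a YAML file whose
#'   top-level keys are `cohort` (arguments of [cohort_config()]) and
#'   optionally `analysis` (elements `cutoff`, `n_boot`, `n_reps`,
#'   `n_bins`, `strategies`).
#' @param seed Master seed (mandatory for the stochastic stages).
#' @param out_dir Output directory.
#' @param stages Subset of
#'   `c("simulate", "score", "evaluate", "compare", "triage", "report")`
#'   or `"all"`.
#' @param force Recompute stages whose outputs already exist.
#' @param analysis Named list overriding analysis settings (`cutoff`,
#'   `n_boot`, `n_reps`, `n_bins`, `strategies`).
#' @param verbose Log stage progress to stderr.
#' @return An object of class `run_report`: per-stage status, wall times,
#'   seeds, warnings and the artifact file list; also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(config, seed, out_dir, stages = "all",
                         force = FALSE, analysis = list(),
                         verbose = TRUE) {
  if (is.character(config)) {
    cfg_yaml <- yaml::read_yaml(config)
    config <- do.call(cohort_config, cfg_yaml$cohort %||% list())
    analysis <- utils::modifyList(cfg_yaml$analysis %||% list(), analysis)
  }
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for the stochastic stages")
  }
  an <- utils::modifyList(
    list(cutoff = 0.5, n_boot = 500L, n_reps = 200L, n_bins = 10L,
         roc_grid = 101L,
         strategies = c("current_practice", "ai_assisted_nonexpert",
                        "ai_assisted_expert", "single_expert",
                        "single_nonexpert", "ai_alone")),
    analysis)
  all_stages <- c("simulate", "score", "evaluate", "compare", "triage",
                  "report")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  report <- list(seed = seed, package_version =
                   as.character(utils::packageVersion("ovatriage")),
                 stages = list())
  t_stage <- function(name, outputs, fun) {
    paths <- file.path(out_dir, outputs)
    if (!name %in% stages) {
      report$stages[[name]] <<- list(status = "not requested")
      return(invisible(NULL))
    }
    if (!force && all(file.exists(paths))) {
      say("[%s] outputs current, skipped", name)
      report$stages[[name]] <<- list(status = "skipped (outputs current)",
                                     files = paths)
      return(invisible(NULL))
    }
    say("[%s] running", name)
    t0 <- proc.time()[["elapsed"]]
    warns <- character()
    withCallingHandlers(fun(), warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    report$stages[[name]] <<- list(
      status = "done", files = paths, warnings = warns,
      seed = stage_seed(seed, name),
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(NULL)
  }

  cohort_files <- c("cases.csv", "examiners.csv", "design.csv",
                    "assessments.csv", "image_preds.csv")
  t_stage("simulate", cohort_files, function() {
    coh <- simulate_cohort(config, stage_seed(seed, "simulate"))
    write_cohort(coh, out_dir)
  })
  coh <- read_cohort(out_dir)
  if (any(an$strategies %in% c("ai_assisted_nonexpert",
                               "ai_assisted_expert", "ai_alone")) &&
      is.null(coh$image_preds) && !"simulate" %in% stages) {
    stop("an AI strategy is requested but image predictions are missing")
  }
  v <- validate_inputs(coh$cases, coh$image_preds, coh$assessments,
                       coh$design, coh$examiners)
  if (!v$ok) {
    stop(sprintf("input validation failed: %s", v$errors[1]))
  }
  labels <- coh$cases[c("case_id", "label")]

  t_stage("score", "case_scores.csv", function() {
    cs <- case_scores(coh$image_preds)
    cs$prediction <- classify(cs$malignancy_score, an$cutoff)
    utils::write.csv(cs, file.path(out_dir, "case_scores.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  })
  scores <- utils::read.csv(file.path(out_dir, "case_scores.csv"),
                            stringsAsFactors = FALSE)
  si <- match(labels$case_id, scores$case_id)
  ai_pred <- scores$prediction[si]
  ai_score <- scores$malignancy_score[si]

  t_stage("evaluate", c("metrics.json", "subgroup_metrics.csv"),
          function() {
    ms <- metric_set(confusion(ai_pred, labels$label),
                     scores = ai_score, labels = labels$label)
    jsonlite::write_json(
      list(ai_models = metrics_json(ms)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    sub <- grouped_metrics(ai_pred, labels$label, coh$cases$center_id,
                           scores = ai_score)
    utils::write.csv(sub, file.path(out_dir, "subgroup_metrics.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  })

  t_stage("compare", c("paired_scores.csv", "roc_curve.csv",
                       "roc_band.csv", "bivariate_summary.json",
                       "calibration.csv", "comparison_report.json"),
          function() {
    sseed <- stage_seed(seed, "compare")
    ps <- paired_scores(coh$assessments, scores, labels,
                        metric = "f1", cutoff = an$cutoff,
                        examiners = coh$examiners)
    utils::write.csv(ps, file.path(out_dir, "paired_scores.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    roc <- roc_curve(ai_score, labels$label)
    utils::write.csv(as.data.frame(roc),
                     file.path(out_dir, "roc_curve.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    band <- roc_confidence_band(ai_score, labels$label,
                                n_boot = max(200L, an$n_boot),
                                grid = seq(0, 1,
                                           length.out = an$roc_grid),
                                seed = sseed)
    utils::write.csv(as.data.frame(band),
                     file.path(out_dir, "roc_band.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    cal <- calibration_curve(ai_score, labels$label, n_bins = an$n_bins)
    utils::write.csv(as.data.frame(cal),
                     file.path(out_dir, "calibration.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    biv <- lapply(c(expert = "expert", nonexpert = "nonexpert"),
                  function(tier) {
      ids <- coh$examiners$examiner_id[coh$examiners$tier == tier]
      sub <- coh$assessments[coh$assessments$examiner_id %in% ids, ]
      lab <- labels$label[match(sub$case_id, labels$case_id)]
      cm_rows <- lapply(split(seq_len(nrow(sub)), sub$examiner_id),
                        function(i) {
        cm <- confusion(sub$call[i], lab[i])
        data.frame(tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp)
      })
      bs <- bivariate_summary(do.call(rbind, cm_rows))
      list(mean_logit = as.list(bs$mean_logit),
           center = as.list(bs$center),
           between_cov = bs$between_cov,
           mean_cov = bs$mean_cov,
           n_examiners = bs$n_examiners)
    })
    jsonlite::write_json(biv,
                         file.path(out_dir, "bivariate_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    wil <- lapply(split(ps, ps$tier), function(df) {
      ok <- !df$undefined
      w <- wilcoxon_signed_rank(df$ai_metric[ok] - df$examiner_metric[ok])
      list(n = sum(ok), statistic = w$statistic, p_value = w$p_value,
           method = w$method,
           mean_delta = mean(df$ai_metric[ok] - df$examiner_metric[ok]))
    })
    pooled <- lapply(c(expert = "expert", nonexpert = "nonexpert"),
                     function(tier) {
      pooled_examiner_metrics(coh$assessments, labels, coh$examiners,
                              tier, n_reps = an$n_reps,
                              seed = stage_seed(seed,
                                                paste0("pool_", tier)))
    })
    jsonlite::write_json(
      list(wilcoxon = wil, pooled = pooled,
           calibration = list(mace = attr(cal, "mace"),
                              max_dev = attr(cal, "max_dev"))),
      file.path(out_dir, "comparison_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })

  t_stage("triage", c("triage_results.json", "decisions.csv"),
          function() {
    res <- lapply(an$strategies, function(s) {
      simulate_triage(coh$cases, coh$assessments, coh$examiners,
                      ai_scores = scores, strategy = s,
                      cutoff = an$cutoff, n_reps = an$n_reps,
                      seed = stage_seed(seed, paste0("triage_", s)))
    })
    names(res) <- an$strategies
    jsonlite::write_json(
      lapply(res, function(r) {
        list(strategy = r$strategy, metrics = r$metrics,
             human_resources = as.list(r$human_resources),
             referral_fraction = r$referral_fraction,
             n_reps = r$n_reps, seed = r$seed)
      }),
      file.path(out_dir, "triage_results.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
    utils::write.csv(res[[1]]$decisions,
                     file.path(out_dir, "decisions.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  })

  t_stage("report", "run_report.json", function() {
    jsonlite::write_json(report,
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  })
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d\n", x$seed))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-9s %s%s\n", nm, st$status,
                if (!is.null(st$wall_time_s))
                  sprintf(" (%.2fs)", st$wall_time_s) else ""))
  }
  invisible(x)
}
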