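#' Pipeline configuration
#'
#' Assembles and validates every knob of the validation pipeline. Defaults
#' reproduce the standard analysis: two-way absolute-agreement single-
#' measure ICC, phi correlations for factorability, the mental-health
#' screening cost weights, and a prevalence grid spanning literature
#' values plus the study prevalence.
#'
#' @param fmap optional [factor_map()]; `NULL` scores the total only.
#' @param weights a [cost_weights()] object.
#' @param prevalence_grid prevalences in (0, 1) for the metrics table.
#' @param diagnosis_rule `"column"` (use a supplied diagnosis flag, e.g. a
#'   clinician's judgement) or `"threshold"` (diagnose at
#'   `criterion_threshold`+ endorsed criteria).
#' @param criterion_threshold integer used when `diagnosis_rule = "threshold"`.
#' @param icc_model passed to [icc_test_retest()].
#' @param correlation_kind `"phi"`, `"tetrachoric"`, or `"both"` for the
#'   factorability block.
#' @param kr20_variance passed to [kr20()].
#' @param seed integer recorded in report metadata.
#' @param rounding decimals used by [format_report()] display.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(fmap = NULL,
                            weights = cost_weights(),
                            prevalence_grid = c(0.05, 0.10, 0.20, 0.3566, 0.40),
                            diagnosis_rule = c("threshold", "column"),
                            criterion_threshold = 5L,
                            icc_model = "twoway_agreement",
                            correlation_kind = c("phi", "tetrachoric", "both"),
                            kr20_variance = "sample",
                            seed = 1234L,
                            rounding = 2L) {
  diagnosis_rule <- match.arg(diagnosis_rule)
  correlation_kind <- match.arg(correlation_kind)
  if (!is.null(fmap) && !inherits(fmap, "factor_map"))
    stop_validation("`fmap` must be a `factor_map` or NULL")
  if (!inherits(weights, "cost_weights"))
    stop_validation("`weights` must be a `cost_weights` object")
  if (any(prevalence_grid <= 0 | prevalence_grid >= 1))
    stop_validation("`prevalence_grid` values must lie strictly in (0, 1)")
  check_scalar_number(criterion_threshold, "criterion_threshold", lower = 0)
  check_scalar_number(seed, "seed")
  check_scalar_number(rounding, "rounding", lower = 0)
  structure(list(fmap = fmap, weights = weights,
                 prevalence_grid = prevalence_grid,
                 diagnosis_rule = diagnosis_rule,
                 criterion_threshold = as.integer(criterion_threshold),
                 icc_model = icc_model,
                 correlation_kind = correlation_kind,
                 kr20_variance = kr20_variance,
                 seed = as.integer(seed), rounding = as.integer(rounding)),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, screenval_error = function(e) {
      e$message <- sprintf("[stage %s] %s", stage, e$message)
      stop(e)
    }),
    warning = function(w) {
      warning(sprintf("[stage %s] %s", stage, conditionMessage(w)), call. = FALSE)
      invokeRestart("muffleWarning")
    })
}

#' Run the full validation pipeline
#'
#' Executes every stage on one data set: scoring, reliability (KR-20, ICC
#' when a retest block is present, Spearman convergent validity),
#' factorability (correlation matrix, KMO, Bartlett, one-factor loadings),
#' ROC/AUC, and the decision-theoretic cut-off table. Deterministic given
#' (data, config); stage warnings are re-raised with the stage name, and
#' stage errors abort with the stage name prefixed.
#'
#' @param data path to a schema-conforming CSV (see [read_responses()]), a
#'   list as returned by [read_responses()], or a `synthetic_cohort`.
#' @param config a [pipeline_config()].
#' @return object of class `validation_report`: a nested list with
#'   `metadata`, `sample`, `reliability`, `factorability`, `roc`,
#'   `cutoffs` blocks, serialisable by [write_report_json()].
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop_validation("`config` must be a `pipeline_config`")
  digest <- NA_character_
  if (is.character(data) && length(data) == 1L) {
    digest <- unname(tools::md5sum(data))
    data <- run_stage("read", read_responses(data))
  } else if (inherits(data, "synthetic_cohort")) {
    data <- list(responses = data$responses,
                 criterion = NULL,
                 criterion_scores = data$criterion_scores,
                 diagnosis = stats::setNames(data$diagnosis,
                                             rownames(data$responses)))
  } else if (!is.list(data) || is.null(data$responses)) {
    stop_validation("`data` must be a CSV path, a read_responses() list, or a synthetic_cohort")
  }

  scores <- run_stage("scoring", score_scale(data$responses, config$fmap))

  # criterion score + diagnosis
  crit <- run_stage("scoring", {
    if (!is.null(data$criterion)) {
      if (config$diagnosis_rule == "column" && !is.null(data$diagnosis)) {
        data.frame(subject_id = rownames(data$responses),
                   criterion_score = as.integer(rowSums(data$criterion)),
                   diagnosis = as.integer(data$diagnosis[rownames(data$responses)]))
      } else {
        score_criterion(data$criterion, config$criterion_threshold)
      }
    } else if (!is.null(data$diagnosis)) {
      data.frame(subject_id = rownames(data$responses),
                 criterion_score = if (!is.null(data$criterion_scores))
                   data$criterion_scores else NA_integer_,
                 diagnosis = as.integer(data$diagnosis[rownames(data$responses)]))
    } else {
      stop_validation("data carries neither criterion items nor a diagnosis column")
    }
  })

  n <- nrow(scores)
  prevalence <- mean(crit$diagnosis)

  reliability <- run_stage("reliability", {
    rel <- list(kr20_total = kr20(data$responses, config$kr20_variance),
                n_test = n)
    rel$kr20_interpretation <- interpretation_band(rel$kr20_total)
    if (!is.null(config$fmap))
      rel$kr20_by_factor <- as.list(kr20_by_factor(data$responses, config$fmap,
                                                   config$kr20_variance))
    if (!anyNA(crit$criterion_score)) {
      sp <- spearman_rho(scores$total, crit$criterion_score)
      rel$spearman_rho <- sp$rho
      rel$spearman_p <- sp$p
      rel$spearman_interpretation <- sp$interpretation
    }
    if (!is.null(data$retest)) {
      ids <- rownames(data$retest)
      retest_totals <- rowSums(data$retest)
      test_totals <- scores$total[match(ids, scores$subject_id)]
      icc <- icc_test_retest(test_totals, retest_totals, config$icc_model)
      rel$icc <- icc$icc; rel$icc_f <- icc$f; rel$icc_p <- icc$p
      rel$icc_model <- icc$model
      rel$icc_interpretation <- icc$interpretation
      rel$n_retest <- icc$n
    }
    rel
  })

  factorability <- run_stage("factor_structure", {
    kinds <- if (config$correlation_kind == "both") c("phi", "tetrachoric")
             else config$correlation_kind
    out <- list()
    for (kind in kinds) {
      r <- if (kind == "phi") phi_matrix(data$responses)
           else nearest_psd(tetrachoric_matrix(data$responses))
      km <- kmo(r)
      bt <- bartlett_sphericity(r, n)
      ld <- one_factor_loadings(r)
      out[[kind]] <- list(kmo = km$kmo, factorable = km$factorable,
                          bartlett_chi2 = bt$chi2, bartlett_df = bt$df,
                          bartlett_p = bt$p,
                          loadings = as.list(ld))
    }
    if (length(kinds) == 1L) out[[1]] else out
  })

  roc <- run_stage("diagnostic_accuracy",
                   roc_curve(scores$total, crit$diagnosis,
                             max_score = ncol(data$responses)))
  cutoffs <- run_stage("diagnostic_accuracy", {
    grid <- unique(sort(c(config$prevalence_grid, prevalence)))
    metrics_table(scores$total, crit$diagnosis, grid, config$weights,
                  max_score = ncol(data$responses))
  })
  best <- suppressMessages(optimal_cutoff(roc, prevalence, config$weights))

  structure(list(
    metadata = list(package_version = as.character(utils::packageVersion("screenval")),
                    seed = config$seed, input_digest = digest,
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sample = list(n = n, n_items = ncol(data$responses),
                  prevalence = prevalence,
                  n_diagnosed = sum(crit$diagnosis)),
    reliability = reliability,
    factorability = factorability,
    roc = list(auc = roc$auc, auc_se = roc$auc_se,
               points = roc$points),
    cutoffs = list(optimal_cutoff = best$cutoff,
                   at_optimal = as.list(best$metrics),
                   table = cutoffs),
    scores = scores, diagnosis = crit$diagnosis),
    class = "validation_report")
}

#' Write a cohort to the pipeline's CSV schema
#'
#' One row per subject with `subject_id`, `spai_01...spai_26` item columns,
#' `goodman_*` criterion columns reconstructed from the criterion count
#' (first `criterion_score` columns set to 1 — the count, not the pattern,
#' is the scored quantity), a `diagnosis` column, and optional
#' `retest_spai_*` columns for the first `retest_n` subjects. A sidecar
#' `<path>.meta.json` records the generator parameters and seeds.
#'
#' @param cohort a [generate_cohort()] result.
#' @param path output CSV path.
#' @param retest_n size of the retest subsample (0 for none).
#' @param stability latent-trait stability used for the retest draw.
#' @param retest_seed seed for the retest stream.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, retest_n = 0L, stability = 0.95,
                             retest_seed = cohort$seed + 1L) {
  if (!inherits(cohort, "synthetic_cohort"))
    stop_validation("`cohort` must be a `synthetic_cohort`")
  n <- nrow(cohort$responses)
  check_scalar_number(retest_n, "retest_n", lower = 0, upper = n)
  K <- cohort$params$criterion_items
  crit <- t(vapply(cohort$criterion_scores,
                   function(s) as.integer(seq_len(K) <= s), integer(K)))
  colnames(crit) <- sprintf("goodman_%02d", seq_len(K))
  df <- data.frame(subject_id = rownames(cohort$responses),
                   cohort$responses, crit,
                   diagnosis = cohort$diagnosis,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (retest_n > 0) {
    rt <- generate_retest(cohort, stability, retest_seed)
    rt <- rt[seq_len(retest_n), , drop = FALSE]
    colnames(rt) <- sprintf("retest_%s", colnames(cohort$responses))
    rtdf <- as.data.frame(matrix(NA_integer_, nrow = n, ncol = ncol(rt),
                                 dimnames = list(NULL, colnames(rt))))
    rtdf[seq_len(retest_n), ] <- rt
    df <- cbind(df, rtdf)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  meta <- list(seed = cohort$seed, n = n, retest_n = retest_n,
               stability = stability, retest_seed = retest_seed,
               params = unclass(cohort$params))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a cohort and write it to CSV
#'
#' Thin driver combining [generate_cohort()] and [write_cohort_csv()].
#'
#' @param params an [irt_params()] object.
#' @param n cohort size.
#' @param seed master seed.
#' @param path output CSV path.
#' @param ... passed to [write_cohort_csv()] (`retest_n`, `stability`, ...).
#' @return `path`, invisibly.
#' @export
simulate_to_csv <- function(params, n, seed, path, ...) {
  write_cohort_csv(generate_cohort(params, n, seed), path, ...)
}

#' Serialise a validation report to JSON
#'
#' @param report a [run_pipeline()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "validation_report"))
    stop_validation("`report` must be a `validation_report`")
  x <- unclass(report)
  x$scores <- NULL; x$diagnosis <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @export
print.validation_report <- function(x, ...) {
  r <- x$reliability
  cat(sprintf("Validation report: n = %d subjects, %d items, prevalence %.2f%%\n",
              x$sample$n, x$sample$n_items, 100 * x$sample$prevalence))
  cat(sprintf("  KR-20 (total scale)     %.3f  [%s]\n",
              r$kr20_total, r$kr20_interpretation))
  if (!is.null(r$icc))
    cat(sprintf("  ICC test-retest         %.3f  (F = %.2f, n = %d)  [%s]\n",
                r$icc, r$icc_f, r$n_retest, r$icc_interpretation))
  if (!is.null(r$spearman_rho))
    cat(sprintf("  Spearman rho vs criterion %.3f  [%s]\n",
                r$spearman_rho, r$spearman_interpretation))
  fb <- if (!is.null(x$factorability$kmo)) list(x$factorability) else x$factorability
  for (blk in fb)
    cat(sprintf("  KMO %.3f | Bartlett chi2 %.2f (df %d, p %.3g)\n",
                blk$kmo, blk$bartlett_chi2, blk$bartlett_df, blk$bartlett_p))
  cat(sprintf("  AUC %.4f (SE %.4f)\n", x$roc$auc, x$roc$auc_se))
  cat(sprintf("  Optimal cut-off at sample prevalence: %d (expected cost %.4f)\n",
              x$cutoffs$optimal_cutoff, x$cutoffs$at_optimal$expected_cost))
  invisible(x)
}

#' Render a report's cut-off table to CSV
#'
#' Mirrors the supplementary-table layout: one row per (prevalence,
#' cut-off) with sensitivity, specificity, +PV, -PV, accuracy and expected
#' cost, percentages rounded to the configured number of decimals.
#'
#' @param report a [run_pipeline()] result.
#' @param path output CSV path.
#' @param rounding decimals for percentage display.
#' @return `path`, invisibly.
#' @export
format_report <- function(report, path, rounding = 2L) {
  if (!inherits(report, "validation_report"))
    stop_validation("`report` must be a `validation_report`")
  tab <- report$cutoffs$table
  pct <- function(x) round(100 * x, rounding)
  out <- data.frame(prevalence = pct(tab$prevalence), cutoff = tab$cutoff,
                    sensitivity = pct(tab$sensitivity),
                    specificity = pct(tab$specificity),
                    ppv = pct(tab$ppv), npv = pct(tab$npv),
                    accuracy = pct(tab$accuracy),
                    expected_cost = round(tab$expected_cost, 4L),
                    optimal = tab$optimal)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
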