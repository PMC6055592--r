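# Top-level analysis: session model -> median aggregation -> combined
# movement + PRS model, each evaluated by ROC.

#' Classify a cohort from its feature table (and optionally PRS)
#'
#' Fits the per-session linear probability model, aggregates each
#' subject's in-sample session predictions by their median, and — when
#' polygenic scores are supplied — fits the combined subject-level model
#' on the frozen median prediction plus the PRS. Each stage is evaluated
#' in-sample by ROC/AUC, mirroring a pilot-scale analysis without
#' cross-validation; see [loocv_subject_auc()] for an out-of-sample
#' variant.
#'
#' @param features per-session feature table from [session_features()].
#' @param subjects roster with `subject_id` and `diagnosis`.
#' @param prs optional PRS table from [compute_prs()].
#' @return A `tremor_analysis` object: list with `session_model`,
#'   `session_roc`, `subject_predictions`, `subject_roc`, and (with PRS)
#'   `combined_model`, `combined_roc`.
#' @export
classify_cohort <- function(features, subjects, prs = NULL) {
  session_model <- fit_session_model(features, subjects)
  yhat <- fitted(session_model)
  df <- session_model$data
  session_roc <- roc_curve(yhat, df$diagnosis)
  subject_predictions <- aggregate_median(yhat, df$subject_id, subjects)
  subject_roc <- roc_curve(subject_predictions$median_prediction,
                           subject_predictions$diagnosis)
  out <- list(
    session_model = session_model,
    session_roc = session_roc,
    subject_predictions = subject_predictions,
    subject_roc = subject_roc,
    combined_model = NULL,
    combined_roc = NULL
  )
  if (!is.null(prs)) {
    out$combined_model <- fit_combined_model(subject_predictions, prs)
    cdf <- out$combined_model$data
    out$combined_roc <- roc_curve(fitted(out$combined_model),
                                  cdf$diagnosis)
  }
  structure(out, class = "tremor_analysis")
}

#' @export
print.tremor_analysis <- function(x, ...) {
  cat("PD vs ET discrimination analysis\n")
  cat(sprintf("  sessions: %d from %d subjects\n", x$session_model$n,
              nrow(x$subject_predictions)))
  cat(sprintf("  session-level AUC:  %.3f\n", x$session_roc$auc))
  cat(sprintf("  subject-level AUC:  %.3f (median aggregation)\n",
              x$subject_roc$auc))
  if (!is.null(x$combined_roc)) {
    cat(sprintf("  combined AUC:       %.3f (movement + PRS)\n",
                x$combined_roc$auc))
  }
  op <- operating_point(x$subject_roc)
  cat(sprintf("  subject operating point: sensitivity %.2f, specificity %.2f\n",
              op["sensitivity"], op["specificity"]))
  invisible(x)
}

#' @export
summary.tremor_analysis <- function(object, ...) {
  cat("Per-session linear probability model:\n")
  print(summary(object$session_model))
  if (!is.null(object$combined_model)) {
    cat("\nCombined movement + PRS model:\n")
    print(summary(object$combined_model))
  }
  cat("\n")
  print(object)
  invisible(object)
}

#' @export
plot.tremor_analysis <- function(x, ...) {
  plot(x$session_roc, col = "black", ...)
  plot(x$subject_roc, add = TRUE, col = "grey40")
  legend_labels <- c(
    sprintf("session (AUC %.2f)", x$session_roc$auc),
    sprintf("subject median (AUC %.2f)", x$subject_roc$auc))
  cols <- c("black", "grey40")
  if (!is.null(x$combined_roc)) {
    plot(x$combined_roc, add = TRUE, col = "grey70")
    legend_labels <- c(legend_labels,
                       sprintf("movement + PRS (AUC %.2f)",
                               x$combined_roc$auc))
    cols <- c(cols, "grey70")
  }
  graphics::legend("bottomright", legend_labels, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Leave-one-subject-out subject-level AUC
#'
#' Out-of-sample variant of the median-aggregated classification: for
#' each subject, the session model is refitted on all other subjects'
#' sessions and the held-out subject's median prediction is computed
#' from that fit.
#'
#' @inheritParams classify_cohort
#' @return A list with `predictions` (per-subject data frame) and `roc`.
#' @export
loocv_subject_auc <- function(features, subjects) {
  ids <- intersect(unique(features$subject_id), subjects$subject_id)
  preds <- vapply(ids, function(sid) {
    train <- features[features$subject_id != sid, , drop = FALSE]
    test <- features[features$subject_id == sid, , drop = FALSE]
    fit <- fit_session_model(train, subjects)
    stats::median(predict(fit, newdata = test))
  }, numeric(1))
  out <- data.frame(
    subject_id = ids, median_prediction = unname(preds),
    diagnosis = subjects$diagnosis[match(ids, subjects$subject_id)],
    stringsAsFactors = FALSE)
  list(predictions = out,
       roc = roc_curve(out$median_prediction, out$diagnosis))
}

#' Run the full pipeline on simulated or on-disk study inputs
#'
#' Convenience wrapper: extracts tremor-positive sessions, computes the
#' feature table, the PRS, and the full classification analysis plus the
#' descriptive group comparisons.
#'
#' @param cohort a list as returned by [simulate_cohort()] (fields
#'   `streams`, `events`, `subjects`, `weights`, `genotypes`).
#' @param lookback_s,max_gap_ms,min_samples session extraction settings
#'   (see [extract_session()]).
#' @return List with `features`, `prs`, `analysis` (a
#'   `tremor_analysis`), `comparisons` (group comparison rows for the
#'   three features, the PRS and the report rates) and `report_rates`.
#' @export
run_pipeline <- function(cohort, lookback_s = 300, max_gap_ms = 1000,
                         min_samples = 250) {
  sessions <- tremor_sessions(cohort$streams, cohort$events,
                              lookback_s = lookback_s,
                              max_gap_ms = max_gap_ms,
                              min_samples = min_samples)
  features <- session_features(sessions)
  prs <- compute_prs(cohort$genotypes, cohort$weights)
  analysis <- classify_cohort(features, cohort$subjects, prs)

  dx <- cohort$subjects$diagnosis[match(features$subject_id,
                                        cohort$subjects$subject_id)]
  pd <- dx == "PD"
  prs_dx <- cohort$subjects$diagnosis[match(prs$subject_id,
                                            cohort$subjects$subject_id)]
  rates <- tremor_report_rates(cohort$events)
  rate_dx <- cohort$subjects$diagnosis[match(rates$subject_id,
                                             cohort$subjects$subject_id)]
  comparisons <- rbind(
    compare_groups(features$log2_energy[pd], features$log2_energy[!pd],
                   "log2_total_energy"),
    compare_groups(features$avg_amp_mg[pd], features$avg_amp_mg[!pd],
                   "avg_amp_mg"),
    compare_groups(features$max_amp_mg[pd], features$max_amp_mg[!pd],
                   "max_amp_mg"),
    compare_groups(prs$score[prs_dx == "PD"], prs$score[prs_dx == "ET"],
                   "prs"),
    compare_groups(rates$proportion[rate_dx == "PD"],
                   rates$proportion[rate_dx == "ET"],
                   "tremor_report_rate", test = "welch-log-t")
  )
  list(features = features, prs = prs, analysis = analysis,
       comparisons = comparisons, report_rates = rates)
}
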