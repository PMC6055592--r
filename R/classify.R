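# Per-session linear-probability classification of PD vs ET, with
# median-per-subject aggregation and a combined movement + PRS model.
#
# The classifier is deliberately a linear probability model fitted by
# ordinary least squares (PD coded 1, ET coded 0): coefficients,
# p-values and the adjusted R^2 are then directly interpretable as
# shifts in predicted class probability, and predictions may fall
# outside [0, 1].

#' Fit the per-session linear probability model
#'
#' OLS regression of diagnosis (PD = 1, ET = 0) on the three tremor
#' features of each gameplay session — log2 total energy, average
#' amplitude and maximum amplitude — with every session treated as an
#' independent observation.
#'
#' @param features per-session feature table from [session_features()].
#' @param subjects data frame with columns `subject_id` and `diagnosis`
#'   (`"PD"` or `"ET"`).
#' @return A `tremor_lpm` object wrapping the [stats::lm] fit; supports
#'   `print`, `summary`, `coef`, `predict`, `fitted` and `residuals`.
#' @export
fit_session_model <- function(features, subjects) {
  df <- merge(features, subjects[, c("subject_id", "diagnosis")],
              by = "subject_id")
  if (nrow(df) < nrow(features)) {
    warning(nrow(features) - nrow(df),
            " session(s) dropped: subject has no diagnosis label")
  }
  flagged <- !is.finite(df$log2_energy)
  if (any(flagged)) {
    warning(sum(flagged), " flagged session(s) with undefined log2 energy",
            " excluded from the model")
    df <- df[!flagged, , drop = FALSE]
  }
  new_lpm(y = as.integer(df$diagnosis == "PD"),
          x = df[, c("log2_energy", "avg_amp_mg", "max_amp_mg")],
          data = df)
}

# Shared OLS core for the session and combined models.
new_lpm <- function(y, x, data) {
  if (length(unique(y)) < 2) {
    stop("both diagnosis classes must be present to fit the model")
  }
  if (min(table(y)) < 2) stop("need at least 2 observations per class")
  zero_var <- vapply(x, function(col) stats::var(col) == 0, logical(1))
  if (any(zero_var)) {
    stop("degenerate predictor(s) with zero variance: ",
         paste(names(x)[zero_var], collapse = ", "))
  }
  df <- cbind(y = y, x)
  fit <- stats::lm(y ~ ., data = df)
  if (fit$rank < ncol(x) + 1) {
    stop("design matrix is rank deficient (n = ", nrow(x), ", p = ",
         ncol(x) + 1, ")")
  }
  structure(
    list(fit = fit, predictors = names(x), data = data,
         n = nrow(x), coding = c(ET = 0, PD = 1)),
    class = "tremor_lpm"
  )
}

#' @export
print.tremor_lpm <- function(x, ...) {
  cat("Linear probability model (PD = 1, ET = 0) on",
      x$n, "observations\n")
  cat("Predictors:", paste(x$predictors, collapse = ", "), "\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' @export
summary.tremor_lpm <- function(object, ...) {
  s <- summary(object$fit)
  out <- list(
    coefficients = s$coefficients,
    adj_r_squared = s$adj.r.squared,
    r_squared = s$r.squared,
    model_p_value = model_p_value(s),
    n = object$n
  )
  class(out) <- "summary.tremor_lpm"
  out
}

model_p_value <- function(s) {
  f <- s$fstatistic
  if (is.null(f)) return(NA_real_)
  unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
}

#' @export
print.summary.tremor_lpm <- function(x, ...) {
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Adjusted R-squared: %.4f  (model p-value %.3g, n = %d)\n",
              x$adj_r_squared, x$model_p_value, x$n))
  invisible(x)
}

#' @export
coef.tremor_lpm <- function(object, ...) stats::coef(object$fit)

#' @export
fitted.tremor_lpm <- function(object, ...) unname(stats::fitted(object$fit))

#' @export
residuals.tremor_lpm <- function(object, ...) {
  unname(stats::residuals(object$fit))
}

#' Predict per-session scores from a fitted linear probability model
#'
#' @param object a `tremor_lpm` fit.
#' @param newdata data frame containing the model's predictor columns;
#'   omitted for in-sample fitted values.
#' @param ... unused.
#' @return Numeric vector of predictions `X beta` (unbounded; this is a
#'   linear probability model).
#' @export
predict.tremor_lpm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata is missing predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  unname(stats::predict(object$fit, newdata = newdata))
}

#' Median-per-subject aggregation of session predictions
#'
#' Summarises each subject's per-session predictions by their median
#' (for an even count, the midpoint of the central pair), the summary
#' used to turn session-level scores into one diagnosis score per
#' subject.
#'
#' @param predictions numeric vector of per-session scores.
#' @param subject_id character vector mapping each session to a subject.
#' @param subjects optional data frame with `subject_id` and `diagnosis`
#'   used to attach the true label.
#' @return Data frame with `subject_id`, `median_prediction`,
#'   `n_sessions` and (when labels were supplied) `diagnosis`.
#' @export
aggregate_median <- function(predictions, subject_id, subjects = NULL) {
  stopifnot(length(predictions) == length(subject_id))
  med <- tapply(predictions, subject_id, stats::median)
  out <- data.frame(
    subject_id = names(med),
    median_prediction = as.numeric(med),
    n_sessions = as.integer(table(subject_id)[names(med)]),
    stringsAsFactors = FALSE
  )
  if (!is.null(subjects)) {
    out$diagnosis <- subjects$diagnosis[match(out$subject_id,
                                              subjects$subject_id)]
  }
  rownames(out) <- NULL
  out
}

#' Fit the combined movement + polygenic risk model
#'
#' OLS of diagnosis (PD = 1) on each subject's median session prediction
#' plus their polygenic risk score. The movement summary enters as a
#' frozen predictor — the session model is not refitted.
#'
#' @param subject_predictions data frame from [aggregate_median()]
#'   (must carry `diagnosis`, or supply `subjects`).
#' @param prs data frame from [compute_prs()].
#' @param subjects optional label table (`subject_id`, `diagnosis`).
#' @return A `tremor_lpm` object with predictors `median_prediction`
#'   and `prs`.
#' @export
fit_combined_model <- function(subject_predictions, prs, subjects = NULL) {
  df <- subject_predictions
  if (!is.null(subjects)) {
    df$diagnosis <- subjects$diagnosis[match(df$subject_id,
                                             subjects$subject_id)]
  }
  if (is.null(df$diagnosis)) stop("diagnosis labels are required")
  df$prs <- prs$score[match(df$subject_id, prs$subject_id)]
  no_prs <- is.na(df$prs)
  if (any(no_prs)) {
    warning(sum(no_prs), " subject(s) without a PRS excluded: ",
            paste(df$subject_id[no_prs], collapse = ", "))
    df <- df[!no_prs, , drop = FALSE]
  }
  if (nrow(df) < 4) stop("fewer than 4 subjects with both inputs")
  new_lpm(y = as.integer(df$diagnosis == "PD"),
          x = df[, c("median_prediction", "prs")],
          data = df)
}
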