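# Descriptive group comparisons: Mann-Whitney U with an exact tie-aware
# null for small samples, the Welch t-test on log-transformed tremor
# report proportions, and cohort summary tables.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The statistic follows the convention
#' `U = #\{x_i > y_j\} + 0.5 * #\{x_i = y_j\}` (so `U + U' = n1 * n2`).
#' For small samples (`n1 * n2 <= exact_limit`) the p-value is computed
#' from the exact permutation null of the midrank sum, obtained by
#' dynamic programming over the observed rank multiset — this remains
#' exact in the presence of ties. Larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples for the two groups.
#' @param exact_limit largest `n1 * n2` for which the exact null is
#'   enumerated.
#' @return An object of class `htest` with the U statistic, the p-value
#'   and the method used.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 400) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  r1 <- sum(r[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  exact <- n1 * n2 <= exact_limit
  if (exact) {
    p <- mwu_exact_p(r, n1, r1)
    method <- "Mann-Whitney U test (exact, tie-aware)"
  } else {
    n <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- u - n1 * n2 / 2
      z <- (z - sign(z) * 0.5) / sigma  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(
    list(statistic = c(U = u), p.value = p, method = method,
         alternative = "two.sided",
         data.name = paste(deparse(substitute(x)), "and",
                           deparse(substitute(y))),
         parameter = c(n1 = n1, n2 = n2)),
    class = "htest"
  )
}

# Exact two-sided p-value for the midrank sum, by dynamic programming
# over the multiset of (doubled, hence integer) midranks. The null
# distribution is symmetric about n1 * (N + 1) / 2, so the two-sided
# p-value doubles up by reflection.
mwu_exact_p <- function(r, n1, r1) {
  n <- length(r)
  r2 <- as.integer(round(2 * r))  # midranks doubled to integers
  max_sum <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # dp[k + 1, s + 1] = number of k-subsets of the ranks seen so far
  # summing to s
  dp <- matrix(0, nrow = n1 + 1, ncol = max_sum + 1)
  dp[1, 1] <- 1
  for (item in r2) {
    kmax <- n1
    for (k in seq(kmax, 1)) {
      shifted <- c(rep(0, item), dp[k, seq_len(max_sum + 1 - item)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  counts <- dp[n1 + 1, ]
  total <- sum(counts)
  support <- which(counts > 0) - 1L
  w_obs <- as.integer(round(2 * r1))
  mu <- n1 * (n + 1)  # doubled mean of the rank sum
  d <- abs(w_obs - mu)
  sum(counts[support + 1L][abs(support - mu) >= d - 1e-9]) / total
}

#' Welch t-test on log-transformed tremor report proportions
#'
#' Compares two groups of per-subject tremor-report proportions after a
#' natural-log transform (the t statistic is invariant to the log base).
#' Subjects with a zero proportion cannot be log-transformed and are
#' excluded with a warning.
#'
#' @param p_group1,p_group2 per-subject proportions in `[0, 1]`.
#' @return An `htest` object from [stats::t.test] on the log scale.
#' @export
t_test_log_proportions <- function(p_group1, p_group2) {
  drop1 <- sum(p_group1 <= 0, na.rm = TRUE)
  drop2 <- sum(p_group2 <= 0, na.rm = TRUE)
  if (drop1 + drop2 > 0) {
    warning(drop1 + drop2,
            " subject(s) with zero report proportion excluded from the",
            " log-scale t-test")
  }
  p1 <- p_group1[!is.na(p_group1) & p_group1 > 0]
  p2 <- p_group2[!is.na(p_group2) & p_group2 > 0]
  if (length(p1) < 2 || length(p2) < 2) {
    stop("each group needs at least 2 positive proportions")
  }
  stats::t.test(log(p1), log(p2))
}

#' Per-subject tremor report rates
#'
#' Proportion of each subject's gameplay sessions in which a tremor was
#' reported on either hand.
#'
#' @param events questionnaire data frame from [read_events_csv()].
#' @return Data frame with `subject_id`, `n_sessions`, `proportion`.
#' @export
tremor_report_rates <- function(events) {
  n <- tapply(events$tremor_reported, events$subject_id, length)
  k <- tapply(events$tremor_reported, events$subject_id, sum)
  data.frame(
    subject_id = names(n),
    n_sessions = as.integer(n),
    proportion = as.numeric(k) / as.numeric(n),
    stringsAsFactors = FALSE
  )
}

#' Group comparison record
#'
#' Convenience wrapper producing one tidy row per compared variable:
#' group means, SDs, sizes, the test statistic and p-value.
#'
#' @param x,y numeric samples (group 1, group 2).
#' @param variable variable name for the row.
#' @param groups character vector of the two group names.
#' @param test `"mann-whitney"` or `"welch-log-t"`.
#' @return One-row data frame.
#' @export
compare_groups <- function(x, y, variable = "value",
                           groups = c("PD", "ET"),
                           test = c("mann-whitney", "welch-log-t")) {
  test <- match.arg(test)
  ht <- switch(test,
               "mann-whitney" = mann_whitney_u(x, y),
               "welch-log-t" = t_test_log_proportions(x, y))
  data.frame(
    variable = variable,
    group1 = groups[1], mean1 = mean(x, na.rm = TRUE),
    sd1 = stats::sd(x, na.rm = TRUE), n1 = sum(!is.na(x)),
    group2 = groups[2], mean2 = mean(y, na.rm = TRUE),
    sd2 = stats::sd(y, na.rm = TRUE), n2 = sum(!is.na(y)),
    test = ht$method, statistic = unname(ht$statistic[1]),
    p_value = ht$p.value,
    stringsAsFactors = FALSE
  )
}

#' Cohort characteristics table
#'
#' Per-diagnosis counts, gender split, median/SD/range of age and of
#' time since diagnosis, and medication counts. Degenerate groups are
#' handled gracefully: an empty roster gives an empty table and a
#' single-subject group reports an undefined (NA) SD.
#'
#' @param subjects roster data frame with columns `subject_id`,
#'   `diagnosis`, and optionally `sex`, `age`, `years_since_diagnosis`,
#'   `medicated`.
#' @return Data frame with one row per diagnosis group.
#' @export
cohort_summary <- function(subjects) {
  if (is.null(subjects) || nrow(subjects) == 0) {
    return(data.frame(diagnosis = character(), n = integer()))
  }
  groups <- split(subjects, subjects$diagnosis)
  rows <- lapply(names(groups), function(g) {
    s <- groups[[g]]
    row <- data.frame(diagnosis = g, n = nrow(s))
    if (!is.null(s$sex)) {
      row$n_male <- sum(s$sex == "M", na.rm = TRUE)
      row$n_female <- sum(s$sex == "F", na.rm = TRUE)
    }
    for (v in c("age", "years_since_diagnosis")) {
      if (!is.null(s[[v]])) {
        row[[paste0(v, "_median")]] <- stats::median(s[[v]], na.rm = TRUE)
        row[[paste0(v, "_sd")]] <- if (sum(!is.na(s[[v]])) > 1) {
          stats::sd(s[[v]], na.rm = TRUE)
        } else NA_real_
        row[[paste0(v, "_min")]] <- min(s[[v]], na.rm = TRUE)
        row[[paste0(v, "_max")]] <- max(s[[v]], na.rm = TRUE)
      }
    }
    if (!is.null(s$medicated)) {
      row$n_medicated <- sum(parse_logical(s$medicated), na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
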