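# Reading raw accelerometer streams and questionnaire logs, and
# reconstructing gameplay sessions around tremor reports.

#' Read a raw accelerometer CSV into one or more accelerometer streams
#'
#' Accepts either a per-subject file with columns `t_ms, ax_mg, ay_mg, az_mg`
#' or a combined file that additionally carries a `subject_id` column.
#' Timestamps are integer milliseconds since epoch; accelerations are in
#' milli-G (1 G = 9.8 m/s^2). Rows containing missing values are rejected
#' (with a message giving the count); rows that are out of time order are
#' sorted with a warning; duplicated timestamps within a subject are an
#' error, as the device emits strictly increasing timestamps.
#'
#' @param path path to the CSV file.
#' @param subject_id subject identifier to attach when the file has no
#'   `subject_id` column; defaults to the file name without extension.
#' @return An `accel_stream` (a data frame with columns `t`, `ax`, `ay`,
#'   `az` and a `subject_id` attribute), or a named list of them when the
#'   file is a combined multi-subject file.
#' @export
read_accel_csv <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("accelerometer file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("t_ms", "ax_mg", "ay_mg", "az_mg")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("accelerometer CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if ("subject_id" %in% names(raw)) {
    parts <- split(raw[required], raw$subject_id)
    return(lapply(stats::setNames(names(parts), names(parts)), function(sid) {
      as_accel_stream(parts[[sid]], sid)
    }))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  as_accel_stream(raw[required], subject_id)
}

# Validate and normalise a raw accelerometer data frame.
as_accel_stream <- function(raw, subject_id) {
  cols <- c("t_ms", "ax_mg", "ay_mg", "az_mg")
  num <- lapply(raw[cols], function(col) {
    if (is.numeric(col)) return(col)
    parsed <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & col != "" & is.na(parsed))
    if (length(bad) > 0) {
      stop("non-numeric accelerometer value at row ", bad[1],
           " (value '", col[bad[1]], "')")
    }
    parsed
  })
  df <- data.frame(t = num$t_ms, ax = num$ax_mg, ay = num$ay_mg,
                   az = num$az_mg)
  complete <- stats::complete.cases(df) & is.finite(df$t) & df$t >= 0
  n_rejected <- sum(!complete)
  if (n_rejected > 0) {
    message(n_rejected, " accelerometer row(s) rejected for subject ",
            subject_id)
  }
  df <- df[complete, , drop = FALSE]
  if (anyDuplicated(df$t)) {
    dup <- df$t[duplicated(df$t)][1]
    stop("duplicated timestamp ", format(dup, scientific = FALSE),
         " in stream for subject ", subject_id)
  }
  if (is.unsorted(df$t)) {
    warning("accelerometer rows out of time order for subject ",
            subject_id, "; sorting")
    df <- df[order(df$t), , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, subject_id = as.character(subject_id),
            n_rejected = n_rejected,
            class = c("accel_stream", "data.frame"))
}

#' Read a tremor questionnaire log
#'
#' Expects columns `subject_id, t_response_ms, tremor_reported,
#' tremor_hand`. `tremor_hand` must be one of `phone`, `watch`, `both`,
#' `none`, and a report is internally consistent only when
#' `tremor_reported` is true exactly when `tremor_hand != "none"`;
#' contradictory rows are an error.
#'
#' @param path path to the questionnaire CSV.
#' @return A data frame with columns `subject_id`, `t_response`,
#'   `tremor_reported` (logical) and `tremor_hand`.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("questionnaire file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "t_response_ms", "tremor_reported",
                "tremor_hand")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("questionnaire CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ev <- data.frame(
    subject_id = as.character(raw$subject_id),
    t_response = as.numeric(raw$t_response_ms),
    tremor_reported = parse_logical(raw$tremor_reported),
    tremor_hand = tolower(as.character(raw$tremor_hand)),
    stringsAsFactors = FALSE
  )
  bad_hand <- !ev$tremor_hand %in% c("phone", "watch", "both", "none")
  if (any(bad_hand)) {
    stop("invalid tremor_hand value(s): ",
         paste(unique(ev$tremor_hand[bad_hand]), collapse = ", "))
  }
  contradiction <- ev$tremor_reported != (ev$tremor_hand != "none")
  if (any(contradiction)) {
    stop("contradictory questionnaire row(s) at line(s) ",
         paste(which(contradiction), collapse = ", "),
         ": tremor_reported must match tremor_hand")
  }
  ev
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "yes", "y", "1")
}

#' Extract the gameplay session tied to one questionnaire response
#'
#' The session span is the data recorded in the window reaching back
#' `lookback_s` seconds from the questionnaire response, restricted to a
#' run of consecutive samples whose inter-sample gaps never exceed
#' `max_gap_ms`. When the window contains several qualifying runs the
#' longest is taken (ties broken toward the most recent), as the gameplay
#' itself is the dominant contiguous block; runs shorter than
#' `min_samples` are discarded because they give unstable spectral
#' features.
#'
#' @param stream an `accel_stream` from [read_accel_csv()].
#' @param event one row of the questionnaire log (see [read_events_csv()]).
#' @param lookback_s window length before the response, in seconds.
#' @param max_gap_ms largest tolerated inter-sample gap, in milliseconds.
#' @param min_samples minimum run length to accept (default 250, about
#'   5 s at the nominal 50 Hz).
#' @return A `gameplay_session` (list with `subject_id`, `event`,
#'   `samples`, `span_start`, `span_end`), or `NULL` when no qualifying
#'   run exists in the window.
#' @export
extract_session <- function(stream, event, lookback_s = 300,
                            max_gap_ms = 1000, min_samples = 250) {
  stopifnot(inherits(stream, "accel_stream"))
  sid <- attr(stream, "subject_id")
  if (!is.null(event$subject_id) && event$subject_id != sid) {
    stop("event subject '", event$subject_id,
         "' does not match stream subject '", sid, "'")
  }
  t_resp <- as.numeric(event$t_response)
  win <- stream$t >= t_resp - lookback_s * 1000 & stream$t <= t_resp
  if (!any(win)) return(NULL)
  samples <- stream[win, , drop = FALSE]
  # split into maximal runs at gaps exceeding max_gap_ms
  breaks <- which(diff(samples$t) > max_gap_ms)
  run_id <- cumsum(c(1L, as.integer(seq_len(nrow(samples) - 1) %in% breaks)))
  runs <- split(seq_len(nrow(samples)), run_id)
  lengths <- vapply(runs, length, integer(1))
  keep <- lengths >= min_samples
  if (!any(keep)) return(NULL)
  runs <- runs[keep]
  lengths <- lengths[keep]
  # longest run wins; ties go to the most recent (runs are in time order)
  best <- max(which(lengths == max(lengths)))
  idx <- runs[[best]]
  sel <- samples[idx, , drop = FALSE]
  rownames(sel) <- NULL
  structure(
    list(subject_id = sid, event = event, samples = sel,
         span_start = sel$t[1], span_end = sel$t[nrow(sel)]),
    class = "gameplay_session"
  )
}

#' @export
print.gameplay_session <- function(x, ...) {
  cat("Gameplay session for subject", x$subject_id, "\n")
  cat("  span:", format(x$span_start, scientific = FALSE), "-",
      format(x$span_end, scientific = FALSE), "ms (",
      round((x$span_end - x$span_start) / 1000, 1), "s,",
      nrow(x$samples), "samples )\n")
  invisible(x)
}

#' Extract all tremor-positive gameplay sessions for a cohort
#'
#' Keeps only questionnaire events where a tremor was reported on either
#' hand, matches each to its subject's accelerometer stream, and runs
#' [extract_session()]. Events whose window yields no qualifying run are
#' tallied but not an error; events with no matching stream raise a
#' warning and are skipped.
#'
#' @param streams a named list of `accel_stream` objects (names are
#'   subject ids), as returned by [read_accel_csv()] on a combined file.
#' @param events questionnaire data frame from [read_events_csv()].
#' @inheritParams extract_session
#' @return A list of `gameplay_session` objects with attributes
#'   `n_failed` (tremor events whose extraction returned nothing) and
#'   `n_unmatched` (tremor events with no stream).
#' @export
tremor_sessions <- function(streams, events, lookback_s = 300,
                            max_gap_ms = 1000, min_samples = 250) {
  pos <- events[events$tremor_reported & events$tremor_hand != "none", ,
                drop = FALSE]
  sessions <- list()
  n_failed <- 0L
  n_unmatched <- 0L
  for (i in seq_len(nrow(pos))) {
    ev <- pos[i, , drop = FALSE]
    stream <- streams[[ev$subject_id]]
    if (is.null(stream)) {
      warning("no accelerometer stream for subject ", ev$subject_id,
              "; event skipped")
      n_unmatched <- n_unmatched + 1L
      next
    }
    s <- extract_session(stream, ev, lookback_s = lookback_s,
                         max_gap_ms = max_gap_ms,
                         min_samples = min_samples)
    if (is.null(s)) {
      n_failed <- n_failed + 1L
    } else {
      sessions[[length(sessions) + 1L]] <- s
    }
  }
  structure(sessions, n_failed = n_failed, n_unmatched = n_unmatched)
}
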