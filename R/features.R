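# Tremor feature extraction: magnitude conversion, 3-7 Hz Butterworth
# band-pass filtering, and the three per-session summary features.

#' Root-sum-of-squares acceleration magnitude
#'
#' Collapses triaxial acceleration to an orientation-invariant scalar,
#' `sqrt(ax^2 + ay^2 + az^2)`, in the same milli-G units as the inputs.
#'
#' @param ax,ay,az acceleration components in milli-G (vectorised).
#' @return Numeric vector of magnitudes.
#' @export
rss_magnitude <- function(ax, ay, az) {
  stopifnot(length(ax) == length(ay), length(ay) == length(az))
  sqrt(ax^2 + ay^2 + az^2)
}

#' Magnitude series of a gameplay session
#'
#' @param session a `gameplay_session` from [extract_session()].
#' @return Data frame with columns `t` (ms) and `m` (magnitude, mG).
#' @export
magnitude_series <- function(session) {
  stopifnot(inherits(session, "gameplay_session"))
  s <- session$samples
  data.frame(t = s$t, m = rss_magnitude(s$ax, s$ay, s$az))
}

#' Band-pass filter a magnitude series to the tremor band
#'
#' Applies a Butterworth band-pass filter (default 3-7 Hz, prototype
#' order 4) forward and backward (zero phase), so the filtered series is
#' not shifted relative to the session and the pass-band gain is the
#' squared one-pass magnitude response. The sampling rate is estimated
#' as the reciprocal of the median inter-sample interval; when that
#' median deviates more than 20% from the nominal 20 ms the series is
#' first resampled to a uniform 50 Hz grid by linear interpolation,
#' since an IIR filter requires uniform sampling.
#'
#' @param series data frame with columns `t` (ms) and `m` (mG), e.g.
#'   from [magnitude_series()].
#' @param low_hz,high_hz band edges in Hz.
#' @param order Butterworth prototype order.
#' @return Data frame with columns `t` and `f` (filtered magnitude, mG)
#'   and attributes `band`, `fs_hz`, `resampled`.
#' @export
bandpass <- function(series, low_hz = 3, high_hz = 7, order = 4) {
  stopifnot(is.data.frame(series), all(c("t", "m") %in% names(series)))
  out <- bandpass_core(series$t, series$m, low_hz, high_hz, order)
  structure(data.frame(t = out$t, f = out$f),
            band = c(low_hz = low_hz, high_hz = high_hz), fs_hz = out$fs,
            resampled = out$resampled)
}

bandpass_core <- function(t, m, low_hz, high_hz, order) {
  if (low_hz <= 0 || high_hz <= low_hz) {
    stop("band edges must satisfy 0 < low_hz < high_hz")
  }
  n <- length(m)
  if (n < 3 * order) {
    stop("series too short to filter (", n, " samples)")
  }
  dt <- stats::median(diff(t))
  if (!is.finite(dt) || dt <= 0) stop("cannot estimate sampling interval")
  if (high_hz >= (1000 / dt) / 2) {
    stop("upper band edge ", high_hz, " Hz is not below Nyquist ",
         "(effective fs = ", round(1000 / dt, 2), " Hz)")
  }
  resampled <- FALSE
  if (abs(dt - 20) / 20 > 0.2) {
    # irregular or off-nominal sampling: linear interpolation to 50 Hz
    grid <- seq(t[1], t[length(t)], by = 20)
    m <- stats::approx(t, m, xout = grid)$y
    t <- grid
    dt <- 20
    resampled <- TRUE
  }
  fs <- 1000 / dt
  if (high_hz >= fs / 2) {
    stop("upper band edge ", high_hz, " Hz is not below Nyquist (fs = ",
         fs, " Hz)")
  }
  bf <- butter_cached(order, low_hz, high_hz, fs)
  # Demean (removes the ~1 G static gravity offset) and pad both ends
  # with a linear-prediction (Burg/maximum-entropy) extension before the
  # forward-backward pass: an autoregressive continuation carries
  # in-band oscillations smoothly past the record ends, so the filter's
  # start-up transient falls in the discarded padding instead of
  # inflating the maximum amplitude near the session edges (reflection
  # or zero padding can ring by several percent there).
  x <- m - mean(m)
  n_pad <- ceiling(2 * fs)
  f <- signal::filtfilt(bf, lp_extend(x, n_pad))
  list(t = t, f = f[seq(n_pad + 1, n_pad + length(x))], fs = fs,
       resampled = resampled)
}

# Extend a series np samples beyond each end by Burg linear prediction
# (AR order 8 fitted to the nearest 100 samples); degenerate segments
# fall back to a constant-mean extension.
lp_extend <- function(x, np, fit_n = 100, order = 8) {
  n <- length(x)
  fit_n <- min(n, fit_n)
  ext <- function(seg) {
    m <- try(stats::ar.burg(seg, order.max = order, aic = FALSE,
                            demean = TRUE), silent = TRUE)
    if (inherits(m, "try-error") || m$order == 0) {
      return(rep(mean(seg), np))
    }
    co <- m$ar
    mu <- m$x.mean
    p <- m$order
    buf <- c(seg[(length(seg) - p + 1):length(seg)] - mu, numeric(np))
    for (k in seq_len(np)) buf[p + k] <- sum(co * buf[(p + k - 1):k])
    buf[(p + 1):(p + np)] + mu
  }
  c(rev(ext(rev(x[seq_len(fit_n)]))), x, ext(x[seq(n - fit_n + 1, n)]))
}

# filter designs are deterministic in (order, band, fs); cache them so
# per-session filtering does not redo the design
.butter_cache <- new.env(parent = emptyenv())
butter_cached <- function(order, low_hz, high_hz, fs) {
  key <- paste(order, low_hz, high_hz, fs, sep = "|")
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2),
                         type = "pass")
    .butter_cache[[key]] <- bf
  }
  bf
}

#' Per-session tremor features of a filtered magnitude series
#'
#' Computes the three per-session summaries of the band-passed magnitude
#' `f_t`: total energy `E = sum(f_t^2)` (mG^2 x samples; or the mean of
#' squares with `energy = "mean"`), average amplitude `mean(|f_t|)` (mG),
#' and maximum amplitude `max(|f_t|)` (mG), plus `log2(E)`. An all-zero
#' series yields `E = 0` with undefined `log2_energy`; such sessions are
#' flagged so downstream models using the log can exclude them.
#'
#' @param filtered data frame with column `f` from [bandpass()].
#' @param energy `"sum"` (default) or `"mean"`: whether total energy is
#'   the raw sum of squares or its time average.
#' @param subject_id,session_id identifiers carried into the output row.
#' @return One-row data frame: `subject_id`, `session_id`, `n_samples`,
#'   `total_energy`, `log2_energy`, `avg_amp_mg`, `max_amp_mg`,
#'   `flagged`.
#' @export
compute_features <- function(filtered, energy = c("sum", "mean"),
                             subject_id = NA_character_,
                             session_id = NA_character_) {
  energy <- match.arg(energy)
  f <- filtered$f
  if (length(f) == 0) stop("empty filtered series")
  e <- sum(f^2)
  if (energy == "mean") e <- e / length(f)
  flagged <- e == 0
  data.frame(
    subject_id = subject_id,
    session_id = session_id,
    n_samples = length(f),
    total_energy = e,
    log2_energy = if (flagged) NA_real_ else log2(e),
    avg_amp_mg = mean(abs(f)),
    max_amp_mg = max(abs(f)),
    flagged = flagged,
    stringsAsFactors = FALSE
  )
}

#' Feature table for a list of gameplay sessions
#'
#' Runs [magnitude_series()], [bandpass()] and [compute_features()] over
#' each session. Sessions too short to filter are skipped with a
#' warning naming the session.
#'
#' @param sessions list of `gameplay_session` objects, e.g. from
#'   [tremor_sessions()].
#' @inheritParams bandpass
#' @inheritParams compute_features
#' @return Data frame with one row per session (see
#'   [compute_features()] for columns).
#' @export
session_features <- function(sessions, low_hz = 3, high_hz = 7, order = 4,
                             energy = c("sum", "mean")) {
  energy <- match.arg(energy)
  n <- length(sessions)
  subject_id <- character(n)
  session_id <- character(n)
  n_samples <- integer(n)
  total_energy <- numeric(n)
  avg_amp <- numeric(n)
  max_amp <- numeric(n)
  ok <- logical(n)
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    sid <- paste0(s$subject_id, "_", format(s$event$t_response,
                                            scientific = FALSE))
    smp <- s$samples
    m <- sqrt(smp$ax^2 + smp$ay^2 + smp$az^2)
    filt <- tryCatch(
      bandpass_core(smp$t, m, low_hz, high_hz, order),
      error = function(e) {
        warning("session ", sid, " not filtered: ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(filt)) next
    f <- filt$f
    e <- sum(f^2)
    if (energy == "mean") e <- e / length(f)
    subject_id[i] <- s$subject_id
    session_id[i] <- sid
    n_samples[i] <- length(f)
    total_energy[i] <- e
    avg_amp[i] <- mean(abs(f))
    max_amp[i] <- max(abs(f))
    ok[i] <- TRUE
  }
  out <- data.frame(
    subject_id = subject_id[ok], session_id = session_id[ok],
    n_samples = n_samples[ok], total_energy = total_energy[ok],
    log2_energy = ifelse(total_energy[ok] > 0, log2(total_energy[ok]),
                         NA_real_),
    avg_amp_mg = avg_amp[ok], max_amp_mg = max_amp[ok],
    flagged = total_energy[ok] == 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
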