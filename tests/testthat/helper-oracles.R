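# Independent reference implementations used as oracles. These are kept
# deliberately naive (loops, enumeration, closed forms) and share no
# code with the package internals they check.

# Analytic zero-phase gain of a digital Butterworth band-pass designed
# by bilinear transform: the prototype (order n) magnitude evaluated at
# the prewarped frequency, squared because the filter runs forward and
# backward.
analytic_bp_gain <- function(f_hz, low_hz, high_hz, fs_hz, order) {
  w <- tan(pi * f_hz / fs_hz)
  wl <- tan(pi * low_hz / fs_hz)
  wh <- tan(pi * high_hz / fs_hz)
  omega <- (w^2 - wl * wh) / (w * (wh - wl))
  (1 / sqrt(1 + omega^(2 * order)))^2
}

# Least-squares amplitude of the component at f_hz in a series
# (sine regression on the central portion, away from any edge effects).
fitted_amplitude <- function(x, t_sec, f_hz, trim = 0.25) {
  n <- length(x)
  idx <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  design <- cbind(sin(2 * pi * f_hz * t_sec[idx]),
                  cos(2 * pi * f_hz * t_sec[idx]))
  co <- stats::coef(stats::lm.fit(design, x[idx]))
  sqrt(sum(co^2))
}

# Brute-force gameplay-session extraction: enumerate every maximal run
# of in-window samples by scanning, then apply the longest/most-recent
# rule, independent of the package's implementation.
oracle_extract_idx <- function(t, t_resp, lookback_s = 300,
                               max_gap_ms = 1000, min_samples = 250) {
  in_win <- which(t >= t_resp - lookback_s * 1000 & t <= t_resp)
  if (length(in_win) == 0) return(NULL)
  runs <- list()
  current <- in_win[1]
  for (i in in_win[-1]) {
    if (t[i] - t[current[length(current)]] <= max_gap_ms) {
      current <- c(current, i)
    } else {
      runs[[length(runs) + 1]] <- current
      current <- i
    }
  }
  runs[[length(runs) + 1]] <- current
  runs <- Filter(function(r) length(r) >= min_samples, runs)
  if (length(runs) == 0) return(NULL)
  best <- NULL
  for (r in runs) {
    if (is.null(best) || length(r) > length(best) ||
        (length(r) == length(best) && t[r[1]] > t[best[1]])) {
      best <- r
    }
  }
  best
}

# Double-loop weighted allele count.
oracle_prs <- function(genotypes, weights) {
  scores <- numeric(nrow(genotypes))
  for (i in seq_len(nrow(genotypes))) {
    s <- 0
    for (j in seq_len(ncol(genotypes))) {
      w <- weights$weight[weights$rsid == colnames(genotypes)[j]]
      if (length(w) == 1 && !is.na(genotypes[i, j])) {
        s <- s + genotypes[i, j] * w
      }
    }
    scores[i] <- s
  }
  scores
}

# Pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# A minimal gameplay_session wrapper around a plain sample data frame,
# for feature tests that do not involve extraction.
make_session <- function(t, ax, ay, az, subject_id = "S1",
                         t_response = max(t) + 1000) {
  structure(
    list(subject_id = subject_id,
         event = data.frame(subject_id = subject_id,
                            t_response = t_response,
                            tremor_reported = TRUE, tremor_hand = "watch"),
         samples = data.frame(t = t, ax = ax, ay = ay, az = az),
         span_start = t[1], span_end = t[length(t)]),
    class = "gameplay_session"
  )
}

make_stream <- function(t, ax = NULL, ay = NULL, az = NULL,
                        subject_id = "S1") {
  n <- length(t)
  if (is.null(ax)) ax <- rep(0, n)
  if (is.null(ay)) ay <- rep(0, n)
  if (is.null(az)) az <- rep(1000, n)
  structure(data.frame(t = t, ax = ax, ay = ay, az = az),
            subject_id = subject_id, n_rejected = 0L,
            class = c("accel_stream", "data.frame"))
}

make_event <- function(subject_id = "S1", t_response, reported = TRUE,
                       hand = "watch") {
  data.frame(subject_id = subject_id, t_response = t_response,
             tremor_reported = reported, tremor_hand = hand,
             stringsAsFactors = FALSE)
}
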