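# Synthetic study generator: raw accelerometer streams, questionnaire
# logs, subject rosters, SNP weight tables and genotypes with the
# statistical structure the analysis pipeline assumes, so the whole
# pipeline can be exercised end to end without patient data.

#' Simulation configuration
#'
#' Bundles and validates the generator's parameters. The defaults are
#' the study conditions the analysis assumes: 40 PD and 27 ET subjects
#' monitored 3 times a day for 14 days at a nominal 50 Hz with 2-minute
#' gameplay sessions; per-subject tremor-report rates Beta-distributed
#' with mean 0.52 (SD 0.31) for PD and 0.63 (SD 0.34) for ET, truncated
#' to (0.02, 1); subject-level tremor frequency uniform over 4-6 Hz (PD,
#' rest tremor) or 4-8 Hz (ET, postural/kinetic tremor); subject-level
#' tremor amplitude normal with mean 280 mG (SD 123) for PD and 328 mG
#' (SD 158) for ET, truncated above 0, with log-normal within-subject
#' session-to-session variation; and 22 risk SNPs with odds ratios
#' uniform in (1.05, 1.4) and no group difference in allele frequencies
#' unless `prs_effect` is set.
#'
#' @param n_pd,n_et subjects per group.
#' @param days monitoring days per subject.
#' @param sessions_per_day gameplay sessions per day.
#' @param fs_hz nominal accelerometer sampling rate (Hz).
#' @param session_length_s gameplay session duration (s).
#' @param report_rate_pd,report_rate_et `c(mean, sd)` of the per-subject
#'   tremor-report rate.
#' @param freq_band_pd,freq_band_et `c(low, high)` Hz of the subject
#'   tremor frequency.
#' @param max_amp_pd,max_amp_et `c(mean, sd)` mG of the subject tremor
#'   amplitude.
#' @param duty_pd,duty_et mean fraction of a session during which the
#'   tremor is active. Tremor comes in bursts rather than running for
#'   the whole recording — that is what makes the average amplitude an
#'   order of magnitude smaller than the maximum — and the rest tremor
#'   of PD is more sustained (higher duty) while ET tremor arrives in
#'   shorter, higher-amplitude kinetic bursts.
#' @param duty_cv log-scale SD of the session-to-session duty-cycle
#'   variation.
#' @param within_subject_cv log-scale SD of the multiplicative
#'   session-to-session amplitude noise.
#' @param noise_sd white accelerometer noise SD per axis (mG).
#' @param gravity_mg static gravity offset (mG) carried by the watch.
#' @param dropout_rate probability a scheduled session is missing.
#' @param gap_rate probability a session's recording has one timestamp
#'   gap.
#' @param gap_length_s length of an injected gap (s).
#' @param questionnaire_delay_s `c(min, max)` delay (s) between the end
#'   of gameplay and the questionnaire response.
#' @param n_snps number of risk SNPs in the synthetic weight table.
#' @param or_range `c(min, max)` of SNP odds ratios.
#' @param freq_range `c(min, max)` of effect-allele frequencies.
#' @param prs_effect standardized PD-minus-ET difference in the
#'   polygenic score (0 = null, the study's finding).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pd = 40, n_et = 27, days = 14,
                       sessions_per_day = 3, fs_hz = 50,
                       session_length_s = 120,
                       report_rate_pd = c(0.52, 0.31),
                       report_rate_et = c(0.63, 0.34),
                       freq_band_pd = c(4, 6), freq_band_et = c(4, 8),
                       max_amp_pd = c(280, 123), max_amp_et = c(328, 158),
                       duty_pd = 0.10, duty_et = 0.07, duty_cv = 0.3,
                       within_subject_cv = 0.2, noise_sd = 10,
                       gravity_mg = 1000, dropout_rate = 0.1,
                       gap_rate = 0.1, gap_length_s = 5,
                       questionnaire_delay_s = c(5, 60),
                       n_snps = 22, or_range = c(1.05, 1.4),
                       freq_range = c(0.05, 0.45), prs_effect = 0) {
  cfg <- as.list(environment())
  stopifnot(
    n_pd >= 1, n_et >= 1, days >= 1, sessions_per_day >= 1,
    fs_hz > 0, session_length_s > 0,
    dropout_rate >= 0, dropout_rate <= 1,
    gap_rate >= 0, gap_rate <= 1,
    duty_pd > 0, duty_pd <= 1, duty_et > 0, duty_et <= 1,
    report_rate_pd[1] > 0, report_rate_pd[1] <= 1,
    report_rate_et[1] > 0, report_rate_et[1] <= 1,
    freq_band_pd[2] < fs_hz / 2, freq_band_et[2] < fs_hz / 2,
    n_snps >= 1, all(or_range > 0)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic tremor study configuration:\n")
  cat(sprintf("  %d PD + %d ET subjects, %d days x %d sessions/day,",
              x$n_pd, x$n_et, x$days, x$sessions_per_day),
      sprintf("%g s sessions at %g Hz\n", x$session_length_s, x$fs_hz))
  cat(sprintf("  amplitude PD %g+/-%g mG, ET %g+/-%g mG; PRS effect %g\n",
              x$max_amp_pd[1], x$max_amp_pd[2], x$max_amp_et[1],
              x$max_amp_et[2], x$prs_effect))
  invisible(x)
}

# Zero-phase (forward-backward) gain of the standard analysis filter —
# squared magnitude response of the digital Butterworth band-pass
# (bilinear design with prewarped edges). The generator divides the raw
# sinusoid amplitude by this so that the configured amplitude
# distributions are distributions of the *filtered* maximum amplitude,
# the scale on which the study conditions are stated, even for tremor
# frequencies near or past the band edge.
zero_phase_band_gain <- function(freq, low = 3, high = 7, order = 4,
                                 fs = 50) {
  w <- tan(pi * freq / fs)
  wl <- tan(pi * low / fs)
  wh <- tan(pi * high / fs)
  om <- (w^2 - wl * wh) / (w * (wh - wl))
  1 / (1 + om^(2 * order))
}

# Beta parameters matched to a mean and SD by method of moments.
beta_moments <- function(mean, sd) {
  v <- sd^2
  if (v <= 0 || mean <= 0 || mean >= 1) return(c(a = NA_real_, b = NA_real_))
  v <- min(v, mean * (1 - mean) * 0.999)  # keep parameters positive
  a <- mean * (mean * (1 - mean) / v - 1)
  b <- (1 - mean) * (mean * (1 - mean) / v - 1)
  c(a = a, b = b)
}

rtruncnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(out <= 0)) {
    k <- out <= 0
    out[k] <- stats::rnorm(sum(k), mean, sd)
  }
  out
}

#' Simulate the triaxial accelerometer signal of one gameplay session
#'
#' Emits samples whose magnitude is approximately
#' `gravity + amp * e(t) * sin(2 * pi * freq * t + phase)` plus white
#' noise, where `e(t)` is a 0/1 burst envelope active for a fraction
#' `duty` of the recording: the sinusoidal tremor rides on the static
#' gravity offset, and the whole vector is rotated to a random wrist
#' orientation, which partitions the amplitude across the three axes
#' while leaving the magnitude (the quantity the pipeline uses)
#' unchanged.
#'
#' @param amp tremor amplitude (mG); 0 gives a tremor-free recording.
#' @param freq tremor frequency (Hz); must be below Nyquist.
#' @param duty fraction of the recording during which the tremor is
#'   active; the burst is placed at a random position (1 = sustained
#'   tremor for the whole session).
#' @param duration_s recording length (s).
#' @param fs_hz sampling rate (Hz).
#' @param noise_sd white noise SD per axis (mG).
#' @param gravity_mg static gravity magnitude (mG).
#' @param t0 timestamp (ms) of the first sample.
#' @return Data frame with columns `t_ms, ax_mg, ay_mg, az_mg`.
#' @export
simulate_session_signal <- function(amp, freq, duty = 1, duration_s = 120,
                                    fs_hz = 50, noise_sd = 10,
                                    gravity_mg = 1000, t0 = 0) {
  sig <- session_signal_core(amp, freq, duty, duration_s, fs_hz,
                             noise_sd, gravity_mg, t0)
  data.frame(t_ms = sig[, 1], ax_mg = sig[, 2], ay_mg = sig[, 3],
             az_mg = sig[, 4])
}

# matrix core (t, ax, ay, az) so bulk simulation avoids per-session
# data.frame construction
session_signal_core <- function(amp, freq, duty, duration_s, fs_hz,
                                noise_sd, gravity_mg, t0) {
  if (freq >= fs_hz / 2) {
    stop("tremor frequency ", freq, " Hz is at or above Nyquist")
  }
  stopifnot(duty > 0, duty <= 1)
  n <- round(duration_s * fs_hz)
  tsec <- (seq_len(n) - 1) / fs_hz
  phase <- stats::runif(1, 0, 2 * pi)
  env <- rep(1, n)
  if (duty < 1) {
    burst_n <- min(n, max(round(duty * n), round(fs_hz / 2)))  # >= ~0.5 s
    start <- sample(n - burst_n + 1, 1)
    env <- rep(0, n)
    env[seq(start, start + burst_n - 1)] <- 1
  }
  a <- gravity_mg + amp * env * sin(2 * pi * freq * tsec + phase)
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))  # random wrist orientation
  sig <- outer(a, u)
  sig <- sig + matrix(stats::rnorm(3 * n, 0, noise_sd), ncol = 3)
  cbind(t0 + round(tsec * 1000), sig, deparse.level = 0)
}

#' Simulate effect-allele dosages for a cohort
#'
#' Dosages are binomial(2, freq) per SNP. A non-zero `prs_effect` tilts
#' the case-group allele frequencies in proportion to
#' `w * f * (1 - f)` so that the expected standardized difference in
#' the weighted score equals `prs_effect`.
#'
#' @param subject_id character vector of subject ids.
#' @param weights weight table (needs `rsid`, `weight`,
#'   `effect_allele_freq`).
#' @param is_case logical vector: `TRUE` for PD subjects.
#' @param prs_effect target standardized case-control score difference.
#' @return Dosage matrix (subjects x SNPs).
#' @export
simulate_genotypes <- function(subject_id, weights, is_case = NULL,
                               prs_effect = 0) {
  n <- length(subject_id)
  f <- weights$effect_allele_freq
  w <- weights$weight
  stopifnot(all(is.finite(f)), all(f >= 0), all(f <= 1))
  f_case <- f
  if (prs_effect != 0) {
    if (is.null(is_case)) stop("is_case is required when prs_effect != 0")
    sd_s <- sqrt(sum(w^2 * 2 * f * (1 - f)))
    f_case <- pmin(0.99, pmax(0.01, f + prs_effect / sd_s * w * f * (1 - f)))
  }
  if (is.null(is_case)) is_case <- rep(FALSE, n)
  g <- t(vapply(seq_len(n), function(i) {
    fr <- if (is_case[i]) f_case else f
    stats::rbinom(length(fr), 2, fr)
  }, numeric(length(f))))
  dimnames(g) <- list(subject_id, weights$rsid)
  g
}

# Synthetic SNP weight table (labelled synthetic: ids are rs900001...).
synthetic_weights <- function(n_snps, or_range, freq_range) {
  data.frame(
    rsid = sprintf("rs%d", 900000 + seq_len(n_snps)),
    effect_allele = sample(c("A", "C", "G", "T"), n_snps, replace = TRUE),
    odds_ratio = stats::runif(n_snps, or_range[1], or_range[2]),
    effect_allele_freq = stats::runif(n_snps, freq_range[1], freq_range[2]),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic study
#'
#' Draws a cohort under the configured study conditions and returns (and
#' optionally writes) every input the pipeline consumes: per-subject
#' accelerometer streams, the questionnaire log, the subject roster, a
#' synthetic SNP weight table and a genotype dosage matrix, together
#' with the ground truth (latent per-subject amplitude, frequency and
#' report rate; per-session tremor status, injected gaps and expected
#' extractable run lengths) that parameter-recovery tests check against.
#'
#' Accelerometer data is generated for every recorded session;
#' tremor-free sessions carry gravity and noise only. With probability
#' `gap_rate` a session's recording loses a `gap_length_s` stretch in
#' the middle, emulating device connectivity dropouts.
#'
#' @param config a [sim_config()] object.
#' @param dir optional directory; when given, writes `accel_<id>.csv`
#'   per subject plus `events.csv`, `subjects.csv`, `snp_weights.tsv`,
#'   `genotypes.csv`, and the ground truth (`truth_subjects.csv`,
#'   `truth_sessions.csv`).
#' @param seed integer seed; the whole draw is a deterministic function
#'   of it.
#' @return Invisible list with `streams` (named list of `accel_stream`),
#'   `events`, `subjects`, `weights`, `genotypes`, `truth` (list with
#'   `subjects` and `sessions` data frames), and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  n <- cfg$n_pd + cfg$n_et
  diagnosis <- rep(c("PD", "ET"), c(cfg$n_pd, cfg$n_et))
  ids <- sprintf("S%03d", seq_len(n))

  # roster demographics (used only by cohort_summary)
  subjects <- data.frame(
    subject_id = ids,
    diagnosis = diagnosis,
    sex = ifelse(stats::runif(n) < ifelse(diagnosis == "PD", 0.60, 0.48),
                 "M", "F"),
    age = round(pmin(95, pmax(30, stats::rnorm(
      n, 73, ifelse(diagnosis == "PD", 8.4, 10.6))))),
    years_since_diagnosis = round(pmax(1, stats::rnorm(
      n, ifelse(diagnosis == "PD", 3, 9),
      ifelse(diagnosis == "PD", 2.6, 13.5)))),
    medicated = stats::runif(n) < ifelse(diagnosis == "PD", 0.83, 0.667),
    stringsAsFactors = FALSE
  )

  # latent per-subject tremor parameters
  amp <- numeric(n)
  freq <- numeric(n)
  rate <- numeric(n)
  duty <- numeric(n)
  bm_pd <- beta_moments(cfg$report_rate_pd[1], cfg$report_rate_pd[2])
  bm_et <- beta_moments(cfg$report_rate_et[1], cfg$report_rate_et[2])
  for (i in seq_len(n)) {
    pd <- diagnosis[i] == "PD"
    ap <- if (pd) cfg$max_amp_pd else cfg$max_amp_et
    fb <- if (pd) cfg$freq_band_pd else cfg$freq_band_et
    bm <- if (pd) bm_pd else bm_et
    amp[i] <- rtruncnorm_pos(1, ap[1], ap[2])
    freq[i] <- stats::runif(1, fb[1], fb[2])
    rate[i] <- if (bm[1] <= 0 || !all(is.finite(bm))) {
      # degenerate (zero-variance or boundary) report rate
      min(1, max(0, if (pd) cfg$report_rate_pd[1] else cfg$report_rate_et[1]))
    } else {
      min(1, max(0.02, stats::rbeta(1, bm["a"], bm["b"])))
    }
    duty[i] <- min(0.6, max(0.02, (if (pd) cfg$duty_pd else cfg$duty_et) *
                              stats::rlnorm(1, 0, 0.5)))
  }

  # genetics
  weights_raw <- synthetic_weights(cfg$n_snps, cfg$or_range, cfg$freq_range)
  weights <- weights_raw
  weights$weight <- log(weights$odds_ratio)
  genotypes <- simulate_genotypes(ids, weights,
                                  is_case = diagnosis == "PD",
                                  prs_effect = cfg$prs_effect)

  # sessions: 3 nominal start hours per day
  slot_hours <- c(8, 13, 21)[seq_len(min(3, cfg$sessions_per_day))]
  if (cfg$sessions_per_day > 3) {
    slot_hours <- seq(8, 21, length.out = cfg$sessions_per_day)
  }
  origin_ms <- 1.6e12  # arbitrary epoch origin
  n_samp <- round(cfg$session_length_s * cfg$fs_hz)

  streams <- vector("list", n)
  names(streams) <- ids
  max_sessions <- n * cfg$days * length(slot_hours)
  ev_subject <- character(max_sessions)
  ev_t <- numeric(max_sessions)
  ev_reported <- logical(max_sessions)
  ev_hand <- character(max_sessions)
  tr_amp <- numeric(max_sessions)
  tr_gap <- logical(max_sessions)
  tr_runs <- character(max_sessions)
  tr_expected <- numeric(max_sessions)
  k <- 0L
  for (i in seq_len(n)) {
    frames <- list()
    for (day in seq_len(cfg$days)) {
      for (slot in seq_along(slot_hours)) {
        if (stats::runif(1) < cfg$dropout_rate) next
        t0 <- origin_ms + ((day - 1) * 24 + slot_hours[slot]) * 3.6e6 +
          round(stats::runif(1, 0, 30) * 60000)
        reported <- stats::runif(1) < rate[i]
        sess_amp <- if (reported) {
          amp[i] * stats::rlnorm(1, 0, cfg$within_subject_cv)
        } else 0
        sess_duty <- min(0.9, max(0.02, duty[i] *
                                    stats::rlnorm(1, 0, cfg$duty_cv)))
        # configured amplitudes live on the filtered scale: undo the
        # analysis filter's gain at this subject's tremor frequency
        raw_amp <- sess_amp / zero_phase_band_gain(freq[i], fs = cfg$fs_hz)
        sig <- session_signal_core(
          raw_amp, freq[i], sess_duty, cfg$session_length_s,
          cfg$fs_hz, cfg$noise_sd, cfg$gravity_mg, t0)
        # inject a mid-recording connectivity gap
        has_gap <- stats::runif(1) < cfg$gap_rate
        run_lengths <- nrow(sig)
        if (has_gap) {
          gap_n <- round(cfg$gap_length_s * cfg$fs_hz)
          max_start <- nrow(sig) - gap_n - cfg$fs_hz
          if (max_start > cfg$fs_hz) {
            gs <- sample(seq(cfg$fs_hz, max_start), 1)
            drop_idx <- seq(gs, gs + gap_n - 1)
            run_lengths <- c(gs - 1, nrow(sig) - gs + 1 - gap_n)
            sig <- sig[-drop_idx, , drop = FALSE]
          } else {
            has_gap <- FALSE
          }
        }
        delay_ms <- round(stats::runif(1, cfg$questionnaire_delay_s[1],
                                       cfg$questionnaire_delay_s[2]) * 1000)
        t_resp <- sig[nrow(sig), 1] + delay_ms
        hand <- if (reported) {
          sample(c("watch", "both", "phone"), 1, prob = c(0.6, 0.3, 0.1))
        } else "none"
        frames[[length(frames) + 1L]] <- sig
        k <- k + 1L
        ev_subject[k] <- ids[i]
        ev_t[k] <- t_resp
        ev_reported[k] <- reported
        ev_hand[k] <- hand
        tr_amp[k] <- sess_amp
        tr_gap[k] <- has_gap
        tr_runs[k] <- paste(run_lengths, collapse = ";")
        tr_expected[k] <- longest_latest(run_lengths)
      }
    }
    all_sig <- do.call(rbind, frames)
    streams[[i]] <- structure(
      data.frame(t = all_sig[, 1], ax = all_sig[, 2],
                 ay = all_sig[, 3], az = all_sig[, 4]),
      subject_id = ids[i], n_rejected = 0L,
      class = c("accel_stream", "data.frame"))
  }
  keep <- seq_len(k)
  events <- data.frame(
    subject_id = ev_subject[keep], t_response_ms = ev_t[keep],
    tremor_reported = ev_reported[keep], tremor_hand = ev_hand[keep],
    stringsAsFactors = FALSE)
  truth <- list(
    subjects = data.frame(subject_id = ids, diagnosis = diagnosis,
                          amp = amp, freq = freq, report_rate = rate,
                          duty = duty, stringsAsFactors = FALSE),
    sessions = data.frame(
      subject_id = ev_subject[keep], t_response_ms = ev_t[keep],
      tremor = ev_reported[keep], session_amp = tr_amp[keep],
      has_gap = tr_gap[keep], run_lengths = tr_runs[keep],
      expected_run_length = tr_expected[keep], stringsAsFactors = FALSE)
  )

  out <- list(streams = streams, events = events, subjects = subjects,
              weights = weights, genotypes = genotypes, truth = truth,
              config = cfg)
  if (!is.null(dir)) write_cohort(out, dir)
  invisible(out)
}

longest_latest <- function(run_lengths) {
  run_lengths[max(which(run_lengths == max(run_lengths)))]
}

# Write a simulated cohort to disk in the formats the readers consume.
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir)
  }
  for (sid in names(cohort$streams)) {
    s <- cohort$streams[[sid]]
    utils::write.csv(
      data.frame(t_ms = s$t, ax_mg = s$ax, ay_mg = s$ay, az_mg = s$az),
      file.path(dir, paste0("accel_", sid, ".csv")), row.names = FALSE)
  }
  utils::write.csv(cohort$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.table(
    cohort$weights[, c("rsid", "effect_allele", "odds_ratio",
                       "effect_allele_freq")],
    file.path(dir, "snp_weights.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.csv(
    data.frame(subject_id = rownames(cohort$genotypes),
               cohort$genotypes, check.names = FALSE),
    file.path(dir, "genotypes.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth$subjects,
                   file.path(dir, "truth_subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$sessions,
                   file.path(dir, "truth_sessions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
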