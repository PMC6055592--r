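small_config <- function(...) {
  sim_config(n_pd = 4, n_et = 3, days = 2, session_length_s = 15, ...)
}

test_that("simulation is a deterministic function of the seed", {
  a <- simulate_cohort(small_config(), seed = 123)
  b <- simulate_cohort(small_config(), seed = 123)
  expect_identical(a$streams, b$streams)
  expect_identical(a$events, b$events)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth, b$truth)

  c_other <- simulate_cohort(small_config(), seed = 124)
  expect_false(identical(a$streams, c_other$streams))
})

test_that("session counts follow the schedule when dropout is zero", {
  co <- simulate_cohort(sim_config(n_pd = 4, n_et = 3, days = 2,
                                   session_length_s = 10,
                                   dropout_rate = 0), seed = 5)
  expect_equal(nrow(co$events), 7 * 2 * 3)
  expect_equal(sort(unique(co$events$subject_id)),
               sprintf("S%03d", 1:7))
})

test_that("degenerate report-rate config makes every session tremor-positive", {
  co <- simulate_cohort(small_config(report_rate_pd = c(1, 0),
                                     report_rate_et = c(1, 0),
                                     dropout_rate = 0), seed = 6)
  expect_true(all(co$events$tremor_reported))
  expect_true(all(co$events$tremor_hand != "none"))
})

test_that("simulated signal magnitude carries the configured tremor", {
  set.seed(30)
  # 4.87 Hz is incommensurate with the 50 Hz grid: samples sweep phases
  sig <- simulate_session_signal(100, 4.87, duty = 1, duration_s = 20,
                                 noise_sd = 0, gravity_mg = 1000)
  expect_equal(nrow(sig), 1000)
  m <- rss_magnitude(sig$ax_mg, sig$ay_mg, sig$az_mg)
  # magnitude is rotation invariant: gravity + sinusoid survive exactly
  expect_equal(mean(m), 1000, tolerance = 0.01)
  expect_equal(max(m) - 1000, 100, tolerance = 0.01)

  # through the analysis filter, the max amplitude is the pass-band
  # response to the 100 mG tremor
  filt <- bandpass(data.frame(t = sig$t_ms, m = m))
  want <- 100 * analytic_bp_gain(4.87, 3, 7, 50, 4)
  expect_equal(max(abs(filt$f)), want, tolerance = 0.05)

  expect_error(simulate_session_signal(100, 30), "Nyquist")
})

test_that("a tremor-free session stays near the noise floor", {
  set.seed(31)
  sig <- simulate_session_signal(0, 5, duration_s = 20, noise_sd = 10)
  m <- rss_magnitude(sig$ax_mg, sig$ay_mg, sig$az_mg)
  filt <- bandpass(data.frame(t = sig$t_ms, m = m))
  expect_lt(max(abs(filt$f)), 3 * 10)
})

test_that("burst duty cycle controls the average-to-maximum ratio", {
  set.seed(32)
  sig <- simulate_session_signal(300, 5, duty = 0.1, duration_s = 60,
                                 noise_sd = 0)
  m <- rss_magnitude(sig$ax_mg, sig$ay_mg, sig$az_mg)
  filt <- bandpass(data.frame(t = sig$t_ms, m = m))
  avg <- mean(abs(filt$f))
  mx <- max(abs(filt$f))
  expect_equal(mx, 300, tolerance = 0.06)
  # sustained sinusoid would give avg/max = 2/pi; a 10% duty cuts it
  expect_lt(avg / mx, 0.12)
  expect_gt(avg / mx, 0.04)
})

test_that("injected gaps are recovered exactly by the extractor", {
  co <- simulate_cohort(small_config(gap_rate = 1, dropout_rate = 0,
                                     report_rate_pd = c(1, 0),
                                     report_rate_et = c(1, 0)),
                        seed = 33)
  truth <- co$truth$sessions
  expect_true(all(truth$has_gap))
  for (i in seq_len(nrow(truth))) {
    ev <- data.frame(subject_id = truth$subject_id[i],
                     t_response = truth$t_response_ms[i],
                     tremor_reported = TRUE, tremor_hand = "watch")
    s <- extract_session(co$streams[[truth$subject_id[i]]], ev,
                         min_samples = 50)
    expect_equal(nrow(s$samples), truth$expected_run_length[i])
  }
})

test_that("emitted files round-trip through the readers with no rejects", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(small_config(), dir = dir, seed = 34)
  events <- read_events_csv(file.path(dir, "events.csv"))
  expect_equal(nrow(events), nrow(co$events))
  w <- read_snp_weights(file.path(dir, "snp_weights.tsv"))
  expect_equal(nrow(w), 22)
  expect_equal(w$weight, co$weights$weight)
  g <- read_dosage_csv(file.path(dir, "genotypes.csv"))
  expect_equal(unname(g), unname(co$genotypes))
  truth_sess <- utils::read.csv(file.path(dir, "truth_sessions.csv"))
  expect_equal(truth_sess$tremor, co$truth$sessions$tremor)
  for (sid in names(co$streams)) {
    s <- read_accel_csv(file.path(dir, paste0("accel_", sid, ".csv")),
                        subject_id = sid)
    expect_equal(attr(s, "n_rejected"), 0L)
    expect_equal(nrow(s), nrow(co$streams[[sid]]))
  }
})

test_that("genotype draws respect frequencies and the PRS tilt", {
  w0 <- data.frame(rsid = sprintf("rs%d", 1:22), effect_allele = "A",
                   odds_ratio = rep(1.2, 22), weight = log(1.2),
                   effect_allele_freq = 0)
  g0 <- simulate_genotypes(sprintf("S%d", 1:10), w0)
  expect_true(all(g0 == 0))
  expect_true(all(compute_prs(g0, w0)$score == 0))

  set.seed(35)
  w5 <- transform(w0, effect_allele_freq = 0.5)
  g5 <- simulate_genotypes(sprintf("S%d", 1:10000), w5)
  se <- sqrt(0.5 / 10000)  # binomial(2, 0.5) variance = 0.5
  expect_true(all(abs(colMeans(g5) - 1) < 3 * se))

  # tilt calibration: standardized group difference near the target
  set.seed(36)
  n <- 2000
  wts <- transform(w0, effect_allele_freq = runif(22, 0.2, 0.5))
  ids <- sprintf("S%d", 1:(2 * n))
  is_case <- rep(c(TRUE, FALSE), each = n)
  g <- simulate_genotypes(ids, wts, is_case = is_case, prs_effect = 0.5)
  s <- compute_prs(g, wts)$score
  d <- (mean(s[is_case]) - mean(s[!is_case])) /
    sqrt((var(s[is_case]) + var(s[!is_case])) / 2)
  expect_equal(d, 0.5, tolerance = 0.1)
})

test_that("a null PRS effect yields calibrated group tests", {
  set.seed(37)
  rejections <- 0
  w <- data.frame(rsid = sprintf("rs%d", 1:22), effect_allele = "A",
                  odds_ratio = runif(22, 1.05, 1.4),
                  weight = NA, effect_allele_freq = runif(22, 0.1, 0.5))
  w$weight <- log(w$odds_ratio)
  for (r in 1:200) {
    g <- simulate_genotypes(sprintf("S%d", 1:60), w,
                            is_case = rep(c(TRUE, FALSE), 30),
                            prs_effect = 0)
    s <- compute_prs(g, w)$score
    p <- mann_whitney_u(s[rep(c(TRUE, FALSE), 30)],
                        s[rep(c(FALSE, TRUE), 30)])$p.value
    if (p < 0.05) rejections <- rejections + 1
  }
  # nonsignificant in at least 90% of replicates under the null
  expect_lte(rejections, 20)
})

test_that("stronger amplitude separation raises the subject-level AUC", {
  base_auc <- numeric(2)
  for (i in 1:2) {
    sep <- list(c(300, 60), c(500, 60))[[i]]
    cfg <- sim_config(n_pd = 8, n_et = 8, days = 4, session_length_s = 10,
                      max_amp_pd = sep, max_amp_et = c(200, 60),
                      dropout_rate = 0, gap_rate = 0)
    co <- simulate_cohort(cfg, seed = 40 + i)
    res <- suppressWarnings(run_pipeline(co))
    base_auc[i] <- res$analysis$subject_roc$auc
  }
  expect_gte(base_auc[2], base_auc[1])
  expect_gt(base_auc[2], 0.8)
})
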