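test_that("well-formed accelerometer CSV loads with rows in order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_ms,ax_mg,ay_mg,az_mg",
               "0,1,2,3", "20,4,5,6", "40,7,8,9"), path)
  s <- read_accel_csv(path, subject_id = "S1")
  expect_s3_class(s, "accel_stream")
  expect_equal(nrow(s), 3)
  expect_equal(s$t, c(0, 20, 40))
  expect_equal(s$az, c(3, 6, 9))
  expect_identical(attr(s, "subject_id"), "S1")
})

test_that("out-of-order rows are sorted with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_ms,ax_mg,ay_mg,az_mg",
               "40,7,8,9", "0,1,2,3", "20,4,5,6"), path)
  expect_warning(s <- read_accel_csv(path, subject_id = "S1"),
                 "out of time order")
  expect_equal(s$t, c(0, 20, 40))
  expect_equal(s$ax, c(1, 4, 7))
})

test_that("malformed accelerometer input is rejected with diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_ms,ax_mg,ay_mg,az_mg", "0,1,2,3", "20,oops,5,6"), path)
  expect_error(read_accel_csv(path), "non-numeric.*row 2")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_ms,ax_mg,ay_mg", "0,1,2"), path2)
  expect_error(read_accel_csv(path2), "missing column")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_ms,ax_mg,ay_mg,az_mg", "0,1,2,3", "0,4,5,6"), path3)
  expect_error(read_accel_csv(path3), "duplicated timestamp 0")

  # rows with missing cells are dropped, not fatal
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_ms,ax_mg,ay_mg,az_mg", "0,1,2,3", "20,,5,6",
               "40,7,8,9"), path4)
  expect_message(s <- read_accel_csv(path4, subject_id = "S1"),
                 "1 accelerometer row\\(s\\) rejected")
  expect_equal(nrow(s), 2)
  expect_equal(attr(s, "n_rejected"), 1L)
})

test_that("combined multi-subject files split into per-subject streams", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,t_ms,ax_mg,ay_mg,az_mg",
               "A,0,1,1,1", "A,20,2,2,2", "B,0,3,3,3"), path)
  streams <- read_accel_csv(path)
  expect_named(streams, c("A", "B"))
  expect_equal(nrow(streams$A), 2)
  expect_identical(attr(streams$B, "subject_id"), "B")
})

test_that("questionnaire log enforces hand/report consistency", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,t_response_ms,tremor_reported,tremor_hand",
               "S1,1000,TRUE,watch", "S1,2000,FALSE,none",
               "S2,1500,TRUE,both"), path)
  ev <- read_events_csv(path)
  expect_equal(nrow(ev), 3)
  expect_identical(ev$tremor_reported, c(TRUE, FALSE, TRUE))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,t_response_ms,tremor_reported,tremor_hand",
               "S1,1000,TRUE,none"), bad)
  expect_error(read_events_csv(bad), "contradictory")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,t_response_ms,tremor_reported,tremor_hand",
               "S1,1000,TRUE,foot"), bad2)
  expect_error(read_events_csv(bad2), "invalid tremor_hand")
})

test_that("a gapless recording ending at the response is kept whole", {
  t <- seq(0, by = 20, length.out = 6000)
  stream <- make_stream(t + 1e6)
  ev <- make_event(t_response = 1e6 + t[6000])
  s <- extract_session(stream, ev)
  expect_equal(nrow(s$samples), 6000)
  expect_equal(s$span_start, 1e6)
  expect_equal(s$span_end, 1e6 + t[6000])
})

test_that("a mid-window gap isolates the longest (post-gap) run", {
  # 30 s of data, a 5 s hole 10 s in: pre-run 500 samples, post-run
  # 750 samples; the post-gap run is longer and must be selected
  t_pre <- seq(0, by = 20, length.out = 500)
  t_post <- seq(15000, by = 20, length.out = 750)
  stream <- make_stream(c(t_pre, t_post))
  ev <- make_event(t_response = max(t_post))
  s <- extract_session(stream, ev)
  expect_equal(nrow(s$samples), 750)
  expect_equal(s$span_start, 15000)
})

test_that("an empty lookback window yields no session", {
  t <- seq(0, by = 20, length.out = 1000)
  stream <- make_stream(t)
  ev <- make_event(t_response = max(t) + 301 * 1000)
  expect_null(extract_session(stream, ev))
})

test_that("runs below the minimum sample floor are rejected", {
  t <- seq(0, by = 20, length.out = 100)
  stream <- make_stream(t)
  ev <- make_event(t_response = max(t))
  expect_null(extract_session(stream, ev))
  expect_s3_class(extract_session(stream, ev, min_samples = 50),
                  "gameplay_session")
})

test_that("extraction matches brute-force run enumeration on random gap layouts", {
  set.seed(42)
  for (rep in 1:25) {
    # build 2-4 disjoint runs with random lengths and gap sizes
    n_runs <- sample(2:4, 1)
    t <- numeric(0)
    cur <- 0
    for (r in seq_len(n_runs)) {
      len <- sample(100:900, 1)
      t <- c(t, seq(cur, by = 20, length.out = len))
      cur <- t[length(t)] + sample(c(1500, 5000, 60000), 1)
    }
    stream <- make_stream(t)
    t_resp <- sample(t, 1) + sample(0:2000, 1)
    ev <- make_event(t_response = t_resp)
    got <- extract_session(stream, ev)
    want <- oracle_extract_idx(t, t_resp)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$samples$t, t[want])
    }
  }
})

test_that("extraction is invariant to input row order", {
  set.seed(7)
  t <- c(seq(0, by = 20, length.out = 400),
         seq(20000, by = 20, length.out = 600))
  perm <- sample(length(t))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t_ms = t[perm], ax_mg = perm, ay_mg = 0,
                              az_mg = 1000), path, row.names = FALSE)
  expect_warning(stream <- read_accel_csv(path, subject_id = "S1"))
  ev <- make_event(t_response = max(t) + 500)
  s <- extract_session(stream, ev)
  expect_equal(s$samples$t, seq(20000, by = 20, length.out = 600))
  # gap invariant holds on the output
  expect_true(all(diff(s$samples$t) <= 1000))
})

test_that("tremor filtering keeps only either-hand tremor reports", {
  t <- seq(0, by = 20, length.out = 20000)
  streams <- list(S1 = make_stream(t, subject_id = "S1"))
  events <- rbind(
    make_event("S1", t_response = 100000, reported = TRUE, hand = "watch"),
    make_event("S1", t_response = 200000, reported = FALSE, hand = "none"),
    make_event("S1", t_response = 300000, reported = TRUE, hand = "both")
  )
  sess <- tremor_sessions(streams, events)
  expect_length(sess, 2)
  expect_equal(attr(sess, "n_failed"), 0L)

  none <- tremor_sessions(streams, events[events$tremor_hand == "none", ])
  expect_length(none, 0)
})

test_that("events without samples or without a stream are tallied, not fatal", {
  t <- seq(0, by = 20, length.out = 1000)
  streams <- list(S1 = make_stream(t, subject_id = "S1"))
  events <- rbind(
    make_event("S1", t_response = max(t)),
    make_event("S1", t_response = max(t) + 400 * 1000),  # empty window
    make_event("S2", t_response = max(t))                # no stream
  )
  expect_warning(sess <- tremor_sessions(streams, events),
                 "no accelerometer stream")
  expect_length(sess, 1)
  expect_equal(attr(sess, "n_failed"), 1L)
  expect_equal(attr(sess, "n_unmatched"), 1L)
})

test_that("subject mismatch between stream and event is an error", {
  stream <- make_stream(seq(0, by = 20, length.out = 300),
                        subject_id = "S1")
  ev <- make_event("S2", t_response = 6000)
  expect_error(extract_session(stream, ev), "does not match")
})
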