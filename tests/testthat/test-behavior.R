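test_that("the CR rule is strict, windowed and sustained", {
  trial <- one_trial()
  # flat zero trace: no CR
  flat <- make_trace(function(t) rep(0, length(t)))
  expect_false(detect_cr(flat, trial)$is_cr)
  # peak exactly at the 0.1 threshold: not a CR (strict inequality)
  at_thr <- make_trace(function(t) ifelse(t > 0.15 & t < 0.25, 0.1, 0))
  expect_false(detect_cr(at_thr, trial)$is_cr)
  # step to 0.3 at 50 ms: too early, ignored entirely
  early <- make_trace(function(t) ifelse(t > 0.05 & t < 0.09, 0.3, 0))
  expect_false(detect_cr(early, trial)$is_cr)
  # same step at 200 ms: a CR with onset ~0.2 s
  late <- make_trace(function(t) ifelse(t >= 0.2 & t < 0.28, 0.3, 0))
  sc <- detect_cr(late, trial)
  expect_true(sc$is_cr)
  expect_lt(abs(sc$cr_onset - 0.2), 0.005)
  expect_equal(sc$cr_amplitude, 0.3, tolerance = 1e-6)
  # a single-frame blip is not sustained
  blip <- make_trace(function(t) ifelse(abs(t - 0.2) < 0.0006, 0.5, 0))
  expect_false(detect_cr(blip, trial)$is_cr)
  # baseline subtraction: elevated pre-CS closure does not fake a CR
  shifted <- make_trace(function(t) 0.3 + ifelse(t >= 0.2, 0.05, 0))
  expect_false(detect_cr(shifted, trial)$is_cr)
})

test_that("CS-only trials are scored up to the nominal US time", {
  trial <- one_trial(kind = "CS_ONLY")
  # closure rising only after the nominal US time: not a CR
  post_us <- make_trace(function(t) ifelse(t >= 0.35, 0.5, 0))
  expect_false(detect_cr(post_us, trial, isi = 0.3)$is_cr)
  in_win <- make_trace(function(t) ifelse(t >= 0.2 & t < 0.29, 0.5, 0))
  expect_true(detect_cr(in_win, trial, isi = 0.3)$is_cr)
})

test_that("UR metrics are windowed on the US and independent of the CR", {
  trial <- one_trial()
  ur_only <- make_trace(function(t)
    ifelse(t >= 0.32 & t < 0.5, 0.9, 0))
  sc <- detect_cr(ur_only, trial)
  ur <- ur_metrics(ur_only, trial)
  expect_false(sc$is_cr)                  # closure begins after the US
  expect_equal(ur$ur_amplitude, 0.9, tolerance = 1e-6)
  expect_lt(abs(ur$ur_latency - 0.02), 0.005)
  flat <- make_trace(function(t) rep(0, length(t)))
  expect_lt(ur_metrics(flat, trial)$ur_amplitude, 0.01)
  expect_error(ur_metrics(flat, one_trial(kind = "CS_ONLY")), "no US")
})

test_that("synthetic UR amplitude is recovered", {
  s <- make_scored_session(n_trials = 10, n_cs_only = 0, cr_prob = 0,
                           seed = 55)
  sc <- score_session(s)
  expect_lt(abs(mean(sc$ur_amplitude) - 1.0), 0.05)
})

test_that("session metrics aggregate scores correctly", {
  s <- make_scored_session(n_trials = 20, n_cs_only = 2, cr_prob = 0,
                           seed = 56)
  sc <- score_session(s)
  m <- session_metrics(sc, s)
  expect_equal(m$summary$percent_cr, 0)
  # hand-made scores: 45 CRs over 90 CS trials -> 50%
  fake <- data.frame(trial_id = 1:90, is_cr = rep(c(TRUE, FALSE), 45),
                     cr_onset = 0.2, cr_amplitude = 0.5, peak_time = 0.28,
                     baseline = 0, kind = "CS_US", ur_amplitude = 1,
                     ur_latency = 0.02)
  m2 <- session_metrics(fake, list(trials = data.frame()), 1L)
  expect_equal(m2$summary$percent_cr, 50)
  # %CR equals a brute-force recount of the flags
  s3 <- make_scored_session(n_trials = 50, n_cs_only = 5, cr_prob = 0.5,
                            seed = 57)
  sc3 <- score_session(s3)
  m3 <- session_metrics(sc3, s3)
  expect_equal(m3$summary$percent_cr,
               100 * sum(sc3$is_cr, na.rm = TRUE) / sum(!is.na(sc3$is_cr)))
})

test_that("raising the CR threshold never raises %CR", {
  s <- make_scored_session(n_trials = 40, n_cs_only = 4, cr_prob = 0.6,
                           cr_amplitude = 0.4, seed = 58)
  pc <- vapply(c(0.05, 0.1, 0.2, 0.35, 0.5), function(thr) {
    sc <- score_session(s, threshold = thr)
    100 * sum(sc$is_cr, na.rm = TRUE) / sum(!is.na(sc$is_cr))
  }, numeric(1))
  expect_true(all(diff(pc) <= 0))
})

test_that("cr_timing finds the windowed peak with a first-index tie rule", {
  tr <- make_trace(function(t) ifelse(abs(t - 0.25) < 0.001, 0.4, 0))
  mt <- data.frame(t = tr$t - 1, mean = tr$closure)
  got <- cr_timing(mt, isi = 0.3)
  expect_lt(abs(got$peak_time - 0.25), 0.002)
  const <- data.frame(t = seq(-0.2, 0.6, by = 1 / 900), mean = 0.2)
  tie <- cr_timing(const, isi = 0.3)
  expect_equal(tie$peak_amplitude, 0)
  expect_equal(tie$peak_time, min(const$t[const$t > 0]))
  expect_error(cr_timing(data.frame(t = c(-0.1, -0.05), mean = 0)),
               "window")
})

test_that("detected peak time tracks the programmed CR peak", {
  peaks <- c(0.2, 0.3, 0.4, 0.5)
  got <- vapply(seq_along(peaks), function(i) {
    s <- make_scored_session(n_trials = 30, n_cs_only = 6, cr_prob = 1,
                             cr_peak_time = peaks[i], isi = peaks[i],
                             seed = 60 + i)
    sc <- score_session(s, threshold = 0.1)
    m <- session_metrics(sc, s)
    cr_timing(m$mean_traces$CS_ONLY, isi = peaks[i])$peak_time
  }, numeric(1))
  expect_true(all(abs(got - peaks) <= 0.03))
})

test_that("learning curves follow the programmed schedules", {
  # monotone acquisition schedule
  mk <- function(extinct, seed) lapply(1:8, function(si) {
    s <- generate_session(session_config(n_trials = 60, n_cs_only = 6,
                                         iti_range = c(2, 3)), seed = seed + si)
    s <- generate_behavior(s, behavior_params(p_max = 0.9, p_tau = 4,
                                              cr_amplitude = 0.8,
                                              extinction_mode = extinct),
                           session_index = si, seed = seed + 100 + si)
    session_metrics(score_session(s), s, session_index = si)
  })
  lc <- learning_curve(mk(FALSE, 70))
  expect_equal(lc$session_index, 1:8)
  expect_gt(cor(lc$session_index, lc$percent_cr, method = "spearman"), 0.8)
  # extinction schedule: decreasing trend
  le <- learning_curve(mk(TRUE, 90))
  expect_lt(cor(le$session_index, le$percent_cr, method = "spearman"), 0)
  # duplicate sessions rejected
  dup <- mk(FALSE, 70)[c(1, 1)]
  expect_error(learning_curve(dup), "duplicate")
})
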