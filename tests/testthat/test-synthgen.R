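test_that("generated sessions follow the 90/10 co-terminating protocol", {
  s <- generate_session(session_config(), seed = 11)
  expect_equal(sum(s$trials$kind == "CS_US"), 90)
  expect_equal(sum(s$trials$kind == "CS_ONLY"), 10)
  expect_true(all(s$trials$iti_before >= 10 & s$trials$iti_before <= 15))
  paired <- s$trials[s$trials$kind == "CS_US", ]
  expect_equal(paired$us_onset - paired$cs_onset, rep(0.3, 90))
  # co-termination: CS offset equals US offset
  expect_equal(paired$cs_onset + paired$cs_duration,
               paired$us_onset + paired$us_duration)
  expect_true(all(diff(s$trials$cs_onset) > 0))
})

test_that("session generation is deterministic under a fixed seed", {
  a <- generate_session(session_config(), seed = 7)
  b <- generate_session(session_config(), seed = 7)
  expect_identical(a$trials, b$trials)
  c <- generate_session(session_config(), seed = 8)
  expect_false(identical(a$trials, c$trials))
})

test_that("ITI marginal matches the uniform(10, 15) law", {
  cfg <- session_config(n_trials = 1000L, n_cs_only = 0L)
  s <- generate_session(cfg, seed = 21)
  se <- (5 / sqrt(12)) / sqrt(1000)
  expect_lt(abs(mean(s$trials$iti_before) - 12.5), 3 * se)
})

test_that("n_cs_only > n_trials is rejected", {
  expect_error(session_config(n_trials = 5, n_cs_only = 6), "exceeds")
})

test_that("behavior generator echoes its programmed parameters", {
  # cr_prob 0: no pre-US closure beyond noise
  s0 <- make_scored_session(n_trials = 10, n_cs_only = 1, cr_prob = 0,
                            seed = 31)
  expect_true(all(!s0$ground_truth$trials$is_cr))
  pre_us <- mapply(function(id, cs) {
    tr <- s0$traces[s0$traces$trial_id == id, ]
    max(tr$closure[tr$t < cs + 0.3])
  }, s0$trials$trial_id, s0$trials$cs_onset)
  expect_true(all(pre_us < 0.1))   # nothing beyond noise before the US
  # cr_prob 1 with amplitude 0.8, peak 0.3 s: every CS trial peaks near 0.8
  s1 <- make_scored_session(n_trials = 10, n_cs_only = 1, cr_prob = 1,
                            cr_amplitude = 0.8, seed = 32)
  for (i in seq_len(nrow(s1$trials))) {
    tr <- s1$traces[s1$traces$trial_id == s1$trials$trial_id[i], ]
    cs <- s1$trials$cs_onset[i]
    win <- tr$t > cs + 0.15 & tr$t < cs + 0.45
    if (s1$trials$kind[i] == "CS_ONLY") {
      expect_gt(max(tr$closure[win]), 0.75)
      expect_lt(max(tr$closure[win]), 0.87)
      pk <- tr$t[win][which.max(tr$closure[win])] - cs
      expect_lt(abs(pk - 0.3), 0.05)
    }
  }
})

test_that("ground-truth CR flags follow the programmed Bernoulli law", {
  s <- make_scored_session(n_trials = 100, n_cs_only = 10, cr_prob = 0.6,
                           seed = 33)
  n_cr <- sum(s$ground_truth$trials$is_cr)
  ci <- qbinom(c(0.005, 0.995), 100, 0.6)
  expect_gte(n_cr, ci[1])
  expect_lte(n_cr, ci[2])
})

test_that("SSpk renewal counting matches its rate law", {
  p <- unit_params(cspk_rate = 0)
  gt <- generate_spike_train(600, p, seed = 41)
  expect_lt(abs(length(gt$sspk_times) - 48000), 3 * sqrt(48000))
  expect_true(all(diff(gt$sspk_times) >= p$refractory - 1e-9))
})

test_that("phenotype multipliers scale the evoked-response law", {
  cfg <- session_config(n_trials = 400, n_cs_only = 0, iti_range = c(1, 1.5))
  trials <- generate_session(cfg, seed = 51)$trials
  dur <- max(trials$us_onset, na.rm = TRUE) + 1
  p <- unit_params(phenotype = "CF_CHR2")   # p_evoked 0.9 * 0.2
  gt <- generate_spike_train(dur, p, trials = trials, seed = 52)
  frac <- mean(gt$evoked$responded)
  ci <- qbinom(c(0.005, 0.995), 400, 0.18) / 400
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("voltage renderer is consistent with its ground truth", {
  p <- unit_params(noise_sd = 0)
  gt <- generate_spike_train(5, p, seed = 61)
  v <- generate_voltage(gt, 5, p, seed = 62)
  # a supra-threshold excursion exists within +-1 sample of each insertion
  for (t in c(gt$sspk_times, gt$cspk_times)) {
    i <- round(t * v$rate) + 1L
    expect_lt(min(v$samples[max(1, i - 1):min(length(v$samples), i + 1)]),
              -0.5)
  }
  # zero rates + zero noise: detector refuses the flat trace
  silent <- generate_voltage(list(sspk_times = numeric(0),
                                  cspk_times = numeric(0),
                                  cspk_spikelets = integer(0)),
                             1, p, seed = 63)
  expect_error(detect_spikes(silent), "flat|degenerate")
})

test_that("generators are bit-reproducible under a fixed seed", {
  p <- unit_params()
  a <- generate_spike_train(20, p, seed = 71)
  b <- generate_spike_train(20, p, seed = 71)
  expect_identical(a, b)
  va <- generate_voltage(a, 20, p, seed = 72)
  vb <- generate_voltage(b, 20, p, seed = 72)
  expect_identical(va$samples, vb$samples)
  s1 <- make_scored_session(seed = 73)
  s2 <- make_scored_session(seed = 73)
  expect_identical(s1$traces, s2$traces)
})

test_that("jaws-style laser trials suppress evoked CSpks and randomize duration", {
  cfg <- session_config(n_trials = 50, n_cs_only = 5, iti_range = c(1, 1.5),
                        laser_mode = "jaws")
  s <- generate_session(cfg, seed = 81)
  lasered <- s$trials[!is.na(s$trials$laser_duration), ]
  expect_true(all(lasered$laser_duration >= 0.3 &
                    lasered$laser_duration <= 0.4))
  dur <- max(s$trials$cs_onset) + 2
  gt <- generate_spike_train(dur, unit_params(), trials = s$trials,
                             laser_mode = "jaws", seed = 82)
  expect_false(any(gt$evoked$responded))
})
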