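test_that("detection finds injected kernels exactly and ignores noise", {
  p <- unit_params(noise_sd = 0.05)
  # three known SSpk times in an otherwise noise-only trace
  t_in <- c(0.10, 0.25, 0.42)
  v <- generate_voltage(list(sspk_times = t_in, cspk_times = numeric(0),
                             cspk_spikelets = integer(0)),
                        0.6, p, seed = 101)
  ev <- detect_spikes(v)
  expect_equal(length(ev$times), 3)
  expect_true(all(abs(ev$times - t_in) <= 1 / v$rate))
  # pure noise: false positives below 0.1 Hz over 100 s
  vn <- generate_voltage(list(sspk_times = numeric(0),
                              cspk_times = numeric(0),
                              cspk_spikelets = integer(0)),
                         100, p, seed = 102)
  expect_lt(length(detect_spikes(vn)$times) / 100, 0.1)
})

test_that("detection rejects flat and too-short traces", {
  expect_error(detect_spikes(rep(0, 25000), rate = 25000), "flat")
  expect_error(detect_spikes(rnorm(100), rate = 25000), "0.1 s")
})

test_that("classification applies the spikelet-and-pause rule", {
  p <- unit_params(noise_sd = 0.02)
  # lone SSpk followed by ordinary firing: SSpk
  lone <- generate_voltage(list(sspk_times = c(0.1, 0.115, 0.13),
                                cspk_times = numeric(0),
                                cspk_spikelets = integer(0)),
                           0.3, p, seed = 111)
  st <- classify_events(detect_spikes(lone))
  expect_equal(length(st$sspk_times), 3)
  expect_equal(length(st$cspk_times), 0)
  # primary + 3 spikelets then silence: one CSpk, count 3
  cs <- generate_voltage(list(sspk_times = c(0.05, 0.2),
                              cspk_times = 0.1,
                              cspk_spikelets = 3L),
                         0.3, p, seed = 112)
  st2 <- classify_events(detect_spikes(cs))
  expect_equal(length(st2$cspk_times), 1)
  expect_equal(st2$cspk_spikelets, 3L)
  expect_lt(abs(st2$cspk_times - 0.1), 0.001)
  expect_equal(length(st2$sspk_times), 2)
})

test_that("the full pipeline recovers a synthetic unit's labels", {
  p <- unit_params()
  gt <- generate_spike_train(60, p, seed = 121)
  v <- generate_voltage(gt, 60, p, seed = 122)
  st <- classify_events(detect_spikes(v))
  truth <- sort(c(gt$sspk_times, gt$cspk_times))
  det <- sort(c(st$sspk_times, st$cspk_times))
  expect_gte(match_rate(truth, det), 0.99)   # recall
  expect_gte(match_rate(det, truth), 0.99)   # precision
  acc <- c(vapply(gt$sspk_times, function(t)
    any(abs(st$sspk_times - t) <= 0.001), logical(1)),
    vapply(gt$cspk_times, function(t)
      any(abs(st$cspk_times - t) <= 0.001), logical(1)))
  expect_gte(mean(acc), 0.95)
})

test_that("unit_stats equals a brute-force oracle on a small instance", {
  ss <- c(0.5, 1.1, 1.8, 2.4, 3.0, 4.2, 5.1, 6.3)
  cs <- c(2.0, 4.9)
  st <- spike_train(ss, cs, c(3L, 4L))
  got <- unit_stats(st, recording = c(0, 10), min_spont = 0)
  want <- oracle_unit_stats(ss, cs, 10)
  for (f in names(want)) expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
  # arithmetic sanity: 100 uniform SSpks over 10 s -> 10 Hz
  u <- spike_train(seq(0.05, 9.95, length.out = 100))
  expect_equal(unit_stats(u, c(0, 10), min_spont = 0)$spont_sspk_rate, 10)
  # perfectly periodic: CV 0
  per <- spike_train(seq(0.1, 9.9, by = 0.1))
  expect_equal(unit_stats(per, c(0, 10), min_spont = 0)$sspk_cv, 0)
})

test_that("spontaneous epochs exclude stimulus windows", {
  trials <- one_trial(cs_onset = 5)
  ss <- c(1, 2, 3, 4.6, 5.2, 5.9, 7, 8)  # some inside the stimulus margin
  st <- spike_train(ss, numeric(0))
  got <- unit_stats(st, c(0, 10), trials = trials, min_spont = 0)
  # epoch margin 0.5 s around [5, 5.35]: spontaneous = [0,4.5) U [5.85,10)
  expect_equal(got$spont_sspk_rate, 6 / (4.5 + 4.15), tolerance = 1e-9)
  expect_error(unit_stats(st, c(0, 10), trials = trials, min_spont = 60),
               "insufficient")
})

test_that("doublet fraction and CV match their renewal-theory limits", {
  # Poisson CSpks at 1 Hz: P(interval < 0.2 s) = 1 - exp(-0.2)
  p <- unit_params(sspk_rate = 0, cspk_rate = 1)
  gt <- generate_spike_train(1000, p, seed = 131)
  st <- spike_train(gt$sspk_times, gt$cspk_times, gt$cspk_spikelets)
  got <- unit_stats(st, c(0, 1000), min_spont = 0)
  n_int <- length(gt$cspk_times) - 1
  target <- 1 - exp(-0.2)
  se <- sqrt(target * (1 - target) / n_int)
  expect_lt(abs(got$doublet_fraction - target), 3 * se)
  # Poisson SSpks: CV -> 1
  pp <- unit_params(sspk_isi_shape = 1, refractory = 0, cspk_rate = 0)
  gt2 <- generate_spike_train(200, pp, seed = 132)
  st2 <- spike_train(gt2$sspk_times)
  cv <- unit_stats(st2, c(0, 200), min_spont = 0)$sspk_cv
  expect_lt(abs(cv - 1), 3 / sqrt(length(gt2$sspk_times)))
})

test_that("the PSTH conserves counts and normalizes per trial", {
  # one SSpk per trial, all in the same 25-ms bin, over 40 trials
  at <- seq(10, 400, by = 10)
  trials <- data.frame(trial_id = seq_along(at), kind = "CS_US",
                       cs_onset = at, cs_duration = 0.35,
                       us_onset = at + 0.3, us_duration = 0.05,
                       laser_onset = NA_real_, laser_duration = NA_real_,
                       iti_before = 10)
  st <- spike_train(at + 0.110)   # 110 ms after CS: bin [0.1, 0.125)
  ps <- psth(st, trials, align = "CS", bin_width = 0.025,
             window = c(-0.2, 0.5))
  b <- which(abs(ps$bin_edges[-length(ps$bin_edges)] - 0.100) < 1e-9)
  expect_equal(ps$sspk_rate[b], 40)
  expect_equal(sum(ps$sspk_rate[-b]), 0)
  # conservation identity, exact
  p <- unit_params()
  gt <- generate_spike_train(max(at) + 2, p, trials = trials, seed = 141)
  st2 <- spike_train(gt$sspk_times, gt$cspk_times)
  ps2 <- psth(st2, trials, align = "US", bin_width = 0.025)
  total <- sum(vapply(trials$us_onset, function(a)
    sum(gt$sspk_times - a >= -0.2 & gt$sspk_times - a < 0.5), numeric(1)))
  expect_equal(sum(ps2$sspk_rate) * 0.025 * ps2$n_trials, total)
  expect_true(all(ps2$cspk_prob >= 0 & ps2$cspk_prob <= 1))
  expect_error(psth(st2, trials, bin_width = 0), "positive")
  # empty train: all-zero histogram
  ps3 <- psth(spike_train(numeric(0)), trials, align = "CS")
  expect_true(all(ps3$sspk_rate == 0) && all(ps3$cspk_prob == 0))
})

test_that("evoked responses report probability and median latency", {
  at <- seq(5, 100, by = 5)
  trials <- data.frame(trial_id = seq_along(at), kind = "CS_US",
                       cs_onset = at - 0.3, cs_duration = 0.35,
                       us_onset = at, us_duration = 0.05,
                       laser_onset = NA_real_, laser_duration = NA_real_,
                       iti_before = 5)
  # CSpk in-window on every trial -> probability 1
  st <- spike_train(numeric(0), at + 0.02)
  ev <- evoked_response(st, trials, event = "US")
  expect_equal(ev$prob, 1)
  expect_equal(ev$latency, 0.02, tolerance = 1e-9)
  # none in-window -> probability 0, latency absent
  st0 <- spike_train(numeric(0), at + 0.2)
  ev0 <- evoked_response(st0, trials, event = "US")
  expect_equal(ev0$prob, 0)
  expect_true(is.na(ev0$latency))
  expect_error(evoked_response(st, trials, event = "US", window = -1),
               "positive")
})

test_that("evoked probability and latency recover generator ground truth", {
  cfg <- session_config(n_trials = 200, n_cs_only = 0, iti_range = c(2, 3))
  trials <- generate_session(cfg, seed = 151)$trials
  dur <- max(trials$us_onset, na.rm = TRUE) + 1
  p <- unit_params(p_evoked = 0.8)
  gt <- generate_spike_train(dur, p, trials = trials, seed = 152)
  st <- spike_train(gt$sspk_times, gt$cspk_times)
  ev <- evoked_response(st, trials, event = "US")
  truth <- mean(gt$evoked$responded)
  ci <- qbinom(c(0.005, 0.995), 200, truth) / 200
  expect_gte(ev$prob, ci[1])
  expect_lte(ev$prob, ci[2] + 0.05)  # spontaneous CSpks can add ~1/20 trials
  expect_lt(abs(ev$latency - 0.02), 0.002)
})

test_that("unit qualification covers the selection-bias scenario", {
  at <- seq(5, 100, by = 5)
  trials <- data.frame(trial_id = seq_along(at), kind = "CS_US",
                       cs_onset = at - 0.3, cs_duration = 0.35,
                       us_onset = at, us_duration = 0.05,
                       laser_onset = at, laser_duration = 0.1,
                       iti_before = 5)
  # no spontaneous CSpks, reliable laser-evoked CSpks
  silent_spont <- spike_train(seq(0.5, 100, by = 0.0125), at + 0.015)
  qc <- qualify_unit(silent_spont, c(0, 101), trials)
  expect_false(qc$spontaneous_cspk)
  expect_true(qc$laser_evoked_cspk)
  # both criteria
  both <- spike_train(numeric(0), sort(c(at + 0.015, at + 2)))
  qc2 <- qualify_unit(both, c(0, 101), trials)
  expect_true(qc2$spontaneous_cspk && qc2$laser_evoked_cspk)
  # neither
  mute <- spike_train(seq(0.5, 100, by = 0.0125))
  qc3 <- qualify_unit(mute, c(0, 101), trials)
  expect_false(qc3$spontaneous_cspk || isTRUE(qc3$laser_evoked_cspk))
  # laser criterion without laser trials is a parameter error
  no_laser <- trials; no_laser$laser_onset <- NA_real_
  expect_error(qualify_unit(both, c(0, 101), no_laser, criteria = "laser"),
               "laser")
})
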