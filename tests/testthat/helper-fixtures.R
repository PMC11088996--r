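# shared fixtures and independent oracles, built in code at test time

# small trial-scored session with programmed behavior
make_scored_session <- function(n_trials = 20, n_cs_only = 2, cr_prob = 1,
                                cr_amplitude = 0.8, cr_peak_time = 0.3,
                                isi = 0.3, seed = 1, noise_sd = 0.02) {
  cfg <- session_config(n_trials = n_trials, n_cs_only = n_cs_only,
                        isi = isi, iti_range = c(2, 3))
  s <- generate_session(cfg, seed = seed)
  generate_behavior(s, behavior_params(cr_prob = cr_prob,
                                       cr_amplitude = cr_amplitude,
                                       cr_peak_time = cr_peak_time,
                                       baseline_noise_sd = noise_sd),
                    seed = seed + 1000)
}

# hand-built closure trace on a 900-Hz grid around a CS at cs_onset;
# `shape_fun(t_re_cs)` gives the closure signal
make_trace <- function(shape_fun, cs_onset = 1, rate = 900,
                       pre = 0.5, post = 1.0, trial_id = 1L) {
  t <- seq(cs_onset - pre, cs_onset + post - 1 / rate, by = 1 / rate)
  data.frame(trial_id = trial_id, frame = seq_along(t) - 1L, t = t,
             distance_px = NA_real_, closure = shape_fun(t - cs_onset))
}

one_trial <- function(cs_onset = 1, kind = "CS_US", isi = 0.3,
                      us_duration = 0.05) {
  data.frame(trial_id = 1L, kind = kind, cs_onset = cs_onset,
             cs_duration = isi + us_duration,
             us_onset = if (kind == "CS_US") cs_onset + isi else NA_real_,
             us_duration = if (kind == "CS_US") us_duration else NA_real_,
             laser_onset = NA_real_, laser_duration = NA_real_,
             iti_before = 10)
}

# greedy matching of detected to true event times within a tolerance
match_rate <- function(from, to, tol = 0.001) {
  if (!length(from)) return(NA_real_)
  mean(vapply(from, function(t) any(abs(to - t) <= tol), logical(1)))
}

# brute-force recomputation of unit statistics for a spontaneous-only
# train: the independent oracle for unit_stats()
oracle_unit_stats <- function(ss, cs, duration, doublet_gap = 0.2) {
  pause <- NA_real_
  if (length(cs)) {
    gaps <- c()
    for (cc in cs) {
      nxt <- ss[ss > cc]
      if (length(nxt)) gaps <- c(gaps, min(nxt) - cc)
    }
    if (length(gaps)) pause <- sum(gaps) / length(gaps)
  }
  list(spont_sspk_rate = length(ss) / duration,
       spont_cspk_rate = length(cs) / duration,
       sspk_cv = if (length(ss) > 2) sd(diff(ss)) / mean(diff(ss))
                 else NA_real_,
       post_cspk_pause = pause,
       doublet_fraction = if (length(cs) > 1)
         sum(diff(cs) < doublet_gap) / (length(cs) - 1) else NA_real_)
}
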