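#' Generate the trial structure of a synthetic session
#'
#' Builds a trial table following the delay-conditioning protocol: CS-only
#' probe trials at uniformly random positions among the paired trials,
#' i.i.d. uniform intertrial intervals, and co-terminating CS/US at the
#' configured ISI on paired trials. With `laser_mode = "us"` the airpuff is
#' replaced by a 100-ms laser pulse at the US onset time; with
#' `laser_mode = "jaws"` an inhibitory laser of duration uniform on
#' 300-400 ms starts at airpuff onset.
#'
#' @param config a [session_config()].
#' @param seed integer seed for reproducibility; falls back to
#'   `config$seed`.
#' @return a [session()] holding the trial table only.
#' @export
#' @examples
#' s <- generate_session(session_config(n_trials = 10, n_cs_only = 1),
#'                       seed = 1)
#' table(s$trials$kind)
generate_session <- function(config = session_config(), seed = NULL) {
  validate_config(config)
  seed <- seed %||% config$seed
  with_seed(seed, {
    n <- config$n_trials
    kind <- rep("CS_US", n)
    if (config$n_cs_only > 0L)
      kind[sample.int(n, config$n_cs_only)] <- "CS_ONLY"
    iti <- runif(n, config$iti_range[1], config$iti_range[2])
    cs_duration <- config$isi + config$us_duration  # co-terminating
    cs_onset <- numeric(n)
    clock <- 0
    for (i in seq_len(n)) {
      clock <- clock + iti[i]
      cs_onset[i] <- clock
      clock <- clock + cs_duration
    }
    us_onset <- ifelse(kind == "CS_US", cs_onset + config$isi, NA_real_)
    us_duration <- ifelse(kind == "CS_US", config$us_duration, NA_real_)
    laser_onset <- rep(NA_real_, n)
    laser_duration <- rep(NA_real_, n)
    if (config$laser_mode == "us") {
      # optogenetic US: 100-ms pulse at the scheduled US onset; the us_*
      # columns keep the nominal US schedule so alignment is unchanged
      laser_onset <- us_onset
      laser_duration <- ifelse(kind == "CS_US", 0.100, NA_real_)
    } else if (config$laser_mode == "jaws") {
      laser_onset <- us_onset
      laser_duration <- ifelse(kind == "CS_US",
                               runif(n, 0.300, 0.400), NA_real_)
    }
    trials <- data.frame(trial_id = seq_len(n), kind = kind,
                         cs_onset = cs_onset, cs_duration = cs_duration,
                         us_onset = us_onset, us_duration = us_duration,
                         laser_onset = laser_onset,
                         laser_duration = laser_duration,
                         iti_before = iti)
    session(config, trials,
            provenance = list(generator = "generate_session", seed = seed))
  })
}
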