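#' Session configuration
#'
#' Bundles the protocol parameters of one eyeblink-conditioning session.
#' Defaults reflect the standard delay-conditioning protocol: 100 trials per
#' session of which 10 are CS-only probes, a fixed 300-ms interstimulus
#' interval (ISI) with CS and US co-terminating, a 50-ms airpuff US,
#' randomized 10-15 s intertrial intervals, 900-fps eye video of a
#' 172 x 160 px region, and 25-kHz extracellular voltage.
#'
#' @param n_trials total trials per session.
#' @param n_cs_only number of CS-only probe trials (must not exceed
#'   `n_trials`).
#' @param isi CS-to-US onset interval, seconds.
#' @param us_duration airpuff duration, seconds.
#' @param iti_range range of the uniformly drawn intertrial interval,
#'   seconds.
#' @param video_rate eye-camera frame rate, Hz.
#' @param video_shape frame height and width in pixels.
#' @param ephys_rate voltage sampling rate, Hz.
#' @param laser_mode `"none"`, `"us"` (laser substitutes for the airpuff on
#'   paired trials, 100-ms pulse) or `"jaws"` (inhibitory laser overlapping
#'   the airpuff, duration randomized in 300-400 ms).
#' @param seed optional integer recorded with the config; generators use it
#'   when no explicit seed is passed.
#' @return an object of class `session_config`.
#' @export
#' @examples
#' session_config(n_trials = 20, n_cs_only = 2)
session_config <- function(n_trials = 100L, n_cs_only = 10L, isi = 0.300,
                           us_duration = 0.050, iti_range = c(10, 15),
                           video_rate = 900, video_shape = c(172L, 160L),
                           ephys_rate = 25000, laser_mode = "none",
                           seed = NULL) {
  laser_mode <- match.arg(laser_mode, c("none", "us", "jaws"))
  cfg <- list(n_trials = as.integer(n_trials),
              n_cs_only = as.integer(n_cs_only),
              isi = isi, us_duration = us_duration,
              iti_range = as.numeric(iti_range),
              video_rate = video_rate,
              video_shape = as.integer(video_shape),
              ephys_rate = ephys_rate,
              laser_mode = laser_mode, seed = seed)
  class(cfg) <- "session_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_cs_only > cfg$n_trials)
    stop("n_cs_only (", cfg$n_cs_only, ") exceeds n_trials (",
         cfg$n_trials, ")")
  if (cfg$n_trials < 1L) stop("a session must contain at least one trial")
  for (f in c("isi", "us_duration", "video_rate", "ephys_rate"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field '", f, "' must be positive")
  if (length(cfg$iti_range) != 2L || diff(cfg$iti_range) < 0 ||
      any(cfg$iti_range < 0))
    stop("iti_range must be an increasing pair of non-negative seconds")
  invisible(cfg)
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config> ", x$n_trials, " trials (", x$n_cs_only,
      " CS-only), ISI ", x$isi * 1000, " ms, US ", x$us_duration * 1000,
      " ms, ITI ", x$iti_range[1], "-", x$iti_range[2], " s, laser '",
      x$laser_mode, "'\n", sep = "")
  invisible(x)
}

trial_columns <- c("trial_id", "kind", "cs_onset", "cs_duration",
                   "us_onset", "us_duration", "laser_onset",
                   "laser_duration", "iti_before")

#' Validate a trial table
#'
#' Checks the schema and timing invariants of a session trial table: known
#' trial kinds, strictly increasing CS onsets, US after CS on paired trials
#' with the onset gap equal to the session ISI, and co-terminating stimuli
#' under the default protocol. Errors name the offending row and column.
#'
#' @param trials data.frame with columns `trial_id`, `kind`, `cs_onset`,
#'   `cs_duration`, `us_onset`, `us_duration`, `laser_onset`,
#'   `laser_duration`, `iti_before`.
#' @param isi expected CS-to-US onset interval, seconds; `NULL` skips the
#'   ISI check (non-default protocols).
#' @param tol numeric tolerance for timing identities.
#' @return the validated table, invisibly.
#' @export
validate_trials <- function(trials, isi = NULL, tol = 1e-6) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols))
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad_kind <- which(!trials$kind %in% c("CS_US", "CS_ONLY", "US_ONLY"))
  if (length(bad_kind))
    stop("row ", bad_kind[1], ", column 'kind': unknown trial kind '",
         trials$kind[bad_kind[1]], "'")
  onset <- ifelse(is.na(trials$cs_onset), trials$us_onset, trials$cs_onset)
  if (anyNA(onset))
    stop("row ", which(is.na(onset))[1],
         ": neither cs_onset nor us_onset present")
  if (nrow(trials) > 1L && any(diff(onset) <= 0))
    stop("row ", which(diff(onset) <= 0)[1] + 1L,
         ", column 'cs_onset': trial onsets must be strictly increasing")
  paired <- which(trials$kind == "CS_US")
  for (i in paired) {
    if (is.na(trials$us_onset[i]))
      stop("row ", i, ", column 'us_onset': missing on CS_US trial")
    if (trials$us_onset[i] < trials$cs_onset[i])
      stop("row ", i, ", column 'us_onset': US precedes CS")
    if (!is.null(isi) &&
        abs(trials$us_onset[i] - trials$cs_onset[i] - isi) > tol)
      stop("row ", i, ", column 'us_onset': CS-US interval ",
           trials$us_onset[i] - trials$cs_onset[i],
           " s does not match the session ISI ", isi, " s")
  }
  cs_only <- which(trials$kind == "CS_ONLY")
  if (length(cs_only) && !all(is.na(trials$us_onset[cs_only])))
    stop("row ", cs_only[which(!is.na(trials$us_onset[cs_only]))[1]],
         ", column 'us_onset': must be absent on CS_ONLY trials")
  invisible(trials)
}

#' Construct a session container
#'
#' A `session` bundles the protocol config, the trial table, and any subset
#' of the per-trial data assets: eyelid traces, eye videos, a voltage trace,
#' and (for synthetic sessions) generator ground truth. Optional assets may
#' be absent; trial-keyed assets must reference trials present in the table.
#'
#' @param config a [session_config()].
#' @param trials trial table (see [validate_trials()]).
#' @param traces optional long-format eyelid table: `trial_id`, `frame`,
#'   `t`, `distance_px`, `closure`.
#' @param video optional named list of video stacks, names `trial_<id>`.
#' @param voltage optional list with elements `samples`, `rate`, `t0`.
#' @param ground_truth optional list of generator ground-truth tables.
#' @param provenance free-form metadata list.
#' @return an object of class `session`.
#' @export
session <- function(config, trials, traces = NULL, video = NULL,
                    voltage = NULL, ground_truth = NULL,
                    provenance = list()) {
  stopifnot(inherits(config, "session_config"))
  if (nrow(trials) < 1L) stop("a session must contain at least one trial")
  validate_trials(trials, isi = config$isi)
  if (!is.null(traces)) {
    orphan <- setdiff(unique(traces$trial_id), trials$trial_id)
    if (length(orphan))
      stop("eyelid traces reference unknown trial_id ", orphan[1])
  }
  s <- list(config = config, trials = as.data.frame(trials),
            traces = if (is.null(traces)) NULL else as.data.frame(traces),
            video = video, voltage = voltage,
            ground_truth = ground_truth, provenance = provenance)
  class(s) <- "session"
  s
}

#' @export
print.session <- function(x, ...) {
  cat("<session> ", nrow(x$trials), " trials; assets:",
      if (!is.null(x$traces)) " traces" else "",
      if (!is.null(x$video)) " video" else "",
      if (!is.null(x$voltage)) " voltage" else "",
      if (!is.null(x$ground_truth)) " ground_truth" else "", "\n", sep = "")
  invisible(x)
}
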