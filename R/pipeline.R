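#' Run the full analysis pipeline on a session
#'
#' Orchestrates the stages in order: videometry (when the session has
#' video but no distance traces), closure normalization, trial scoring and
#' session metrics, and - when a voltage trace is present - spike
#' detection, classification, unit statistics, and CS/US-aligned
#' peri-stimulus histograms. Stage errors are re-signalled with the stage
#' name attached. Given the same session and configuration the output,
#' including the optional CSV reports, is identical run to run.
#'
#' @param sess a [session()] with at least traces or video.
#' @param out_dir optional directory for CSV report tables
#'   (`trial_scores.csv`, `session_metrics.csv`, `unit_stats.csv`,
#'   `psth.csv`, `spike_train.csv`) and an `analysis_log.txt` echoing the
#'   thresholds used.
#' @param session_index training-session index for the metrics table.
#' @param cr_threshold CR amplitude threshold (see [detect_cr()]).
#' @param detection_k spike-detection threshold multiplier.
#' @param denominator %CR denominator mode (see [session_metrics()]).
#' @param min_spont spontaneous-time floor for [unit_stats()], seconds.
#' @return list of class `pipeline_result`: `scores`, `metrics`, and when
#'   voltage is present `spikes`, `units`, `psth_cs`, `psth_us`.
#' @export
run_pipeline <- function(sess, out_dir = NULL, session_index = 1L,
                         cr_threshold = 0.1, detection_k = 4.5,
                         denominator = "all_cs", min_spont = 60) {
  stopifnot(inherits(sess, "session"))
  if (is.null(sess$traces) && is.null(sess$video))
    stop("session has neither eyelid traces nor video")
  log_lines <- c(sprintf("cr_threshold=%g", cr_threshold),
                 sprintf("detection_k=%g", detection_k),
                 sprintf("denominator=%s", denominator))
  if (is.null(sess$traces)) {
    sess$traces <- tryCatch(
      do.call(rbind, lapply(sess$video, extract_trace)),
      error = function(e) stop_stage("videometry", e))
    log_lines <- c(log_lines, "videometry: threshold=otsu")
  }
  if (anyNA(sess$traces$closure)) {
    sess$traces <- tryCatch(
      normalize_session(sess$traces, sess$trials),
      error = function(e) stop_stage("normalize", e))
    cal <- attr(sess$traces, "calibration")
    log_lines <- c(log_lines, sprintf("normalize: d_open=%.3f d_closed=%.3f",
                                      cal["d_open"], cal["d_closed"]))
  }
  scores <- tryCatch(score_session(sess, threshold = cr_threshold),
                     error = function(e) stop_stage("behavior", e))
  metrics <- tryCatch(
    session_metrics(scores, sess, session_index = session_index,
                    denominator = denominator),
    error = function(e) stop_stage("behavior", e))
  out <- list(scores = scores, metrics = metrics, log = log_lines)
  if (!is.null(sess$voltage)) {
    out$spikes <- tryCatch({
      ev <- detect_spikes(sess$voltage, k = detection_k)
      classify_events(ev)
    }, error = function(e) stop_stage("ephys", e))
    dur <- length(sess$voltage$samples) / sess$voltage$rate
    out$units <- tryCatch(
      unit_stats(out$spikes, recording = c(0, dur), trials = sess$trials,
                 min_spont = min_spont),
      error = function(e) stop_stage("ephys", e))
    out$psth_cs <- tryCatch(psth(out$spikes, sess$trials, align = "CS"),
                            error = function(e) stop_stage("ephys", e))
    if (any(!is.na(sess$trials$us_onset)))
      out$psth_us <- psth(out$spikes, sess$trials, align = "US")
  }
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(scores, file.path(out_dir, "trial_scores.csv"))
    fwrite(metrics$summary, file.path(out_dir, "session_metrics.csv"))
    if (!is.null(out$units))
      fwrite(as.data.frame(out$units), file.path(out_dir, "unit_stats.csv"))
    if (!is.null(out$spikes)) {
      st <- out$spikes
      fwrite(data.frame(
        time = c(st$sspk_times, st$cspk_times),
        label = c(rep("SSpk", length(st$sspk_times)),
                  rep("CSpk", length(st$cspk_times))),
        spikelets = c(rep(NA_integer_, length(st$sspk_times)),
                      st$cspk_spikelets))[order(c(st$sspk_times,
                                                  st$cspk_times)), ],
        file.path(out_dir, "spike_train.csv"))
    }
    if (!is.null(out$psth_cs))
      fwrite(data.frame(bin_start = head(out$psth_cs$bin_edges, -1),
                        sspk_rate = out$psth_cs$sspk_rate,
                        cspk_prob = out$psth_cs$cspk_prob),
             file.path(out_dir, "psth.csv"))
    writeLines(log_lines, file.path(out_dir, "analysis_log.txt"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$metrics)
  if (!is.null(x$spikes)) print(x$spikes)
  invisible(x)
}
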