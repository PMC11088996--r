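#' Score one trial for a conditioned response
#'
#' Applies the standard CR rule: a trial contains a CR if the
#' baseline-subtracted normalized closure strictly exceeds the amplitude
#' threshold (default 0.1) at some time more than 100 ms after CS onset
#' and before US onset (for CS-only trials, before the nominal US time
#' `cs_onset + isi`), sustained for at least `min_sustain` seconds to
#' reject single-frame noise. The baseline is the mean closure over the
#' 200 ms preceding CS onset. Deflections within the first 100 ms after
#' the CS (startle) are ignored entirely rather than disqualifying the
#' trial.
#'
#' @param trace one trial's normalized eyelid table (`t`, `closure`).
#' @param trial the matching row of the trial table.
#' @param isi nominal CS-US interval, seconds (scoring window end on
#'   CS-only trials).
#' @param threshold CR amplitude threshold on baseline-subtracted closure
#'   (strict inequality).
#' @param min_sustain minimum supra-threshold duration, seconds.
#' @param baseline_window pre-CS baseline extent, seconds.
#' @return one-row data.frame: `trial_id`, `is_cr`, `cr_onset` (s re CS,
#'   `NA` if no CR), `cr_amplitude`, `peak_time` (s re CS), `baseline`.
#' @export
detect_cr <- function(trace, trial, isi = 0.300, threshold = 0.1,
                      min_sustain = 0.010, baseline_window = 0.2) {
  if (anyNA(trace$closure))
    stop("trace is not normalized: closure contains NA")
  if (is.na(trial$cs_onset))
    stop("trial has no CS onset; CR scoring applies to CS-containing trials")
  cs <- trial$cs_onset
  dt <- sample_dt(trace$t)
  base_idx <- trace$t >= cs - baseline_window & trace$t < cs
  if (!any(base_idx)) stop("trace does not cover the pre-CS baseline window")
  baseline <- mean(trace$closure[base_idx])
  w_end <- if (!is.na(trial$us_onset)) trial$us_onset else cs + isi
  win <- trace$t > cs + 0.1 & trace$t < w_end
  out <- data.frame(trial_id = trial$trial_id, is_cr = FALSE,
                    cr_onset = NA_real_, cr_amplitude = 0,
                    peak_time = NA_real_, baseline = baseline)
  if (!any(win)) return(out)
  x <- trace$closure[win] - baseline
  tt <- trace$t[win] - cs
  out$cr_amplitude <- max(x)
  out$peak_time <- tt[which.max(x)]
  runs <- true_runs(x > threshold, min_len = max(1L, ceiling(min_sustain / dt)))
  if (length(runs$starts)) {
    out$is_cr <- TRUE
    out$cr_onset <- tt[runs$starts[1]]
  }
  out
}

#' Measure the unconditioned response on an airpuff trial
#'
#' Maximum baseline-subtracted closure, and the first crossing of the
#' amplitude threshold, within 200 ms of US onset.
#'
#' @inheritParams detect_cr
#' @param window UR search window after US onset, seconds.
#' @return one-row data.frame: `trial_id`, `ur_amplitude`, `ur_latency`
#'   (s re US onset; `NA` if the threshold is never crossed).
#' @export
ur_metrics <- function(trace, trial, threshold = 0.1, window = 0.2,
                       baseline_window = 0.2) {
  if (is.na(trial$us_onset))
    stop("trial has no US; UR metrics apply to US-containing trials")
  anchor <- if (!is.na(trial$cs_onset)) trial$cs_onset else trial$us_onset
  base_idx <- trace$t >= anchor - baseline_window & trace$t < anchor
  baseline <- if (any(base_idx)) mean(trace$closure[base_idx]) else 0
  win <- trace$t >= trial$us_onset & trace$t < trial$us_onset + window
  if (!any(win)) stop("trace does not cover the UR window")
  x <- trace$closure[win] - baseline
  cross <- which(x > threshold)
  data.frame(trial_id = trial$trial_id, ur_amplitude = max(x),
             ur_latency = if (length(cross))
               trace$t[win][cross[1]] - trial$us_onset else NA_real_)
}

#' Score every trial of a session
#'
#' Runs [detect_cr()] on all CS-containing trials and [ur_metrics()] on
#' all US trials, merging the results into one table.
#'
#' @param sess a [session()] with normalized traces.
#' @inheritParams detect_cr
#' @return data.frame with one row per trial: CR and UR fields combined.
#' @export
score_session <- function(sess, threshold = 0.1, min_sustain = 0.010) {
  stopifnot(!is.null(sess$traces))
  isi <- sess$config$isi
  rows <- lapply(seq_len(nrow(sess$trials)), function(i) {
    tr <- sess$trials[i, ]
    tt <- sess$traces[sess$traces$trial_id == tr$trial_id, ]
    cr <- if (!is.na(tr$cs_onset))
      detect_cr(tt, tr, isi = isi, threshold = threshold,
                min_sustain = min_sustain)
    else data.frame(trial_id = tr$trial_id, is_cr = NA, cr_onset = NA_real_,
                    cr_amplitude = NA_real_, peak_time = NA_real_,
                    baseline = NA_real_)
    ur <- if (!is.na(tr$us_onset)) ur_metrics(tt, tr)
    else data.frame(trial_id = tr$trial_id, ur_amplitude = NA_real_,
                    ur_latency = NA_real_)
    cbind(cr, kind = tr$kind, ur[, c("ur_amplitude", "ur_latency")])
  })
  do.call(rbind, rows)
}

#' Session-level learning metrics
#'
#' Aggregates per-trial scores into the session summary plotted in
#' learning curves: %CR over CS-containing trials, mean CR amplitude and
#' peak time over CR trials, mean UR amplitude over airpuff trials, and a
#' category-averaged closure trace (mean and pointwise s.e.m., time
#' re-referenced to CS onset) for paired and CS-only trials.
#'
#' @param scores output of [score_session()].
#' @param sess the scored [session()] (for traces and trial kinds).
#' @param session_index training-session index carried into the output.
#' @param denominator `"all_cs"` counts every CS-containing trial (paired
#'   and probe) in the %CR denominator; `"cs_only"` restricts %CR to the
#'   CS-only probe trials.
#' @return list of class `session_metrics` with elements `summary`
#'   (one-row data.frame) and `mean_traces` (per-category data.frames:
#'   `t`, `mean`, `sem`, `n`).
#' @export
session_metrics <- function(scores, sess, session_index = 1L,
                            denominator = c("all_cs", "cs_only")) {
  denominator <- match.arg(denominator)
  cs_scores <- scores[!is.na(scores$is_cr), ]
  if (denominator == "cs_only")
    cs_scores <- cs_scores[cs_scores$kind == "CS_ONLY", ]
  if (nrow(cs_scores) == 0L)
    stop("no CS-containing trials to score")
  crs <- cs_scores[cs_scores$is_cr, ]
  summary <- data.frame(
    session_index = session_index,
    n_cs_trials = nrow(cs_scores),
    n_cr = nrow(crs),
    percent_cr = 100 * nrow(crs) / nrow(cs_scores),
    mean_cr_amplitude = if (nrow(crs)) mean(crs$cr_amplitude) else NA_real_,
    mean_cr_peak_time = if (nrow(crs)) mean(crs$peak_time) else NA_real_,
    mean_ur_amplitude = mean(scores$ur_amplitude, na.rm = TRUE))
  mean_traces <- list()
  if (!is.null(sess$traces)) {
    for (k in intersect(c("CS_US", "CS_ONLY"), unique(sess$trials$kind))) {
      ids <- sess$trials$trial_id[sess$trials$kind == k]
      mats <- lapply(ids, function(id) {
        tr <- sess$traces[sess$traces$trial_id == id, ]
        cs <- sess$trials$cs_onset[sess$trials$trial_id == id]
        list(t = tr$t - cs, x = tr$closure)
      })
      len <- min(vapply(mats, function(m) length(m$x), integer(1)))
      xm <- vapply(mats, function(m) m$x[seq_len(len)], numeric(len))
      mean_traces[[k]] <- data.frame(
        t = mats[[1]]$t[seq_len(len)],
        mean = rowMeans(xm),
        sem = apply(xm, 1, sd) / sqrt(ncol(xm)),
        n = ncol(xm))
    }
  }
  structure(list(summary = summary, mean_traces = mean_traces),
            class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<session_metrics> session %d: %%CR %.1f (%d/%d)",
              s$session_index, s$percent_cr, s$n_cr, s$n_cs_trials))
  if (!is.na(s$mean_cr_amplitude))
    cat(sprintf(", CR amp %.2f, peak %.0f ms", s$mean_cr_amplitude,
                1000 * s$mean_cr_peak_time))
  cat("\n")
  invisible(x)
}

#' CR timing from an averaged CS-only trace
#'
#' Peak time and amplitude of the baseline-subtracted averaged closure in
#' the window from CS onset to 200 ms past the nominal US time - the
#' measurement behind ISI-shift timing comparisons. Ties take the first
#' index; a constant trace therefore reports the window start with
#' amplitude 0.
#'
#' @param mean_trace data.frame with `t` (seconds re CS onset, CS at 0)
#'   and `mean` closure (as produced by [session_metrics()]).
#' @param isi nominal CS-US interval, seconds.
#' @param baseline_window pre-CS baseline extent, seconds.
#' @return list with `peak_time` (s re CS) and `peak_amplitude`.
#' @export
cr_timing <- function(mean_trace, isi = 0.300, baseline_window = 0.2) {
  win <- mean_trace$t > 0 & mean_trace$t <= isi + 0.2
  if (!any(win))
    stop("timing window (0, ", isi + 0.2, "] s lies outside the trace")
  base_idx <- mean_trace$t >= -baseline_window & mean_trace$t < 0
  baseline <- if (any(base_idx)) mean(mean_trace$mean[base_idx]) else 0
  x <- mean_trace$mean[win] - baseline
  list(peak_time = mean_trace$t[win][which.max(x)],
       peak_amplitude = max(x))
}

#' Assemble a learning curve across sessions
#'
#' Orders per-session metrics into the %CR (and CR amplitude) series
#' plotted across training days.
#'
#' @param metrics list of [session_metrics()] results.
#' @return data.frame ordered by `session_index` with `percent_cr`,
#'   `mean_cr_amplitude`, `mean_cr_peak_time`.
#' @export
learning_curve <- function(metrics) {
  if (!length(metrics)) stop("need at least one session")
  tab <- do.call(rbind, lapply(metrics, function(m) m$summary))
  if (anyDuplicated(tab$session_index))
    stop("duplicate session indices: ",
         tab$session_index[duplicated(tab$session_index)][1])
  tab[order(tab$session_index),
      c("session_index", "percent_cr", "mean_cr_amplitude",
        "mean_cr_peak_time", "n_cs_trials", "n_cr")]
}

#' Plot a learning curve
#'
#' @param x output of [learning_curve()].
#' @param ... passed to [plot()].
#' @export
plot_learning_curve <- function(x, ...) {
  plot(x$session_index, x$percent_cr, type = "b", pch = 16,
       xlab = "Session", ylab = "%CR", ylim = c(0, 100), ...)
}
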