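#' Detect spike events in an extracellular voltage trace
#'
#' Amplitude-threshold detection with a robust noise estimate: the
#' threshold is `k` times the MAD-based sigma `median(|x|) / 0.6745`,
#' which is insensitive to the spikes themselves. Candidate events are the
#' local extrema of supra-threshold excursions, excursions closer than the
#' dead time are merged, and a waveform snippet spanning -1 to +12 ms is
#' cut around each event. Negative-going primary peaks are the default
#' extracellular convention; set `polarity = "pos"` to invert.
#'
#' @param trace a `voltage_trace` (list with `samples`, `rate`, `t0`) or a
#'   numeric vector (then `rate` must be given).
#' @param k threshold multiplier on the robust sigma.
#' @param polarity `"neg"` or `"pos"` primary peaks.
#' @param dead_time minimum event separation, seconds.
#' @param rate sampling rate, Hz (taken from `trace` when available).
#' @param snippet_window snippet extent around the event, seconds.
#' @return list of class `spike_events`: `times` (seconds), `index`,
#'   `amplitude` (oriented, positive), `snippets` (events x samples
#'   matrix, oriented so the primary peak is positive), `sigma`,
#'   `threshold`, `rate`, `t0`, `polarity`.
#' @export
detect_spikes <- function(trace, k = 4.5, polarity = c("neg", "pos"),
                          dead_time = 0.001, rate = NULL,
                          snippet_window = c(-0.001, 0.012)) {
  polarity <- match.arg(polarity)
  if (is.list(trace)) {
    x <- trace$samples; rate <- trace$rate; t0 <- trace$t0 %||% 0
  } else {
    x <- trace; t0 <- 0
    if (is.null(rate)) stop("rate must be supplied for a bare vector")
  }
  if (length(x) < 0.1 * rate)
    stop("trace shorter than 0.1 s")
  sigma <- median(abs(x)) / 0.6745
  if (sigma == 0) stop("degenerate signal: flat trace (sigma = 0)")
  thr <- k * sigma
  y <- if (polarity == "neg") -x else x
  above <- y > thr
  if (!any(above)) {
    return(structure(list(times = numeric(0), index = integer(0),
                          amplitude = numeric(0),
                          snippets = matrix(numeric(0), 0, 0),
                          sigma = sigma, threshold = thr, rate = rate,
                          t0 = t0, polarity = polarity),
                     class = "spike_events"))
  }
  idx_above <- which(above)
  dead <- max(1L, round(dead_time * rate))
  # group supra-threshold samples separated by <= dead samples
  brk <- c(TRUE, diff(idx_above) > dead)
  grp <- cumsum(brk)
  peak_idx <- vapply(split(idx_above, grp), function(ii)
    ii[which.max(y[ii])], integer(1))
  peak_idx <- unname(sort(peak_idx))
  pre <- round(-snippet_window[1] * rate)
  post <- round(snippet_window[2] * rate)
  snips <- t(vapply(peak_idx, function(i) {
    lo <- i - pre; hi <- i + post
    s <- rep(NA_real_, pre + post + 1L)
    ok <- max(lo, 1L):min(hi, length(y))
    s[ok - lo + 1L] <- y[ok]
    s
  }, numeric(pre + post + 1L)))
  structure(list(times = t0 + (peak_idx - 1L) / rate, index = peak_idx,
                 amplitude = y[peak_idx], snippets = snips,
                 sigma = sigma, threshold = thr, rate = rate, t0 = t0,
                 polarity = polarity),
            class = "spike_events")
}

# secondary peaks in an oriented snippet after the primary: local maxima
# of supra-floor runs with amplitude within [lo, hi] of the primary
secondary_peaks <- function(snip, rate, primary_at, amp, lo, hi,
                            search_start = 5e-4, search_end = 0.010) {
  i0 <- primary_at + round(search_start * rate)
  i1 <- min(primary_at + round(search_end * rate), length(snip))
  if (i1 <= i0) return(numeric(0))
  seg <- snip[i0:i1]
  seg[is.na(seg)] <- 0
  runs <- true_runs(seg >= lo * amp)
  if (!length(runs$starts)) return(numeric(0))
  peaks <- mapply(function(s, e) {
    j <- s + which.max(seg[s:e]) - 1L
    c(j, seg[j])
  }, runs$starts, runs$ends)
  keep <- peaks[2, ] <= hi * amp
  if (!any(keep)) return(numeric(0))
  (i0 + peaks[1, keep] - 1L - primary_at) / rate  # lags in seconds
}

#' Classify detected events into simple and complex spikes
#'
#' Deterministic rule built on the complex spike's electrophysiological
#' signature - a large initial spike followed by multiple smaller
#' spikelets and a pause in simple spiking. Walking the detected events in
#' time order, an event is labeled a CSpk iff (1) at least `min_spikelets`
#' secondary peaks with amplitude between `spikelet_min` and
#' `spikelet_max` of the primary occur within `spikelet_window` after the
#' primary peak, and (2) no further detected event follows within
#' `pause_window` after that spikelet window. Detected events inside an
#' accepted CSpk's spikelet window are absorbed into it (they are its
#' spikelets, not separate spikes); all remaining events are SSpks. The
#' upper amplitude bound excludes full-size follower spikes, which are
#' ordinary SSpks, from being read as spikelets.
#'
#' @param events a `spike_events` object from [detect_spikes()].
#' @param spikelet_window window after the primary peak searched for
#'   spikelets, seconds.
#' @param spikelet_min,spikelet_max spikelet amplitude bounds as fractions
#'   of the primary amplitude.
#' @param min_spikelets minimum spikelet count for a CSpk.
#' @param pause_window required event-free gap after the spikelet window,
#'   seconds.
#' @return a `spike_train`: list with `sspk_times`, `cspk_times`,
#'   `cspk_spikelets` (spikelet count per CSpk), `unit_id`, `qc`.
#' @export
classify_events <- function(events, spikelet_window = 0.010,
                            spikelet_min = 0.25, spikelet_max = 0.90,
                            min_spikelets = 2L, pause_window = 0.008) {
  stopifnot(inherits(events, "spike_events"))
  n <- length(events$times)
  pre <- round(0.001 * events$rate)  # snippet primary index
  label <- rep(NA_character_, n)
  spikelets <- rep(NA_integer_, n)
  i <- 1L
  while (i <= n) {
    t_i <- events$times[i]
    lags <- secondary_peaks(events$snippets[i, ], events$rate,
                            primary_at = pre + 1L,
                            amp = events$amplitude[i],
                            lo = spikelet_min, hi = spikelet_max,
                            search_end = spikelet_window)
    is_cspk <- FALSE
    if (length(lags) >= min_spikelets) {
      nxt <- which(events$times > t_i + spikelet_window)
      nxt <- if (length(nxt)) nxt[1] else NA_integer_
      gap_ok <- is.na(nxt) ||
        events$times[nxt] > t_i + spikelet_window + pause_window
      if (gap_ok) {
        is_cspk <- TRUE
        label[i] <- "CSpk"
        spikelets[i] <- length(lags)
        absorbed <- which(events$times > t_i &
                            events$times <= t_i + spikelet_window)
        label[absorbed] <- "absorbed"
        i <- if (is.na(nxt)) n + 1L else nxt
      }
    }
    if (!is_cspk) {
      label[i] <- "SSpk"
      i <- i + 1L
    }
  }
  cs <- which(label == "CSpk")
  structure(list(sspk_times = events$times[label == "SSpk"],
                 cspk_times = events$times[cs],
                 cspk_spikelets = spikelets[cs],
                 unit_id = NA_character_,
                 qc = NULL,
                 labels = label),
            class = "spike_train")
}

#' Build a spike train directly from labeled times
#'
#' Wraps ground-truth or externally sorted spike times in the container
#' used by the statistics layer, bypassing detection.
#'
#' @param sspk_times,cspk_times strictly increasing event times, seconds.
#' @param cspk_spikelets spikelet count per CSpk (optional).
#' @param unit_id identifier.
#' @return a `spike_train`.
#' @export
spike_train <- function(sspk_times, cspk_times = numeric(0),
                        cspk_spikelets = rep(NA_integer_,
                                             length(cspk_times)),
                        unit_id = NA_character_) {
  if (is.unsorted(sspk_times, strictly = TRUE) && length(sspk_times) > 1)
    stop("sspk_times must be strictly increasing")
  if (is.unsorted(cspk_times, strictly = TRUE) && length(cspk_times) > 1)
    stop("cspk_times must be strictly increasing")
  structure(list(sspk_times = sspk_times, cspk_times = cspk_times,
                 cspk_spikelets = cspk_spikelets, unit_id = unit_id,
                 qc = NULL),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train> ", length(x$sspk_times), " SSpks, ",
      length(x$cspk_times), " CSpks\n", sep = "")
  invisible(x)
}

# spontaneous epochs: the recording interval minus a margin around every
# CS/US/laser event; returns a two-column matrix of [start, end) epochs
spontaneous_epochs <- function(recording, trials = NULL, margin = 0.5) {
  if (is.null(trials) || nrow(trials) == 0L)
    return(matrix(recording, 1, 2))
  ev <- rbind(
    cbind(trials$cs_onset, trials$cs_onset + trials$cs_duration),
    cbind(trials$us_onset, trials$us_onset + trials$us_duration),
    cbind(trials$laser_onset, trials$laser_onset + trials$laser_duration))
  ev <- ev[stats::complete.cases(ev), , drop = FALSE]
  if (nrow(ev) == 0L) return(matrix(recording, 1, 2))
  ev[, 1] <- ev[, 1] - margin
  ev[, 2] <- ev[, 2] + margin
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  # merge overlaps, then complement within the recording interval
  merged <- ev[1, , drop = FALSE]
  for (i in seq_len(nrow(ev))[-1]) {
    last <- nrow(merged)
    if (ev[i, 1] <= merged[last, 2])
      merged[last, 2] <- max(merged[last, 2], ev[i, 2])
    else merged <- rbind(merged, ev[i, ])
  }
  starts <- c(recording[1], merged[, 2])
  ends <- c(merged[, 1], recording[2])
  keep <- ends > starts
  cbind(pmax(starts[keep], recording[1]), pmin(ends[keep], recording[2]))
}

in_epochs <- function(t, epochs) {
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(epochs)))
    out <- out | (t >= epochs[i, 1] & t < epochs[i, 2])
  out
}

#' Unit-level spike-train statistics
#'
#' The per-unit metric bundle used for group comparisons: spontaneous
#' SSpk and CSpk firing rates, SSpk inter-spike-interval coefficient of
#' variation, the post-CSpk pause, the CSpk doublet fraction, and (when
#' the trial table carries airpuff events) evoked CSpk probability and
#' latency. Spontaneous epochs are all time at least `margin` seconds
#' away from any CS/US/laser event; rates and the CV use only those
#' epochs, and ISIs spanning an epoch boundary are discarded. The pause
#' is the mean over all CSpks of the delay to the next SSpk (CSpks with
#' no subsequent SSpk excluded). The doublet fraction is the fraction of
#' consecutive spontaneous inter-CSpk intervals shorter than
#' `doublet_gap`; it is reported as `NA` with fewer than two spontaneous
#' CSpks.
#'
#' @param train a `spike_train`.
#' @param recording recording interval `c(t0, t1)`, seconds.
#' @param trials optional trial table (defines stimulus epochs and evoked
#'   responses).
#' @param margin exclusion margin around stimulus events, seconds.
#' @param min_spont minimum spontaneous time required for rate estimates,
#'   seconds; shortfalls raise an error naming the deficit.
#' @param doublet_gap doublet interval criterion, seconds.
#' @param evoked_window evoked-response window passed to
#'   [evoked_response()].
#' @return one-row data.frame of class `unit_stats`.
#' @export
unit_stats <- function(train, recording, trials = NULL, margin = 0.5,
                       min_spont = 60, doublet_gap = 0.2,
                       evoked_window = 0.05) {
  stopifnot(inherits(train, "spike_train"))
  ep <- spontaneous_epochs(recording, trials, margin)
  spont_dur <- sum(ep[, 2] - ep[, 1])
  if (spont_dur < min_spont)
    stop(sprintf(paste0("insufficient spontaneous time: %.1f s available,",
                        " %.1f s required (%.1f s short)"),
                 spont_dur, min_spont, min_spont - spont_dur))
  ss <- train$sspk_times
  cs <- train$cspk_times
  ss_sp <- ss[in_epochs(ss, ep)]
  cs_sp <- cs[in_epochs(cs, ep)]
  # ISIs between consecutive SSpks lying in the same epoch
  isi <- numeric(0)
  cs_isi <- numeric(0)
  for (i in seq_len(nrow(ep))) {
    s <- ss_sp[ss_sp >= ep[i, 1] & ss_sp < ep[i, 2]]
    if (length(s) > 1L) isi <- c(isi, diff(s))
    cse <- cs_sp[cs_sp >= ep[i, 1] & cs_sp < ep[i, 2]]
    if (length(cse) > 1L) cs_isi <- c(cs_isi, diff(cse))
  }
  pause <- NA_real_
  if (length(cs)) {
    gaps <- vapply(cs, function(cc) {
      nxt <- ss[ss > cc]
      if (length(nxt)) nxt[1] - cc else NA_real_
    }, numeric(1))
    if (any(!is.na(gaps))) pause <- mean(gaps, na.rm = TRUE)
  }
  ev <- list(prob = NA_real_, latency = NA_real_, n_trials = 0L)
  if (!is.null(trials) && any(!is.na(trials$us_onset)))
    ev <- evoked_response(train, trials, event = "US",
                          window = evoked_window)
  out <- data.frame(
    spont_sspk_rate = length(ss_sp) / spont_dur,
    spont_cspk_rate = length(cs_sp) / spont_dur,
    sspk_cv = if (length(isi) > 1L) sd(isi) / mean(isi) else NA_real_,
    post_cspk_pause = pause,
    doublet_fraction = if (length(cs_isi))
      mean(cs_isi < doublet_gap) else NA_real_,
    evoked_cspk_prob = ev$prob,
    evoked_latency = ev$latency,
    n_trials = ev$n_trials,
    spont_duration = spont_dur)
  class(out) <- c("unit_stats", "data.frame")
  out
}

#' Trial-aligned peri-stimulus histogram
#'
#' Bins SSpk counts and per-trial CSpk occurrence around an alignment
#' event. Bins are half-open `[edge, next_edge)`. The SSpk channel is a
#' rate in Hz (`count / (n_trials * bin_width)`); the CSpk channel is the
#' per-trial probability of at least one CSpk in the bin. The identity
#' `sum(sspk_rate) * bin_width * n_trials == total SSpk count in the
#' window` holds exactly.
#'
#' @param train a `spike_train`.
#' @param trials trial table.
#' @param align `"CS"`, `"US"` or `"LASER"`.
#' @param bin_width bin width, seconds.
#' @param window histogram extent around the alignment event, seconds.
#' @return list of class `psth`: `bin_edges`, `sspk_rate`, `cspk_prob`,
#'   `n_trials`, `align`.
#' @export
psth <- function(train, trials, align = c("CS", "US", "LASER"),
                 bin_width = 0.025, window = c(-0.2, 0.5)) {
  align <- match.arg(align)
  if (bin_width <= 0) stop("bin width must be positive")
  at <- switch(align, CS = trials$cs_onset, US = trials$us_onset,
               LASER = trials$laser_onset)
  at <- at[!is.na(at)]
  if (!length(at)) stop("no trial carries the alignment event ", align)
  nb <- floor((window[2] - window[1]) / bin_width + 1e-9)
  edges <- window[1] + bin_width * (0:nb)
  ss_counts <- integer(nb)
  cs_any <- matrix(FALSE, length(at), nb)
  for (j in seq_along(at)) {
    rs <- train$sspk_times - at[j]
    rs <- rs[rs >= edges[1] & rs < edges[nb + 1L]]
    if (length(rs)) {
      b <- findInterval(rs, edges, rightmost.closed = FALSE)
      ss_counts <- ss_counts + tabulate(b, nbins = nb)
    }
    rc <- train$cspk_times - at[j]
    rc <- rc[rc >= edges[1] & rc < edges[nb + 1L]]
    if (length(rc))
      cs_any[j, unique(findInterval(rc, edges))] <- TRUE
  }
  structure(list(bin_edges = edges,
                 sspk_rate = ss_counts / (length(at) * bin_width),
                 cspk_prob = colMeans(cs_any),
                 n_trials = length(at), align = align),
            class = "psth")
}

#' Plot a peri-stimulus histogram
#'
#' SSpk rate as gray bars (left axis) with per-bin CSpk probability
#' overlaid in red (right axis), aligned on the stimulus.
#'
#' @param x a `psth`.
#' @param ... passed to [barplot()].
#' @export
plot.psth <- function(x, ...) {
  mids <- head(x$bin_edges, -1) + diff(x$bin_edges) / 2
  op <- par(mar = c(4, 4, 2, 4)); on.exit(par(op))
  barplot(x$sspk_rate, names.arg = round(mids, 3), col = "gray",
          border = NA, xlab = sprintf("Time re %s onset (s)", x$align),
          ylab = "SSpk rate (Hz)", ...)
  par(new = TRUE)
  plot(mids, x$cspk_prob, type = "b", col = "red", pch = 16, axes = FALSE,
       xlab = "", ylab = "", ylim = c(0, 1))
  axis(4, col.axis = "red"); mtext("p(CSpk)", 4, line = 2.5, col = "red")
  invisible(x)
}

#' Evoked complex-spike probability and latency
#'
#' Fraction of event trials with at least one CSpk in the response window
#' `(event, event + window]`, and the median over responding trials of
#' the first-CSpk latency. The 50-ms default window covers airpuff-evoked
#' latencies while admitting few spontaneous CSpks at ~1 Hz.
#'
#' @param train a `spike_train`.
#' @param trials trial table.
#' @param event `"US"` or `"LASER"`.
#' @param window response window length, seconds.
#' @return list: `prob`, `latency` (`NA` when no trial responds),
#'   `n_trials`, `n_responded`.
#' @export
evoked_response <- function(train, trials, event = c("US", "LASER"),
                            window = 0.05) {
  event <- match.arg(event)
  if (window <= 0) stop("window must be positive")
  at <- if (event == "US") trials$us_onset else trials$laser_onset
  at <- at[!is.na(at)]
  if (!length(at)) stop("no trial carries the event ", event)
  first <- vapply(at, function(e) {
    inw <- train$cspk_times[train$cspk_times > e &
                              train$cspk_times <= e + window]
    if (length(inw)) inw[1] - e else NA_real_
  }, numeric(1))
  responded <- !is.na(first)
  list(prob = mean(responded),
       latency = if (any(responded)) median(first[responded]) else NA_real_,
       n_trials = length(at), n_responded = sum(responded))
}

#' Unit inclusion criteria
#'
#' Records whether a unit qualifies as an identified Purkinje cell under
#' either criterion: at least one spontaneous CSpk
#' (`SPONTANEOUS_CSPK`, the conventional criterion), or reliable
#' laser-evoked complex spiking (`LASER_EVOKED_CSPK`: evoked probability
#' on laser trials above 0.5), which avoids the selection bias against
#' units whose spontaneous complex spiking is suppressed.
#'
#' @param train a `spike_train`.
#' @param recording recording interval `c(t0, t1)`, seconds.
#' @param trials trial table (laser trials drive the second criterion).
#' @param criteria `"both"`, `"spontaneous"` or `"laser"`; requesting
#'   `"laser"` without laser trials is an error.
#' @param margin spontaneous-epoch margin, seconds.
#' @return data.frame with logical `spontaneous_cspk`,
#'   `laser_evoked_cspk` (`NA` when not evaluable) and the supporting
#'   numbers.
#' @export
qualify_unit <- function(train, recording, trials = NULL,
                         criteria = c("both", "spontaneous", "laser"),
                         margin = 0.5) {
  criteria <- match.arg(criteria)
  has_laser <- !is.null(trials) && any(!is.na(trials$laser_onset))
  if (criteria == "laser" && !has_laser)
    stop("LASER_EVOKED_CSPK requested but the session has no laser trials")
  ep <- spontaneous_epochs(recording, trials, margin)
  n_spont <- sum(in_epochs(train$cspk_times, ep))
  laser_ok <- NA
  laser_prob <- NA_real_
  if (has_laser && criteria != "spontaneous") {
    ev <- evoked_response(train, trials, event = "LASER")
    laser_prob <- ev$prob
    laser_ok <- ev$prob > 0.5
  }
  data.frame(spontaneous_cspk = n_spont >= 1L,
             laser_evoked_cspk = laser_ok,
             n_spontaneous_cspk = n_spont,
             laser_evoked_prob = laser_prob)
}
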