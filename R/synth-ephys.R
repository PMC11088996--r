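#' Purkinje unit generator parameters
#'
#' Statistical description of one synthetic Purkinje cell. Simple spikes
#' (SSpks) form a gamma renewal process (shape 4 gives the CV of 0.5
#' typical of regular Purkinje firing; shape 1 recovers a Poisson train
#' for analytic tests) with an absolute refractory period. Complex spikes
#' (CSpks) occur spontaneously as a Poisson process at ~1 Hz and are
#' evoked with probability `p_evoked` at a short normal-distributed
#' latency after each airpuff/laser event. Each CSpk bears 2-6 spikelets
#' at fixed spacing with geometrically decaying amplitude and silences
#' SSpks for the post-CSpk pause.
#'
#' The `phenotype` argument applies multipliers `(cspk_rate, p_evoked,
#' evoked latency)` emulating the effect of channelrhodopsin expression in
#' climbing fibers: `"CF_CHR2"` uses `(0.5, 0.2, 1.5)` - halved
#' spontaneous CSpk rate, strongly reduced evoked probability, delayed
#' responses - while `"CF_CHR2_LE"` (low expression) uses the subtle
#' `(0.85, 0.85, 1.1)` that should not separate statistically from
#' control at ordinary sample sizes.
#'
#' @param sspk_rate spontaneous SSpk rate, Hz.
#' @param sspk_isi_shape gamma shape of SSpk inter-spike intervals.
#' @param refractory absolute refractory period, seconds.
#' @param cspk_rate spontaneous CSpk rate, Hz.
#' @param spikelet_probs probabilities of 2..6 spikelets per CSpk.
#' @param spikelet_spacing inter-spikelet interval, seconds.
#' @param spikelet_decay geometric amplitude decay factor per spikelet.
#' @param post_cspk_pause SSpk silence after each CSpk, seconds.
#' @param p_evoked probability of a US/laser-evoked CSpk.
#' @param evoked_latency_mean,evoked_latency_sd evoked CSpk latency law,
#'   seconds.
#' @param sspk_amp,cspk_amp waveform peak amplitudes (trace units).
#' @param noise_sd voltage noise s.d. (trace units).
#' @param phenotype `"CONTROL"`, `"CF_CHR2"` or `"CF_CHR2_LE"`.
#' @return an object of class `unit_params`.
#' @export
unit_params <- function(sspk_rate = 80, sspk_isi_shape = 4,
                        refractory = 0.001, cspk_rate = 1.0,
                        spikelet_probs = c(0.15, 0.30, 0.30, 0.15, 0.10),
                        spikelet_spacing = 0.002, spikelet_decay = 0.7,
                        post_cspk_pause = 0.020, p_evoked = 0.9,
                        evoked_latency_mean = 0.020,
                        evoked_latency_sd = 0.003,
                        sspk_amp = 1.0, cspk_amp = 1.5, noise_sd = 0.05,
                        phenotype = c("CONTROL", "CF_CHR2", "CF_CHR2_LE")) {
  phenotype <- match.arg(phenotype)
  mult <- switch(phenotype,
                 CONTROL    = c(1, 1, 1),
                 CF_CHR2    = c(0.5, 0.2, 1.5),
                 CF_CHR2_LE = c(0.85, 0.85, 1.1))
  p <- list(sspk_rate = sspk_rate, sspk_isi_shape = sspk_isi_shape,
            refractory = refractory,
            cspk_rate = cspk_rate * mult[1],
            spikelet_probs = spikelet_probs / sum(spikelet_probs),
            spikelet_spacing = spikelet_spacing,
            spikelet_decay = spikelet_decay,
            post_cspk_pause = post_cspk_pause,
            p_evoked = p_evoked * mult[2],
            evoked_latency_mean = evoked_latency_mean * mult[3],
            evoked_latency_sd = evoked_latency_sd,
            sspk_amp = sspk_amp, cspk_amp = cspk_amp, noise_sd = noise_sd,
            phenotype = phenotype)
  if (any(c(p$sspk_rate, p$cspk_rate) < 0)) stop("rates must be >= 0")
  if (p$p_evoked < 0 || p$p_evoked > 1) stop("p_evoked must lie in [0, 1]")
  if (p$post_cspk_pause < 0) stop("post_cspk_pause must be >= 0")
  if (p$sspk_rate > 0 && 1 / p$sspk_rate <= p$refractory)
    stop("sspk_rate implies a mean ISI shorter than the refractory period")
  class(p) <- "unit_params"
  p
}

#' Generate ground-truth spike times for one unit
#'
#' Simulates the labeled event times of one Purkinje unit over
#' `[0, duration]`: gamma-renewal SSpks, Poisson spontaneous CSpks,
#' Bernoulli evoked CSpks after each US (or laser, for Jaws-style trials
#' where the laser sets the evoked probability to zero), per-CSpk spikelet
#' counts, and the post-CSpk SSpk pause (SSpks falling inside a pause are
#' deleted). This is the generative half of the pipeline's ground truth:
#' [generate_voltage()] renders exactly these times into a trace.
#'
#' @param duration recording length, seconds.
#' @param params a [unit_params()].
#' @param trials optional trial table; US/laser events drive evoked CSpks.
#' @param laser_mode `"none"` or `"jaws"`: under `"jaws"` the inhibitory
#'   laser covering the airpuff suppresses evoked CSpks (`p_evoked` is
#'   forced to zero on trials carrying a laser).
#' @param seed integer seed.
#' @return list with `sspk_times`, `cspk_times`, `cspk_spikelets`
#'   (count per CSpk), and `evoked` (per event trial: time, responded,
#'   latency).
#' @export
generate_spike_train <- function(duration, params = unit_params(),
                                 trials = NULL, laser_mode = "none",
                                 seed = NULL) {
  stopifnot(inherits(params, "unit_params"), duration > 0)
  with_seed(seed, {
    # SSpk renewal process
    sspk <- numeric(0)
    if (params$sspk_rate > 0) {
      n_exp <- ceiling(duration * params$sspk_rate * 1.5) + 50L
      shape <- params$sspk_isi_shape
      isi <- rgamma(n_exp, shape = shape,
                    rate = shape * params$sspk_rate)
      isi <- pmax(isi, params$refractory)
      sspk <- cumsum(isi)
      while (sspk[length(sspk)] < duration) {
        isi <- pmax(rgamma(n_exp, shape = shape,
                           rate = shape * params$sspk_rate),
                    params$refractory)
        sspk <- c(sspk, sspk[length(sspk)] + cumsum(isi))
      }
      sspk <- sspk[sspk < duration]
    }
    # spontaneous CSpks: Poisson
    n_cs <- if (params$cspk_rate > 0)
      stats::rpois(1, params$cspk_rate * duration) else 0L
    cspk <- sort(runif(n_cs, 0, duration))
    # evoked CSpks on US/laser trials
    evoked <- NULL
    if (!is.null(trials)) {
      has_us <- !is.na(trials$us_onset) & trials$us_onset < duration
      ev_t <- trials$us_onset[has_us]
      if (length(ev_t)) {
        suppressed <- if (identical(laser_mode, "jaws"))
          !is.na(trials$laser_onset[has_us]) else rep(FALSE, length(ev_t))
        responded <- runif(length(ev_t)) < params$p_evoked & !suppressed
        lat <- rnorm(length(ev_t), params$evoked_latency_mean,
                     params$evoked_latency_sd)
        lat <- pmax(lat, 0.001)
        cspk <- sort(c(cspk, ev_t[responded] + lat[responded]))
        evoked <- data.frame(event_time = ev_t, responded = responded,
                             latency = ifelse(responded, lat, NA_real_))
      }
    }
    # enforce a short minimal CSpk separation (climbing-fiber
    # refractoriness); small enough to leave the Poisson interval law
    # essentially intact
    if (length(cspk) > 1L)
      cspk <- cspk[c(TRUE, diff(cspk) > 0.005)]
    spikelets <- if (length(cspk))
      sample(2:6, length(cspk), replace = TRUE,
             prob = params$spikelet_probs) else integer(0)
    # post-CSpk pause: delete SSpks within [c, c + pause]; also clear the
    # CSpk waveform span so the initial spike is unambiguous
    if (length(cspk)) {
      for (cc in cspk)
        sspk <- sspk[sspk < cc - 0.001 | sspk > cc + params$post_cspk_pause]
    }
    list(sspk_times = sspk, cspk_times = cspk,
         cspk_spikelets = spikelets, evoked = evoked)
  })
}

#' Sample a heterogeneous population of Purkinje units
#'
#' Draws per-unit generator parameters emulating the between-cell
#' variability seen in recorded Purkinje populations: spontaneous SSpk
#' rates spread over tens of Hz, regularity (gamma ISI shape, hence ISI
#' CV) varying cell to cell, and spontaneous CSpk rates spanning roughly
#' 0.5-1.5 Hz. Without this spread, population comparisons would detect
#' the generator's small deterministic couplings (for example fewer
#' CSpks mean fewer post-CSpk pauses, nudging the measured SSpk rate) -
#' effects that in real recordings are buried under cell-to-cell
#' differences.
#'
#' @param n number of units.
#' @param phenotype passed to [unit_params()] for every unit.
#' @param sspk_rate_mean,sspk_rate_sd normal law of per-unit SSpk rates,
#'   truncated below at 30 Hz.
#' @param sspk_shape_range uniform range of the per-unit gamma ISI shape.
#' @param cspk_rate_mean,cspk_rate_sd normal law of per-unit spontaneous
#'   CSpk rates, truncated below at 0.3 Hz.
#' @param seed integer seed.
#' @param ... further arguments passed to [unit_params()].
#' @return list of `n` [unit_params()] objects.
#' @export
sample_unit_params <- function(n, phenotype = "CONTROL",
                               sspk_rate_mean = 80, sspk_rate_sd = 10,
                               sspk_shape_range = c(3, 6),
                               cspk_rate_mean = 1.0, cspk_rate_sd = 0.3,
                               seed = NULL, ...) {
  with_seed(seed, {
    lapply(seq_len(n), function(i)
      unit_params(sspk_rate = max(rnorm(1, sspk_rate_mean, sspk_rate_sd),
                                  30),
                  sspk_isi_shape = runif(1, sspk_shape_range[1],
                                         sspk_shape_range[2]),
                  cspk_rate = max(rnorm(1, cspk_rate_mean, cspk_rate_sd),
                                  0.3),
                  phenotype = phenotype, ...))
  })
}

# biphasic action-potential kernel sampled at `rate`; negative-going
# primary trough of unit amplitude at lag 0
spike_kernel <- function(rate, width = 0.0012) {
  lag <- seq(-0.0003, width, by = 1 / rate)
  k <- -exp(-((lag) / 0.00012)^2) + 0.30 * exp(-((lag - 0.00055) / 0.00025)^2)
  k / max(abs(k))
}

#' Render a ground-truth spike train into an extracellular voltage trace
#'
#' Places a fixed biphasic kernel (negative-going primary trough) at every
#' SSpk time and a larger initial spike followed by the unit's spikelets -
#' geometrically decaying copies at the configured spacing - at every CSpk
#' time, then adds white Gaussian noise. The trace plus the generating
#' train constitute a fully labeled benchmark for [detect_spikes()] and
#' [classify_events()].
#'
#' @param train output of [generate_spike_train()].
#' @param duration trace length, seconds.
#' @param params the [unit_params()] used to build `train`.
#' @param rate sampling rate, Hz.
#' @param seed integer seed (noise only).
#' @return a `voltage_trace`: list with `samples`, `rate`, `t0 = 0`.
#' @export
generate_voltage <- function(train, duration, params = unit_params(),
                             rate = 25000, seed = NULL) {
  n <- round(duration * rate)
  with_seed(seed, {
    x <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd)
         else numeric(n)
    kern <- spike_kernel(rate)
    k0 <- which.min(kern)  # index of the trough within the kernel
    nk <- length(kern)
    # flatten all insertions (SSpks, CSpk primaries, spikelets) into one
    # time/amplitude list and add kernels in place
    times <- train$sspk_times
    amps <- rep(params$sspk_amp, length(times))
    for (j in seq_along(train$cspk_times)) {
      tc <- train$cspk_times[j]
      ks <- seq_len(train$cspk_spikelets[j])
      times <- c(times, tc, tc + ks * params$spikelet_spacing)
      amps <- c(amps, params$cspk_amp,
                params$cspk_amp * params$spikelet_decay^ks)
    }
    for (j in seq_along(times)) {
      i0 <- round(times[j] * rate) + 1L - (k0 - 1L)
      idx <- i0:(i0 + nk - 1L)
      ok <- which(idx >= 1L & idx <= n)
      x[idx[ok]] <- x[idx[ok]] + amps[j] * kern[ok]
    }
    structure(list(samples = x, rate = rate, t0 = 0),
              class = "voltage_trace")
  })
}
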