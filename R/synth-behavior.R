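#' Behavioral generator parameters
#'
#' Parameters of the synthetic eyelid-kinematics generator. Unconditioned
#' responses (URs) are full reflexive closures shortly after airpuff onset;
#' conditioned responses (CRs) are smooth raised-cosine closures whose
#' probability and amplitude grow saturating-exponentially across training
#' sessions and whose peak is timed to the expected US arrival, the
#' signature of well-timed conditioning.
#'
#' @param ur_amplitude UR peak closure (normalized 0-1).
#' @param ur_latency airpuff-to-blink latency, seconds.
#' @param ur_decay exponential decay time of the UR after its plateau,
#'   seconds.
#' @param p_max,p_tau asymptote and e-folding constant (in sessions) of the
#'   CR probability schedule `p(s) = p_max * (1 - exp(-s / p_tau))`.
#' @param amp_max,amp_tau same schedule for CR amplitude.
#' @param cr_prob,cr_amplitude optional constants overriding the schedules
#'   (used for single-session simulations at a fixed CR rate).
#' @param cr_peak_time CR peak relative to CS onset, seconds; defaults to
#'   the 300-ms ISI so the CR crests at expected US arrival.
#' @param cr_peak_jitter_sd trial-to-trial s.d. of the CR peak time,
#'   seconds.
#' @param cr_width raised-cosine half-width of the CR bump, seconds.
#' @param baseline_noise_sd additive Gaussian noise on normalized closure.
#' @param extinction_mode if `TRUE`, the probability schedule decays as
#'   `p_max * exp(-s / p_tau)` (CS-only extinction sessions).
#' @param a_open eyelid distance (ellipse minor axis, px) of the fully open
#'   eye; used to express traces in pixel units.
#' @param trace_pre,trace_post trace extent around CS onset, seconds.
#' @return an object of class `behavior_params`.
#' @export
behavior_params <- function(ur_amplitude = 1.0, ur_latency = 0.020,
                            ur_decay = 0.100,
                            p_max = 0.8, p_tau = 2,
                            amp_max = 0.8, amp_tau = 2,
                            cr_prob = NULL, cr_amplitude = NULL,
                            cr_peak_time = 0.300,
                            cr_peak_jitter_sd = 0.010,
                            cr_width = 0.250,
                            baseline_noise_sd = 0.02,
                            extinction_mode = FALSE,
                            a_open = 60, trace_pre = 0.5,
                            trace_post = 1.0) {
  p <- as.list(environment())
  for (f in c("ur_amplitude", "p_max", "amp_max"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (!is.null(cr_prob) && (cr_prob < 0 || cr_prob > 1))
    stop("cr_prob must lie in [0, 1]")
  if (!is.null(cr_amplitude) && (cr_amplitude < 0 || cr_amplitude > 1))
    stop("cr_amplitude must lie in [0, 1]")
  class(p) <- "behavior_params"
  p
}

cr_schedule <- function(params, session_index) {
  if (!is.null(params$cr_prob)) p <- params$cr_prob
  else if (params$extinction_mode)
    p <- params$p_max * exp(-session_index / params$p_tau)
  else p <- params$p_max * (1 - exp(-session_index / params$p_tau))
  if (!is.null(params$cr_amplitude)) a <- params$cr_amplitude
  else if (params$extinction_mode)
    a <- params$amp_max * exp(-session_index / params$amp_tau)
  else a <- params$amp_max * (1 - exp(-session_index / params$amp_tau))
  list(p = p, amplitude = a)
}

# raised-cosine bump of unit peak centered at 0 with half-width w
raised_cosine <- function(t, w) {
  ifelse(abs(t) < w, 0.5 * (1 + cos(pi * t / w)), 0)
}

# UR kinematic: raised-cosine rise over `rise` s, plateau through the
# airpuff, then exponential decay
ur_pulse <- function(t, onset, amplitude, plateau = 0.05, decay = 0.1,
                     rise = 0.015) {
  u <- numeric(length(t))
  ph <- t - onset
  rising <- ph >= 0 & ph < rise
  u[rising] <- 0.5 * (1 - cos(pi * ph[rising] / rise))
  hold <- ph >= rise & ph < rise + plateau
  u[hold] <- 1
  falling <- ph >= rise + plateau
  u[falling] <- exp(-(ph[falling] - rise - plateau) / decay)
  amplitude * u
}

#' Generate synthetic eyelid traces for a session
#'
#' Produces one normalized eyelid-closure trace per trial plus the ground
#' truth used to make it. Every airpuff trial carries a UR; every
#' CS-containing trial independently carries a CR with the scheduled
#' probability, peaking near `cr_peak_time` after CS onset. Traces carry
#' additive Gaussian noise and are clipped to the normalized range
#' `[0, 1]`; the pixel-distance channel is the affine inverse of closure
#' at the configured open-eye axis length.
#'
#' @param sess a [session()] with a trial table.
#' @param params a [behavior_params()].
#' @param session_index 1-based training-session index driving the CR
#'   schedules.
#' @param seed integer seed.
#' @return `sess` with `traces` (long-format eyelid table) and
#'   `ground_truth$trials` filled in.
#' @export
#' @examples
#' s <- generate_session(session_config(n_trials = 5, n_cs_only = 1), seed = 1)
#' s <- generate_behavior(s, behavior_params(cr_prob = 1), seed = 2)
#' head(s$traces)
generate_behavior <- function(sess, params = behavior_params(),
                              session_index = 1L, seed = NULL) {
  stopifnot(inherits(sess, "session"), inherits(params, "behavior_params"))
  sched <- cr_schedule(params, session_index)
  rate <- sess$config$video_rate
  with_seed(seed, {
    out <- vector("list", nrow(sess$trials))
    gt <- vector("list", nrow(sess$trials))
    for (i in seq_len(nrow(sess$trials))) {
      tr <- sess$trials[i, ]
      anchor <- if (!is.na(tr$cs_onset)) tr$cs_onset else tr$us_onset
      nf <- round((params$trace_pre + params$trace_post) * rate)
      t <- anchor - params$trace_pre + (seq_len(nf) - 1L) / rate
      closure <- rnorm(nf, 0, params$baseline_noise_sd)
      has_us <- !is.na(tr$us_onset) && sess$config$laser_mode != "us"
      if (has_us)
        closure <- closure + ur_pulse(t, tr$us_onset + params$ur_latency,
                                      params$ur_amplitude,
                                      plateau = tr$us_duration,
                                      decay = params$ur_decay)
      is_cr <- FALSE; cr_amp <- 0; cr_peak <- NA_real_
      if (!is.na(tr$cs_onset) && runif(1) < sched$p) {
        is_cr <- TRUE
        cr_amp <- sched$amplitude
        cr_peak <- params$cr_peak_time + rnorm(1, 0, params$cr_peak_jitter_sd)
        closure <- closure +
          cr_amp * raised_cosine(t - tr$cs_onset - cr_peak, params$cr_width)
      }
      closure <- clamp(closure, 0, 1)
      out[[i]] <- data.frame(trial_id = tr$trial_id,
                             frame = seq_len(nf) - 1L, t = t,
                             distance_px = params$a_open * (1 - closure),
                             closure = closure)
      gt[[i]] <- data.frame(trial_id = tr$trial_id, is_cr = is_cr,
                            cr_amplitude = cr_amp, cr_peak_time = cr_peak,
                            ur_amplitude = if (has_us) params$ur_amplitude
                                           else 0,
                            cr_prob = sched$p)
    }
    sess$traces <- do.call(rbind, out)
    sess$ground_truth <- c(sess$ground_truth %||% list(),
                           list(trials = do.call(rbind, gt)))
    sess$provenance$behavior_seed <- seed
    sess$provenance$session_index <- session_index
    sess
  })
}

#' Render an eyelid trace into a synthetic eye video
#'
#' The inverse of the videometry stage: each frame shows a bright filled
#' ellipse (the open eye) on a dark background, with fixed major axis and a
#' minor axis of `round(a_open * (1 - closure))` pixels, plus additive
#' Gaussian pixel noise clipped to the 8-bit range. Full closure yields a
#' frame with no foreground ellipse.
#'
#' @param trace one trial's eyelid table (`t`, `closure`).
#' @param shape frame height and width, pixels.
#' @param a_open open-eye minor axis, pixels.
#' @param major_px fixed ellipse major axis, pixels.
#' @param fg,bg foreground and background gray levels (0-255).
#' @param noise_sd pixel noise s.d. (gray levels).
#' @param rate frame rate, Hz.
#' @param seed integer seed.
#' @return a `video_stack`: list with `frames` (H x W x N array, 0-255),
#'   `rate`, `trial_id`, `t0`.
#' @export
render_video <- function(trace, shape = c(172L, 160L), a_open = 60,
                         major_px = 100, fg = 200, bg = 20, noise_sd = 5,
                         rate = 900, seed = NULL) {
  if (any(trace$closure < 0 | trace$closure > 1))
    stop("closure values must lie in [0, 1]")
  H <- shape[1]; W <- shape[2]
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  n <- nrow(trace)
  minors <- round(a_open * (1 - trace$closure))
  # the minor axis takes few distinct integer values: cache one clean
  # frame per value and add fresh noise per output frame
  clean <- lapply(sort(unique(minors)), function(minor) {
    img <- matrix(bg, H, W)
    if (minor >= 1)
      img[((xs - cx) / (major_px / 2))^2 +
            ((ys - cy) / (minor / 2))^2 <= 1] <- fg
    img
  })
  names(clean) <- as.character(sort(unique(minors)))
  with_seed(seed, {
    frames <- array(0L, c(H, W, n))
    for (i in seq_len(n)) {
      img <- clean[[as.character(minors[i])]]
      if (noise_sd > 0) img <- img + rnorm(H * W, 0, noise_sd)
      frames[, , i] <- as.integer(pmin.int(pmax.int(img, 0), 255) + 0.5)
    }
    structure(list(frames = frames, rate = rate,
                   trial_id = trace$trial_id[1], t0 = trace$t[1]),
              class = "video_stack")
  })
}

#' Render all trials of a session to video
#'
#' Applies [render_video()] to every per-trial trace in a session,
#' attaching the resulting stacks as `sess$video`.
#'
#' @inheritParams render_video
#' @param sess a [session()] with traces.
#' @return the session with `video` populated.
#' @export
render_session_video <- function(sess, a_open = 60, noise_sd = 5,
                                 seed = NULL) {
  stopifnot(!is.null(sess$traces))
  ids <- unique(sess$traces$trial_id)
  with_seed(seed, {
    sess$video <- lapply(ids, function(id)
      render_video(sess$traces[sess$traces$trial_id == id, ],
                   shape = sess$config$video_shape, a_open = a_open,
                   noise_sd = noise_sd, rate = sess$config$video_rate))
    names(sess$video) <- paste0("trial_", ids)
    sess
  })
}
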