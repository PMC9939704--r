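#' Configuration for the synthetic free-viewing simulator
#'
#' The defaults emulate free visual exploration of still scenes at 500 Hz:
#' roughly three to four fixations per second lasting on average about
#' 300 ms, separated by ballistic saccades of 1--15 degrees whose peak
#' velocity follows a main-sequence relation, with occasional blinks and
#' additive sensor noise.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Trace duration, seconds.
#' @param seed Integer seed; a fixed seed gives identical output.
#' @param modality `"video"` (pixels + pupil, blinks as pupil loss),
#'   `"eog"` (arbitrary units, slow baseline drift, blinks as large slow
#'   vertical deflections) or `"coil"` (volts, no pupil, no blinks).
#' @param fixation_rate Nominal fixation rate, events/s; the realized rate
#'   is slightly lower because saccades also take time. `0` produces a
#'   single drifting fixation with no gaze shifts at all.
#' @param fixation_duration_mean Mean fixation duration, seconds (gamma
#'   distributed with shape `fixation_duration_shape`).
#' @param fixation_duration_shape Gamma shape of fixation durations
#'   (shape 4 gives the right-skewed spread seen in free viewing).
#' @param saccade_amplitude_range Uniform amplitude range, degrees.
#' @param main_sequence_slope Peak velocity per degree of amplitude
#'   (deg/s per deg).
#' @param main_sequence_floor Minimum peak velocity (deg/s): peak velocity
#'   is `max(floor, slope * amplitude)`. Saccade duration follows from the
#'   sine-velocity profile, `D = pi * A / (2 * v_peak)`, so amplitude,
#'   duration and peak velocity are mutually consistent.
#' @param overshoot_prob Fraction of saccades followed by a small
#'   corrective reverse movement within the overshoot gap.
#' @param overshoot_amplitude_range Amplitude range of overshoots, degrees.
#' @param blink_rate Blink rate, events/minute (ignored for `"coil"`).
#' @param blink_duration_range Blink duration range, seconds.
#' @param drift_sd Fixational drift: per-sample random-walk step SD,
#'   degrees (0.002 deg at 500 Hz is about 1 deg/s instantaneous drift).
#' @param noise_sd Additive Gaussian sensor noise SD per axis, degrees
#'   (0.01 deg is typical video eye-tracker noise; EOG gets
#'   `eog_noise_mult` times this).
#' @param pix_per_degree Video calibration, px/deg.
#' @param screen_center Screen center, pixels (video).
#' @param eog_gain Native units per degree for EOG/coil traces.
#' @param eog_noise_mult Noise multiplier for the EOG floor.
#' @param eog_blink_amplitude EOG blink deflection, in degree-equivalents
#'   (large and slow, well off the saccade main sequence).
#' @param pupil_baseline,pupil_noise_sd Pupil size baseline and noise
#'   (native units).
#' @return A `sim_config` list.
#' @export
sim_config <- function(fs = 500, duration = 3, seed = 1,
                       modality = c("video", "eog", "coil"),
                       fixation_rate = 3.5,
                       fixation_duration_mean = 0.30,
                       fixation_duration_shape = 4,
                       saccade_amplitude_range = c(1, 15),
                       main_sequence_slope = 30,
                       main_sequence_floor = 200,
                       overshoot_prob = 0.15,
                       overshoot_amplitude_range = c(0.3, 1.0),
                       blink_rate = 10,
                       blink_duration_range = c(0.25, 0.40),
                       drift_sd = 0.002,
                       noise_sd = 0.01,
                       pix_per_degree = 39.38,
                       screen_center = c(960, 540),
                       eog_gain = 35,
                       eog_noise_mult = 2,
                       eog_blink_amplitude = 45,
                       pupil_baseline = 1000,
                       pupil_noise_sd = 2) {
  modality <- match.arg(modality)
  stopifnot(fs > 0, duration > 0, fixation_rate >= 0,
            fixation_duration_mean > 0, fixation_duration_shape > 0,
            all(saccade_amplitude_range > 0), main_sequence_slope > 0,
            main_sequence_floor > 0, blink_rate >= 0,
            drift_sd >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# sigmoidal displacement profile with sine-shaped velocity: h(0)=0, h(1)=1,
# peak velocity pi/(2D) per unit amplitude at mid-movement, non-vanishing
# acceleration at launch (ballistic onset).
sacc_profile <- function(tau) (1 - cos(pi * pmin(pmax(tau, 0), 1))) / 2

sacc_duration <- function(amp, cfg) {
  vpk <- pmax(cfg$main_sequence_floor, cfg$main_sequence_slope * amp)
  list(vpk = vpk, D = pi * amp / (2 * vpk))
}

#' Simulate one free-viewing gaze trace with ground truth
#'
#' Generates alternating fixations (2-D random-walk drift) and saccades
#' (sine-velocity sigmoidal displacement whose peak velocity follows the
#' configured main-sequence relation), optionally followed by small reverse
#' overshoots, plus blinks (video: pupil ramps into a missing gap and the
#' gaze samples during occlusion are missing; EOG: a large slow vertical
#' deflection), additive Gaussian noise, and per-modality unit conversion.
#' Ground truth records every event's exact (continuous-time) onset and
#' offset, amplitude, duration and generating peak velocity; a saccade and
#' its overshoot are one ground-truth saccade flagged `overshoot`.
#'
#' @param cfg A [sim_config()].
#' @return List with `trace` (a [gaze_trace()]) and `truth` (an
#'   [event_list()] partitioning the trace extent).
#' @export
simulate_trace <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration * fs)) + 1L
  tt <- (0:(n - 1L)) / fs
  t_end <- tt[n]

  xdeg <- numeric(n); ydeg <- numeric(n)
  occluded <- logical(n)
  pupil_mult <- rep(1, n)        # 1 = open, ramps in (0,1), NA = occluded

  ev <- list()
  add_ev <- function(onset, offset, label, amplitude = NA_real_,
                     peak_velocity = NA_real_, overshoot = FALSE) {
    ev[[length(ev) + 1L]] <<- data.frame(
      onset = onset, offset = offset, label = label,
      amplitude = amplitude, duration = offset - onset,
      peak_velocity = peak_velocity, overshoot = overshoot,
      truncated = FALSE, stringsAsFactors = FALSE)
  }
  samples_in <- function(a, b) which(tt >= a - 1e-12 & tt < b - 1e-12)

  bounds <- c(12, 9)             # keep gaze within a screen-like box, deg
  mean_cycle <- cfg$fixation_duration_mean + 0.045
  p_blink <- if (cfg$modality == "coil") 0 else
    min(0.9, cfg$blink_rate / 60 * mean_cycle)

  tcur <- 0; pos <- c(0, 0)
  repeat {
    # --- fixation ---
    fdur <- if (cfg$fixation_rate <= 0) Inf else   # no gaze shifts at all
      max(0.04, stats::rgamma(1L, shape = cfg$fixation_duration_shape,
                 rate = cfg$fixation_duration_shape /
                   cfg$fixation_duration_mean))
    f_end <- min(tcur + fdur, t_end)
    ii <- samples_in(tcur, f_end)
    if (length(ii)) {
      steps_x <- stats::rnorm(length(ii), 0, cfg$drift_sd)
      steps_y <- stats::rnorm(length(ii), 0, cfg$drift_sd)
      xdeg[ii] <- pos[1L] + cumsum(steps_x)
      ydeg[ii] <- pos[2L] + cumsum(steps_y)
      pos <- c(xdeg[ii[length(ii)]], ydeg[ii[length(ii)]])
    }
    add_ev(tcur, f_end, "fixation")
    tcur <- f_end
    if (tcur >= t_end) break

    # --- next movement: blink or saccade ---
    if (stats::runif(1L) < p_blink) {
      bdur <- stats::runif(1L, cfg$blink_duration_range[1L],
                           cfg$blink_duration_range[2L])
      if (tcur + bdur + 0.05 >= t_end) { extend_last <- TRUE; break }
      if (cfg$modality == "video") {
        ramp <- 0.02
        ii_all <- samples_in(tcur, tcur + bdur)
        xdeg[ii_all] <- pos[1L]; ydeg[ii_all] <- pos[2L]
        ii_core <- samples_in(tcur + ramp, tcur + bdur - ramp)
        occluded[ii_core] <- TRUE
        ii_dn <- samples_in(tcur, tcur + ramp)
        if (length(ii_dn))
          pupil_mult[ii_dn] <- 1 - 0.9 * (tt[ii_dn] - tcur) / ramp
        ii_up <- samples_in(tcur + bdur - ramp, tcur + bdur)
        if (length(ii_up))
          pupil_mult[ii_up] <- 0.1 + 0.9 * (tt[ii_up] -
            (tcur + bdur - ramp)) / ramp
      } else {                    # eog: large slow vertical deflection
        ii_all <- samples_in(tcur, tcur + bdur)
        tau <- (tt[ii_all] - tcur) / bdur
        xdeg[ii_all] <- pos[1L]
        ydeg[ii_all] <- pos[2L] +
          cfg$eog_blink_amplitude * (1 - cos(2 * pi * tau)) / 2
      }
      add_ev(tcur, tcur + bdur, "blink")
      tcur <- tcur + bdur
    } else {
      amp <- stats::runif(1L, cfg$saccade_amplitude_range[1L],
                          cfg$saccade_amplitude_range[2L])
      sd1 <- sacc_duration(amp, cfg)
      # direction keeping the target on screen
      disp <- NULL
      for (try in 1:20) {
        ang <- stats::runif(1L, 0, 2 * pi)
        cand <- amp * c(cos(ang), sin(ang))
        tgt <- pos + cand
        if (abs(tgt[1L]) <= bounds[1L] && abs(tgt[2L]) <= bounds[2L]) {
          disp <- cand; break
        }
      }
      if (is.null(disp)) {        # aim back toward center
        ang <- atan2(-pos[2L], -pos[1L]) + stats::rnorm(1L, 0, 0.3)
        disp <- amp * c(cos(ang), sin(ang))
      }
      has_os <- stats::runif(1L) < cfg$overshoot_prob
      gap <- 0; amp2 <- 0; disp2 <- c(0, 0); D2 <- 0; vpk2 <- 0
      if (has_os) {
        gap <- stats::runif(1L, 0.006, 0.012)
        amp2 <- stats::runif(1L, cfg$overshoot_amplitude_range[1L],
                             cfg$overshoot_amplitude_range[2L])
        sd2 <- sacc_duration(amp2, cfg)
        D2 <- sd2$D; vpk2 <- sd2$vpk
        jit <- stats::runif(1L, -pi / 6, pi / 6)
        back <- atan2(-disp[2L], -disp[1L]) + jit
        disp2 <- amp2 * c(cos(back), sin(back))
      }
      span <- sd1$D + gap + D2
      if (tcur + span + 0.05 >= t_end) { extend_last <- TRUE; break }
      ii1 <- samples_in(tcur, tcur + sd1$D)
      if (length(ii1)) {
        h <- sacc_profile((tt[ii1] - tcur) / sd1$D)
        xdeg[ii1] <- pos[1L] + disp[1L] * h
        ydeg[ii1] <- pos[2L] + disp[2L] * h
      }
      p1 <- pos + disp
      if (has_os) {
        ii_g <- samples_in(tcur + sd1$D, tcur + sd1$D + gap)
        xdeg[ii_g] <- p1[1L]; ydeg[ii_g] <- p1[2L]
        ii2 <- samples_in(tcur + sd1$D + gap, tcur + span)
        if (length(ii2)) {
          h2 <- sacc_profile((tt[ii2] - (tcur + sd1$D + gap)) / D2)
          xdeg[ii2] <- p1[1L] + disp2[1L] * h2
          ydeg[ii2] <- p1[2L] + disp2[2L] * h2
        }
      }
      final <- p1 + disp2
      add_ev(tcur, tcur + span, "saccade",
             amplitude = sqrt(sum((final - pos)^2)),
             peak_velocity = max(sd1$vpk, vpk2), overshoot = has_os)
      pos <- final
      tcur <- tcur + span
    }
  }
  truth <- do.call(rbind, ev)
  # the loop always ends inside/after a fixation or by bailing out before a
  # movement that would not fit: stretch the last (fixation) row to t_end
  last <- nrow(truth)
  if (truth$offset[last] < t_end) {
    if (truth$label[last] == "fixation") {
      ii <- samples_in(truth$offset[last], t_end + 1e-9)
      if (length(ii)) {
        steps_x <- stats::rnorm(length(ii), 0, cfg$drift_sd)
        steps_y <- stats::rnorm(length(ii), 0, cfg$drift_sd)
        xdeg[ii] <- pos[1L] + cumsum(steps_x)
        ydeg[ii] <- pos[2L] + cumsum(steps_y)
      }
      truth$offset[last] <- t_end
      truth$duration[last] <- t_end - truth$onset[last]
    }
  }
  # last sample (tt == t_end) was excluded by the half-open windows
  xdeg[n] <- xdeg[n - 1L]; ydeg[n] <- ydeg[n - 1L]
  truth$truncated <- truth$onset <= 1e-9 | truth$offset >= t_end - 1e-9

  # --- sensor noise + unit conversion ---
  nx <- stats::rnorm(n, 0, cfg$noise_sd)
  ny <- stats::rnorm(n, 0, cfg$noise_sd)
  if (cfg$modality == "video") {
    x <- cfg$screen_center[1L] + (xdeg + nx) * cfg$pix_per_degree
    y <- cfg$screen_center[2L] + (ydeg + ny) * cfg$pix_per_degree
    x[occluded] <- NA_real_; y[occluded] <- NA_real_
    pupil <- (cfg$pupil_baseline + 10 * sin(2 * pi * tt / 20) +
                stats::rnorm(n, 0, cfg$pupil_noise_sd)) * pupil_mult
    pupil[occluded] <- NA_real_
    trace <- gaze_trace(tt, x, y, pupil = pupil, units = "pixels",
                        fs_nominal = fs,
                        pix_per_degree = cfg$pix_per_degree,
                        modality = "video")
  } else {
    g <- cfg$eog_gain
    mult <- if (cfg$modality == "eog") cfg$eog_noise_mult else 1
    x <- g * (xdeg + nx * mult)
    y <- g * (ydeg + ny * mult)
    if (cfg$modality == "eog") {   # slow baseline drift (electrode/skin)
      x <- x + cumsum(stats::rnorm(n, 0, g * 2e-4))
      y <- y + cumsum(stats::rnorm(n, 0, g * 2e-4))
    }
    trace <- gaze_trace(tt, x, y, pupil = NULL,
                        units = if (cfg$modality == "coil") "volts"
                                else "arbitrary",
                        fs_nominal = fs, modality = cfg$modality)
  }
  truth <- event_list(truth, extent = c(0, t_end))
  list(trace = trace, truth = truth)
}

#' Simulate a session of independent trials
#'
#' Each trial gets its own seed drawn deterministically from the session
#' seed, so the session is reproducible as a whole while trials are
#' independent.
#'
#' @param cfg A [sim_config()]; `cfg$seed` seeds the session.
#' @param n_trials Number of trials.
#' @return List of `n_trials` elements, each a `list(trace, truth)`.
#' @export
simulate_session <- function(cfg, n_trials) {
  stopifnot(inherits(cfg, "sim_config"), n_trials >= 1)
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  lapply(seeds, function(s) {
    cfg$seed <- s
    simulate_trace(cfg)
  })
}
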