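#' Construct a labeled event list
#'
#' An ordered, pairwise-disjoint set of labeled intervals (saccade /
#' fixation / blink) tiling — or contained in — a trace extent. The final
#' output of [detect()] covers the extent exactly.
#'
#' @param events Data frame with columns `onset`, `offset`, `label`,
#'   `amplitude`, `duration`, `peak_velocity`, `overshoot`, `truncated`.
#' @param extent Numeric length-2: the trace's first and last timestamp.
#' @return An object of class `safide_events` (a data frame with an
#'   `extent` attribute).
#' @export
event_list <- function(events, extent) {
  need <- c("onset", "offset", "label", "amplitude", "duration",
            "peak_velocity", "overshoot", "truncated")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event data frame lacks column(s): ", paste(miss, collapse = ", "))
  events <- events[need]
  if (nrow(events)) {
    events <- events[order(events$onset), , drop = FALSE]
    rownames(events) <- NULL
    if (any(events$offset <= events$onset))
      stop("every event must have onset < offset")
    if (any(bad <- events$overshoot & events$label != "saccade"))
      stop("overshoot flag on a non-saccade event (row ",
           which(bad)[1L], ")")
    ov <- which(events$onset[-1L] < events$offset[-nrow(events)] - 1e-9)
    if (length(ov))
      stop("events ", ov[1L], " and ", ov[1L] + 1L, " overlap")
  }
  structure(events, extent = as.numeric(extent),
            class = c("safide_events", "data.frame"))
}

empty_events <- function() {
  data.frame(onset = numeric(0), offset = numeric(0),
             label = character(0), amplitude = numeric(0),
             duration = numeric(0), peak_velocity = numeric(0),
             overshoot = logical(0), truncated = logical(0),
             stringsAsFactors = FALSE)
}

#' @export
print.safide_events <- function(x, ...) {
  ext <- attr(x, "extent")
  tab <- table(factor(x$label, levels = c("saccade", "fixation", "blink")))
  cat("<safide_events> ", nrow(x), " events on [",
      sprintf("%.3f", ext[1L]), ", ", sprintf("%.3f", ext[2L]), "] s: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L),
                                digits = 4)
  if (nrow(x) > 10L) cat("  ... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Discard candidate saccades that are too small or too brief
#'
#' Removes candidates with amplitude below `min_amplitude` or duration
#' below `min_duration`; candidates exactly at either bound are kept. The
#' default bounds (0.1 degrees, 4 ms) assume amplitudes in visual degrees;
#' for uncalibrated traces pass a native-unit amplitude bound or `NA` to
#' filter on duration alone.
#'
#' @param candidates Candidate data frame ([group_candidates()]).
#' @param min_amplitude Minimum amplitude (same units as the candidates'
#'   `amplitude`; `NA` disables the amplitude condition).
#' @param min_duration Minimum duration in seconds.
#' @return The surviving candidates.
#' @export
filter_short_saccades <- function(candidates, min_amplitude = 0.1,
                                  min_duration = 0.004) {
  if (!nrow(candidates)) return(candidates)
  keep <- candidates$duration >= min_duration
  if (!is.na(min_amplitude))
    keep <- keep & candidates$amplitude >= min_amplitude
  candidates[keep, , drop = FALSE]
}

#' Merge overshoots into their parent saccades
#'
#' An overshoot is a small corrective movement right after a saccade; the
#' eye is still travelling to its final position, so both belong to one
#' saccade. Scanning left to right, consecutive saccades are merged when
#' the gap between them is strictly below `max_gap` AND the second one's
#' amplitude is at most `max_second_amplitude` (inclusive). The merged
#' saccade spans first onset to second offset, is flagged `overshoot`, its
#' amplitude is recomputed from the merged endpoints (when the trace is
#' available) and its peak velocity is the pair's maximum. A merged saccade
#' may merge again with its successor.
#'
#' @param saccades Ordered, disjoint candidate data frame with an
#'   `overshoot` logical column (added as `FALSE` if absent).
#' @param max_gap Maximum inter-saccade gap in seconds (strict).
#' @param max_second_amplitude Amplitude cap on the second saccade
#'   (inclusive); `NA`/`NULL` drops the amplitude condition (uncalibrated
#'   traces with no native-unit cap configured: gap-only merging).
#' @param trace Optional [gaze_trace()] for recomputing merged amplitudes
#'   from the endpoint gaze positions; without it the merged amplitude is
#'   the Euclidean endpoint distance reconstructed from the parts is not
#'   available and is set to `NA`.
#' @param in_degrees Whether candidate amplitudes are in degrees (then the
#'   recomputed amplitude is converted with the trace calibration).
#' @return The saccades after merging, with `overshoot` flags.
#' @export
merge_overshoots <- function(saccades, max_gap = 0.016,
                             max_second_amplitude = 1.5, trace = NULL,
                             in_degrees = !is.null(trace) &&
                               !is.null(trace$pix_per_degree)) {
  if (is.null(max_second_amplitude)) max_second_amplitude <- NA_real_
  if (!"overshoot" %in% names(saccades))
    saccades$overshoot <- logical(nrow(saccades))
  if (nrow(saccades) < 2L) return(saccades)
  s <- saccades
  i <- 1L
  while (i < nrow(s)) {
    gap <- s$onset_t[i + 1L] - s$offset_t[i]
    amp_ok <- is.na(max_second_amplitude) ||
      s$amplitude[i + 1L] <= max_second_amplitude
    if (gap < max_gap && amp_ok) {
      s$offset_t[i] <- s$offset_t[i + 1L]
      s$offset_index[i] <- s$offset_index[i + 1L]
      s$duration[i] <- s$offset_t[i] - s$onset_t[i]
      s$peak_velocity[i] <- max(s$peak_velocity[i], s$peak_velocity[i + 1L])
      s$amplitude[i] <- merged_amplitude(trace, s$onset_index[i],
                                         s$offset_index[i], in_degrees)
      s$overshoot[i] <- TRUE
      if ("touches_missing" %in% names(s))
        s$touches_missing[i] <- s$touches_missing[i] ||
          s$touches_missing[i + 1L]
      s <- s[-(i + 1L), , drop = FALSE]
    } else {
      i <- i + 1L
    }
  }
  rownames(s) <- NULL
  s
}

merged_amplitude <- function(trace, on_i, off_i, in_degrees) {
  if (is.null(trace)) return(NA_real_)
  amp <- sqrt((trace$x[off_i] - trace$x[on_i])^2 +
              (trace$y[off_i] - trace$y[on_i])^2)
  if (in_degrees) amp <- amp / trace$pix_per_degree
  amp
}

#' Define fixations as the periods between saccades and blinks
#'
#' A fixation is any maximal sub-interval of the trace extent not covered
#' by a saccade or blink: the periods when the eye moves slowly within a
#' small area. No minimum-duration filter is applied. Residual periods at
#' the trace edges become fixations flagged `truncated` (their true onset
#' or offset lies outside the recording), as does any saccade or blink
#' touching an edge. The result covers the extent exactly.
#'
#' @param saccades Saccade data frame (`onset_t`, `offset_t`, `amplitude`,
#'   `duration`, `peak_velocity`, optional `overshoot`).
#' @param blinks Blink data frame (`onset_t`, `offset_t`), disjoint from
#'   the saccades.
#' @param extent Numeric length-2 trace extent (first, last timestamp).
#' @param tol Gaps shorter than this are not turned into (zero-length)
#'   fixations.
#' @return An [event_list()] covering `extent`.
#' @export
define_fixations <- function(saccades, blinks, extent, tol = 1e-9) {
  mk <- function(df, label) {
    if (is.null(df) || !nrow(df)) return(empty_events())
    data.frame(onset = df$onset_t, offset = df$offset_t, label = label,
               amplitude = if ("amplitude" %in% names(df)) df$amplitude
                           else NA_real_,
               duration = df$offset_t - df$onset_t,
               peak_velocity = if ("peak_velocity" %in% names(df))
                                 df$peak_velocity else NA_real_,
               overshoot = if ("overshoot" %in% names(df) &&
                               label == "saccade") df$overshoot else FALSE,
               truncated = FALSE, stringsAsFactors = FALSE)
  }
  ev <- rbind(mk(saccades, "saccade"), mk(blinks, "blink"))
  if (nrow(ev)) {
    ev <- ev[order(ev$onset), , drop = FALSE]
    ov <- which(ev$onset[-1L] < ev$offset[-nrow(ev)] - tol)
    if (length(ov))
      stop("overlapping saccade/blink inputs: events at ",
           sprintf("%.4f", ev$onset[ov[1L]]), " s (", ev$label[ov[1L]],
           ") and ", sprintf("%.4f", ev$onset[ov[1L] + 1L]), " s (",
           ev$label[ov[1L] + 1L], ")")
    if (any(ev$onset < extent[1L] - tol) || any(ev$offset > extent[2L] + tol))
      stop("saccade/blink outside the trace extent")
  }
  bounds_on <- c(ev$onset, extent[2L])
  bounds_off <- c(extent[1L], ev$offset)
  gaps_on <- bounds_off
  gaps_off <- bounds_on
  keep <- gaps_off - gaps_on > tol
  fx <- data.frame(onset = gaps_on[keep], offset = gaps_off[keep],
                   label = "fixation", amplitude = NA_real_,
                   duration = gaps_off[keep] - gaps_on[keep],
                   peak_velocity = NA_real_, overshoot = FALSE,
                   truncated = FALSE, stringsAsFactors = FALSE)
  all_ev <- rbind(ev, fx)
  all_ev$truncated <- all_ev$onset <= extent[1L] + tol |
    all_ev$offset >= extent[2L] - tol
  event_list(all_ev, extent = extent)
}

#' Detect saccades, fixations and blinks in a gaze trace
#'
#' Runs the full deterministic pipeline: kinematics; threshold suggestion
#' from the trace's own velocity/acceleration ECDFs (unless manual
#' thresholds are supplied); candidate labeling and grouping; blink
#' detection appropriate to the modality (pupil noise for video,
#' main-sequence classification for EOG, none for scleral coil, where
#' blinks are undetectable); removal of candidates overlapping blinks;
#' the short-saccade filter; overshoot merging; and fixation definition.
#' Repeating the call on the same input yields an identical result — no
#' step uses randomness.
#'
#' @param trace A [gaze_trace()].
#' @param params Parameter list from [safide_params()].
#' @param thresholds Optional [threshold_set()]; overrides both suggested
#'   and config-supplied manual thresholds.
#' @return An [event_list()] covering the trace extent, with the applied
#'   `threshold_set` attached as attribute `thresholds`.
#' @export
detect <- function(trace, params = safide_params(), thresholds = NULL) {
  stopifnot(inherits(trace, "gaze_trace"))
  k <- kinematics(trace)
  thr <- thresholds
  if (is.null(thr)) {
    manual <- c(params$velocity.threshold, params$acceleration.pos,
                params$acceleration.neg)
    thr <- if (all(is.finite(manual)))
      threshold_set(manual[1L], manual[2L], manual[3L], source = "manual")
    else
      suggest_thresholds(k, params$velocity.level, params$acceleration.level)
  }
  mask <- label_candidates(k, thr)
  cands <- group_candidates(mask, trace, k)
  cands$overshoot <- logical(nrow(cands))

  blinks <- empty_blinks("none")
  ext <- trace_extent(trace)
  if (trace$modality == "video" && !is.null(trace$pupil)) {
    blinks <- detect_blinks_pupil(
      trace$pupil, trace$t, trace$fs_nominal,
      smooth_window = params$blink.pupil.smooth_window,
      noise_factor = params$blink.pupil.noise_factor,
      margin_ms = params$blink.pupil.margin_ms)
  } else if (trace$modality == "eog") {
    cls <- classify_blinks_eog(
      cands, min_duration = params$blink.eog.min_duration_ms / 1000,
      amp_factor = params$blink.eog.amp_factor)
    blinks <- cls$blinks
    cands <- cls$remaining
  }
  if (nrow(blinks)) {
    blinks <- merge_blink_intervals(blinks, params$blink.merge_gap_ms / 1000)
    if (nrow(cands)) {
      # gaze during lid closure is artifactual: drop overlapping candidates
      drop <- vapply(seq_len(nrow(cands)), function(i)
        any(cands$onset_t[i] < blinks$offset_t &
            cands$offset_t[i] > blinks$onset_t), logical(1L))
      cands <- cands[!drop, , drop = FALSE]
    }
  }

  in_deg <- k$in_degrees
  min_amp <- if (in_deg) params$saccade.min_amplitude_deg
             else params$saccade.min_amplitude_native
  min_dur <- params$saccade.min_duration_ms / 1000
  max2 <- if (in_deg) params$overshoot.max_second_amplitude_deg
          else params$overshoot.max_second_amplitude_native
  max_gap <- params$overshoot.max_gap_ms / 1000

  if (isTRUE(params$overshoot.before_filter)) {
    cands <- merge_overshoots(cands, max_gap, max2, trace, in_deg)
    cands <- filter_short_saccades(cands, min_amp, min_dur)
  } else {
    cands <- filter_short_saccades(cands, min_amp, min_dur)
    cands <- merge_overshoots(cands, max_gap, max2, trace, in_deg)
  }

  out <- define_fixations(cands, blinks, ext)
  attr(out, "thresholds") <- thr
  out
}
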