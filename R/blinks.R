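#' Detect blinks from pupillometry noise
#'
#' Video eye trackers lose the pupil during a blink, leaving a missing gap,
#' but the lid starts occluding the pupil earlier and releases it later:
#' the pupil-size trace ramps down into the gap and back up out of it.
#' Following the noise-based approach, each maximal missing gap is extended
#' backward and forward along the smoothed pupil derivative until the
#' derivative re-enters a noise band estimated from blink-free segments;
#' overlapping extended gaps are merged.
#'
#' @param pupil Numeric pupil-size series; `NA` marks occlusion/missing.
#' @param t Timestamps in seconds (same length).
#' @param fs Sampling rate in Hz (> 0), used to size the exclusion margin.
#' @param smooth_window Moving-average window (samples, odd) applied to the
#'   pupil before differentiation; 1 disables smoothing.
#' @param noise_factor The noise band is `noise_factor` times the standard
#'   deviation of the smoothed derivative over blink-free samples.
#' @param margin_ms Samples closer than this to any gap are excluded from
#'   the noise estimate.
#' @return A data frame of disjoint, ordered blink intervals with columns
#'   `onset_t`, `offset_t`, `source = "pupil"`. Zero rows if there are no
#'   missing gaps.
#' @export
detect_blinks_pupil <- function(pupil, t, fs, smooth_window = 11,
                                noise_factor = 2.5, margin_ms = 200) {
  if (is.null(pupil))
    stop("no pupil series: pupil-based blink detection is not applicable")
  n <- length(pupil)
  stopifnot(length(t) == n, fs > 0)
  isna <- is.na(pupil)
  if (!any(isna)) return(empty_blinks("pupil"))

  w <- max(1L, as.integer(smooth_window))
  if (w %% 2L == 0L) w <- w + 1L
  ps <- if (w > 1L) {
    half <- (w - 1L) %/% 2L
    padded <- c(rep(pupil[1L], half), pupil, rep(pupil[n], half))
    as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[
      (half + 1L):(half + n)]
  } else pupil
  dd <- diff(ps)                      # dd[i] spans samples i, i+1

  # maximal missing runs
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  g1 <- starts[r$values]; g2 <- ends[r$values]

  # blink-free samples for the noise estimate
  margin <- as.integer(round(margin_ms / 1000 * fs))
  excl <- logical(n)
  for (j in seq_along(g1)) {
    lo <- max(1L, g1[j] - margin); hi <- min(n, g2[j] + margin)
    excl[lo:hi] <- TRUE
  }
  dd_free <- dd[!(excl[-n] | excl[-1L])]
  dd_free <- dd_free[is.finite(dd_free)]
  sd_noise <- if (length(dd_free) >= 10L) stats::sd(dd_free)
              else stats::sd(dd[is.finite(dd)])
  if (!is.finite(sd_noise)) sd_noise <- 0
  band <- noise_factor * sd_noise

  onset <- integer(length(g1)); offset <- integer(length(g1))
  for (j in seq_along(g1)) {
    i <- g1[j]
    while (i > 1L && (is.na(dd[i - 1L]) || abs(dd[i - 1L]) > band))
      i <- i - 1L
    onset[j] <- i
    i <- g2[j]
    while (i < n && (is.na(dd[i]) || abs(dd[i]) > band))
      i <- i + 1L
    offset[j] <- i
  }
  # merge overlapping/abutting extended gaps
  ord <- order(onset)
  onset <- onset[ord]; offset <- offset[ord]
  mo <- onset[1L]; mf <- offset[1L]
  out_on <- integer(0); out_off <- integer(0)
  for (j in seq_along(onset)[-1L]) {
    if (onset[j] <= mf) {
      mf <- max(mf, offset[j])
    } else {
      out_on <- c(out_on, mo); out_off <- c(out_off, mf)
      mo <- onset[j]; mf <- offset[j]
    }
  }
  out_on <- c(out_on, mo); out_off <- c(out_off, mf)
  data.frame(onset_t = t[out_on], offset_t = t[out_off],
             source = "pupil", stringsAsFactors = FALSE)
}

#' Classify EOG candidate saccades as blinks on the main sequence
#'
#' On EOG, a blink is picked up as a large, slow vertical deflection that
#' crosses the saccade thresholds, so it first appears among the candidate
#' saccades. On the amplitude-duration main sequence, blinks sit far off
#' the saccade cluster: much longer and much larger. A candidate is
#' relabeled as a blink when its duration is at least `min_duration` AND
#' its amplitude is at least `amp_factor` times the median amplitude of all
#' candidates. EOG units are uncalibrated, hence the relative amplitude
#' bound. The two outputs partition the input.
#'
#' The amplitude placed on the main sequence is the candidate's maximum
#' excursion (`excursion` column, if present) rather than its endpoint
#' distance: a blink deflection returns toward baseline, so its endpoint
#' amplitude can collapse to zero even though the artifact is huge; the
#' excursion preserves the separation from actual saccades, for which the
#' two measures nearly coincide.
#'
#' @param candidates Candidate data frame from [group_candidates()].
#' @param min_duration Duration bound in seconds (> 0).
#' @param amp_factor Multiple of the median candidate amplitude (> 1).
#' @return List with `blinks` (data frame `onset_t`, `offset_t`,
#'   `source = "eog_main_sequence"`) and `remaining` (the other
#'   candidates).
#' @export
classify_blinks_eog <- function(candidates, min_duration = 0.1,
                                amp_factor = 2.0) {
  stopifnot(min_duration > 0, amp_factor > 1)
  if (!nrow(candidates))
    return(list(blinks = empty_blinks("eog_main_sequence"),
                remaining = candidates))
  ms_amp <- if ("excursion" %in% names(candidates)) candidates$excursion
            else candidates$amplitude
  med <- stats::median(ms_amp)
  is_blink <- candidates$duration >= min_duration &
    ms_amp >= amp_factor * med
  blinks <- candidates[is_blink, , drop = FALSE]
  list(blinks = data.frame(onset_t = blinks$onset_t,
                           offset_t = blinks$offset_t,
                           source = rep("eog_main_sequence", nrow(blinks)),
                           stringsAsFactors = FALSE),
       remaining = candidates[!is_blink, , drop = FALSE])
}

empty_blinks <- function(source) {
  data.frame(onset_t = numeric(0), offset_t = numeric(0),
             source = character(0), stringsAsFactors = FALSE)
}

# merge blink intervals separated by less than gap seconds (lid still closed)
merge_blink_intervals <- function(blinks, gap) {
  if (nrow(blinks) < 2L) return(blinks)
  ord <- order(blinks$onset_t)
  blinks <- blinks[ord, , drop = FALSE]
  keep_on <- blinks$onset_t[1L]; keep_off <- blinks$offset_t[1L]
  src <- blinks$source[1L]
  out <- list()
  for (j in seq_len(nrow(blinks))[-1L]) {
    if (blinks$onset_t[j] - keep_off < gap) {
      keep_off <- max(keep_off, blinks$offset_t[j])
    } else {
      out[[length(out) + 1L]] <- c(keep_on, keep_off)
      keep_on <- blinks$onset_t[j]; keep_off <- blinks$offset_t[j]
    }
  }
  out[[length(out) + 1L]] <- c(keep_on, keep_off)
  m <- do.call(rbind, out)
  data.frame(onset_t = m[, 1L], offset_t = m[, 2L], source = src,
             stringsAsFactors = FALSE)
}
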