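#' Label candidate-saccade intervals by threshold crossing
#'
#' Interval `i` (between samples `i` and `i + 1`) is a candidate when its
#' velocity is at or above the velocity threshold, or its acceleration is at
#' or beyond either acceleration threshold ("equal to or above" is
#' inclusive on both sides). The acceleration series is one element shorter
#' than the velocity series, so the last interval is judged on velocity
#' alone. Missing (NA) entries are never candidates.
#'
#' @param k A [kinematics()] series.
#' @param thr A [threshold_set()].
#' @return Logical vector over the `n - 1` intervals of the trace.
#' @export
label_candidates <- function(k, thr) {
  stopifnot(inherits(k, "kinematic_series"), inherits(thr, "threshold_set"))
  m <- length(k$v)
  mask <- k$v >= thr$v_thr
  acc <- k$a >= thr$a_pos | k$a <= thr$a_neg
  acc[is.na(acc)] <- FALSE
  mask[seq_along(acc)] <- mask[seq_along(acc)] | acc
  mask[is.na(mask)] <- FALSE
  mask
}

#' Group consecutive candidate intervals into candidate saccades
#'
#' Maximal runs of `TRUE` intervals become candidate saccades: the onset is
#' the left sample of the first supra-threshold interval, the offset the
#' right sample of the last one. Amplitude is the Euclidean distance
#' between the gaze positions at onset and offset (in degrees when the
#' kinematics are calibrated), duration the timestamp difference, and
#' peak velocity the maximum interval velocity within the run. `excursion`
#' is the maximum distance from the onset position reached anywhere inside
#' the run: for a saccade it nearly equals the amplitude, but for a blink
#' artifact — which deflects far and returns — it stays large while the
#' endpoint amplitude collapses, which is what separates blinks on the
#' amplitude-duration main sequence. Runs bordering a missing-data region
#' are flagged `touches_missing` for the blink stage.
#'
#' @param mask Logical interval mask, as from [label_candidates()].
#' @param trace The [gaze_trace()] the mask refers to.
#' @param k Optional matching [kinematics()] series (recomputed if absent).
#' @return A data frame with one row per candidate: `onset_index`,
#'   `offset_index` (1-based sample indices), `onset_t`, `offset_t`,
#'   `amplitude`, `duration`, `peak_velocity`, `excursion`,
#'   `touches_missing`.
#' @export
group_candidates <- function(mask, trace, k = NULL) {
  stopifnot(inherits(trace, "gaze_trace"))
  n <- n_samples(trace)
  if (length(mask) != n - 1L)
    stop("mask must have one entry per inter-sample interval (n - 1)")
  if (is.null(k)) k <- kinematics(trace)
  mask <- as.logical(mask)
  mask[is.na(mask)] <- FALSE

  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(empty_candidates())

  on_i <- starts                 # left sample of first true interval
  off_i <- ends + 1L             # right sample of last true interval
  dx <- trace$x[off_i] - trace$x[on_i]
  dy <- trace$y[off_i] - trace$y[on_i]
  amp <- sqrt(dx^2 + dy^2)
  if (k$in_degrees) amp <- amp / trace$pix_per_degree
  pv <- vapply(seq_along(starts), function(j)
    max(k$v[starts[j]:ends[j]], na.rm = TRUE), numeric(1L))
  exc <- vapply(seq_along(starts), function(j) {
    ii <- on_i[j]:off_i[j]
    max(sqrt((trace$x[ii] - trace$x[on_i[j]])^2 +
             (trace$y[ii] - trace$y[on_i[j]])^2), na.rm = TRUE)
  }, numeric(1L))
  if (k$in_degrees) exc <- exc / trace$pix_per_degree
  na_int <- is.na(trace$x) | is.na(trace$y)
  na_int <- na_int[-n] | na_int[-1L]   # interval touches a missing sample
  touches <- vapply(seq_along(starts), function(j) {
    lo <- starts[j] - 1L; hi <- ends[j] + 1L
    (lo >= 1L && na_int[lo]) || (hi <= n - 1L && na_int[hi])
  }, logical(1L))
  data.frame(onset_index = on_i, offset_index = off_i,
             onset_t = trace$t[on_i], offset_t = trace$t[off_i],
             amplitude = amp, duration = trace$t[off_i] - trace$t[on_i],
             peak_velocity = pv, excursion = exc,
             touches_missing = touches)
}

empty_candidates <- function() {
  data.frame(onset_index = integer(0), offset_index = integer(0),
             onset_t = numeric(0), offset_t = numeric(0),
             amplitude = numeric(0), duration = numeric(0),
             peak_velocity = numeric(0), excursion = numeric(0),
             touches_missing = logical(0))
}
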