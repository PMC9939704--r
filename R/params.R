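#' Detection parameters
#'
#' Returns the full parameter set of the detector as a flat named list;
#' pass overrides as `name = value`. All keys can also be given in a
#' key-value config file ([read_config()]).
#'
#' \describe{
#'   \item{`velocity.level`, `acceleration.level`}{ECDF accumulation levels
#'     for [suggest_thresholds()] (defaults 0.85 and 0.90).}
#'   \item{`velocity.threshold`, `acceleration.pos`, `acceleration.neg`}{
#'     Manual thresholds in native units; when all three are set they are
#'     used instead of the suggested ones.}
#'   \item{`saccade.min_amplitude_deg`}{Minimum saccade amplitude in visual
#'     degrees (default 0.1; applied when the trace is calibrated).
#'     Candidates at exactly the bound are kept.}
#'   \item{`saccade.min_amplitude_native`}{Minimum amplitude in native
#'     units for uncalibrated traces; `NA` skips the amplitude filter.}
#'   \item{`saccade.min_duration_ms`}{Minimum saccade duration (default 4).}
#'   \item{`overshoot.max_gap_ms`}{Two consecutive saccades closer than
#'     this (strictly) are one movement with an overshoot (default 16,
#'     below the ~50 ms shortest reported fixation).}
#'   \item{`overshoot.max_second_amplitude_deg`}{The second movement must
#'     not exceed this amplitude to count as an overshoot (default 1.5,
#'     inclusive; calibrated traces only).}
#'   \item{`overshoot.max_second_amplitude_native`}{Native-unit equivalent
#'     for uncalibrated traces. When `NA` (default) the amplitude condition
#'     is skipped there and merging is gap-only — supply a value if your
#'     EOG/coil gain makes one meaningful.}
#'   \item{`overshoot.before_filter`}{Merge overshoots before instead of
#'     after the short-saccade filter (default `FALSE`).}
#'   \item{`blink.pupil.smooth_window`, `blink.pupil.noise_factor`,
#'     `blink.pupil.margin_ms`}{Pupil blink detector settings, see
#'     [detect_blinks_pupil()].}
#'   \item{`blink.eog.min_duration_ms`, `blink.eog.amp_factor`}{Main-sequence
#'     blink boundary, see [classify_blinks_eog()].}
#'   \item{`blink.merge_gap_ms`}{Blink intervals closer than this are one
#'     blink (default 50).}
#'   \item{`match.onset_tolerance_ms`}{Onset tolerance of [match_events()]
#'     (default 10).}
#' }
#'
#' @param ... Name-value overrides of the defaults.
#' @return Named list of parameters.
#' @export
safide_params <- function(...) {
  p <- list(
    velocity.level = 0.85,
    acceleration.level = 0.90,
    velocity.threshold = NA_real_,
    acceleration.pos = NA_real_,
    acceleration.neg = NA_real_,
    saccade.min_amplitude_deg = 0.1,
    saccade.min_amplitude_native = NA_real_,
    saccade.min_duration_ms = 4,
    overshoot.max_gap_ms = 16,
    overshoot.max_second_amplitude_deg = 1.5,
    overshoot.max_second_amplitude_native = NA_real_,
    overshoot.before_filter = FALSE,
    blink.pupil.smooth_window = 11,
    blink.pupil.noise_factor = 2.5,
    blink.pupil.margin_ms = 200,
    blink.eog.min_duration_ms = 100,
    blink.eog.amp_factor = 2.0,
    blink.merge_gap_ms = 50,
    match.onset_tolerance_ms = 10
  )
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1L]]) && is.null(names(dots)))
    dots <- dots[[1L]]
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}
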