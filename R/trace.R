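#' Construct a gaze trace
#'
#' A `gaze_trace` holds one eye's sampled position over time, in the native
#' units of the recording device (screen pixels for video eye tracking,
#' volts for scleral search coils, arbitrary units for uncalibrated EOG),
#' plus optional pupil size and a pixels-per-degree calibration. Missing
#' samples (tracking loss, pupil occlusion) are explicit `NA`s and are never
#' interpolated.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y Numeric vectors of horizontal / vertical gaze position in
#'   native units; `NA` marks a missing sample.
#' @param pupil Optional numeric vector of pupil size (native units,
#'   `NA` = occluded/missing), same length as `t`.
#' @param units One of `"pixels"`, `"volts"`, `"arbitrary"`.
#' @param fs_nominal Nominal sampling rate in Hz (> 0). Kinematics always
#'   use the actual timestamps; the nominal rate is metadata (e.g. for the
#'   pupil-noise blink detector's sample-count parameters).
#' @param pix_per_degree Optional pixels-per-visual-degree calibration
#'   (> 0); only meaningful for `units = "pixels"`.
#' @param modality One of `"video"`, `"eog"`, `"coil"`; controls which blink
#'   detector [detect()] applies. Defaults to `"video"` for pixel data and
#'   `"eog"` otherwise (scleral-coil traces must be declared explicitly,
#'   since blinks are undetectable there and blink detection is skipped).
#'
#' @return An object of class `gaze_trace`.
#' @export
gaze_trace <- function(t, x, y, pupil = NULL,
                       units = c("pixels", "volts", "arbitrary"),
                       fs_nominal, pix_per_degree = NULL, modality = NULL) {
  units <- match.arg(units)
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (n < 2L)
    stop("a gaze trace needs at least 2 samples, got ", n)
  if (length(x) != n || length(y) != n)
    stop("t, x and y must have equal length")
  if (!is.null(pupil)) {
    pupil <- as.numeric(pupil)
    if (length(pupil) != n) stop("pupil must have the same length as t")
  }
  if (anyNA(t)) stop("timestamps must not contain NA")
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop("timestamps must be strictly increasing; first offending row: ",
         bad[1L] + 1L, " (t = ", t[bad[1L] + 1L], ")")
  if (!is.numeric(fs_nominal) || length(fs_nominal) != 1L || fs_nominal <= 0)
    stop("fs_nominal must be a single positive number")
  if (!is.null(pix_per_degree)) {
    if (!is.numeric(pix_per_degree) || length(pix_per_degree) != 1L ||
        pix_per_degree <= 0)
      stop("pix_per_degree must be a single positive number")
  }
  if (is.null(modality))
    modality <- if (units == "pixels") "video" else "eog"
  modality <- match.arg(modality, c("video", "eog", "coil"))
  structure(
    list(t = t, x = x, y = y, pupil = pupil, units = units,
         fs_nominal = as.numeric(fs_nominal),
         pix_per_degree = if (is.null(pix_per_degree)) NULL
                          else as.numeric(pix_per_degree),
         modality = modality),
    class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  n <- length(x$t)
  cat("<gaze_trace> ", n, " samples, ",
      sprintf("%.3f", x$t[n] - x$t[1L]), " s @ ", x$fs_nominal, " Hz nominal\n",
      sep = "")
  cat("  units: ", x$units, "; modality: ", x$modality,
      if (!is.null(x$pix_per_degree))
        paste0("; calibration: ", x$pix_per_degree, " px/deg"),
      "\n", sep = "")
  nmiss <- sum(is.na(x$x) | is.na(x$y))
  cat("  pupil: ", if (is.null(x$pupil)) "absent" else "present",
      "; missing gaze samples: ", nmiss, "\n", sep = "")
  invisible(x)
}

n_samples <- function(trace) length(trace$t)

trace_extent <- function(trace) c(trace$t[1L], trace$t[length(trace$t)])
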