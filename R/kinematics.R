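#' Per-step Euclidean distance of a gaze trace
#'
#' `d[i]` is the Euclidean distance travelled between samples `i` and
#' `i + 1`, in the trace's native units; a trace of `n` samples yields
#' `n - 1` distances. Steps touching a missing sample are `NA`.
#'
#' @param trace A [gaze_trace()].
#' @return Numeric vector of length `n - 1`.
#' @export
step_distance <- function(trace) {
  stopifnot(inherits(trace, "gaze_trace"))
  sqrt(diff(trace$x)^2 + diff(trace$y)^2)
}

#' Convert a pixel distance series to visual degrees
#'
#' Divides each element by the pixels-per-degree calibration constant.
#' Only defined for pixel data: for uncalibrated volt/arbitrary traces the
#' kinematics keep relative values and this conversion is an error.
#'
#' @param d Numeric distance series in pixels.
#' @param pix_per_degree Pixels per visual degree (> 0).
#' @param units Units of `d`; must be `"pixels"`.
#' @return `d / pix_per_degree`, in degrees.
#' @export
to_degrees <- function(d, pix_per_degree, units = "pixels") {
  if (!identical(units, "pixels"))
    stop("degree conversion is only defined for pixel units; ",
         "kinematics in '", units, "' keep relative values")
  if (!is.numeric(pix_per_degree) || length(pix_per_degree) != 1L ||
      is.na(pix_per_degree) || pix_per_degree <= 0)
    stop("pix_per_degree must be a single positive number")
  d / pix_per_degree
}

#' Per-step velocity
#'
#' `v[i] = d[i] / (t[i+1] - t[i])`, the average speed over the interval
#' starting at sample `i`. Distances are non-negative, so velocities are
#' non-negative speeds.
#'
#' @param d Step-distance series (length `n - 1`).
#' @param t Timestamps in seconds (length `n`).
#' @return Numeric vector of length `n - 1`, units/s.
#' @export
velocity <- function(d, t) {
  if (length(t) != length(d) + 1L)
    stop("t must have one more element than d")
  dt <- diff(t)
  bad <- which(dt <= 0)
  if (length(bad))
    stop("non-positive time step at index ", bad[1L],
         " (dt = ", dt[bad[1L]], ")")
  d / dt
}

#' Per-step acceleration
#'
#' `a[i] = (v[i+1] - v[i]) / (t[i+1] - t[i])`; may be negative. A trace of
#' `n` samples yields `n - 2` accelerations.
#'
#' @param v Velocity series (length `n - 1`).
#' @param t Timestamps in seconds (length `n`).
#' @return Numeric vector of length `n - 2`, units/s^2.
#' @export
acceleration <- function(v, t) {
  if (length(t) != length(v) + 1L)
    stop("t must have one more element than v")
  dt <- diff(t)
  bad <- which(dt <= 0)
  if (length(bad))
    stop("non-positive time step at index ", bad[1L],
         " (dt = ", dt[bad[1L]], ")")
  m <- length(v)
  (v[-1L] - v[-m]) / dt[seq_len(m - 1L)]
}

#' Kinematic series of a gaze trace
#'
#' Computes step distances, velocities and accelerations from the actual
#' timestamps (so dropped frames do not corrupt velocities). If the trace is
#' in pixels and carries a pixels-per-degree calibration, distances are
#' converted to visual degrees (and velocities/accelerations to deg/s,
#' deg/s^2); otherwise all kinematics are in native units and the detector
#' operates on relative values.
#'
#' Index alignment: `d[i]` and `v[i]` describe the interval starting at
#' sample `i`; `a[i]` the interval pair starting at `i`. Entries touching a
#' missing gaze sample are `NA`.
#'
#' @param trace A [gaze_trace()].
#' @param in_degrees Convert to visual degrees? Defaults to `TRUE` exactly
#'   when the trace is calibrated pixel data.
#' @return An object of class `kinematic_series`: list with elements `t`,
#'   `d`, `v`, `a`, `in_degrees`, `units`.
#' @export
kinematics <- function(trace,
                       in_degrees = trace$units == "pixels" &&
                         !is.null(trace$pix_per_degree)) {
  stopifnot(inherits(trace, "gaze_trace"))
  d <- step_distance(trace)
  if (in_degrees)
    d <- to_degrees(d, trace$pix_per_degree, trace$units)
  v <- velocity(d, trace$t)
  a <- acceleration(v, trace$t)
  structure(
    list(t = trace$t, d = d, v = v, a = a,
         in_degrees = isTRUE(in_degrees),
         units = if (isTRUE(in_degrees)) "degrees" else trace$units),
    class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat("<kinematic_series> ", length(x$v), " intervals (", x$units, ")\n",
      sep = "")
  cat("  velocity: median ", sprintf("%.3g", stats::median(x$v, na.rm = TRUE)),
      ", max ", sprintf("%.3g", suppressWarnings(max(x$v, na.rm = TRUE))),
      " ", x$units, "/s\n", sep = "")
  invisible(x)
}
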