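#' Type-1 empirical-CDF quantile
#'
#' Returns the smallest sample value `q` such that the fraction of samples
#' `<= q` is at least `level` (the inverse empirical CDF, with no
#' interpolation, i.e. quantile type 1). The result is always an element of
#' `samples`.
#'
#' @param samples Non-empty numeric vector; `NA`s are dropped.
#' @param level Accumulation level, a fraction in (0, 1).
#' @return A single sample value.
#' @export
ecdf_quantile <- function(samples, level) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("ecdf_quantile: no finite samples")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be a single fraction in (0, 1)")
  s <- sort(samples)
  s[ceiling(level * length(s))]
}

#' Construct a threshold set
#'
#' Velocity and asymmetric acceleration thresholds used to label candidate
#' saccade samples. A sample is a candidate when its velocity reaches
#' `v_thr` or its acceleration falls outside `(a_neg, a_pos)`.
#'
#' @param v_thr Velocity threshold, units/s (> 0).
#' @param a_pos Positive acceleration threshold, units/s^2 (> 0).
#' @param a_neg Negative acceleration threshold, units/s^2 (< 0).
#' @param v_level,a_level ECDF accumulation levels the thresholds were taken
#'   at (`NA` for manual thresholds).
#' @param source `"suggested"` (from [suggest_thresholds()]) or `"manual"`.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(v_thr, a_pos, a_neg, v_level = NA_real_,
                          a_level = NA_real_,
                          source = c("manual", "suggested")) {
  source <- match.arg(source)
  if (!is.finite(v_thr) || v_thr <= 0) stop("v_thr must be > 0")
  if (!is.finite(a_pos) || a_pos <= 0) stop("a_pos must be > 0")
  if (!is.finite(a_neg) || a_neg >= 0) stop("a_neg must be < 0")
  for (lv in c(v_level, a_level))
    if (!is.na(lv) && (lv <= 0 || lv >= 1))
      stop("ECDF levels must lie in (0, 1)")
  structure(list(v_thr = v_thr, a_pos = a_pos, a_neg = a_neg,
                 v_level = v_level, a_level = a_level, source = source),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> (", x$source, ")\n", sep = "")
  cat(sprintf("  velocity     >= %.6g units/s", x$v_thr),
      if (!is.na(x$v_level)) sprintf("  [ECDF level %.2f]", x$v_level), "\n")
  cat(sprintf("  acceleration >= %.6g or <= %.6g units/s^2", x$a_pos, x$a_neg),
      if (!is.na(x$a_level)) sprintf("  [ECDF level %.2f]", x$a_level), "\n")
  invisible(x)
}

#' Suggest detection thresholds from a trace's own kinematics
#'
#' During free viewing the eye fixates 80--90% of the time, so the long
#' upper tail of the velocity distribution belongs to saccades. The
#' suggested velocity threshold is the type-1 ECDF quantile of the velocity
#' samples at `v_level` (default 85% accumulation); acceleration thresholds
#' are taken per sign at `a_level` (default 90%): the positive threshold
#' from the positive accelerations and the negative one as minus the
#' quantile of the negated negative accelerations, which is what yields the
#' asymmetric pairs seen on real recordings. Missing entries are excluded.
#'
#' The defaults mirror common practice but remain a visual-inspection aid:
#' inspect the distributions ([histogram_summary()]) before trusting them.
#'
#' @param k A [kinematics()] series.
#' @param v_level ECDF accumulation level for velocity, in (0, 1).
#' @param a_level ECDF accumulation level for each acceleration sign.
#' @return A [threshold_set()] with `source = "suggested"`.
#' @export
suggest_thresholds <- function(k, v_level = 0.85, a_level = 0.90) {
  stopifnot(inherits(k, "kinematic_series"))
  v <- k$v[is.finite(k$v)]
  a <- k$a[is.finite(k$a)]
  if (length(v) < 10L || length(a) < 10L)
    stop("need at least 10 non-missing velocity and acceleration samples")
  a_pos_s <- a[a > 0]
  a_neg_s <- a[a < 0]
  if (!length(a_pos_s) || !length(a_neg_s))
    stop("all accelerations have one sign; ",
         "asymmetric acceleration thresholds are undefined")
  threshold_set(v_thr = ecdf_quantile(v, v_level),
                a_pos = ecdf_quantile(a_pos_s, a_level),
                a_neg = -ecdf_quantile(-a_neg_s, a_level),
                v_level = v_level, a_level = a_level,
                source = "suggested")
}

#' Binned velocity / acceleration distributions with threshold markers
#'
#' Plot-ready summary of the velocity and acceleration histograms together
#' with the threshold positions, for visual inspection of where the
#' suggested (or manual) thresholds sit relative to the fixation bulk and
#' the saccadic tail.
#'
#' @param k A [kinematics()] series.
#' @param thresholds A [threshold_set()].
#' @param bins Suggested number of histogram bins.
#' @return An object of class `safide_histograms`: list with `velocity` and
#'   `acceleration` histogram objects (as from [graphics::hist()],
#'   unplotted) and the `thresholds`.
#' @export
histogram_summary <- function(k, thresholds, bins = 60) {
  stopifnot(inherits(k, "kinematic_series"),
            inherits(thresholds, "threshold_set"))
  v <- k$v[is.finite(k$v)]
  a <- k$a[is.finite(k$a)]
  structure(list(velocity = graphics::hist(v, breaks = bins, plot = FALSE),
                 acceleration = graphics::hist(a, breaks = bins, plot = FALSE),
                 thresholds = thresholds, units = k$units),
            class = "safide_histograms")
}

#' @export
plot.safide_histograms <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$velocity, main = "Velocity",
       xlab = paste0("velocity (", x$units, "/s)"), ...)
  graphics::abline(v = x$thresholds$v_thr, lty = 2)
  plot(x$acceleration, main = "Acceleration",
       xlab = paste0("acceleration (", x$units, "/s²)"), ...)
  graphics::abline(v = c(x$thresholds$a_neg, x$thresholds$a_pos), lty = 2)
  invisible(x)
}
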