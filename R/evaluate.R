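#' Match detected events against ground truth
#'
#' Greedy one-to-one matching by maximal temporal overlap: a detected event
#' can match a truth event of the same label only if the two intervals
#' overlap and their onsets differ by at most `max_onset_tolerance`.
#' Candidate pairs are taken in order of decreasing overlap, ties broken by
#' earliest truth onset then earliest detected onset, so the matching is
#' deterministic.
#'
#' @param detected An [event_list()] (or data frame with `onset`, `offset`,
#'   `label`).
#' @param truth Ground-truth [event_list()].
#' @param label Event label to score (default `"saccade"`).
#' @param max_onset_tolerance Maximum |onset difference| for a hit, seconds.
#' @return An object of class `match_report`: list with counts `n_truth`,
#'   `n_detected`, `n_hits`, `n_misses`, `n_false_alarms`, fractions
#'   `recall`, `precision`, the per-hit signed onset differences
#'   `onset_errors` (detected minus truth, seconds) and
#'   `mean_abs_onset_error` (seconds).
#' @export
match_events <- function(detected, truth, label = "saccade",
                         max_onset_tolerance = 0.010) {
  d <- as.data.frame(detected)
  g <- as.data.frame(truth)
  d <- d[d$label == label, , drop = FALSE]
  g <- g[g$label == label, , drop = FALSE]
  nd <- nrow(d); ng <- nrow(g)

  pairs <- NULL
  if (nd && ng) {
    gi <- rep(seq_len(ng), each = nd)
    di <- rep(seq_len(nd), times = ng)
    ov <- pmin(g$offset[gi], d$offset[di]) - pmax(g$onset[gi], d$onset[di])
    derr <- d$onset[di] - g$onset[gi]
    ok <- ov > 0 & abs(derr) <= max_onset_tolerance
    pairs <- data.frame(gi = gi[ok], di = di[ok], ov = ov[ok],
                        err = derr[ok])
    pairs <- pairs[order(-pairs$ov, g$onset[pairs$gi], d$onset[pairs$di]), ,
                   drop = FALSE]
  }
  used_g <- logical(ng); used_d <- logical(nd)
  errs <- numeric(0)
  if (!is.null(pairs) && nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      gi_ <- pairs$gi[r]; di_ <- pairs$di[r]
      if (!used_g[gi_] && !used_d[di_]) {
        used_g[gi_] <- TRUE; used_d[di_] <- TRUE
        errs <- c(errs, pairs$err[r])
      }
    }
  }
  n_hits <- sum(used_g)
  structure(list(
    label = label,
    n_truth = ng, n_detected = nd, n_hits = n_hits,
    n_misses = ng - n_hits, n_false_alarms = nd - n_hits,
    recall = if (ng) n_hits / ng else NA_real_,
    precision = if (nd) n_hits / nd else NA_real_,
    onset_errors = errs,
    mean_abs_onset_error = if (length(errs)) mean(abs(errs)) else NA_real_),
    class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report> label:", x$label, "\n")
  cat(sprintf("  truth %d | detected %d | hits %d | misses %d | false alarms %d\n",
              x$n_truth, x$n_detected, x$n_hits, x$n_misses,
              x$n_false_alarms))
  cat(sprintf("  recall %.3f | precision %.3f | mean |onset error| %s\n",
              x$recall, x$precision,
              if (is.na(x$mean_abs_onset_error)) "NA"
              else sprintf("%.2f ms", 1000 * x$mean_abs_onset_error)))
  invisible(x)
}

#' Compare per-trial event counts between two detectors
#'
#' For two detectors run on the same trials (e.g. video eye tracking vs
#' EOG), summarizes the per-trial saccade counts of each and of their
#' difference, optionally restricted to events of at least `min_amplitude`
#' (useful because uncalibrated recordings under-detect small saccades).
#'
#' @param trials_a,trials_b Lists of [event_list()]s, one per trial, same
#'   length and trial order.
#' @param min_amplitude Optional amplitude floor; events with `NA`
#'   amplitude are excluded when a floor is set.
#' @param label Event label to count.
#' @return List with `n_trials`, per-detector `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, the difference summary `mean_diff`, `sd_diff` (a minus b), and
#'   the per-trial `counts` data frame.
#' @export
compare_counts <- function(trials_a, trials_b, min_amplitude = NULL,
                           label = "saccade") {
  if (length(trials_a) != length(trials_b))
    stop("mismatched trial counts: ", length(trials_a), " vs ",
         length(trials_b))
  count1 <- function(ev) {
    df <- as.data.frame(ev)
    df <- df[df$label == label, , drop = FALSE]
    if (!is.null(min_amplitude))
      df <- df[!is.na(df$amplitude) & df$amplitude >= min_amplitude, ,
               drop = FALSE]
    nrow(df)
  }
  ca <- vapply(trials_a, count1, integer(1L))
  cb <- vapply(trials_b, count1, integer(1L))
  list(n_trials = length(ca),
       mean_a = mean(ca), sd_a = stats::sd(ca),
       mean_b = mean(cb), sd_b = stats::sd(cb),
       mean_diff = mean(ca - cb), sd_diff = stats::sd(ca - cb),
       counts = data.frame(trial = seq_along(ca), a = ca, b = cb,
                           diff = ca - cb))
}
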