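# Fixture builders and independent brute-force oracles used across tests.

make_trace <- function(x, y, fs = 500, units = "pixels", ppd = NULL,
                       pupil = NULL, modality = NULL, t = NULL) {
  n <- length(x)
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  gaze_trace(t, x, y, pupil = pupil, units = units, fs_nominal = fs,
             pix_per_degree = ppd, modality = modality)
}

# random fixation-and-jump style trace (no physiological structure needed)
random_trace <- function(n = 1000, fs = 500, seed = 1, na_frac = 0) {
  set.seed(seed)
  x <- cumsum(stats::rnorm(n)) + 500
  y <- cumsum(stats::rnorm(n)) + 300
  if (na_frac > 0) {
    ii <- sample.int(n, max(1L, round(na_frac * n)))
    x[ii] <- NA_real_
  }
  make_trace(x, y, fs = fs)
}

# per-sample loop version of the kinematics, straight from the definitions
oracle_kinematics <- function(trace, ppd = NULL) {
  t <- trace$t; x <- trace$x; y <- trace$y
  n <- length(t)
  d <- numeric(n - 1L); v <- numeric(n - 1L); a <- numeric(n - 2L)
  for (i in seq_len(n - 1L)) {
    d[i] <- sqrt((y[i + 1L] - y[i])^2 + (x[i + 1L] - x[i])^2)
    if (!is.null(ppd)) d[i] <- d[i] / ppd
    v[i] <- d[i] / (t[i + 1L] - t[i])
  }
  for (i in seq_len(n - 2L))
    a[i] <- (v[i + 1L] - v[i]) / (t[i + 1L] - t[i])
  list(d = d, v = v, a = a)
}

# brute-force run finder: scan for maximal stretches of TRUE
oracle_runs <- function(mask) {
  runs <- list()
  i <- 1L
  while (i <= length(mask)) {
    if (isTRUE(mask[i])) {
      j <- i
      while (j < length(mask) && isTRUE(mask[j + 1L])) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# smallest sample value whose cumulative fraction reaches the level
oracle_ecdf_quantile <- function(x, level) {
  s <- sort(x)
  for (q in s) if (mean(x <= q) >= level) return(q)
  stop("unreachable")
}

# minimal candidate data frame for event-stage tests
cand_df <- function(onset_t, offset_t, amplitude,
                    peak_velocity = 100, onset_index = NA_integer_,
                    offset_index = NA_integer_) {
  data.frame(onset_index = onset_index, offset_index = offset_index,
             onset_t = onset_t, offset_t = offset_t,
             amplitude = amplitude, duration = offset_t - onset_t,
             peak_velocity = peak_velocity,
             excursion = amplitude, touches_missing = FALSE)
}

expect_partition <- function(events, tol = 1e-9) {
  ext <- attr(events, "extent")
  df <- as.data.frame(events)
  df <- df[order(df$onset), ]
  expect_true(all(df$offset > df$onset))
  expect_equal(df$onset[1L], ext[1L], tolerance = tol)
  expect_equal(df$offset[nrow(df)], ext[2L], tolerance = tol)
  if (nrow(df) > 1L)
    expect_equal(df$onset[-1L], df$offset[-nrow(df)], tolerance = tol)
}
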