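mk_kin <- function(v, a, fs = 500) {
  structure(list(t = (0:length(v)) / fs, d = v / fs, v = v, a = a,
                 in_degrees = FALSE, units = "arbitrary"),
            class = "kinematic_series")
}

test_that("candidate labeling is inclusive and ORs velocity with either acceleration bound", {
  thr <- threshold_set(14.3, 4160, -5600)

  expect_equal(label_candidates(mk_kin(c(1, 20, 1), c(0, 0)), thr),
               c(FALSE, TRUE, FALSE))
  # sample with a = -6000 a.u./s^2 is a candidate on acceleration alone
  expect_equal(label_candidates(mk_kin(c(1, 1, 1), c(-6000, 0)), thr),
               c(TRUE, FALSE, FALSE))
  expect_equal(label_candidates(mk_kin(c(1, 1, 1), c(0, 5000)), thr),
               c(FALSE, TRUE, FALSE))
  # everything strictly inside the thresholds -> no candidates
  expect_false(any(label_candidates(
    mk_kin(c(14.2, 10, 0.1), c(4159, -5599)), thr)))
  # equality counts ("equal to or above")
  expect_equal(label_candidates(mk_kin(c(14.3, 1, 1), c(0, 0)), thr)[1L], TRUE)
  expect_equal(label_candidates(mk_kin(c(1, 1, 1), c(4160, -5600)), thr),
               c(TRUE, TRUE, FALSE))
  # the last interval has no acceleration: judged on velocity only
  expect_equal(label_candidates(mk_kin(c(1, 1, 99), c(0, 0)), thr),
               c(FALSE, FALSE, TRUE))
  # missing kinematics are never candidates
  expect_equal(label_candidates(mk_kin(c(NA, 99, NA), c(NA, NA)), thr),
               c(FALSE, TRUE, FALSE))
})

test_that("grouping returns maximal runs with onset/offset samples and metrics", {
  tr <- make_trace(x = c(0, 1, 3, 6, 6, 8, 8), y = rep(0, 7))
  k <- kinematics(tr)
  cands <- group_candidates(c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE), tr, k)
  expect_equal(nrow(cands), 2L)
  expect_equal(cands$onset_index, c(2L, 5L))
  expect_equal(cands$offset_index, c(4L, 6L))
  expect_equal(cands$amplitude, c(5, 2))          # x: 1 -> 6 and 6 -> 8
  expect_equal(cands$duration, c(0.004, 0.002))
  expect_equal(cands$peak_velocity, c(1500, 1000))

  expect_equal(nrow(group_candidates(rep(FALSE, 6), tr, k)), 0L)
  all_on <- group_candidates(rep(TRUE, 6), tr, k)
  expect_equal(nrow(all_on), 1L)
  expect_equal(c(all_on$onset_index, all_on$offset_index), c(1L, 7L))
})

test_that("grouping matches a brute-force run-length oracle on random masks", {
  set.seed(77)
  tr <- random_trace(n = 201, seed = 77)
  k <- kinematics(tr)
  for (rep in 1:50) {
    mask <- runif(200) < runif(1, 0.1, 0.9)
    cands <- group_candidates(mask, tr, k)
    runs <- oracle_runs(mask)
    expect_equal(nrow(cands), length(runs))
    if (length(runs)) {
      expect_equal(cands$onset_index, vapply(runs, `[`, integer(1L), 1L))
      expect_equal(cands$offset_index,
                   vapply(runs, `[`, integer(1L), 2L) + 1L)
      # intervals are maximal: no two runs touch
      if (nrow(cands) > 1L)
        expect_true(all(cands$onset_index[-1L] >
                          cands$offset_index[-nrow(cands)]))
    }
  }
})

test_that("raising the velocity threshold never adds candidate samples", {
  set.seed(13)
  v <- rgamma(500, 2, 0.1); a <- rnorm(499, 0, 50)
  k <- mk_kin(v, a)
  a_pos <- ecdf_quantile(a[a > 0], 0.9); a_neg <- -ecdf_quantile(-a[a < 0], 0.9)
  counts <- sapply(seq(1, 60, by = 2), function(vt)
    sum(label_candidates(k, threshold_set(vt, a_pos, a_neg))))
  expect_true(all(diff(counts) <= 0))
})

test_that("each candidate reaches the velocity threshold or crosses an acceleration bound", {
  st <- simulate_trace(sim_config(duration = 5, seed = 14))
  k <- kinematics(st$trace)
  thr <- suggest_thresholds(k)
  mask <- label_candidates(k, thr)
  cands <- group_candidates(mask, st$trace, k)
  for (i in seq_len(nrow(cands))) {
    ii <- cands$onset_index[i]:(cands$offset_index[i] - 1L)
    acc_ii <- ii[ii <= length(k$a)]
    acc_cross <- any(k$a[acc_ii] >= thr$a_pos | k$a[acc_ii] <= thr$a_neg,
                     na.rm = TRUE)
    expect_true(cands$peak_velocity[i] >= thr$v_thr || acc_cross)
  }
})
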