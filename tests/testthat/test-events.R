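test_that("the short-saccade filter removes small-or-brief candidates, keeping the boundary", {
  cands <- rbind(
    cand_df(0.10, 0.12, amplitude = 0.05),   # 20 ms but tiny -> removed
    cand_df(0.20, 0.203, amplitude = 1.0),   # 3 ms -> removed
    cand_df(0.30, 0.33, amplitude = 1.0),    # comfortable -> kept
    cand_df(0.40, 0.404, amplitude = 0.1))   # exactly 0.1 deg & 4 ms -> kept
  out <- filter_short_saccades(cands)
  expect_equal(out$onset_t, c(0.30, 0.40))

  # NA amplitude bound = duration-only filtering (uncalibrated traces)
  out2 <- filter_short_saccades(cands, min_amplitude = NA)
  expect_equal(out2$onset_t, c(0.10, 0.30, 0.40))
})

test_that("overshoot merging obeys the strict 16 ms gap and inclusive 1.5 deg bounds", {
  pair <- function(gap, amp2) rbind(
    cand_df(0.100, 0.140, amplitude = 5, peak_velocity = 300),
    cand_df(0.140 + gap, 0.150 + gap, amplitude = amp2, peak_velocity = 80))

  m <- merge_overshoots(pair(0.010, 1.0))
  expect_equal(nrow(m), 1L)
  expect_true(m$overshoot)
  expect_equal(m$offset_t, 0.160)
  expect_equal(m$peak_velocity, 300)

  expect_equal(nrow(merge_overshoots(pair(0.016, 1.0))), 2L)   # gap == 16 ms: strict
  expect_equal(nrow(merge_overshoots(pair(0.0159, 1.5))), 1L)  # amp == 1.5: inclusive
  expect_equal(nrow(merge_overshoots(pair(0.010, 1.51))), 2L)
  expect_false(any(merge_overshoots(pair(0.020, 1.0))$overshoot))

  # gap-only merging when no amplitude cap is available (uncalibrated data)
  expect_equal(nrow(merge_overshoots(pair(0.010, 8),
                                     max_second_amplitude = NA)), 1L)

  single <- cand_df(0.1, 0.14, amplitude = 5)
  expect_equal(merge_overshoots(single)$onset_t, 0.1)
})

test_that("a merged saccade can merge again with its successor", {
  triple <- rbind(
    cand_df(0.100, 0.140, amplitude = 6, peak_velocity = 300),
    cand_df(0.150, 0.160, amplitude = 1.0, peak_velocity = 90),
    cand_df(0.170, 0.180, amplitude = 0.8, peak_velocity = 70))
  m <- merge_overshoots(triple)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$onset_t, m$offset_t), c(0.100, 0.180))
  expect_true(m$overshoot)
})

test_that("merged amplitude is recomputed from the endpoint gaze positions", {
  # saccade 0->10 deg then 1 deg back: merged amplitude is the net 9 deg
  ppd <- 10
  x <- c(0, 0, 50, 100, 100, 100, 90, 90) # px; ppd=10 -> 0..10..9 deg
  tr <- make_trace(x, rep(0, 8), ppd = ppd)
  cands <- rbind(
    cand_df(tr$t[2], tr$t[4], amplitude = 10, onset_index = 2L,
            offset_index = 4L),
    cand_df(tr$t[6], tr$t[7], amplitude = 1, onset_index = 6L,
            offset_index = 7L))
  m <- merge_overshoots(cands, trace = tr, in_degrees = TRUE)
  expect_equal(nrow(m), 1L)
  expect_equal(m$amplitude, 9)
})

test_that("fixations are exactly the residual periods and edge events are truncated", {
  # nothing detected: one fixation spanning the extent, truncated both ends
  ev <- define_fixations(NULL, NULL, extent = c(0, 3))
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$label, "fixation")
  expect_true(ev$truncated)
  expect_partition(ev)

  # one saccade mid-trace -> fixation, saccade, fixation
  sacc <- cand_df(1.0, 1.05, amplitude = 5)
  ev2 <- define_fixations(sacc, NULL, extent = c(0, 3))
  expect_identical(ev2$label, c("fixation", "saccade", "fixation"))
  expect_equal(ev2$truncated, c(TRUE, FALSE, TRUE))
  expect_partition(ev2)

  # saccade immediately followed by a blink: no zero-length fixation between
  blink <- data.frame(onset_t = 1.05, offset_t = 1.4)
  ev3 <- define_fixations(sacc, blink, extent = c(0, 3))
  expect_identical(ev3$label, c("fixation", "saccade", "blink", "fixation"))
  expect_partition(ev3)

  # overlapping inputs are rejected, naming the pair
  bad_blink <- data.frame(onset_t = 1.02, offset_t = 1.4)
  expect_error(define_fixations(sacc, bad_blink, extent = c(0, 3)),
               "overlapping")
})

test_that("detect() is deterministic and recovers a fixed simulated trace exactly", {
  st <- simulate_trace(sim_config(duration = 3, seed = 42))
  ev1 <- detect(st$trace)
  ev2 <- detect(st$trace)
  expect_identical(serialize(ev1, NULL), serialize(ev2, NULL))

  big <- st$truth[st$truth$label == "saccade" & st$truth$amplitude >= 1, ,
                  drop = FALSE]
  m <- match_events(ev1, event_list(big, attr(st$truth, "extent")))
  expect_gt(m$n_truth, 0L)
  expect_equal(m$n_hits, m$n_truth)                  # every injected saccade
  expect_equal(sum(ev1$label == "saccade"), m$n_truth)  # and nothing else
})

test_that("a trace with no injected saccades and sub-threshold noise detects none", {
  st <- simulate_trace(sim_config(duration = 3, seed = 5, fixation_rate = 0))
  expect_equal(sum(st$truth$label == "saccade"), 0L)
  ev <- detect(st$trace)
  expect_equal(sum(ev$label == "saccade"), 0L)
})

test_that("overshoot merge order relative to the short filter is configurable", {
  st <- simulate_trace(sim_config(duration = 5, seed = 21,
                                  overshoot_prob = 1))
  ev_after <- detect(st$trace)
  ev_before <- detect(st$trace,
                      safide_params(overshoot.before_filter = TRUE))
  # both orders give valid partitions over the same extent
  expect_partition(ev_after)
  expect_partition(ev_before)
  expect_true(any(ev_after$overshoot))
})
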