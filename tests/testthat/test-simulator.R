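test_that("the simulator is deterministic in its seed, and trials differ", {
  cfg <- sim_config(duration = 2, seed = 33)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$trace$x, b$trace$x)
  expect_identical(a$trace$pupil, b$trace$pupil)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))

  s1 <- simulate_session(cfg, 3)
  s2 <- simulate_session(cfg, 3)
  expect_identical(s1[[2L]]$trace$x, s2[[2L]]$trace$x)
  expect_false(identical(s1[[1L]]$trace$x, s1[[2L]]$trace$x))
})

test_that("ground truth partitions every trace, across modalities", {
  for (mod in c("video", "eog", "coil")) {
    st <- simulate_trace(sim_config(duration = 4, seed = 17, modality = mod))
    expect_partition(st$truth)
    expect_length(st$trace$t, 4 * 500 + 1)
    # no two adjacent fixations
    lab <- st$truth$label
    expect_false(any(lab[-1L] == "fixation" & lab[-length(lab)] == "fixation"))
    if (mod == "coil") {
      expect_null(st$trace$pupil)
      expect_equal(sum(st$truth$label == "blink"), 0L)
    }
  }
})

test_that("saccade counts follow the renewal expectation of the configured statistics", {
  cfg <- sim_config(duration = 60, seed = 1)
  st <- simulate_trace(cfg)
  n_sacc <- sum(st$truth$label == "saccade")

  # closed-form expectation: cycle = fixation + movement, movement a
  # blink/saccade mixture, all from the configured means
  a_lo <- cfg$saccade_amplitude_range[1L]; a_hi <- cfg$saccade_amplitude_range[2L]
  mean_D <- integrate(function(a)
    pi * a / (2 * pmax(cfg$main_sequence_floor, cfg$main_sequence_slope * a)),
    a_lo, a_hi)$value / (a_hi - a_lo)
  os_lo <- cfg$overshoot_amplitude_range[1L]
  os_hi <- cfg$overshoot_amplitude_range[2L]
  mean_os <- cfg$overshoot_prob *
    (0.009 + pi * mean(c(os_lo, os_hi)) / (2 * cfg$main_sequence_floor))
  p_blink <- min(0.9, cfg$blink_rate / 60 * (cfg$fixation_duration_mean + 0.045))
  cycle <- cfg$fixation_duration_mean +
    (1 - p_blink) * (mean_D + mean_os) +
    p_blink * mean(cfg$blink_duration_range)
  expected <- (1 - p_blink) * cfg$duration / cycle

  expect_gte(n_sacc, 0.8 * expected)
  expect_lte(n_sacc, 1.2 * expected)
  # and the count never exceeds the nominal fixation-rate budget
  expect_lte(n_sacc, 1.2 * cfg$fixation_rate * cfg$duration)
})

test_that("fixation durations average near the configured mean on long traces", {
  st <- simulate_trace(sim_config(duration = 120, seed = 1))
  fx <- st$truth[st$truth$label == "fixation", ]
  expect_equal(mean(fx$duration), 0.30, tolerance = 0.10)
})

test_that("generated saccades obey the configured main-sequence relation within 5%", {
  cfg <- sim_config(duration = 20, seed = 2, noise_sd = 0, drift_sd = 0,
                    overshoot_prob = 0, blink_rate = 0)
  st <- simulate_trace(cfg)
  k <- kinematics(st$trace)
  ts <- st$truth[st$truth$label == "saccade", ]
  expect_gt(nrow(ts), 30L)
  meas <- vapply(seq_len(nrow(ts)), function(i) {
    ii <- which(st$trace$t >= ts$onset[i] & st$trace$t < ts$offset[i])
    max(k$v[ii[-length(ii)]], na.rm = TRUE)
  }, numeric(1L))
  target <- pmax(cfg$main_sequence_floor,
                 cfg$main_sequence_slope * ts$amplitude)
  # regression check: sampled peak velocity tracks the configured relation
  # (individual short saccades can read a few % low from sampling phase)
  fit <- stats::lm(meas ~ 0 + target)
  expect_equal(unname(coef(fit)), 1, tolerance = 0.05)
  expect_equal(mean(meas / target), 1, tolerance = 0.05)
  expect_equal(meas, ts$peak_velocity, tolerance = 0.11)
})

test_that("video blinks appear as pupil gaps with ramps; truth blinks cover them", {
  st <- simulate_trace(sim_config(duration = 20, seed = 6, blink_rate = 20))
  tb <- st$truth[st$truth$label == "blink", ]
  expect_gt(nrow(tb), 0L)
  gaps <- is.na(st$trace$pupil)
  expect_true(any(gaps))
  # every missing pupil sample lies inside some truth blink
  tt <- st$trace$t[gaps]
  inside <- vapply(tt, function(z)
    any(z >= tb$onset - 1e-9 & z <= tb$offset + 1e-9), logical(1L))
  expect_true(all(inside))
})
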