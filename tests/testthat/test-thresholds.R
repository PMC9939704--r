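test_that("ecdf_quantile is the type-1 inverse ECDF", {
  expect_equal(ecdf_quantile(1:100, 0.85), 85)
  expect_equal(ecdf_quantile(c(1, 2, 3), 0.5), 2)
  expect_equal(ecdf_quantile(rep(7.7, 50), 0.3), 7.7)
  expect_error(ecdf_quantile(numeric(0), 0.5), "no finite samples")
  expect_error(ecdf_quantile(1:10, 1), "fraction")

  set.seed(5)
  x <- rgamma(333, shape = 1.2)            # long-tailed, like real velocities
  for (lv in c(0.1, 0.5, 0.85, 0.9, 0.99)) {
    q <- ecdf_quantile(x, lv)
    expect_identical(q, oracle_ecdf_quantile(x, lv))
    expect_true(q %in% x)                  # always an observed sample
    expect_gte(mean(x <= q), lv)           # reaches the level...
    smaller <- max(x[x < q])
    expect_lt(mean(x <= smaller), lv)      # ...and is the smallest that does
  }
  qs <- sapply(seq(0.05, 0.95, by = 0.05), function(l) ecdf_quantile(x, l))
  expect_true(all(diff(qs) >= 0))          # monotone in the level
})

test_that("suggested thresholds sit at the 85%/90% accumulation by default and per sign", {
  set.seed(9)
  n <- 20000
  v <- rgamma(n, shape = 1.5, rate = 0.5)
  a <- c(rnorm(n / 2, 4, 1), -rnorm(n / 2, 6, 2))   # asymmetric by sign
  k <- structure(list(t = numeric(0), d = v, v = v,
                      a = a, in_degrees = FALSE, units = "arbitrary"),
                 class = "kinematic_series")
  thr <- suggest_thresholds(k)
  expect_identical(thr$source, "suggested")
  expect_identical(thr$v_thr, oracle_ecdf_quantile(v, 0.85))
  expect_identical(thr$a_pos, oracle_ecdf_quantile(a[a > 0], 0.90))
  expect_identical(thr$a_neg, -oracle_ecdf_quantile(-a[a < 0], 0.90))
  expect_true(thr$a_neg < 0 && thr$a_pos > 0)

  # symmetric acceleration distribution gives near-symmetric thresholds
  a_sym <- c(a[a > 0], -a[a > 0])
  k2 <- k; k2$a <- a_sym
  thr2 <- suggest_thresholds(k2)
  expect_equal(thr2$a_pos, -thr2$a_neg, tolerance = 0.01)
})

test_that("velocity threshold of a large uniform sample is close to the level itself", {
  set.seed(10)
  v <- runif(1e5)
  k <- structure(list(t = numeric(0), d = v, v = v,
                      a = c(rnorm(5e4), -rnorm(5e4)),
                      in_degrees = FALSE, units = "arbitrary"),
                 class = "kinematic_series")
  thr <- suggest_thresholds(k)
  expect_equal(thr$v_thr, 0.85, tolerance = 0.01)
})

test_that("threshold suggestion is scale-equivariant and rejects degenerate input", {
  set.seed(11)
  v <- rgamma(500, 2); a <- rnorm(499)
  k <- structure(list(t = numeric(0), d = v, v = v, a = a,
                      in_degrees = FALSE, units = "arbitrary"),
                 class = "kinematic_series")
  thr <- suggest_thresholds(k)
  k10 <- k; k10$v <- 10 * v; k10$a <- 10 * a
  thr10 <- suggest_thresholds(k10)
  expect_equal(thr10$v_thr, 10 * thr$v_thr)
  expect_equal(thr10$a_pos, 10 * thr$a_pos)
  expect_equal(thr10$a_neg, 10 * thr$a_neg)

  k_small <- k; k_small$v <- v[1:5]; k_small$a <- a[1:4]
  expect_error(suggest_thresholds(k_small), "at least 10")
  k_onesign <- k; k_onesign$a <- abs(a)
  expect_error(suggest_thresholds(k_onesign), "one sign")
})

test_that("histogram summary conserves counts and brackets the thresholds", {
  set.seed(12)
  v <- rgamma(2000, 2); a <- c(rnorm(1000), -2 * rnorm(999))
  k <- structure(list(t = numeric(0), d = v, v = v, a = a,
                      in_degrees = FALSE, units = "arbitrary"),
                 class = "kinematic_series")
  thr <- suggest_thresholds(k)
  h <- histogram_summary(k, thr)
  expect_equal(sum(h$velocity$counts), length(v))
  expect_equal(sum(h$acceleration$counts), length(a))
  expect_true(thr$v_thr >= min(v) && thr$v_thr <= max(v))
  expect_true(thr$a_pos <= max(a) && thr$a_neg >= min(a))
})
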