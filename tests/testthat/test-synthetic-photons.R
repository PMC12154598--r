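test_that("arrival-time sampling is seeded, empty-safe and validated", {
  m <- decay_model(PAD = 0.3, calibration = cal_rab10_egfp)
  expect_length(sample_arrival_times(m, 0, seed = 1), 0)
  a <- sample_arrival_times(m, 5000, seed = 7)
  b <- sample_arrival_times(m, 5000, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, sample_arrival_times(m, 5000, seed = 8)))
  expect_error(sample_arrival_times(m, -5, seed = 1), "non-negative")
  # sampling must not disturb the caller's RNG stream
  set.seed(123); r1 <- runif(1)
  set.seed(123); invisible(sample_arrival_times(m, 10, seed = 1))
  expect_identical(runif(1), r1)
})

test_that("sample mean matches the photon-weighted mixture moment", {
  # single component, no IRF, no window: mean is tauD
  m <- decay_model(PAD = 0, tauD = 2.46, tauAD = 1.10, t0 = 0, tauG = 0)
  t <- sample_arrival_times(m, 1e6, seed = 2, period = Inf)
  expect_lt(abs(mean(t) - 2.46), 3 * 2.46 / sqrt(1e6))
  # mixture: amplitude-weighted second moment over first moment
  for (pad in c(0.25, 0.6)) {
    m2 <- decay_model(PAD = pad, tauD = 2.6, tauAD = 1.1, t0 = 0.5,
                      tauG = 0)
    t2 <- sample_arrival_times(m2, 1e6, seed = 3, period = Inf)
    expected <- 0.5 + mixture_mean_lifetime(pad, cal_rab10_egfp)
    sd_theory <- sd(t2)  # close enough for an SE scale
    expect_lt(abs(mean(t2) - expected), 3 * sd_theory / sqrt(1e6))
  }
})

test_that("windowing wraps photons by default and clips on request", {
  m <- decay_model(PAD = 0, tauD = 4.15, tauAD = 1.6, t0 = 1.2, tauG = 0.2)
  tw <- sample_arrival_times(m, 2e4, seed = 4, period = 12.5)
  expect_length(tw, 2e4)             # wrap conserves photons
  expect_true(all(tw >= 0 & tw < 12.5))
  tc <- sample_arrival_times(m, 2e4, seed = 4, period = 12.5, clip = TRUE)
  expect_lt(length(tc), 2e4)         # ~7% of this slow decay leaves window
  expect_equal(length(tc) + attr(tc, "n_clipped"), 2e4)
})

test_that("histogram construction conserves counts and bins correctly", {
  h0 <- build_histogram(numeric(0), 256, 12.5)
  expect_true(all(h0$counts == 0))
  # two channels split the period at 6.25 ns
  h <- build_histogram(c(1.0, 1.0, 7.0), n_channels = 2, period = 12.5)
  expect_equal(h$counts, c(2, 1))
  expect_equal(h$channel_centers, c(3.125, 9.375))
  expect_equal(build_histogram(c(1.0, 1.0, 6.0), 2, 12.5)$counts, c(3, 0))
  # totals equal in-window photons
  m <- decay_model(PAD = 0.3, calibration = cal_rab10_egfp)
  t <- sample_arrival_times(m, 12345, seed = 5)
  expect_equal(sum(build_histogram(t)$counts), 12345)
})

test_that("simulated histogram matches the expected curve (chi-square)", {
  m <- decay_model(PAD = 0.3, calibration = cal_rab10_egfp, t0 = 1.2,
                   tauG = 0.2)
  n <- 1e5
  h <- simulate_histogram(m, n, seed = 6)
  expected <- model_curve(h$channel_centers, m, period = h$period,
                          wrap_periods = 3)
  expected <- expected / sum(expected) * n
  keep <- expected >= 5
  chi2 <- sum((h$counts[keep] - expected[keep])^2 / expected[keep])
  dof <- sum(keep)
  expect_gt(chi2 / dof, 0.8)
  expect_lt(chi2 / dof, 1.25)
})

test_that("mean arrival time implements the discrete first moment", {
  h <- photon_histogram(c(0, 0, 5, 0), period = 4)  # all mass at 2.5 ns
  expect_equal(mean_arrival_time(h), 2.5)
  h2 <- photon_histogram(c(0, 3, 0, 3), period = 8)  # 3 ns and 7 ns
  expect_equal(mean_arrival_time(h2), 5)
  expect_error(mean_arrival_time(photon_histogram(c(0, 0), period = 4)),
               "no photons")
})

test_that("pooling histograms adds counts channel-wise", {
  m <- decay_model(PAD = 0.2, calibration = cal_rab10_egfp)
  h1 <- simulate_histogram(m, 2000, seed = 10)
  h2 <- simulate_histogram(m, 3000, seed = 11)
  pooled <- pool_histograms(h1, h2)
  expect_equal(pooled$counts, h1$counts + h2$counts)
  expect_equal(mean_arrival_time(pooled),
               (2000 * mean_arrival_time(h1) + 3000 * mean_arrival_time(h2))
               / 5000, tolerance = 1e-12)
  h3 <- simulate_histogram(m, 1000, seed = 12, n_channels = 128)
  expect_error(pool_histograms(h1, h3), "share")
})
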