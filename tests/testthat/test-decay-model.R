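test_that("IRF-convolved exponential reduces to a plain exponential", {
  t <- seq(0, 12, by = 0.25)
  t0 <- 1.0
  tau <- 2.6
  # tauG = 0 exactly
  expect_equal(irf_convolved_exponential(t0 + tau, t0, tau, 0), exp(-1))
  expect_equal(irf_convolved_exponential(0.5, t0, tau, 0), 0)
  # tauG -> 0+ converges pointwise for t > t0
  h_small <- irf_convolved_exponential(t0 + tau, t0, tau, 1e-5)
  expect_equal(h_small, exp(-1), tolerance = 1e-6)
  # long before the pulse the curve vanishes
  expect_lt(irf_convolved_exponential(t0 - 1, t0, tau, 0.2), 1e-6)
  expect_error(irf_convolved_exponential(NaN, t0, tau, 0.2), "finite")
})

test_that("H(t) matches quadrature convolution to 1e-6 relative", {
  t0 <- 1.0
  t <- seq(t0 - 1, t0 + 10, by = 0.25)
  for (tauG in c(0.05, 0.2, 0.5)) {
    for (tau in c(1.10, 2.60)) {
      a <- irf_convolved_exponential(t, t0, tau, tauG)
      b <- quadrature_H(t, t0, tau, tauG)
      rel <- abs(a - b) / pmax(abs(b), 1e-12)
      expect_lt(max(rel[b > 1e-12]), 1e-6)
    }
  }
})

test_that("H is numerically stable far before the pulse (large erfc args)", {
  # literal evaluation overflows here; the scaled form must return ~0
  h <- irf_convolved_exponential(c(-50, -10, -5), 1.2, 1.1, 0.05)
  expect_true(all(is.finite(h)))
  expect_true(all(h >= 0 & h < 1e-10))
})

test_that("model_curve is linear in the component mixture", {
  cal <- cal_rab10_egfp
  centers <- seq(0.025, 12.475, by = 0.05)
  m_mix <- decay_model(PAD = 0.3, calibration = cal, t0 = 1.2, tauG = 0.2)
  m_d <- decay_model(PAD = 0, calibration = cal, t0 = 1.2, tauG = 0.2)
  m_ad <- decay_model(PAD = 1, calibration = cal, t0 = 1.2, tauG = 0.2)
  y <- model_curve(centers, m_mix)
  expect_equal(y, 0.7 * model_curve(centers, m_d) +
                 0.3 * model_curve(centers, m_ad))
  expect_true(all(y >= 0))
  # pure-component limits collapse to a single H
  expect_equal(model_curve(centers, m_d),
               irf_convolved_exponential(centers, 1.2, cal$tauD, 0.2))
})

test_that("mixture mean lifetime and closed-form inversion round trip", {
  pads <- seq(0, 1, length.out = 101)
  cals <- c(calibration_presets(),
            list(flim_calibration(tauD = 4.15, tauAD = 1.10)))
  for (cal in cals) {
    mt <- mixture_mean_lifetime(pads, cal)
    back <- binding_fraction_from_mean_lifetime(mt, cal)
    expect_lt(max(abs(as.numeric(back) - pads)), 1e-9)
    expect_equal(mixture_mean_lifetime(0, cal), cal$tauD)
    expect_equal(mixture_mean_lifetime(1, cal), cal$tauAD)
  }
  # hand-checked values
  cal <- cal_rab10_egfp
  expect_equal(mixture_mean_lifetime(0.5, cal), 3.985 / 1.85,
               tolerance = 1e-12)
  expect_equal(as.numeric(binding_fraction_from_mean_lifetime(2.0, cal)),
               2.6 * 0.6 / (1.5 * 1.7), tolerance = 1e-12)
})

test_that("binding fraction is strictly decreasing in mean lifetime", {
  set.seed(42)
  for (i in 1:25) {
    tauAD <- runif(1, 0.5, 3)
    tauD <- tauAD + runif(1, 0.3, 3)
    cal <- flim_calibration(tauD = tauD, tauAD = tauAD)
    mt <- seq(tauAD + 1e-4, tauD - 1e-4, length.out = 200)
    p <- as.numeric(binding_fraction_from_mean_lifetime(mt, cal))
    expect_true(all(diff(p) < 0))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("out-of-range mean lifetimes are clamped with a flag", {
  cal <- cal_rab10_egfp
  p <- binding_fraction_from_mean_lifetime(c(2.8, 2.0, 0.9), cal)
  expect_equal(as.numeric(p), c(0, 0.611764705882353, 1),
               tolerance = 1e-12)
  expect_equal(attr(p, "clamped"), c(TRUE, FALSE, TRUE))
  # singular point is an error, never silently clamped
  expect_error(
    binding_fraction_from_mean_lifetime(cal$tauD + cal$tauAD, cal),
    "singular")
})

test_that("model constructors validate their invariants", {
  expect_error(decay_model(PAD = 1.2, tauD = 2.6, tauAD = 1.1), "PAD")
  expect_error(decay_model(PAD = 0.5, tauD = -1, tauAD = 1.1), "positive")
  expect_error(flim_calibration(tauD = 1.0, tauAD = 2.0), "smaller")
  expect_error(flim_calibration("nope"), "valid presets")
  pres <- calibration_presets()
  expect_setequal(vapply(pres, `[[`, 0, "tauD"), c(2.46, 2.60, 4.15))
  expect_setequal(vapply(pres, `[[`, 0, "tauAD"), c(1.10, 1.10, 1.60))
})
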