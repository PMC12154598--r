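test_that("spine volume estimator is exact for the rendered scene", {
  # noiseless render: recovery should be essentially exact
  ser <- small_series(seed = 51, n_frames = 4, photons = 1e4,
                      intensity_noise_sd = 0)
  ve <- estimate_spine_volume(ser$frames[[1]]$intensity_acceptor,
                              ser$masks == 2, ser$masks == 1,
                              psf_volume = 0.08, pixel_size = 0.125)
  expect_equal(ve$volume, 0.10, tolerance = 1e-6)
  # zero spine intensity -> zero volume
  img0 <- ser$frames[[1]]$intensity_acceptor
  img0[ser$masks == 2] <- 0
  ve0 <- estimate_spine_volume(img0, ser$masks == 2, ser$masks == 1,
                               0.08, 0.125)
  expect_equal(ve0$volume, 0)
  # linearity: doubling spine pixels doubles the volume exactly
  img2 <- ser$frames[[1]]$intensity_acceptor
  img2[ser$masks == 2] <- 2 * img2[ser$masks == 2]
  ve2 <- estimate_spine_volume(img2, ser$masks == 2, ser$masks == 1,
                               0.08, 0.125)
  expect_equal(ve2$volume, 2 * ve$volume, tolerance = 1e-12)
  expect_error(estimate_spine_volume(img0 * 0, ser$masks == 2,
                                     ser$masks == 1, 0.08, 0.125),
               "zero")
})

test_that("volume change timecourse is exact arithmetic on the summed channel", {
  ser <- small_series(seed = 52, n_frames = 6, photons = 1e4,
                      intensity_noise_sd = 0)
  # overwrite the acceptor channel with a hand-made x3.5 step at t >= 0
  for (k in seq_along(ser$frames)) {
    f <- if (ser$frames[[k]]$time_min >= 0) 3.5 else 1
    ser$frames[[k]]$intensity_acceptor <-
      matrix(f, 32, 32)
  }
  tc <- volume_change_timecourse(ser, ser$masks == 2)
  expect_equal(tc$value[tc$time_min < 0], rep(0, sum(tc$time_min < 0)))
  expect_equal(tc$value[tc$time_min >= 0],
               rep(2.5, sum(tc$time_min >= 0)), tolerance = 1e-12)
  # scale invariance of the ratio
  for (k in seq_along(ser$frames)) {
    ser$frames[[k]]$intensity_acceptor <-
      ser$frames[[k]]$intensity_acceptor * 77
  }
  expect_equal(volume_change_timecourse(ser, ser$masks == 2)$value,
               tc$value, tolerance = 1e-12)
})

test_that("phase summaries: windows, endpoints, errors", {
  tc <- data.frame(time_min = seq(-2, 35, by = 1 / 3), value = 1.7)
  s <- summarize_phases(tc)
  expect_equal(s$transient_mean, 1.7)
  expect_equal(s$sustained_mean, 1.7)
  expect_equal(s$transient_sem, 0)
  # piecewise trace: 2.5 on [0,5], 0.8 after
  tc2 <- data.frame(time_min = seq(0, 35, by = 0.5),
                    value = ifelse(seq(0, 35, by = 0.5) <= 5, 2.5, 0.8))
  s2 <- summarize_phases(tc2)
  expect_equal(s2$transient_mean, 2.5)
  expect_equal(s2$sustained_mean, 0.8)
  # closed windows include endpoint frames
  tc3 <- data.frame(time_min = c(0, 1.3, 4, 19, 31), value = 1:5)
  s3 <- summarize_phases(tc3)
  expect_equal(s3$n_transient, 2L)   # t = 1.3 and t = 4
  expect_equal(s3$n_sustained, 2L)   # t = 19 and t = 31
  # order within a window is irrelevant
  perm <- tc2[sample(nrow(tc2)), ]
  expect_equal(summarize_phases(perm)$transient_mean, 2.5)
  # NA frames are dropped and reduce n, never interpolated
  tc4 <- tc2
  tc4$value[tc4$time_min == 2] <- NA
  expect_equal(summarize_phases(tc4)$n_transient, s2$n_transient - 1L)
  expect_error(summarize_phases(tc2, sustained_window = c(50, 60)),
               "sustained window")
  expect_error(summarize_phases(tc2, transient_window = c(1, 20)),
               "overlap")
})

test_that("group summary computes mean, SEM and a calibrated t-test", {
  g <- group_summary(lapply(c(1, 2, 3), fake_summary))
  expect_equal(g$groups$mean, c(2, 2))
  expect_equal(g$groups$sem, rep(sd(1:3) / sqrt(3), 2), tolerance = 1e-12)
  g0 <- group_summary(lapply(c(2, 2, 2), fake_summary))
  expect_equal(g0$groups$sem, c(0, 0))
  expect_error(group_summary(list(fake_summary(1))), "at least 2")
  # two groups: t-test output matches stats::t.test
  s1 <- lapply(c(1, 2, 3, 4), fake_summary)
  s2 <- lapply(c(2, 3, 4, 6), fake_summary)
  g2 <- group_summary(s1, s2)
  tt <- t.test(c(1, 2, 3, 4), c(2, 3, 4, 6), var.equal = TRUE)
  expect_equal(g2$tests$p_value[1], tt$p.value)
  # type-I error calibration under the null
  set.seed(99)
  rej <- mean(replicate(1000, {
    a <- lapply(rnorm(6), fake_summary)
    b <- lapply(rnorm(6), fake_summary)
    group_summary(a, b)$tests$p_value[1] < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.075)
})

test_that("binding-fraction timecourse recovers preset dynamics", {
  ser <- small_series(seed = 53, n_frames = 12, photons = 2e5)
  tc <- binding_fraction_timecourse(ser, ser$masks == 2, t0 = 1.2,
                                    roi_label = "spine_stim")
  post <- tc$time_min >= 1
  expect_lt(mean(tc$value[post]), -0.05)
  expect_lt(abs(attr(tc, "baseline_PAD") - 0.25), 0.03)
  # adjacent spine stays put
  tca <- binding_fraction_timecourse(ser, ser$masks == 3, t0 = 1.2)
  expect_lt(abs(mean(tca$value[post])), 0.05)
})
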