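test_that("scene and profile constructors enforce their invariants", {
  expect_error(sim_scene(structures = list(
    a = list(label = "dendrite", center = c(0.1, 2), radii = c(1, 0.3),
             volume = 1))), "outside the grid")
  expect_error(sim_scene(structures = list(
    a = list(label = "dendrite", center = c(2, 2), radii = c(1, 0.3),
             volume = -1),
    b = list(label = "spine_stim", center = c(2, 1), radii = c(0.2, 0.2),
             volume = 0.1))), "> 0")
  tms <- default_times <- c(-2, -1.5, -1, 0, 1)
  expect_error(dynamics_profile(
    tms, list(a = rep(2, 5)), list(a = rep(1, 5))), "\\[0, 1\\]")
  expect_error(dynamics_profile(
    tms, list(a = rep(0.5, 5)), list(a = c(2, 1, 1, 1, 1))),
    "before the stimulus")
  expect_error(dynamics_profile(
    c(-1, 0, 1, 2), list(a = rep(0.5, 4)), list(a = rep(1, 4))),
    "baseline")
  # preset shapes: persistent step stays down; transient pulse decays
  p10 <- profile_rab10()
  stim10 <- p10$binding_fraction$spine_stim
  expect_true(all(stim10[p10$times >= 0] == 0.15))
  expect_true(all(stim10[p10$times < 0] == 0.25))
  p4 <- profile_rab4()
  stim4 <- p4$binding_fraction$spine_stim
  expect_gt(max(stim4) - 0.15, 0.09)
  expect_lt(stim4[length(stim4)] - 0.15, 0.001)
})

test_that("profile/scene label mismatch is a configuration error", {
  pr <- profile_rab10(n_frames = 6)
  pr$binding_fraction$extra <- pr$binding_fraction$dendrite
  pr$volume_multiplier$extra <- pr$volume_multiplier$dendrite
  expect_error(
    simulate_flim_series(sim_scene(), pr, "rab10_mturq2_mvenus",
                         photons_per_frame = 1000, seed = 1),
    "do not match")
})

test_that("series simulation is reproducible and photon budgets track volume", {
  ser1 <- small_series(seed = 41, n_frames = 8, photons = 3e4)
  ser2 <- small_series(seed = 41, n_frames = 8, photons = 3e4)
  expect_identical(ser1$frames[[3]]$hist, ser2$frames[[3]]$hist)
  expect_identical(ser1$frames[[5]]$intensity_acceptor,
                   ser2$frames[[5]]$intensity_acceptor)
  expect_false(identical(
    ser1$frames[[3]]$hist,
    small_series(seed = 42, n_frames = 8, photons = 3e4)$frames[[3]]$hist))
  # stimulated-spine photon count rises ~3x between baseline and peak
  spine_photons <- function(fr) {
    sum(matrix(fr$hist, 32 * 32, 256)[as.vector(ser1$masks == 2), ])
  }
  base <- spine_photons(ser1$frames[[2]])
  peak <- spine_photons(ser1$frames[[8]])  # t = 1.33 min, mult ~3.3
  expect_gt(peak / base, 2)
})

test_that("null dynamics give flat binding-fraction and volume traces", {
  ser <- small_series(seed = 43, n_frames = 10, photons = 1e5,
                      preset = profile_null)
  tc <- binding_fraction_timecourse(ser, ser$masks == 1, t0 = 1.2,
                                    roi_label = "dendrite")
  sem <- sd(tc$value) / sqrt(nrow(tc))
  expect_lt(abs(mean(tc$value)), 2 * max(sem, 1e-4))
  vtc <- volume_change_timecourse(ser, ser$masks == 2)
  expect_lt(max(abs(vtc$value)), 0.1)
  # baseline frames of a delta trace average to zero by construction
  expect_equal(mean(tc$value[tc$time_min < 0]), 0, tolerance = 1e-12)
})

test_that("bleed-through adds donor-shaped signal to the acceptor channel", {
  ser0 <- small_series(seed = 44, n_frames = 4, photons = 5e4,
                       intensity_noise_sd = 0, bleed_through = 0)
  serb <- small_series(seed = 44, n_frames = 4, photons = 5e4,
                       intensity_noise_sd = 0, bleed_through = 0.2)
  extra <- serb$frames[[1]]$intensity_acceptor -
    ser0$frames[[1]]$intensity_acceptor
  don <- ser0$frames[[1]]$intensity_donor
  expect_gt(cor(as.vector(extra), as.vector(don)), 0.99)
  expect_true(all(extra >= 0))
})

test_that("NMDA bath-application preset changes every compartment", {
  pr <- profile_nmda()
  post <- pr$times >= 2
  for (lab in names(pr$binding_fraction)) {
    expect_true(all(pr$binding_fraction[[lab]][post] == 0.15))
    expect_true(all(pr$binding_fraction[[lab]][pr$times < 0] == 0.25))
  }
  expect_equal(pr$stimulus_window, c(0, 2))
})
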