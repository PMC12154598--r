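test_that("FRAP ground truth validates its invariants", {
  expect_s3_class(frap_ground_truth(), "frap_truth")
  tms <- c(-7:-3, 0:7)
  expect_error(frap_ground_truth(
    tms, exocytosis_component = c(rep(0, 5), 3, 2, 1, 1, 1, 1, 1, 1),
    volume_trace = rep(0, 13)), "non-decreasing")
  expect_error(frap_ground_truth(
    tms, exocytosis_component = rep(0, 13),
    volume_trace = rep(-1.5, 13)), "above -1")
  # surface area is consistent with the 2/3-power scaling
  tr <- frap_ground_truth()
  expect_equal(tr$surface_area, (1 + tr$volume_trace)^(2 / 3))
})

test_that("FRAP simulation follows the protocol and is seeded", {
  tr <- frap_ground_truth()
  s <- simulate_frap_series(tr, residual = 0.15, noise_sd = 0, seed = 1)
  expect_equal(sum(s$times < -2), 5)   # five baseline frames
  expect_equal(sum(s$times >= 0), 8)   # eight recovery frames
  # null recovery: post-bleach trace flat at the residual
  tr0 <- frap_ground_truth(exocytosis_component = rep(0, 13),
                           volume_trace = rep(0, 13))
  s0 <- simulate_frap_series(tr0, residual = 0.154, noise_sd = 0, seed = 1)
  n0 <- normalize_frap(s0)
  expect_equal(n0$recovery[n0$post], rep(0.154, 8), tolerance = 1e-12)
  expect_equal(n0$Fo, 0.154, tolerance = 1e-12)
  a <- simulate_frap_series(tr, seed = 5)
  b <- simulate_frap_series(tr, seed = 5)
  expect_identical(a$F_sep, b$F_sep)
  expect_error(simulate_frap_series(tr, residual = -0.1, seed = 1),
               ">= 0")
})

test_that("normalisation is scale invariant and guards degenerate input", {
  tr <- frap_ground_truth()
  s <- simulate_frap_series(tr, noise_sd = 0.05, seed = 2)
  n1 <- normalize_frap(s)
  s10 <- frap_series(s$times, s$F_sep * 10, s$F_vol * 10,
                     s$bleach_window, s$uncaging_window)
  n10 <- normalize_frap(s10)
  expect_equal(n1$recovery, n10$recovery, tolerance = 1e-12)
  expect_equal(n1$volume_change, n10$volume_change, tolerance = 1e-12)
  expect_error(normalize_frap(frap_series(
    c(-7, -6, 0, 1), c(0, 0, 1, 1), c(1, 1, 1, 1))), "baseline is zero")
})

test_that("surface-area correction recovers the exocytosis component exactly", {
  tr <- frap_ground_truth()
  s <- simulate_frap_series(tr, noise_sd = 0, seed = 1)
  res <- diffusion_corrected_recovery(normalize_frap(s))
  post <- res$post
  expect_lt(max(abs(res$corrected[post] -
                      tr$exocytosis_component[post])), 1e-10)
  # flat volume: corrected is identically dF/F
  tr_flat <- frap_ground_truth(volume_trace = rep(0, 13))
  sf <- simulate_frap_series(tr_flat, noise_sd = 0, seed = 1)
  rf <- diffusion_corrected_recovery(normalize_frap(sf))
  dFF <- (rf$recovery - rf$Fo) / rf$Fo
  expect_equal(rf$corrected[rf$post], dFF[rf$post], tolerance = 1e-12)
  # pure dilation: no exocytosis, x2 volume step one frame after the
  # Fo reference frame -> corrected ~ 0
  tr_dil <- frap_ground_truth(exocytosis_component = rep(0, 13),
                              volume_trace = c(rep(0, 6), rep(1, 7)))
  sd_ <- simulate_frap_series(tr_dil, noise_sd = 0, seed = 1)
  rd <- diffusion_corrected_recovery(normalize_frap(sd_))
  expect_lt(max(abs(rd$corrected[rd$post])), 1e-12)
})

test_that("sphere mode matches its generator and handles shrinkage", {
  tr <- frap_ground_truth()
  s <- simulate_frap_series(tr, noise_sd = 0, seed = 1,
                            surface_mode = "sphere")
  res <- diffusion_corrected_recovery(normalize_frap(s),
                                      surface_mode = "sphere")
  expect_lt(max(abs(res$corrected[res$post] -
                      tr$exocytosis_component[res$post])), 1e-10)
  # literal rule flags negative volume changes instead of going complex
  tr_neg <- frap_ground_truth(exocytosis_component = rep(0, 13),
                              volume_trace = c(rep(0, 5), rep(-0.2, 8)))
  sn <- simulate_frap_series(tr_neg, noise_sd = 0, seed = 1,
                             surface_mode = "sphere")
  expect_warning(
    rn <- diffusion_corrected_recovery(normalize_frap(sn)),
    "undefined")
  expect_true(all(is.na(rn$corrected[rn$post])))
  expect_equal(rn$negative_volume_frames, which(sn$times >= 0))
  # sphere mode handles the same input without complaint
  expect_no_warning(
    diffusion_corrected_recovery(normalize_frap(sn),
                                 surface_mode = "sphere"))
})

test_that("pre-bleach Fo convention and vector interface work", {
  tr <- frap_ground_truth()
  s <- simulate_frap_series(tr, noise_sd = 0, seed = 1)
  n <- normalize_frap(s)
  r_pre <- diffusion_corrected_recovery(n, Fo_convention = "pre")
  r_post <- diffusion_corrected_recovery(n, Fo_convention = "post")
  # the two conventions differ exactly by the Fo scale on dF
  post <- n$post
  expect_equal(r_pre$corrected[post] + (1 / n$Fo - 1) *
                 (n$recovery[post] - n$Fo) - r_post$corrected[post],
               rep(0, sum(post)), tolerance = 1e-10)
  # plain vector input requires aligned timestamps
  expect_error(diffusion_corrected_recovery(c(1, 2, 3), c(0, 0),
                                            times = c(0, 1, 2)),
               "share timestamps")
  rv <- diffusion_corrected_recovery(n$recovery[post],
                                     n$volume_change[post],
                                     times = n$times[post])
  expect_length(rv$corrected, sum(post))
})

test_that("noisy correction is unbiased across seeds", {
  # sphere surface rule on both sides: defined for noisy volume traces
  # that dip below zero, unlike the literal power rule
  tr <- frap_ground_truth()
  post <- tr$times >= 0
  runs <- sapply(1:30, function(sd) {
    s <- simulate_frap_series(tr, noise_sd = 0.05, seed = sd,
                              surface_mode = "sphere")
    diffusion_corrected_recovery(normalize_frap(s),
                                 surface_mode = "sphere")$corrected[post]
  })
  m <- rowMeans(runs)
  sem <- apply(runs, 1, sd) / sqrt(ncol(runs))
  expect_true(all(abs(m - tr$exocytosis_component[post]) <=
                    2 * sem + 1e-8))
})
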