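# Shared fixtures: everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

cal_rab10_turq <- flim_calibration("rab10_mturq2_mvenus")
cal_rab10_egfp <- flim_calibration("rab10_egfp_mcherry")

# numerical convolution oracle: one-sided exponential (x) Gaussian
quadrature_H <- function(t, t0, tau, tauG) {
  vapply(t, function(tt) {
    stats::integrate(function(s) {
      u <- tt - s - t0
      ifelse(u >= 0, exp(-u / tau), 0) * stats::dnorm(s, 0, tauG)
    }, lower = -Inf, upper = Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}

# small simulated series for image-level tests
small_series <- function(seed = 1, n_frames = 8, photons = 5e4,
                         preset = profile_rab10, ...) {
  simulate_flim_series(sim_scene(), preset(n_frames = n_frames),
                       "rab10_mturq2_mvenus",
                       photons_per_frame = photons, seed = seed, ...)
}

# synthetic phase summaries with a given phase-mean value (for group stats)
fake_summary <- function(v) {
  structure(list(transient_mean = v, transient_sem = 0,
                 sustained_mean = v, sustained_sem = 0,
                 transient_window = c(1.3, 4), sustained_window = c(19, 31),
                 n_transient = 1L, n_sustained = 1L, roi_label = "x"),
            class = "phase_summary")
}
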