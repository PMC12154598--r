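#' Per-structure activity and volume dynamics for the simulator
#'
#' A dynamics profile specifies, for every structure in the scene and every
#' frame time, the sensor binding fraction `P_AD(t)` (the activity readout)
#' and the volume multiplier `V(t)/V(0)`. Presets emulate the two signature
#' behaviours of small-GTPase activity during single-spine structural
#' plasticity, plus a bath-application scenario and a null control.
#'
#' @param times frame times (minutes), uniformly spaced; the stimulus is at
#'   `t = 0` and at least 3 baseline frames must precede it.
#' @param binding_fraction named list of numeric vectors (one per structure
#'   label), each `length(times)` long, values in \[0, 1\].
#' @param volume_multiplier named list of numeric vectors, `> 0`,
#'   identically 1 before the stimulus.
#' @param stimulus_window `c(start, end)` of the stimulus (min).
#' @return Object of class `"dynamics_profile"`.
#' @export
dynamics_profile <- function(times, binding_fraction, volume_multiplier,
                             stimulus_window = c(0, 1)) {
  stopifnot(is.numeric(times), length(times) >= 4L,
            identical(sort(names(binding_fraction)),
                      sort(names(volume_multiplier))))
  if (sum(times < stimulus_window[1L]) < 3L) {
    stop("profile must include at least 3 pre-stimulus baseline frames",
         call. = FALSE)
  }
  for (nm in names(binding_fraction)) {
    p <- binding_fraction[[nm]]
    v <- volume_multiplier[[nm]]
    if (length(p) != length(times) || length(v) != length(times)) {
      stop("trace lengths must equal length(times) (structure '", nm, "')",
           call. = FALSE)
    }
    if (any(p < 0 | p > 1)) {
      stop("binding fractions must lie in [0, 1] (structure '", nm, "')",
           call. = FALSE)
    }
    if (any(v <= 0)) stop("volume multipliers must be > 0", call. = FALSE)
    if (any(v[times < stimulus_window[1L]] != 1)) {
      stop("volume multiplier must be 1 before the stimulus (structure '",
           nm, "')", call. = FALSE)
    }
  }
  structure(
    list(times = times, binding_fraction = binding_fraction,
         volume_multiplier = volume_multiplier,
         stimulus_window = stimulus_window),
    class = "dynamics_profile"
  )
}

#' @export
print.dynamics_profile <- function(x, ...) {
  cat(sprintf(
    "Dynamics profile: %d frames, t = %.2f..%.2f min, stimulus [%g, %g]\n",
    length(x$times), min(x$times), max(x$times),
    x$stimulus_window[1L], x$stimulus_window[2L]))
  cat("  structures:", paste(names(x$binding_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

# Default frame grid: 50 frames at 40 s, five baseline frames before the
# stimulus at t = 0.
default_sltp_times <- function(n_frames = 50L, interval_min = 2 / 3,
                               n_baseline = 5L) {
  (seq_len(n_frames) - n_baseline - 1L) * interval_min
}

# Spine volume multiplier during structural LTP: linear rise to `peak`
# during the one-minute stimulus, then exponential decay to `sustained`.
sltp_volume_multiplier <- function(times, peak = 3.5, sustained = 1.8,
                                   tau_decay = 4) {
  ifelse(times < 0, 1,
         ifelse(times <= 1, 1 + (peak - 1) * times,
                sustained + (peak - sustained) *
                  exp(-(times - 1) / tau_decay)))
}

#' @param n_frames,interval_min frame count and interval (default 50 frames
#'   at 40 s).
#' @param baseline_PAD resting binding fraction of the sensor.
#' @param delta_PAD activity change in the stimulated spine: held step for
#'   the persistent-inactivation preset (`profile_rab10`), peak of the
#'   decaying pulse for the transient-activation preset (`profile_rab4`).
#' @param decay_min decay time constant of the transient pulse (min).
#' @param volume_peak,volume_sustained stimulated-spine volume multipliers
#'   (transient peak and sustained plateau).
#' @rdname dynamics_profile
#' @export
profile_rab10 <- function(n_frames = 50L, interval_min = 2 / 3,
                          baseline_PAD = 0.25, delta_PAD = -0.10,
                          volume_peak = 3.5, volume_sustained = 1.8) {
  times <- default_sltp_times(n_frames, interval_min)
  flat <- rep(baseline_PAD, length(times))
  ones <- rep(1, length(times))
  # persistent inactivation: step change at the stimulus, held to the end
  stim <- baseline_PAD + ifelse(times >= 0, delta_PAD, 0)
  dynamics_profile(
    times,
    binding_fraction = list(dendrite = flat, spine_stim = stim,
                            spine_adj = flat),
    volume_multiplier = list(
      dendrite = ones,
      spine_stim = sltp_volume_multiplier(times, volume_peak,
                                          volume_sustained),
      spine_adj = ones)
  )
}

#' @rdname dynamics_profile
#' @export
profile_rab4 <- function(n_frames = 50L, interval_min = 2 / 3,
                         baseline_PAD = 0.15, delta_PAD = 0.10,
                         decay_min = 3,
                         volume_peak = 3.5, volume_sustained = 1.8) {
  times <- default_sltp_times(n_frames, interval_min)
  flat <- rep(baseline_PAD, length(times))
  ones <- rep(1, length(times))
  # transient activation: pulse at the stimulus decaying over ~decay_min
  stim <- baseline_PAD +
    ifelse(times >= 0, delta_PAD * exp(-times / decay_min), 0)
  dynamics_profile(
    times,
    binding_fraction = list(dendrite = flat, spine_stim = stim,
                            spine_adj = flat),
    volume_multiplier = list(
      dendrite = ones,
      spine_stim = sltp_volume_multiplier(times, volume_peak,
                                          volume_sustained),
      spine_adj = ones)
  )
}

#' @rdname dynamics_profile
#' @export
profile_null <- function(n_frames = 50L, interval_min = 2 / 3,
                         baseline_PAD = 0.25) {
  times <- default_sltp_times(n_frames, interval_min)
  flat <- rep(baseline_PAD, length(times))
  ones <- rep(1, length(times))
  dynamics_profile(
    times,
    binding_fraction = list(dendrite = flat, spine_stim = flat,
                            spine_adj = flat),
    volume_multiplier = list(dendrite = ones, spine_stim = ones,
                             spine_adj = ones)
  )
}

#' @rdname dynamics_profile
#' @export
profile_nmda <- function(interval_min = 1, baseline_PAD = 0.25,
                         delta_PAD = -0.10) {
  # 6 min baseline imaging, 2 min bath application at t = 0, 32 min washout;
  # chemical stimulation reaches every compartment, so the activity change
  # is global rather than spine-restricted
  times <- seq(-6, 32, by = interval_min)
  ones <- rep(1, length(times))
  glob <- baseline_PAD +
    ifelse(times >= 0, delta_PAD * pmin(1, (times + interval_min) / 2), 0)
  dynamics_profile(
    times,
    binding_fraction = list(dendrite = glob, spine_stim = glob,
                            spine_adj = glob),
    volume_multiplier = list(dendrite = ones, spine_stim = ones,
                             spine_adj = ones),
    stimulus_window = c(0, 2)
  )
}
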