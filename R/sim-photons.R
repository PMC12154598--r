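# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream. Seeds are mandatory throughout the simulators: no generator
# touches hidden global state.
with_seed <- function(seed, expr) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate photon arrival times from a decay model
#'
#' Draws `n_photons` arrival times from the two-component decay model: each
#' photon picks the free or bound component with probability proportional to
#' the component's photon yield `P * tau` (amplitude fractions weight the
#' decay peak, so photon totals scale with fraction times lifetime), then
#' `t = t0 + Exponential(tau) + Gaussian(0, tauG)`.
#'
#' Photons falling outside the measurement window `[0, period)` are wrapped
#' modulo the period by default (periodic pulsed excitation: late photons
#' are recorded in the next sweep) or dropped when `clip = TRUE`. Use
#' `period = Inf` for an unbounded window.
#'
#' @param model a [decay_model].
#' @param n_photons number of photons to draw (`>= 0`).
#' @param seed RNG seed (mandatory; same seed, same output).
#' @param period measurement window length (ns); `Inf` disables windowing.
#' @param clip drop out-of-window photons instead of wrapping.
#' @return Numeric vector of arrival times (ns), length `n_photons` (or
#'   fewer when `clip = TRUE`; the number dropped is in attribute
#'   `"n_clipped"`).
#' @examples
#' m <- decay_model(PAD = 0.3, calibration = "rab10_egfp_mcherry")
#' t <- sample_arrival_times(m, 1000, seed = 1)
#' @export
sample_arrival_times <- function(model, n_photons, seed, period = 12.5,
                                 clip = FALSE) {
  stopifnot(inherits(model, "decay_model"))
  if (length(n_photons) != 1L || !is.finite(n_photons) || n_photons < 0) {
    stop("n_photons must be a single non-negative number", call. = FALSE)
  }
  if (model$tauD <= 0 || model$tauAD <= 0) {
    stop("lifetimes must be positive", call. = FALSE)
  }
  n_photons <- as.integer(round(n_photons))
  if (n_photons == 0L) {
    out <- numeric(0)
    attr(out, "n_clipped") <- 0L
    return(out)
  }
  # photon-count weighting: yield of each component is fraction x lifetime
  wAD <- model$PAD * model$tauAD /
    (model$PD * model$tauD + model$PAD * model$tauAD)
  with_seed(seed, {
    bound <- stats::runif(n_photons) < wAD
    tau <- ifelse(bound, model$tauAD, model$tauD)
    t <- model$t0 + stats::rexp(n_photons, rate = 1) * tau
    if (model$tauG > 0) t <- t + stats::rnorm(n_photons, sd = model$tauG)
    if (is.finite(period)) {
      if (clip) {
        keep <- t >= 0 & t < period
        n_clipped <- sum(!keep)
        t <- t[keep]
        attr(t, "n_clipped") <- n_clipped
      } else {
        t <- t %% period
        attr(t, "n_clipped") <- 0L
      }
    } else {
      attr(t, "n_clipped") <- 0L
    }
    t
  })
}

#' Simulate a TCSPC histogram from a decay model
#'
#' Convenience wrapper: [sample_arrival_times()] followed by
#' [build_histogram()].
#'
#' @inheritParams sample_arrival_times
#' @param n_channels number of histogram channels.
#' @return A [photon_histogram].
#' @export
simulate_histogram <- function(model, n_photons, seed, n_channels = 256,
                               period = 12.5, clip = FALSE) {
  t <- sample_arrival_times(model, n_photons, seed, period = period,
                            clip = clip)
  build_histogram(t, n_channels = n_channels, period = period)
}
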