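#' Ground truth for a simulated FRAP experiment
#'
#' Defines the components of surface-fluorophore recovery after a
#' whole-dendrite photobleach: the exocytosis (trafficking) component
#' `exocytosis_component(t)` = \eqn{\Delta F_t(t)/F_o} (dimensionless,
#' non-negative and non-decreasing after the bleach) and the fractional
#' volume change `volume_trace(t)` = \eqn{\Delta V(t)/V}. The spine surface
#' area scales as \eqn{S \propto V^{2/3}}, so the lateral-diffusion
#' (dilution) term in the recovery is the surface-area change
#' \eqn{\Delta S/S}, computed from the volume trace under the selected
#' `surface_mode` (see [diffusion_corrected_recovery()]).
#'
#' Defaults emulate single-spine stimulation immediately after the bleach:
#' a volume transient peaking ~3.5x above baseline with a slow decay, and a
#' saturating exocytosis component.
#'
#' @param times frame times (min); must contain pre-bleach frames.
#' @param exocytosis_component \eqn{\Delta F_t/F_o} per frame (0 before the
#'   bleach), or `NULL` for the default saturating curve.
#' @param volume_trace \eqn{\Delta V/V} per frame, or `NULL` for the
#'   default transient.
#' @param f surface fluorescence per unit area (a.u./um^2, informational).
#' @param bleach_window,uncaging_window event intervals (min).
#' @param ex_amplitude,ex_tau amplitude and time constant (min) of the
#'   default exocytosis component.
#' @param vol_peak,vol_tau peak \eqn{\Delta V/V} and decay constant of the
#'   default volume transient.
#' @return Object of class `"frap_truth"`.
#' @export
frap_ground_truth <- function(times = c(-7:-3, 0:7),
                              exocytosis_component = NULL,
                              volume_trace = NULL, f = 1,
                              bleach_window = c(-2, 0),
                              uncaging_window = c(0, 1),
                              ex_amplitude = 4.5, ex_tau = 1.2,
                              vol_peak = 3.5, vol_tau = 8) {
  post <- times >= bleach_window[2L]
  if (is.null(exocytosis_component)) {
    exocytosis_component <- ifelse(
      post, ex_amplitude * (1 - exp(-pmax(times, 0) / ex_tau)), 0)
  }
  if (is.null(volume_trace)) {
    volume_trace <- ifelse(
      times < 0, 0,
      ifelse(times <= 2, vol_peak * times / 2,
             vol_peak * exp(-(times - 2) / vol_tau)))
  }
  stopifnot(length(exocytosis_component) == length(times),
            length(volume_trace) == length(times))
  ex_post <- exocytosis_component[post]
  if (any(ex_post < 0) || any(diff(ex_post) < -1e-12)) {
    stop("exocytosis_component must be non-negative and non-decreasing ",
         "after the bleach", call. = FALSE)
  }
  if (any(volume_trace <= -1)) {
    stop("volume_trace must stay above -1", call. = FALSE)
  }
  structure(
    list(times = times, exocytosis_component = exocytosis_component,
         volume_trace = volume_trace, f = f,
         surface_area = (1 + volume_trace)^(2 / 3),
         bleach_window = bleach_window,
         uncaging_window = uncaging_window),
    class = "frap_truth"
  )
}

#' Two-channel FRAP series
#'
#' @param times frame times (min).
#' @param F_sep surface-reporter channel ROI intensity (a.u.).
#' @param F_vol volume-marker channel ROI intensity (a.u.).
#' @param bleach_window,uncaging_window event intervals (min); the bleach
#'   must precede the uncaging.
#' @param roi_label ROI name.
#' @return Object of class `"frap_series"`.
#' @export
frap_series <- function(times, F_sep, F_vol, bleach_window = c(-2, 0),
                        uncaging_window = c(0, 1), roi_label = "spine") {
  stopifnot(length(F_sep) == length(times),
            length(F_vol) == length(times))
  if (any(F_sep < 0) || any(F_vol < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (sum(times < bleach_window[1L]) < 2L) {
    stop("need at least 2 pre-bleach frames", call. = FALSE)
  }
  if (bleach_window[1L] > uncaging_window[1L]) {
    stop("bleach must precede uncaging", call. = FALSE)
  }
  structure(
    list(times = times, F_sep = F_sep, F_vol = F_vol,
         bleach_window = bleach_window, uncaging_window = uncaging_window,
         roi_label = roi_label),
    class = "frap_series"
  )
}

#' @export
print.frap_series <- function(x, ...) {
  cat(sprintf(
    "FRAP series '%s': %d frames, bleach [%g, %g] min, uncaging [%g, %g] min\n",
    x$roi_label, length(x$times), x$bleach_window[1L], x$bleach_window[2L],
    x$uncaging_window[1L], x$uncaging_window[2L]))
  invisible(x)
}

#' Simulate a FRAP series from known ground truth
#'
#' Builds the surface-reporter trace as
#' \eqn{F(t) = F_o (1 + \Delta F_t/F_o(t) + \Delta S/S(t))} after the
#' bleach (with \eqn{F_o} = `residual` x pre-bleach baseline) and the
#' volume channel from the volume trace, both with multiplicative Gaussian
#' noise.
#'
#' @param truth a [frap_ground_truth].
#' @param residual post-bleach residual fraction of the surface reporter.
#' @param noise_sd multiplicative Gaussian noise fraction (0 = noiseless).
#' @param seed RNG seed (mandatory).
#' @param surface_mode how \eqn{\Delta S/S} is built from the volume trace:
#'   `"literal"` uses \eqn{(\Delta V/V)^{2/3}}; `"sphere"` uses the exact
#'   dilating-sphere form \eqn{(1 + \Delta V/V)^{2/3} - 1}.
#' @param F0_pre,V0 pre-bleach baselines (a.u.).
#' @return A [frap_series].
#' @export
simulate_frap_series <- function(truth, residual = 0.15, noise_sd = 0.05,
                                 seed = 1,
                                 surface_mode = c("literal", "sphere"),
                                 F0_pre = 100, V0 = 100) {
  stopifnot(inherits(truth, "frap_truth"))
  surface_mode <- match.arg(surface_mode)
  if (residual < 0) stop("residual fraction must be >= 0", call. = FALSE)
  times <- truth$times
  post <- times >= truth$bleach_window[2L]
  dSS <- surface_change(truth$volume_trace, surface_mode)
  Fo <- residual * F0_pre
  F_sep <- ifelse(post, Fo * (1 + truth$exocytosis_component + dSS), F0_pre)
  F_vol <- V0 * (1 + truth$volume_trace)
  with_seed(seed, {
    if (noise_sd > 0) {
      F_sep <- pmax(F_sep * (1 + stats::rnorm(length(times), sd = noise_sd)),
                    0)
      F_vol <- pmax(F_vol * (1 + stats::rnorm(length(times), sd = noise_sd)),
                    0)
    }
    frap_series(times, F_sep, F_vol, truth$bleach_window,
                truth$uncaging_window)
  })
}

surface_change <- function(dVV, mode) {
  if (mode == "sphere") return((1 + dVV)^(2 / 3) - 1)
  out <- rep(NA_real_, length(dVV))
  nonneg <- !is.na(dVV) & dVV >= 0
  out[nonneg] <- dVV[nonneg]^(2 / 3)
  # negative base under a fractional power is undefined; left NA and
  # flagged by the caller
  out
}

#' Normalise a FRAP series
#'
#' Per channel, divides by the mean of the pre-bleach frames (`F/F0`), and
#' records \eqn{F_o}, the first post-bleach surface-reporter value (the
#' reference the surface-area correction algebra is written against).
#'
#' @param series a [frap_series].
#' @return Object of class `"frap_norm"`: `times`, `recovery` (F/F0 of the
#'   surface channel), `volume_change` (\eqn{\Delta V/V}), `Fo`
#'   (normalised, i.e. as a fraction of the pre-bleach baseline),
#'   `excluded` (frames inside bleach/uncaging intervals), plus the event
#'   windows.
#' @export
normalize_frap <- function(series) {
  stopifnot(inherits(series, "frap_series"))
  pre <- series$times < series$bleach_window[1L]
  if (!any(pre)) stop("no pre-bleach frames", call. = FALSE)
  F0_sep <- mean(series$F_sep[pre])
  F0_vol <- mean(series$F_vol[pre])
  if (F0_sep <= 0 || F0_vol <= 0) {
    stop("pre-bleach baseline is zero", call. = FALSE)
  }
  post <- series$times >= series$bleach_window[2L]
  if (!any(post)) stop("no post-bleach frames", call. = FALSE)
  excluded <- (series$times > series$bleach_window[1L] &
                 series$times < series$bleach_window[2L]) |
    (series$times > series$uncaging_window[1L] &
       series$times < series$uncaging_window[2L])
  structure(
    list(times = series$times,
         recovery = series$F_sep / F0_sep,
         volume_change = series$F_vol / F0_vol - 1,
         Fo = series$F_sep[which(post)[1L]] / F0_sep,
         post = post, excluded = excluded,
         bleach_window = series$bleach_window,
         uncaging_window = series$uncaging_window,
         roi_label = series$roi_label),
    class = "frap_norm"
  )
}

#' @export
print.frap_norm <- function(x, ...) {
  cat(sprintf(
    "Normalised FRAP '%s': Fo = %.3f of baseline, %d post-bleach frames\n",
    x$roi_label, x$Fo, sum(x$post)))
  invisible(x)
}

#' Surface-area-corrected FRAP recovery (exocytosis component)
#'
#' Separates the exocytosis contribution from lateral diffusion in the
#' fluorescence recovery of a surface-only reporter. The total recovery is
#' \eqn{\Delta F = \Delta F_t + f \Delta S}; since the fluorescence
#' immediately after the bleach is \eqn{F_o = f S}, dividing gives
#' \eqn{\Delta F/F_o = \Delta F_t/F_o + \Delta S/S}, and with surface area
#' scaling as volume to the 2/3 power the trafficking component is
#' \deqn{\Delta F_t/F = \Delta F/F - (\Delta V/V)^{2/3}.}
#'
#' @param norm a [normalize_frap()] result, or a numeric recovery trace
#'   (then `volume_change` must be supplied and share timestamps).
#' @param volume_change \eqn{\Delta V/V} trace (taken from `norm` when it
#'   is a `frap_norm`).
#' @param times timestamps, required when traces are passed as vectors;
#'   both traces must be on identical timestamps (no resampling).
#' @param surface_mode `"literal"` \eqn{(\Delta V/V)^{2/3}} (the quoted
#'   rule; negative \eqn{\Delta V/V} frames are undefined, returned `NA`
#'   and flagged) or `"sphere"` \eqn{(1+\Delta V/V)^{2/3} - 1}.
#' @param Fo_convention reference for \eqn{\Delta F/F}: `"post"` (default)
#'   normalises the change by the post-bleach \eqn{F_o}, as the derivation
#'   requires; `"pre"` normalises by the pre-bleach baseline.
#' @return Object of class `"frap_result"`: `times`, `recovery`,
#'   `volume_change`, `corrected` (\eqn{\Delta F_t/F_o}; `NA` before the
#'   bleach and at undefined frames), `Fo`, `excluded`,
#'   `negative_volume_frames`.
#' @export
diffusion_corrected_recovery <- function(norm, volume_change = NULL,
                                         times = NULL,
                                         surface_mode = c("literal",
                                                          "sphere"),
                                         Fo_convention = c("post", "pre")) {
  surface_mode <- match.arg(surface_mode)
  Fo_convention <- match.arg(Fo_convention)
  if (inherits(norm, "frap_norm")) {
    times <- norm$times
    recovery <- norm$recovery
    volume_change <- norm$volume_change
    Fo <- norm$Fo
    post <- norm$post
    excluded <- norm$excluded
  } else {
    recovery <- norm
    if (is.null(volume_change) || is.null(times)) {
      stop("vector input requires both volume_change and times",
           call. = FALSE)
    }
    if (length(recovery) != length(volume_change) ||
        length(times) != length(recovery)) {
      stop("recovery and volume_change must share timestamps",
           call. = FALSE)
    }
    Fo <- recovery[1L]
    post <- rep(TRUE, length(times))
    excluded <- rep(FALSE, length(times))
  }
  if (any(volume_change <= -1, na.rm = TRUE)) {
    stop("volume_change must stay above -1", call. = FALSE)
  }
  dFF <- switch(Fo_convention,
                post = (recovery - Fo) / Fo,
                pre = recovery - Fo)
  dSS <- surface_change(volume_change, surface_mode)
  neg <- which(post & !is.na(volume_change) & volume_change < 0)
  if (surface_mode == "literal" && length(neg) > 0) {
    warning("volume change is negative at ", length(neg),
            " post-bleach frame(s); (ΔV/V)^(2/3) is undefined there ",
            "and the corrected trace is NA (consider surface_mode = ",
            "'sphere')", call. = FALSE)
  }
  corrected <- ifelse(post, dFF - dSS, NA_real_)
  structure(
    list(times = times, recovery = recovery,
         volume_change = volume_change, corrected = corrected,
         Fo = Fo, post = post, excluded = excluded,
         negative_volume_frames = neg,
         surface_mode = surface_mode, Fo_convention = Fo_convention),
    class = "frap_result"
  )
}

#' @export
print.frap_result <- function(x, ...) {
  ok <- x$post & !x$excluded & !is.na(x$corrected)
  cat(sprintf(
    "Corrected FRAP recovery (%s surface rule, %s-bleach Fo)\n",
    x$surface_mode, x$Fo_convention))
  if (any(ok)) {
    cat(sprintf("  exocytosis component at last frame: %.3f\n",
                x$corrected[max(which(ok))]))
  }
  invisible(x)
}

#' @export
plot.frap_result <- function(x, ...) {
  graphics::plot(x$times, x$recovery, type = "b", pch = 16, cex = 0.6,
                 xlab = "time (min)", ylab = "F/F0 and components", ...)
  graphics::lines(x$times, 1 + x$volume_change, type = "b", pch = 1,
                  cex = 0.6, col = 4)
  graphics::points(x$times, x$corrected, type = "b", pch = 17, cex = 0.6,
                   col = 2)
  graphics::abline(v = 0, col = "grey", lty = 3)
  graphics::legend("topleft", bty = "n", pch = c(16, 1, 17),
                   col = c(1, 4, 2),
                   legend = c("recovery F/F0", "1 + dV/V",
                              "corrected dFt/Fo"))
  invisible(x)
}
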