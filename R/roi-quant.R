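#' PSF-calibrated spine volume in femtolitres
#'
#' Implements the intensity-ratio volume estimator: the integrated
#' volume-marker fluorescence in the spine is normalised by the per-pixel
#' fluorescence of a thick dendrite from the same cell (a region thicker
#' than the PSF, so its per-pixel intensity samples one full PSF column of
#' cytosol), and multiplied by the PSF volume. Because the dendrite
#' reference is a per-pixel intensity while the spine signal is integrated
#' over pixels, the ratio is additionally divided by the PSF cross-section
#' expressed in pixels (`psf_area_um2 / pixel_size^2`), so that a structure
#' that exactly fills one PSF yields `psf_volume`.
#'
#' @param acceptor_image volume-marker intensity image (matrix).
#' @param spine_mask,dendrite_mask logical or integer masks; the dendrite
#'   mask must cover a region thicker than the PSF (caller's
#'   responsibility).
#' @param psf_volume PSF volume (fL).
#' @param pixel_size pixel size (um).
#' @param psf_area_um2 lateral PSF cross-section (um^2).
#' @param reference dendrite reference statistic: mean per-pixel intensity
#'   (default) or the peak pixel.
#' @return Object of class `"volume_estimate"`: list with `volume` (fL),
#'   `psf_volume`, `integrated_spine_intensity`,
#'   `dendrite_reference_intensity`.
#' @export
estimate_spine_volume <- function(acceptor_image, spine_mask, dendrite_mask,
                                  psf_volume, pixel_size,
                                  psf_area_um2 = 0.13,
                                  reference = c("mean", "peak")) {
  reference <- match.arg(reference)
  spine_mask <- spine_mask > 0
  dendrite_mask <- dendrite_mask > 0
  if (!any(spine_mask) || !any(dendrite_mask)) {
    stop("spine and dendrite masks must both be non-empty", call. = FALSE)
  }
  spine_sum <- sum(acceptor_image[spine_mask])
  dend_ref <- if (reference == "mean") {
    mean(acceptor_image[dendrite_mask])
  } else {
    max(acceptor_image[dendrite_mask])
  }
  if (dend_ref <= 0) stop("dendrite reference intensity is zero",
                          call. = FALSE)
  psf_area_px <- psf_area_um2 / pixel_size^2
  structure(
    list(volume = spine_sum / dend_ref * psf_volume / psf_area_px,
         psf_volume = psf_volume,
         integrated_spine_intensity = spine_sum,
         dendrite_reference_intensity = dend_ref),
    class = "volume_estimate"
  )
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("Spine volume: %.4g fL (PSF %.3g fL)\n",
              x$volume, x$psf_volume))
  invisible(x)
}

new_timecourse <- function(times, values, roi_label, baseline_window,
                           n_photons = NA_real_) {
  structure(
    data.frame(time_min = times, value = values, roi_label = roi_label,
               n_photons = n_photons),
    baseline_window = baseline_window,
    class = c("flim_timecourse", "data.frame")
  )
}

#' @export
plot.flim_timecourse <- function(x, ylab = "value", ...) {
  graphics::plot(x$time_min, x$value, type = "b", pch = 16, cex = 0.6,
                 xlab = "time (min)", ylab = ylab, ...)
  graphics::abline(h = 0, v = 0, col = "grey", lty = 3)
  invisible(x)
}

baseline_frames <- function(times, baseline_window) {
  if (is.null(baseline_window)) times < 0
  else times >= baseline_window[1L] & times <= baseline_window[2L]
}

#' Fractional spine volume change over time
#'
#' \eqn{\Delta V/V(t) = (F(t) - \bar F_{base}) / \bar F_{base}} from the
#' summed volume-channel intensity over the ROI mask; the baseline is the
#' mean over the pre-stimulus window. Scale-invariant in the raw intensity
#' units. A configured donor bleed-through fraction can be subtracted from
#' the volume channel first.
#'
#' @param series a [flim_series].
#' @param mask logical/integer matrix selecting the ROI.
#' @param baseline_window `c(start, end)` in minutes, or `NULL` (default)
#'   for all pre-stimulus (`t < 0`) frames.
#' @param roi_label label stored in the result.
#' @param bleed_through fraction of the donor image subtracted from the
#'   acceptor image before summing (default 0).
#' @return A `flim_timecourse` data frame (`time_min`, `value`,
#'   `roi_label`).
#' @export
volume_change_timecourse <- function(series, mask, baseline_window = NULL,
                                     roi_label = "roi", bleed_through = 0) {
  stopifnot(inherits(series, "flim_series"))
  mask <- mask > 0
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  times <- series_times(series)
  f <- vapply(series$frames, function(fr) {
    img <- fr$intensity_acceptor
    if (bleed_through > 0) {
      img <- img - bleed_through * fr$intensity_donor /
        max(sum(fr$intensity_donor), 1) * sum(fr$intensity_acceptor)
    }
    sum(img[mask])
  }, 0)
  base <- baseline_frames(times, baseline_window)
  if (!any(base)) stop("no baseline frames in the requested window",
                       call. = FALSE)
  f0 <- mean(f[base])
  if (f0 <= 0) stop("baseline volume-channel intensity is zero",
                    call. = FALSE)
  new_timecourse(times, f / f0 - 1, roi_label,
                 baseline_window %||% c(min(times), 0))
}

#' Binding-fraction change over time for one ROI
#'
#' Per frame, pools the ROI photons and computes the binding fraction
#' ([roi_binding_fraction()]); reports the absolute change
#' \eqn{\Delta P_{AD}(t) = P_{AD}(t) - \bar P_{AD,base}} relative to the
#' mean over the baseline window.
#'
#' @inheritParams volume_change_timecourse
#' @param t0 image-wide pulse offset (ns), from [fit_decay()].
#' @param calibration a [flim_calibration] or preset name.
#' @param tauG IRF width for the truncation-corrected inversion (ns).
#' @param correct_truncation see [roi_binding_fraction()].
#' @return A `flim_timecourse` with attributes `baseline_PAD` and
#'   `clamped_frames`.
#' @export
binding_fraction_timecourse <- function(series, mask, t0, calibration = NULL,
                                        baseline_window = NULL,
                                        roi_label = "roi", tauG = 0.2,
                                        correct_truncation = TRUE) {
  stopifnot(inherits(series, "flim_series"))
  cal <- as_calibration(calibration %||% series$calibration)
  times <- series_times(series)
  res <- lapply(series$frames, function(fr) {
    roi_binding_fraction(fr, mask, t0, cal, tauG = tauG,
                         correct_truncation = correct_truncation)
  })
  pad <- vapply(res, `[[`, 0, "binding_fraction")
  nph <- vapply(res, `[[`, 0, "n_photons")
  clamped <- vapply(res, `[[`, TRUE, "clamped")
  base <- baseline_frames(times, baseline_window)
  if (!any(base)) stop("no baseline frames in the requested window",
                       call. = FALSE)
  out <- new_timecourse(times, pad - mean(pad[base]), roi_label,
                        baseline_window %||% c(min(times), 0),
                        n_photons = nph)
  attr(out, "baseline_PAD") <- mean(pad[base])
  attr(out, "clamped_frames") <- which(clamped)
  out
}

#' Transient and sustained phase summary of a time course
#'
#' Means and standard errors of a time-course over the two reporting
#' windows used for structural plasticity: a transient phase shortly after
#' the stimulus and a sustained phase tens of minutes later. Windows are
#' closed intervals; frames exactly on an endpoint are included. Missing
#' (`NA`) frames inside a window are excluded and reduce `n`.
#'
#' @param tc a `flim_timecourse` (or data frame with `time_min`, `value`).
#' @param transient_window,sustained_window closed intervals in minutes.
#'   Defaults: 1.3–4 min and 19–31 min (volume-only protocols convention-
#'   ally use 20–35 min for the sustained phase).
#' @return Object of class `"phase_summary"`: `transient_mean`,
#'   `transient_sem`, `sustained_mean`, `sustained_sem`, the windows, and
#'   the per-phase frame counts.
#' @export
summarize_phases <- function(tc, transient_window = c(1.3, 4),
                             sustained_window = c(19, 31)) {
  stopifnot(all(c("time_min", "value") %in% names(tc)))
  if (transient_window[2L] >= sustained_window[1L]) {
    stop("transient and sustained windows must not overlap", call. = FALSE)
  }
  phase <- function(w, name) {
    v <- tc$value[tc$time_min >= w[1L] & tc$time_min <= w[2L]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      stop("no frames fall in the ", name, " window [", w[1L], ", ",
           w[2L], "] min", call. = FALSE)
    }
    list(mean = mean(v),
         sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0,
         n = length(v))
  }
  tr <- phase(transient_window, "transient")
  su <- phase(sustained_window, "sustained")
  structure(
    list(transient_mean = tr$mean, transient_sem = tr$sem,
         sustained_mean = su$mean, sustained_sem = su$sem,
         transient_window = transient_window,
         sustained_window = sustained_window,
         n_transient = tr$n, n_sustained = su$n,
         roi_label = if ("roi_label" %in% names(tc))
           tc$roi_label[1L] else NA_character_),
    class = "phase_summary"
  )
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf(
    "Phase summary%s:\n  transient [%g, %g] min: %.4g +/- %.2g (n = %d)\n  sustained [%g, %g] min: %.4g +/- %.2g (n = %d)\n",
    if (!is.na(x$roi_label)) paste0(" (", x$roi_label, ")") else "",
    x$transient_window[1L], x$transient_window[2L],
    x$transient_mean, x$transient_sem, x$n_transient,
    x$sustained_window[1L], x$sustained_window[2L],
    x$sustained_mean, x$sustained_sem, x$n_sustained))
  invisible(x)
}

#' Group mean +/- SEM across phase summaries, with optional t-test
#'
#' Aggregates per-cell (or per-seed) phase summaries into group mean, SEM
#' and n per phase. When a second group is supplied, an equal-variance
#' unpaired two-tailed Student's t-test compares the groups per phase.
#'
#' @param summaries list of [summarize_phases()] results (group 1).
#' @param summaries2 optional second group for the t-test.
#' @return List with a `groups` data frame (group, phase, mean, sem, n) and,
#'   when two groups are given, `tests` (phase, t, df, p_value).
#' @export
group_summary <- function(summaries, summaries2 = NULL) {
  pull <- function(ss, field) vapply(ss, `[[`, 0, field)
  one_group <- function(ss, label) {
    if (length(ss) < 2L) {
      stop("need at least 2 summaries per group for a SEM", call. = FALSE)
    }
    do.call(rbind, lapply(c("transient", "sustained"), function(ph) {
      v <- pull(ss, paste0(ph, "_mean"))
      data.frame(group = label, phase = ph, mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)), n = length(v))
    }))
  }
  out <- list(groups = one_group(summaries, "group1"))
  if (!is.null(summaries2)) {
    out$groups <- rbind(out$groups, one_group(summaries2, "group2"))
    out$tests <- do.call(rbind, lapply(c("transient", "sustained"),
                                       function(ph) {
      v1 <- pull(summaries, paste0(ph, "_mean"))
      v2 <- pull(summaries2, paste0(ph, "_mean"))
      tt <- stats::t.test(v1, v2, var.equal = TRUE)
      data.frame(phase = ph, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
    }))
  }
  out
}
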