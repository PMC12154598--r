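#' Donor/acceptor lifetime calibration for a FLIM-FRET sensor
#'
#' A calibration fixes the two lifetimes of the biexponential decay model:
#' the free-donor lifetime `tauD` and the lifetime `tauAD` of donor bound to
#' its acceptor. FRET shortens the donor lifetime, so `tauAD < tauD` always.
#' Three presets ship with the package, corresponding to the sensor pairs the
#' decay model was calibrated for:
#'
#' * `"rab4_egfp_mcherry"`: mEGFP donor, mCherry acceptor
#'   (tauD = 2.46 ns, tauAD = 1.10 ns)
#' * `"rab10_egfp_mcherry"`: mEGFP donor, mCherry acceptor
#'   (tauD = 2.60 ns, tauAD = 1.10 ns)
#' * `"rab10_mturq2_mvenus"`: mTurquoise2 donor, mVenus acceptor
#'   (tauD = 4.15 ns, tauAD = 1.60 ns)
#'
#' @param preset name of a shipped preset (see above), or `NULL` to build a
#'   custom calibration from `tauD`/`tauAD`.
#' @param tauD free-donor fluorescence lifetime (ns).
#' @param tauAD lifetime of donor bound to acceptor (ns); must be `< tauD`.
#' @param donor,acceptor fluorophore names (informational).
#' @return An object of class `"flim_calibration"`: a list with fields
#'   `donor`, `acceptor`, `tauD`, `tauAD`, `preset`.
#' @examples
#' flim_calibration("rab10_mturq2_mvenus")
#' flim_calibration(tauD = 2.6, tauAD = 1.1)
#' @export
flim_calibration <- function(preset = NULL, tauD = NULL, tauAD = NULL,
                             donor = "donor", acceptor = "acceptor") {
  if (!is.null(preset)) {
    presets <- calibration_presets()
    if (!preset %in% names(presets)) {
      stop("unknown calibration preset '", preset, "'; valid presets: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    return(presets[[preset]])
  }
  if (is.null(tauD) || is.null(tauAD)) {
    stop("either 'preset' or both 'tauD' and 'tauAD' must be given",
         call. = FALSE)
  }
  stopifnot(is.numeric(tauD), is.numeric(tauAD),
            length(tauD) == 1L, length(tauAD) == 1L)
  if (!is.finite(tauD) || !is.finite(tauAD) || tauD <= 0 || tauAD <= 0) {
    stop("lifetimes must be positive and finite", call. = FALSE)
  }
  if (tauAD >= tauD) {
    stop("tauAD must be smaller than tauD (FRET shortens the donor lifetime)",
         call. = FALSE)
  }
  structure(
    list(donor = donor, acceptor = acceptor,
         tauD = tauD, tauAD = tauAD, preset = NA_character_),
    class = "flim_calibration"
  )
}

#' @rdname flim_calibration
#' @export
calibration_presets <- function() {
  mk <- function(donor, acceptor, tauD, tauAD, preset) {
    structure(list(donor = donor, acceptor = acceptor, tauD = tauD,
                   tauAD = tauAD, preset = preset),
              class = "flim_calibration")
  }
  list(
    rab4_egfp_mcherry   = mk("mEGFP-Rab4a", "mCherry-RBD-mCherry",
                             2.46, 1.10, "rab4_egfp_mcherry"),
    rab10_egfp_mcherry  = mk("mEGFP-Rab10", "mCherry-RBD-mCherry",
                             2.60, 1.10, "rab10_egfp_mcherry"),
    rab10_mturq2_mvenus = mk("mTurquoise2-Rab10", "mVenus-RBD-mVenus",
                             4.15, 1.60, "rab10_mturq2_mvenus")
  )
}

#' @export
print.flim_calibration <- function(x, ...) {
  cat("FLIM-FRET sensor calibration",
      if (!is.na(x$preset)) paste0("(preset '", x$preset, "')"), "\n")
  cat(sprintf("  donor    : %s  (tauD  = %.2f ns)\n", x$donor, x$tauD))
  cat(sprintf("  acceptor : %s  (tauAD = %.2f ns)\n", x$acceptor, x$tauAD))
  invisible(x)
}

as_calibration <- function(x) {
  if (inherits(x, "flim_calibration")) return(x)
  if (is.character(x) && length(x) == 1L) return(flim_calibration(x))
  stop("expected a flim_calibration object or preset name", call. = FALSE)
}
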