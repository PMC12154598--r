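#' Synthetic imaging scene: a dendrite with spines
#'
#' Describes the geometry the FLIM simulator renders: a field of view
#' containing a dendrite segment and two spines (one to be stimulated, one
#' adjacent control), each a filled ellipse with an associated cytosolic
#' volume in femtolitres. The point-spread-function (PSF) parameters tie
#' image intensity to volume: a structure much thicker than the PSF yields a
#' per-pixel intensity of `concentration * psf_volume / psf_area` per unit
#' pixel area, while a sub-PSF structure contributes its total
#' `concentration * volume` spread over its footprint.
#'
#' @param grid_shape image size in pixels, `c(rows, cols)`.
#' @param pixel_size pixel size (micrometres).
#' @param structures named list; each element a list with `label` (one of
#'   `"dendrite"`, `"spine_stim"`, `"spine_adj"`), `center` (x, y in um),
#'   `radii` (rx, ry in um) and `volume` (fL). Default: a dendrite band
#'   crossing the field with one spine above and one below.
#' @param psf_volume two-photon excitation PSF volume (fL).
#' @param psf_area_um2 lateral PSF cross-section area (um^2).
#' @param donor_concentration,acceptor_concentration fluorophore
#'   concentrations (arbitrary units per fL).
#' @return Object of class `"sim_scene"`.
#' @export
sim_scene <- function(grid_shape = c(32L, 32L), pixel_size = 0.125,
                      structures = NULL, psf_volume = 0.08,
                      psf_area_um2 = 0.13,
                      donor_concentration = 1, acceptor_concentration = 1) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 4L),
            pixel_size > 0, psf_volume > 0, psf_area_um2 > 0)
  if (is.null(structures)) {
    w <- grid_shape[2L] * pixel_size
    h <- grid_shape[1L] * pixel_size
    structures <- list(
      dendrite = list(label = "dendrite", center = c(w / 2, h / 2),
                      radii = c(0.47 * w, 0.09 * h), volume = 2.0),
      spine_stim = list(label = "spine_stim",
                        center = c(0.3 * w, 0.28 * h),
                        radii = c(0.25, 0.25), volume = 0.10),
      spine_adj = list(label = "spine_adj",
                       center = c(0.7 * w, 0.72 * h),
                       radii = c(0.25, 0.25), volume = 0.12)
    )
  }
  labels <- vapply(structures, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("structure labels must be unique",
                                  call. = FALSE)
  vols <- vapply(structures, `[[`, 0, "volume")
  if (any(vols <= 0)) stop("all structure volumes must be > 0",
                           call. = FALSE)
  for (s in structures) {
    if (s$center[1L] - s$radii[1L] < 0 ||
        s$center[1L] + s$radii[1L] > grid_shape[2L] * pixel_size ||
        s$center[2L] - s$radii[2L] < 0 ||
        s$center[2L] + s$radii[2L] > grid_shape[1L] * pixel_size) {
      stop("structure '", s$label, "' extends outside the grid",
           call. = FALSE)
    }
  }
  names(structures) <- labels
  structure(
    list(grid_shape = as.integer(grid_shape), pixel_size = pixel_size,
         structures = structures, psf_volume = psf_volume,
         psf_area_um2 = psf_area_um2,
         donor_concentration = donor_concentration,
         acceptor_concentration = acceptor_concentration),
    class = "sim_scene"
  )
}

#' @export
print.sim_scene <- function(x, ...) {
  cat(sprintf("Simulated scene: %d x %d px (%.3g um/px)\n",
              x$grid_shape[1L], x$grid_shape[2L], x$pixel_size))
  for (s in x$structures) {
    cat(sprintf("  %-10s  %.2f fL at (%.2f, %.2f) um\n",
                s$label, s$volume, s$center[1L], s$center[2L]))
  }
  cat(sprintf("  PSF: %.3g fL, %.3g um^2 cross-section\n",
              x$psf_volume, x$psf_area_um2))
  invisible(x)
}

# Filled-ellipse pixel mask for one structure. Pixel (r, c) covers
# x in [(c-1), c] * pixel_size; its center is ((c-0.5), (r-0.5)) * px.
structure_mask <- function(scene, label) {
  s <- scene$structures[[label]]
  if (is.null(s)) stop("no structure labelled '", label, "' in scene",
                       call. = FALSE)
  nr <- scene$grid_shape[1L]
  nc <- scene$grid_shape[2L]
  px <- scene$pixel_size
  xc <- (matrix(rep(seq_len(nc), each = nr), nr, nc) - 0.5) * px
  yc <- (matrix(rep(seq_len(nr), times = nc), nr, nc) - 0.5) * px
  ((xc - s$center[1L]) / s$radii[1L])^2 +
    ((yc - s$center[2L]) / s$radii[2L])^2 <= 1
}

#' Integer label mask for a scene
#'
#' 0 = background, 1 = dendrite, 2 = stimulated spine, 3 = adjacent spine.
#' Spines are drawn on top of the dendrite.
#'
#' @param scene a [sim_scene].
#' @return Integer matrix of labels.
#' @export
scene_label_mask <- function(scene) {
  codes <- c(dendrite = 1L, spine_stim = 2L, spine_adj = 3L)
  m <- matrix(0L, scene$grid_shape[1L], scene$grid_shape[2L])
  for (lab in intersect(names(codes), names(scene$structures))) {
    m[structure_mask(scene, lab)] <- codes[[lab]]
  }
  m
}

# Visible (image-sampled) donor volume of a structure: sub-PSF structures
# contribute their full volume; the thick dendrite contributes one PSF
# axial column per pixel of footprint.
visible_volume <- function(scene, label) {
  s <- scene$structures[[label]]
  if (s$label == "dendrite") {
    n_px <- sum(structure_mask(scene, label) &
                  scene_label_mask(scene) == 1L)
    psf_area_px <- scene$psf_area_um2 / scene$pixel_size^2
    n_px * scene$psf_volume / psf_area_px
  } else {
    s$volume
  }
}
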