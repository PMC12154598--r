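#' Write / read a FLIM series in the package's HDF5 layout
#'
#' Layout (version 1): one group `/frames/<k>` per frame (k = 1..n, zero
#' padded) holding datasets `hist` (rows x cols x n_channels, unsigned
#' integer counts), `intensity_donor` and `intensity_acceptor`
#' (rows x cols, float), with frame attributes `time_min`, `period_ns`,
#' `n_channels`; root attributes `pixel_size_um`, `layout_version`, and a
#' `calibration` group with `donor`, `acceptor`, `tauD`, `tauAD`. The label
#' mask travels separately as an integer TIFF ([write_mask_tiff()]).
#'
#' @param series a [flim_series].
#' @param path output `.h5` file path (overwritten).
#' @return `path`, invisibly (`write`); a [flim_series] (`read`).
#' @export
write_flim_h5 <- function(series, path) {
  stopifnot(inherits(series, "flim_series"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(series$pixel_size_um, fid, "pixel_size_um")
  rhdf5::h5writeAttribute(1L, fid, "layout_version")
  rhdf5::H5Fclose(fid)
  cal <- series$calibration
  rhdf5::h5createGroup(path, "calibration")
  rhdf5::h5write(cal$donor, path, "calibration/donor")
  rhdf5::h5write(cal$acceptor, path, "calibration/acceptor")
  rhdf5::h5write(cal$tauD, path, "calibration/tauD")
  rhdf5::h5write(cal$tauAD, path, "calibration/tauAD")
  rhdf5::h5createGroup(path, "frames")
  for (k in seq_along(series$frames)) {
    fr <- series$frames[[k]]
    g <- sprintf("frames/%04d", k)
    rhdf5::h5createGroup(path, g)
    h <- fr$hist
    storage.mode(h) <- "integer"
    rhdf5::h5write(h, path, paste0(g, "/hist"))
    rhdf5::h5write(fr$intensity_donor, path, paste0(g, "/intensity_donor"))
    rhdf5::h5write(fr$intensity_acceptor, path,
                   paste0(g, "/intensity_acceptor"))
    gid <- rhdf5::H5Gopen(rhdf5::H5Fopen(path), g)
    rhdf5::h5writeAttribute(fr$time_min, gid, "time_min")
    rhdf5::h5writeAttribute(fr$period_ns, gid, "period_ns")
    rhdf5::h5writeAttribute(as.integer(fr$n_channels), gid, "n_channels")
    rhdf5::H5Gclose(gid)
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' @param masks integer label mask applied to the series on read (the HDF5
#'   file itself carries no mask); defaults to all-background.
#' @rdname write_flim_h5
#' @export
read_flim_h5 <- function(path, masks = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  root_attrs <- rhdf5::h5readAttributes(path, "/")
  for (a in c("pixel_size_um", "layout_version")) {
    if (is.null(root_attrs[[a]])) {
      stop("FLIM HDF5 schema error: missing root attribute '", a, "'",
           call. = FALSE)
    }
  }
  top <- contents$name[contents$group == "/"]
  known <- c("calibration", "frames")
  extra <- setdiff(top, known)
  if (length(extra) > 0) {
    warning("ignoring unknown group(s) in FLIM file: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  for (g in known) {
    if (!g %in% top) {
      stop("FLIM HDF5 schema error: missing group '/", g, "'",
           call. = FALSE)
    }
  }
  cal_read <- function(what) {
    as.vector(rhdf5::h5read(path, paste0("calibration/", what)))
  }
  cal <- flim_calibration(tauD = cal_read("tauD"), tauAD = cal_read("tauAD"),
                          donor = cal_read("donor"),
                          acceptor = cal_read("acceptor"))
  frame_names <- sort(contents$name[contents$group == "/frames"])
  if (length(frame_names) == 0) {
    stop("FLIM HDF5 schema error: '/frames' contains no frames",
         call. = FALSE)
  }
  frames <- lapply(frame_names, function(nm) {
    g <- paste0("frames/", nm)
    at <- rhdf5::h5readAttributes(path, g)
    for (a in c("time_min", "period_ns", "n_channels")) {
      if (is.null(at[[a]])) {
        stop("FLIM HDF5 schema error: frame '", nm,
             "' is missing attribute '", a, "'", call. = FALSE)
      }
    }
    in_frame <- contents$name[contents$group == paste0("/", g)]
    for (d in c("hist", "intensity_donor", "intensity_acceptor")) {
      if (!d %in% in_frame) {
        stop("FLIM HDF5 schema error: frame '", nm,
             "' is missing dataset '", d, "'", call. = FALSE)
      }
    }
    flim_frame(rhdf5::h5read(path, paste0(g, "/hist")),
               rhdf5::h5read(path, paste0(g, "/intensity_donor")),
               rhdf5::h5read(path, paste0(g, "/intensity_acceptor")),
               time_min = as.vector(at$time_min),
               period_ns = as.vector(at$period_ns))
  })
  if (is.null(masks)) {
    d <- dim(frames[[1L]]$hist)
    masks <- matrix(0L, d[1L], d[2L])
  }
  flim_series(frames, masks, as.vector(root_attrs$pixel_size_um), cal)
}

#' Write / read integer label masks as TIFF
#'
#' Label images (0 = background, 1 = dendrite, 2 = stimulated spine,
#' 3 = adjacent spine) stored as 8-bit TIFF.
#'
#' @param mask integer matrix of labels (0–255).
#' @param path TIFF path.
#' @return `path` invisibly; `read_mask_tiff` returns the integer matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(all(mask >= 0), all(mask <= 255))
  tiff::writeTIFF(mask / 255, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write / read a lifetime map as 32-bit float TIFF
#'
#' TIFF float samples are stored on \[0, 1\], so the map is divided by
#' `scale` (default: one laser period, 12.5 ns, the maximum possible mean
#' arrival time) on write and multiplied back on read. Masked (`NA`) pixels
#' are written as 0.
#'
#' @param map numeric matrix (ns).
#' @param path TIFF path.
#' @param scale full-scale value in ns.
#' @export
write_lifetime_tiff <- function(map, path, scale = 12.5) {
  map[is.na(map)] <- 0
  tiff::writeTIFF(map / scale, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_lifetime_tiff
#' @export
read_lifetime_tiff <- function(path, scale = 12.5) {
  tiff::readTIFF(path) * scale
}
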