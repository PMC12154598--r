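#' Photon arrival-time histogram
#'
#' A time-correlated single-photon-counting (TCSPC) histogram: photon counts
#' binned by arrival time within one laser repetition period. Channel edges
#' are uniform on `[0, period)`; `channel_centers` are the bin midpoints.
#'
#' @param counts non-negative photon counts per channel.
#' @param period laser repetition period (ns).
#' @return An object of class `"photon_histogram"` with fields
#'   `channel_centers`, `counts`, `period`.
#' @seealso [build_histogram()], [mean_arrival_time()], [fit_decay()]
#' @export
photon_histogram <- function(counts, period) {
  stopifnot(is.numeric(counts), length(counts) >= 2L, period > 0)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  n <- length(counts)
  width <- period / n
  structure(
    list(channel_centers = (seq_len(n) - 0.5) * width,
         counts = as.numeric(counts),
         period = period),
    class = "photon_histogram"
  )
}

#' @export
print.photon_histogram <- function(x, ...) {
  cat(sprintf(
    "Photon histogram: %d channels over %.3g ns, %d photons\n",
    length(x$counts), x$period, round(sum(x$counts))))
  invisible(x)
}

#' @export
plot.photon_histogram <- function(x, log = "", ...) {
  graphics::plot(x$channel_centers, x$counts, type = "s", log = log,
                 xlab = "arrival time (ns)", ylab = "photons / channel", ...)
  invisible(x)
}

#' Bin photon arrival times into a TCSPC histogram
#'
#' @param times photon arrival times (ns). Times outside `[0, period)` are
#'   dropped (out-of-window).
#' @param n_channels number of uniform channels (`>= 2`).
#' @param period laser repetition period (ns).
#' @return A [photon_histogram]; its counts sum to the number of in-window
#'   times.
#' @examples
#' build_histogram(c(1.0, 1.0, 6.0), n_channels = 2, period = 12.5)
#' @export
build_histogram <- function(times, n_channels = 256, period = 12.5) {
  stopifnot(n_channels >= 2L, period > 0)
  times <- times[times >= 0 & times < period]
  idx <- floor(times / period * n_channels) + 1L
  counts <- tabulate(idx, nbins = n_channels)
  photon_histogram(counts, period)
}

#' Mean photon arrival time of a histogram
#'
#' Discrete form of \eqn{\langle t\rangle = \int t F(t)\,dt / \int F(t)\,dt}
#' over the measurement window: the count-weighted mean of the channel
#' centers. Subtracting the fitted pulse offset `t0` turns this into the mean
#' fluorescence lifetime.
#'
#' @param hist a [photon_histogram].
#' @return Mean arrival time (ns).
#' @export
mean_arrival_time <- function(hist) {
  stopifnot(inherits(hist, "photon_histogram"))
  tot <- sum(hist$counts)
  if (tot <= 0) stop("mean arrival time undefined: histogram has no photons",
                     call. = FALSE)
  sum(hist$channel_centers * hist$counts) / tot
}

#' Pool several histograms by summing counts
#'
#' Photon counts are additive, so pooling regions of interest is simply a
#' channel-wise sum; all inputs must share binning and period.
#'
#' @param ... [photon_histogram] objects (or a single list of them).
#' @return A [photon_histogram] with summed counts.
#' @export
pool_histograms <- function(...) {
  hs <- list(...)
  if (length(hs) == 1L && !inherits(hs[[1L]], "photon_histogram")) {
    hs <- hs[[1L]]
  }
  stopifnot(length(hs) >= 1L,
            all(vapply(hs, inherits, TRUE, "photon_histogram")))
  n <- length(hs[[1L]]$counts)
  per <- hs[[1L]]$period
  for (h in hs) {
    if (length(h$counts) != n || h$period != per) {
      stop("histograms must share channel count and period", call. = FALSE)
    }
  }
  photon_histogram(Reduce(`+`, lapply(hs, `[[`, "counts")), per)
}
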