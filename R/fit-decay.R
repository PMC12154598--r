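#' Fit a biexponential decay model to a photon histogram
#'
#' Maximum-likelihood fit of the IRF-convolved two-component decay model to
#' TCSPC photon counts. The two lifetimes `tauD`/`tauAD` are fixed by the
#' sensor `calibration`; the fit estimates the binding fraction `PAD` (with
#' `PD = 1 - PAD`), the pulse offset `t0`, the IRF width `tauG` (optionally
#' fixed), and the amplitude `F0`.
#'
#' Photon counts per channel are Poisson, so the default objective is the
#' Poisson negative log-likelihood (profile over `F0`, which has the
#' closed-form solution `sum(n)/sum(shape)`); at high counts this reduces to
#' least squares, and a weighted-least-squares objective is available via
#' `method = "wls"`. The expected curve folds the decay tail of preceding
#' excitation periods back into the window (`wrap_periods`), matching
#' periodic pulsed excitation.
#'
#' Typical use is image-wide: pool all pixels of a frame into one histogram,
#' fit it, and reuse the fitted `t0` for per-pixel lifetime maps and ROI
#' binding fractions ([lifetime_image()], [roi_binding_fraction()]).
#'
#' @param hist a [photon_histogram].
#' @param calibration a [flim_calibration] or preset name.
#' @param start optional named list of starting values (`PAD`, `t0`,
#'   `tauG`).
#' @param fix_tauG fix the IRF width at this value instead of fitting it.
#' @param method `"poisson"` (default) or `"wls"`.
#' @param wrap_periods periods of decay tail folded into the window
#'   (default 2; 0 fits the literal unwrapped curve).
#' @param min_photons minimum total counts required to attempt a fit.
#' @param max_iter iteration cap passed to the optimiser.
#' @return An object of class `"decay_fit"`: a list with elements
#'   `model` (the fitted [decay_model]), `se` (standard errors for the free
#'   parameters), `deviance`, `df_residual`, `logLik`, `fitted`, `hist`,
#'   `calibration`, `convergence`, `method`.
#' @examples
#' truth <- decay_model(PAD = 0.3, calibration = "rab10_egfp_mcherry")
#' h <- simulate_histogram(truth, 1e5, seed = 1)
#' fit <- fit_decay(h, "rab10_egfp_mcherry")
#' coef(fit)
#' @export
fit_decay <- function(hist, calibration, start = NULL, fix_tauG = NULL,
                      method = c("poisson", "wls"), wrap_periods = 2,
                      min_photons = 1000, max_iter = 500) {
  stopifnot(inherits(hist, "photon_histogram"))
  cal <- as_calibration(calibration)
  method <- match.arg(method)
  n <- hist$counts
  total <- sum(n)
  if (total < min_photons) {
    stop("too few photons to fit (", round(total), " < ", min_photons, ")",
         call. = FALSE)
  }
  centers <- hist$channel_centers
  period <- hist$period
  fit_tauG <- is.null(fix_tauG)

  shape_of <- function(PAD, t0, tauG) {
    m <- decay_model(PAD = PAD, tauD = cal$tauD, tauAD = cal$tauAD,
                     t0 = t0, tauG = tauG, F0 = 1)
    model_curve(centers, m, period = period, wrap_periods = wrap_periods)
  }
  objective <- function(par) {
    PAD <- par[[1L]]
    t0 <- par[[2L]]
    tauG <- if (fit_tauG) par[[3L]] else fix_tauG
    s <- shape_of(PAD, t0, tauG)
    s <- pmax(s, 1e-300)
    if (method == "poisson") {
      F0 <- total / sum(s)
      mu <- F0 * s
      sum(mu - n * log(mu))
    } else {
      F0 <- sum(n * s / pmax(n, 1)) / sum(s^2 / pmax(n, 1))
      sum((n - F0 * s)^2 / pmax(n, 1))
    }
  }

  if (is.null(start)) start <- list()
  t0_start <- start$t0 %||% {
    # crude pulse locator: channel where the smoothed curve peaks
    sm <- stats::filter(n, rep(1 / 5, 5), sides = 2)
    max(centers[which.max(sm)] - 0.1, period / 1000)
  }
  par0 <- c(PAD = start$PAD %||% 0.3, t0 = t0_start)
  lower <- c(0, period / 1000)
  upper <- c(1, period / 2)
  if (fit_tauG) {
    par0 <- c(par0, tauG = start$tauG %||% 0.2)
    lower <- c(lower, 0.01)
    upper <- c(upper, 1.5)
  }
  opt <- stats::optim(par0, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = max_iter))
  if (opt$convergence != 0) {
    cond <- structure(
      class = c("spineflim_fit_error", "error", "condition"),
      list(message = paste0("decay fit did not converge: ", opt$message),
           call = sys.call(-1), last_iterate = opt$par)
    )
    stop(cond)
  }
  PAD <- opt$par[[1L]]
  t0 <- opt$par[[2L]]
  tauG <- if (fit_tauG) opt$par[[3L]] else fix_tauG
  s <- shape_of(PAD, t0, tauG)
  F0 <- if (method == "poisson") total / sum(s) else {
    sum(n * s / pmax(n, 1)) / sum(s^2 / pmax(n, 1))
  }
  mu <- pmax(F0 * s, 1e-300)

  # observed-information standard errors on the full parameter set
  full_nll <- function(par) {
    s2 <- pmax(shape_of(par[[2L]], par[[3L]],
                        if (fit_tauG) par[[4L]] else fix_tauG), 1e-300)
    mu2 <- pmax(par[[1L]] * s2, 1e-300)
    sum(mu2 - n * log(mu2))
  }
  full_par <- c(F0 = F0, PAD = PAD, t0 = t0,
                if (fit_tauG) c(tauG = tauG))
  se <- rep(NA_real_, length(full_par))
  names(se) <- names(full_par)
  hess <- try(stats::optimHess(full_par, full_nll), silent = TRUE)
  if (!inherits(hess, "try-error")) {
    cov <- try(solve(hess), silent = TRUE)
    if (!inherits(cov, "try-error")) {
      d <- diag(cov)
      se[d > 0] <- sqrt(d[d > 0])
    }
  }

  dev_terms <- ifelse(n > 0, n * log(n / mu), 0) - (n - mu)
  deviance <- 2 * sum(dev_terms)
  logl <- sum(stats::dpois(round(n), mu, log = TRUE))

  structure(
    list(
      model = decay_model(PAD = PAD, tauD = cal$tauD, tauAD = cal$tauAD,
                          t0 = t0, tauG = tauG, F0 = F0),
      se = se,
      deviance = deviance,
      df_residual = length(n) - length(full_par),
      logLik = logl,
      fitted = mu,
      hist = hist,
      calibration = cal,
      convergence = opt$convergence,
      method = method,
      wrap_periods = wrap_periods
    ),
    class = "decay_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decay_fit <- function(x, ...) {
  cat("IRF-convolved biexponential decay fit (", x$method, ")\n", sep = "")
  cat(sprintf("  photons: %d   channels: %d   deviance: %.1f on %d df\n",
              round(sum(x$hist$counts)), length(x$hist$counts),
              x$deviance, x$df_residual))
  print(x$model)
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  m <- object$model
  c(F0 = m$F0, PAD = m$PAD, t0 = m$t0, tauG = m$tauG)
}

#' @export
logLik.decay_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$se), class = "logLik")
}

#' @export
summary.decay_fit <- function(object, ...) {
  m <- object$model
  est <- coef(object)
  se <- object$se[names(est)]
  tab <- cbind(Estimate = est, `Std. Error` = unname(se))
  out <- list(coefficients = tab,
              fixed = c(tauD = m$tauD, tauAD = m$tauAD),
              deviance = object$deviance,
              df_residual = object$df_residual,
              n_photons = sum(object$hist$counts),
              mean_lifetime = mean_arrival_time(object$hist) - m$t0,
              calibration = object$calibration)
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  cat("Decay fit summary\n")
  stats::printCoefmat(x$coefficients, na.print = "-")
  cat(sprintf("Fixed lifetimes: tauD = %.2f ns, tauAD = %.2f ns\n",
              x$fixed[["tauD"]], x$fixed[["tauAD"]]))
  cat(sprintf("Deviance %.1f on %d df; %d photons; <tau> = %.3f ns\n",
              x$deviance, x$df_residual, round(x$n_photons),
              x$mean_lifetime))
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  centers <- if (is.null(newdata)) object$hist$channel_centers else newdata
  model_curve(centers, object$model, period = object$hist$period,
              wrap_periods = object$wrap_periods)
}

#' @export
residuals.decay_fit <- function(object,
                                type = c("pearson", "deviance", "response"),
                                ...) {
  type <- match.arg(type)
  n <- object$hist$counts
  mu <- object$fitted
  switch(type,
         response = n - mu,
         pearson = (n - mu) / sqrt(mu),
         deviance = {
           d <- 2 * (ifelse(n > 0, n * log(n / mu), 0) - (n - mu))
           sign(n - mu) * sqrt(pmax(d, 0))
         })
}

#' @export
plot.decay_fit <- function(x, log = "y", ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  h <- x$hist
  ylo <- if (grepl("y", log)) pmax(h$counts, 0.5) else h$counts
  graphics::plot(h$channel_centers, ylo, type = "p", pch = 16, cex = 0.4,
                 log = log, xlab = "", ylab = "photons / channel", ...)
  graphics::lines(h$channel_centers, x$fitted, col = 2, lwd = 2)
  graphics::plot(h$channel_centers, residuals(x), type = "h",
                 xlab = "arrival time (ns)", ylab = "Pearson resid.")
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Simulate photon arrival times from a fitted decay model
#'
#' Draws new arrival-time datasets from the fitted model, each with the same
#' total photon count as the fitted histogram (parametric bootstrap).
#'
#' @param object a [decay_fit].
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return A list of `nsim` numeric vectors of arrival times (ns).
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = 1, ...) {
  n <- round(sum(object$hist$counts))
  lapply(seq_len(nsim), function(k) {
    sample_arrival_times(object$model, n, seed = seed + k - 1,
                         period = object$hist$period)
  })
}
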