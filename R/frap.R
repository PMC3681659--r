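# FRAP recovery analysis: trace container, normalization, Soumpasis
# uniform-disk recovery model, diffusivity and mobile-fraction estimation.

#' FRAP intensity trace
#'
#' Bleach-corrected mean ROI intensity versus time. Time zero is the end of
#' bleaching; pre-bleach samples have negative times. When the anchor
#' intensities are not supplied they are estimated from the trace: `I_pre` as
#' the mean of pre-bleach samples, `I_0` as the first post-bleach sample and
#' `I_inf` as the mean of the last 10% of samples (clamped into
#' `[I_0, I_pre]`).
#'
#' @param times Sample times, s, strictly increasing.
#' @param intensities Mean ROI fluorescence, arbitrary units.
#' @param roi_radius Bleach-spot radius, um.
#' @param I_pre,I_0,I_inf Optional anchor intensities (pre-bleach, immediately
#'   post-bleach, plateau).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(times, intensities, roi_radius,
                       I_pre = NULL, I_0 = NULL, I_inf = NULL) {
  if (length(times) != length(intensities)) stop("times/intensities length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.finite(roi_radius) || roi_radius <= 0) stop("roi_radius must be positive (um)")
  post <- times >= 0
  if (!any(post)) stop("no post-bleach samples (times >= 0)")
  if (is.null(I_pre)) {
    if (!any(!post)) stop("I_pre not given and no pre-bleach samples to estimate it")
    I_pre <- mean(intensities[!post])
  }
  if (is.null(I_0)) I_0 <- intensities[post][1]
  if (I_0 >= I_pre) stop("no bleach contrast: I_0 must be below I_pre")
  if (is.null(I_inf)) {
    n <- length(times)
    tail_idx <- seq.int(max(1L, ceiling(0.9 * n)), n)
    I_inf <- mean(intensities[tail_idx])
  }
  I_inf <- min(max(I_inf, I_0), I_pre)
  structure(list(times = times, intensities = intensities,
                 roi_radius = roi_radius,
                 I_pre = I_pre, I_0 = I_0, I_inf = I_inf),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d samples, roi = %g um, I_pre = %.4g, I_0 = %.4g, I_inf = %.4g\n",
              length(x$times), x$roi_radius, x$I_pre, x$I_0, x$I_inf))
  invisible(x)
}

#' Normalize a FRAP trace to fractional recovery
#'
#' `f(t) = (I(t) - I_0) / (I_pre - I_0)` over the post-bleach samples, so
#' `f(0) = 0` for a full bleach and the plateau sits below 1 when an immobile
#' fraction is present.
#'
#' @param trace A [frap_trace()].
#' @return `data.frame` with columns `time` (s) and `f`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (trace$I_pre == trace$I_0) stop("no bleach contrast (I_pre == I_0)")
  post <- trace$times >= 0
  data.frame(time = trace$times[post],
             f = (trace$intensities[post] - trace$I_0) /
               (trace$I_pre - trace$I_0))
}

#' Soumpasis recovery curve for a uniform circular bleach spot
#'
#' Closed-form fractional recovery of free diffusion into a uniformly bleached
#' disk: `f(t) = exp(-2*tau/t) * (I0(2*tau/t) + I1(2*tau/t))` with modified
#' Bessel functions of the first kind. `tau_D = w^2 / (4 D)` is the
#' characteristic diffusion time for spot radius `w`.
#'
#' @param t Time since bleach, s (vectorized; `t = 0` maps to 0).
#' @param tau_D Characteristic diffusion time, s.
#' @return Fractional recovery in \[0, 1).
#' @examples
#' soumpasis_recovery(1.66, 1.66)   # ~0.524 at t = tau_D
#' @export
soumpasis_recovery <- function(t, tau_D) {
  if (tau_D <= 0) stop("tau_D must be positive")
  if (any(t < 0)) stop("t must be non-negative")
  out <- numeric(length(t))
  pos <- t > 0
  x <- 2 * tau_D / t[pos]
  # exponentially scaled Bessels: exp(-x) * I_nu(x), stable for large x
  out[pos] <- besselI(x, 0, expon.scaled = TRUE) +
    besselI(x, 1, expon.scaled = TRUE)
  out
}

# t_half / tau_D for the Soumpasis curve (f = 1/2), used for initial guesses.
.soumpasis_half_time_ratio <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- stats::uniroot(function(u) soumpasis_recovery(u, 1) - 0.5,
                             c(0.1, 10), tol = 1e-10)$root
    val
  }
})

#' Fit the Soumpasis model to a FRAP trace
#'
#' Fits `f(t) = M * f_s(t; tau_D)` to the normalized recovery by
#' Levenberg-Marquardt least squares, where `f_s` is [soumpasis_recovery()]
#' and `M` the mobile fraction. Initial guesses: `M` from the plateau of the
#' last 10% of the trace, `tau_D` from the half-recovery time through the
#' Soumpasis half-time relation. Box bounds `tau_D` in (0, 1e3\] s and `M` in
#' \[0, 1.05\] (slight overshoot allowed for noise; clipped on report).
#'
#' @param trace A [frap_trace()] with at least 10 post-bleach samples.
#' @return An object of class `frap_fit`: list with `D` (um^2/s), `tau_D` (s),
#'   `mobile_fraction` (clipped to \[0, 1\]), `M_raw`, `residual` (RSS),
#'   `covariance` (2x2, may be `NULL` if unavailable), `roi_radius`,
#'   `at_bounds` flag.
#' @examples
#' tr <- gen_frap_trace(D = 110, M = 1, w = 27, noise = 0)
#' fit_frap(tr)$D
#' @export
fit_frap <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  nf <- normalize_trace(trace)
  nf <- nf[nf$time > 0, ]
  if (nrow(nf) < 10) stop("need at least 10 post-bleach samples")
  M0 <- {
    n <- nrow(nf)
    mean(nf$f[seq.int(max(1L, ceiling(0.9 * n)), n)])
  }
  M0 <- min(max(M0, 0.05), 1.05)
  i_half <- which(nf$f >= M0 / 2)[1]
  t_half <- if (is.na(i_half)) stats::median(nf$time) else nf$time[i_half]
  tau0 <- max(t_half / .soumpasis_half_time_ratio(), min(nf$time))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ M * soumpasis_recovery(time, tau),
      data = nf,
      start = list(M = M0, tau = tau0),
      lower = c(M = 0, tau = 1e-8),
      upper = c(M = 1.05, tau = 1e3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(
        "FRAP fit did not converge (start M = %.3g, tau = %.3g s): %s",
        M0, tau0, conditionMessage(e)), call. = FALSE))
  cf <- stats::coef(fit)
  tau_D <- unname(cf["tau"]); M <- unname(cf["M"])
  at_bounds <- tau_D >= 1e3 * (1 - 1e-6) || tau_D <= 1e-8 * (1 + 1e-6)
  if (at_bounds) warning("tau_D hit a fitting bound; estimate unreliable")
  span <- diff(range(nf$time))
  if (span < 2 * tau_D)
    warning("trace spans less than 2*tau_D; diffusivity poorly constrained")
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(list(D = trace$roi_radius^2 / (4 * tau_D),
                 tau_D = tau_D,
                 mobile_fraction = min(max(M, 0), 1),
                 M_raw = M,
                 residual = sum(stats::resid(fit)^2),
                 covariance = vc,
                 roi_radius = trace$roi_radius,
                 at_bounds = at_bounds),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> D = %.4g um^2/s (tau_D = %.4g s, roi = %g um), mobile fraction = %.3f, RSS = %.3g\n",
              x$D, x$tau_D, x$roi_radius, x$mobile_fraction, x$residual))
  invisible(x)
}

#' Mobile fraction from trace anchor intensities
#'
#' `M = (I_inf - I_0) / (I_pre - I_0)`, the fraction of probe molecules free
#' to exchange into the bleached spot, read directly from the plateau.
#'
#' @param trace A [frap_trace()].
#' @return Mobile fraction in \[0, 1\].
#' @export
mobile_fraction <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (trace$I_pre == trace$I_0) stop("no bleach contrast (I_pre == I_0)")
  M <- (trace$I_inf - trace$I_0) / (trace$I_pre - trace$I_0)
  min(max(M, 0), 1)
}
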