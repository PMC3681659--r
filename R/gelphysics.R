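# Gel-level calibration: Darcy permeability, fibrin volume fraction, fiber
# radius from the random-fibre permeability relation, and hindered-diffusion
# models for globular proteins in fibrin networks.
#
# Units contract (applies package-wide): lengths nm or um as documented per
# argument, permeability um^2, diffusivity um^2/s, viscosity Pa*s; permeation
# geometry is SI (m, m^2, Pa) because that is how it is measured.

.kB <- 1.380649e-23            # Boltzmann constant, J/K
.water_density <- 998          # kg/m^3, perfusate at room temperature

#' Diffusing-probe specification
#'
#' Describes a globular protein probe by its hydrodynamic size, free-solution
#' diffusivity and the obstruction-model flexibility parameters.
#'
#' @param name Label for the probe (e.g. `"thrombin"`).
#' @param d_h Hydrodynamic diameter, nm.
#' @param D0 Free-solution diffusivity, um^2/s.
#' @param alpha Solute flexibility factor, in (0, 1].
#' @param beta Fiber flexibility factor, in (0, 1].
#' @param s Obstruction step-size constant (dimensionless, > 0).
#' @return An object of class `probe_spec`.
#' @examples
#' thrombin <- probe_spec("thrombin", d_h = 4.1, D0 = 110, alpha = 0.1, beta = 1, s = 17)
#' @export
probe_spec <- function(name, d_h, D0, alpha = 0.1, beta = 1, s = 17) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(d_h) || d_h <= 0) stop("d_h must be a positive diameter in nm")
  if (!is.finite(D0) || D0 <= 0) stop("D0 must be a positive diffusivity in um^2/s")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  if (s <= 0) stop("s must be positive")
  structure(list(name = name, d_h = d_h, D0 = D0,
                 alpha = alpha, beta = beta, s = s),
            class = "probe_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf("<probe_spec> %s: d_h = %.2f nm, D0 = %.1f um^2/s, alpha = %g, beta = %g, s = %g\n",
              x$name, x$d_h, x$D0, x$alpha, x$beta, x$s))
  invisible(x)
}

#' Fibrin gel sample
#'
#' A single gel: fibrinogen concentration, fibrin volume fraction and the two
#' structural quantities derived from permeation, fiber radius and Darcy
#' permeability. Derived fields may be `NA` until calibrated.
#'
#' @param c_fg Fibrinogen concentration, mg/mL (`NA` if unknown).
#' @param phi Fibrin volume fraction, in \[0, 1).
#' @param r_f Fiber radius, nm (`NA` until derived).
#' @param k_s Darcy permeability, um^2 (`NA` until measured).
#' @return An object of class `gel_sample`.
#' @export
gel_sample <- function(c_fg = NA_real_, phi, r_f = NA_real_, k_s = NA_real_) {
  if (!is.finite(phi) || phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  if (!is.na(r_f) && r_f <= 0) stop("r_f must be positive when set")
  if (!is.na(k_s) && k_s <= 0) stop("k_s must be positive when set")
  structure(list(c_fg = c_fg, phi = phi, r_f = r_f, k_s = k_s),
            class = "gel_sample")
}

#' @export
print.gel_sample <- function(x, ...) {
  cat(sprintf("<gel_sample> c_fg = %s mg/mL, phi = %.3g, r_f = %s nm, k_s = %s um^2\n",
              format(x$c_fg), x$phi, format(x$r_f), format(x$k_s)))
  invisible(x)
}

#' Permeation measurement of a cylindrical clot
#'
#' Raw data of a constant-pressure perfusion experiment: cumulative outflow
#' mass versus time through a clot of known geometry.
#'
#' @param clot_length Length of the cylindrical clot, m.
#' @param tube_area Cross-sectional area of the tube, m^2.
#' @param pressure_drop Pressure drop across the clot, Pa (must be > 0).
#' @param viscosity Perfusate dynamic viscosity, Pa*s.
#' @param flow_series `data.frame` with columns `time_s` (strictly increasing)
#'   and `mass_g` (cumulative outflow mass).
#' @param strict If `TRUE` (default) reject series whose cumulative mass
#'   decreases anywhere; noisy synthetic series may set `FALSE`.
#' @return An object of class `permeation_measurement`.
#' @export
permeation_measurement <- function(clot_length, tube_area, pressure_drop,
                                   viscosity, flow_series, strict = TRUE) {
  for (nm in c("clot_length", "tube_area", "viscosity")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) stop(sprintf("%s must be positive", nm))
  }
  if (!is.finite(pressure_drop) || pressure_drop <= 0)
    stop("pressure_drop must be positive")
  if (!is.data.frame(flow_series) ||
      !all(c("time_s", "mass_g") %in% names(flow_series)))
    stop("flow_series must have columns time_s and mass_g")
  if (nrow(flow_series) < 2) stop("flow_series needs at least 2 points")
  if (any(diff(flow_series$time_s) <= 0))
    stop("flow_series time must be strictly increasing")
  if (strict && any(diff(flow_series$mass_g) < 0))
    stop("cumulative outflow mass must be non-decreasing")
  structure(list(clot_length = clot_length, tube_area = tube_area,
                 pressure_drop = pressure_drop, viscosity = viscosity,
                 flow_series = flow_series),
            class = "permeation_measurement")
}

#' Darcy permeability from a permeation measurement
#'
#' The volumetric flow rate Q is the ordinary least-squares slope of
#' cumulative outflow volume (mass / water density) against time; the
#' permeability then follows from Darcy's law, k = Q * mu * L / (A * dP).
#'
#' @param m A [permeation_measurement()].
#' @return Permeability in um^2. A series with zero slope returns 0 with
#'   attribute `degenerate = TRUE`.
#' @examples
#' m <- gen_permeation(k = 10, noise = 0)
#' darcy_permeability(m)   # 10
#' @export
darcy_permeability <- function(m) {
  if (!inherits(m, "permeation_measurement"))
    stop("m must be a permeation_measurement")
  fs <- m$flow_series
  volume_m3 <- fs$mass_g / 1000 / .water_density
  Q <- unname(stats::coef(stats::lm(volume_m3 ~ fs$time_s))[2])  # m^3/s
  if (!is.finite(Q)) stop("flow series slope is not finite")
  k_m2 <- Q * m$viscosity * m$clot_length / (m$tube_area * m$pressure_drop)
  k <- k_m2 * 1e12
  if (abs(k) < .Machine$double.eps * 100 || Q <= 0) {
    k <- 0
    attr(k, "degenerate") <- TRUE
  }
  k
}

#' Fibrin volume fraction of a prepared gel
#'
#' Volume balance of a gel prepared from desiccated fibrinogen, water and
#' buffer: `phi = f * m_f*nu_f / (m_f*nu_f + (m_w + m_b)*nu_wb)` where `f`
#' corrects for the density difference between polymerized fibrin and
#' fibrinogen.
#'
#' @param m_f Desiccated fibrinogen mass, g.
#' @param m_w Water mass, g.
#' @param m_b Buffer mass, g.
#' @param nu_f Fibrinogen specific volume, cm^3/g (default 0.725).
#' @param nu_wb Water-buffer specific volume, cm^3/g (default 1.02).
#' @param density_factor Fibrin/fibrinogen density correction (default 1.25).
#' @return Fibrin volume fraction, in \[0, 1).
#' @examples
#' fibrin_volume_fraction(m_f = 0.004, m_w = 1, m_b = 0)   # ~3.5e-3 at 4 mg/mL
#' @export
fibrin_volume_fraction <- function(m_f, m_w, m_b = 0, nu_f = 0.725,
                                   nu_wb = 1.02, density_factor = 1.25) {
  if (any(c(m_f, m_w, m_b) < 0)) stop("masses must be non-negative")
  if (m_f + m_w + m_b == 0) stop("all masses are zero")
  if (nu_f <= 0 || nu_wb <= 0) stop("specific volumes must be positive")
  phi <- density_factor * (m_f * nu_f) / (m_f * nu_f + (m_w + m_b) * nu_wb)
  if (phi >= 1) stop("computed volume fraction >= 1; check inputs")
  phi
}

# Validity bound of the random-fibre relation: the log term must be positive.
.phi_max_jackson_james <- exp(-0.931)

.check_phi_jj <- function(phi) {
  if (any(!is.finite(phi) | phi <= 0 | phi >= .phi_max_jackson_james))
    stop(sprintf(
      "phi must lie in (0, %.3f) for the random-fibre permeability relation",
      .phi_max_jackson_james))
}

#' Permeability of a random fibrous medium (forward relation)
#'
#' Jackson-James relation for flow through a 3-D random array of fibres:
#' `k = r_f^2 * 3/(20*phi) * (-ln(phi) - 0.931)`.
#'
#' @param r_f Fiber radius, nm.
#' @param phi Fibrin volume fraction, in (0, exp(-0.931)).
#' @return Permeability, um^2.
#' @seealso [fiber_radius_from_permeability()] for the inverse.
#' @export
permeability_from_fiber_radius <- function(r_f, phi) {
  .check_phi_jj(phi)
  if (any(r_f <= 0)) stop("r_f must be positive")
  r_um <- r_f / 1000
  r_um^2 * 3 / (20 * phi) * (-log(phi) - 0.931)
}

#' Fiber radius from measured permeability and volume fraction
#'
#' Inverts the Jackson-James random-fibre relation for the fiber radius.
#'
#' @param k_s Darcy permeability, um^2 (> 0).
#' @param phi Fibrin volume fraction, in (0, exp(-0.931)).
#' @return Fiber radius, nm.
#' @examples
#' k <- permeability_from_fiber_radius(300, 0.002)
#' fiber_radius_from_permeability(k, 0.002)   # 300
#' @export
fiber_radius_from_permeability <- function(k_s, phi) {
  .check_phi_jj(phi)
  if (any(k_s <= 0)) stop("k_s must be positive")
  r_um <- sqrt(k_s * 20 * phi / (3 * (-log(phi) - 0.931)))
  r_um * 1000
}

#' Power-law fit of permeability against volume fraction
#'
#' Least-squares fit of `k_s = prefactor * (phi - offset)^exponent` in log
#' space. The offset is profiled out: for each candidate offset the remaining
#' two parameters are a linear regression of `log(k)` on `log(phi - offset)`;
#' the offset minimising the residual sum of squares over `[0, min(phi))` is
#' kept (0 is always considered, so zero-offset laws are recovered exactly).
#'
#' @param samples `data.frame` (or `gel_panel`) with columns `phi` and `k_s`;
#'   at least 3 rows with distinct `phi`.
#' @return An object of class `power_law_fit`: list with `prefactor` (um^2),
#'   `exponent`, `offset`, `residual` (RSS in log space), `n`.
#' @export
fit_permeability_power_law <- function(samples) {
  if (inherits(samples, "gel_sample")) samples <- as.data.frame(unclass(samples))
  if (!is.data.frame(samples) || !all(c("phi", "k_s") %in% names(samples)))
    stop("samples must have columns phi and k_s")
  samples <- samples[is.finite(samples$phi) & is.finite(samples$k_s), ]
  if (nrow(samples) < 3 || length(unique(samples$phi)) < 3)
    stop("need at least 3 samples with distinct phi")
  if (any(samples$k_s <= 0) || any(samples$phi <= 0))
    stop("phi and k_s must be positive")
  phi <- samples$phi; k <- samples$k_s
  logk <- log(k)
  rss_at <- function(phi0) {
    x <- log(phi - phi0)
    sum(stats::resid(stats::lm(logk ~ x))^2)
  }
  upper <- min(phi) * (1 - 1e-9)
  opt <- stats::optimize(rss_at, c(0, upper), tol = 1e-12)
  phi0 <- if (rss_at(0) <= opt$objective) 0 else opt$minimum
  x <- log(phi - phi0)
  fit <- stats::lm(logk ~ x)
  cf <- stats::coef(fit)
  structure(list(prefactor = exp(unname(cf[1])), exponent = unname(cf[2]),
                 offset = phi0, residual = sum(stats::resid(fit)^2),
                 n = length(phi)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> k = %.4g * (phi - %.3g)^%.4g  [n = %d, RSS(log) = %.3g]\n",
              x$prefactor, x$offset, x$exponent, x$n, x$residual))
  invisible(x)
}

#' Predict permeability from a power-law fit
#'
#' @param object A [fit_permeability_power_law()] result.
#' @param phi Volume fractions at which to evaluate (must exceed the offset).
#' @param ... Unused.
#' @return Permeability, um^2.
#' @export
predict.power_law_fit <- function(object, phi, ...) {
  if (any(phi <= object$offset)) stop("phi must exceed the fitted offset")
  object$prefactor * (phi - object$offset)^object$exponent
}

#' Stokes-Einstein diffusivity of a sphere
#'
#' `D = kB * T / (3 * pi * mu * d_h)` for a sphere of hydrodynamic diameter
#' `d_h`; the relation used to convert between measured diffusivities and
#' hydrodynamic sizes.
#'
#' @param d_h Hydrodynamic diameter, nm.
#' @param T_K Absolute temperature, K (default 293.15).
#' @param mu Solvent dynamic viscosity, Pa*s (default water, 1e-3).
#' @return Diffusivity, um^2/s.
#' @examples
#' stokes_einstein_diffusivity(4.1, T_K = 303.15, mu = 0.797e-3)
#' @export
stokes_einstein_diffusivity <- function(d_h, T_K = 293.15, mu = 1e-3) {
  if (any(d_h <= 0) || T_K <= 0 || mu <= 0) stop("all inputs must be positive")
  D_m2 <- .kB * T_K / (3 * pi * mu * d_h * 1e-9)
  D_m2 * 1e12
}

#' Hindered diffusivity: extended Ogston obstruction model
#'
#' Stretched-exponential obstruction model for a flexible solute in a network
#' of flexible thick fibres:
#' `D/D0 = exp(-alpha*beta*s*sqrt(phi)*(1 + d_h/(2*r_f)))`.
#'
#' @param probe A [probe_spec()].
#' @param gel A [gel_sample()] with `phi` (and `r_f` in nm) set.
#' @return Relative diffusivity `D/D0` in (0, 1].
#' @export
ogston_diffusivity <- function(probe, gel) {
  stopifnot(inherits(probe, "probe_spec"), inherits(gel, "gel_sample"))
  phi <- gel$phi
  if (phi == 0) return(1)
  if (!is.finite(gel$r_f) || gel$r_f <= 0)
    stop("gel must carry a positive fiber radius r_f (nm)")
  exp(-probe$alpha * probe$beta * probe$s * sqrt(phi) *
        (1 + probe$d_h / (2 * gel$r_f)))
}

#' Hindered diffusivity: effective-medium (Johnson) model
#'
#' Product of a steric obstruction factor `S = exp(-0.84 * f^1.09)` with
#' `f = phi * (1 + r_s/r_f)^2`, and a hydrodynamic screening factor
#' `H = 1 / (1 + r_s/sqrt(k_s) + r_s^2/(9*k_s))` built on the Brinkman
#' screening length of the medium.
#'
#' @param probe A [probe_spec()]; `r_s = d_h/2`.
#' @param gel A [gel_sample()] with `phi`, `r_f` (nm) and, when
#'   `include_hydrodynamic`, permeability `k_s` (um^2).
#' @param include_hydrodynamic Include the hydrodynamic factor H (default
#'   `TRUE`); for fibrin-gel permeabilities of 1-1000 um^2 and nm-scale probes
#'   H differs from 1 by well under 1%.
#' @return Relative diffusivity `D/D0` in (0, 1].
#' @export
johnson_diffusivity <- function(probe, gel, include_hydrodynamic = TRUE) {
  stopifnot(inherits(probe, "probe_spec"), inherits(gel, "gel_sample"))
  phi <- gel$phi
  r_s_nm <- probe$d_h / 2
  S <- if (phi == 0) 1 else {
    if (!is.finite(gel$r_f) || gel$r_f <= 0)
      stop("gel must carry a positive fiber radius r_f (nm)")
    f <- phi * (1 + r_s_nm / gel$r_f)^2
    exp(-0.84 * f^1.09)
  }
  H <- 1
  if (include_hydrodynamic) {
    k <- gel$k_s
    if (is.finite(k)) {
      if (k <= 0) stop("k_s must be positive for the hydrodynamic factor")
      r_s_um <- r_s_nm / 1000
      H <- 1 / (1 + r_s_um / sqrt(k) + r_s_um^2 / (9 * k))
    }
  }
  S * H
}

#' Tortuosity of a gel for a given solute
#'
#' Ratio of the free-solution diffusivity to the in-gel diffusivity.
#'
#' @param D0 Free-solution diffusivity, um^2/s.
#' @param D_gel In-gel diffusivity, um^2/s (must not exceed `D0`).
#' @return Tortuosity, >= 1.
#' @examples
#' tortuosity(110, 110 * (1 - 0.13))   # ~1.15
#' @export
tortuosity <- function(D0, D_gel) {
  if (any(D0 <= 0) || any(D_gel <= 0)) stop("diffusivities must be positive")
  if (any(D_gel > D0)) stop("D_gel must not exceed D0")
  D0 / D_gel
}
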