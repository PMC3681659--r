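# Seeded generators for the three measurement types the analysis consumes:
# FRAP recovery traces, constant-pressure permeation series, and fibrin-gel
# calibration panels. All are pure functions of (parameters, seed): the same
# seed reproduces the same object bit for bit. Noise is additive Gaussian,
# proportional to the signal scale.

# Run fn() under a temporary RNG state; restores the caller's stream.
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Generate a synthetic FRAP trace
#'
#' Forward model of a circular-spot photobleaching experiment: the recovery
#' follows `M * f_s(t; tau_D)` with `tau_D = w^2/(4 D)` ([soumpasis_recovery()]),
#' mapped to raw intensities between `I_bleach` and `I_pre`, with additive
#' Gaussian noise proportional to the bleach contrast. Pre-bleach samples at
#' negative times are included.
#'
#' @param D Diffusivity, um^2/s.
#' @param M Mobile fraction in \[0, 1\].
#' @param w Bleach-spot (ROI) radius, um (default 27).
#' @param noise Noise standard deviation as a fraction of the bleach contrast
#'   `I_pre - I_bleach`.
#' @param seed Integer seed.
#' @param n_pre,n_post Number of pre-/post-bleach samples.
#' @param t_max Last sample time, s (default `12 * tau_D`).
#' @param I_pre,I_bleach Pre-bleach and immediately-post-bleach intensities.
#' @return A [frap_trace()] carrying the exact anchor intensities.
#' @examples
#' tr <- gen_frap_trace(D = 110, M = 0.97, noise = 0.02, seed = 7)
#' fit_frap(tr)
#' @export
gen_frap_trace <- function(D, M = 1, w = 27, noise = 0, seed = 1,
                           n_pre = 10, n_post = 200, t_max = NULL,
                           I_pre = 1000, I_bleach = 300) {
  if (D <= 0 || w <= 0) stop("D and w must be positive")
  if (M < 0 || M > 1) stop("M must lie in [0, 1]")
  if (noise < 0) stop("noise must be non-negative")
  if (I_bleach >= I_pre) stop("I_bleach must be below I_pre")
  tau_D <- w^2 / (4 * D)
  if (is.null(t_max)) t_max <- 12 * tau_D
  dt <- t_max / n_post
  times <- c(-rev(seq_len(n_pre)) * dt, seq_len(n_post) * dt)
  contrast <- I_pre - I_bleach
  clean <- c(rep(I_pre, n_pre),
             I_bleach + M * contrast * soumpasis_recovery(seq_len(n_post) * dt,
                                                          tau_D))
  intens <- .with_seed(seed, function()
    clean + stats::rnorm(length(clean), sd = noise * contrast))
  frap_trace(times, intens, roi_radius = w,
             I_pre = I_pre, I_0 = I_bleach,
             I_inf = I_bleach + M * contrast)
}

#' Generate a synthetic permeation measurement
#'
#' Linear cumulative-outflow series of a Darcy flow at permeability `k`
#' through a cylindrical clot, with additive Gaussian noise on the mass
#' readings; round-trips through [darcy_permeability()].
#'
#' @param k Permeability, um^2.
#' @param clot_length Clot length, m (default 1 cm).
#' @param tube_diameter Tube internal diameter, m (default 1.5 mm).
#' @param pressure_drop Pressure drop, Pa.
#' @param viscosity Perfusate viscosity, Pa*s.
#' @param noise Noise sd as a fraction of the final outflow mass.
#' @param seed Integer seed.
#' @param times Sampling times, s.
#' @return A [permeation_measurement()].
#' @export
gen_permeation <- function(k, clot_length = 0.01, tube_diameter = 0.0015,
                           pressure_drop = 100, viscosity = 1e-3,
                           noise = 0, seed = 1,
                           times = seq(60, 600, by = 60)) {
  if (k <= 0) stop("k must be positive (um^2)")
  if (noise < 0) stop("noise must be non-negative")
  A <- pi * tube_diameter^2 / 4
  Q <- (k * 1e-12) * A * pressure_drop / (viscosity * clot_length)  # m^3/s
  mass <- Q * .water_density * 1000 * times                         # g
  if (noise > 0)
    mass <- .with_seed(seed, function()
      mass + stats::rnorm(length(mass), sd = noise * max(mass)))
  permeation_measurement(
    clot_length = clot_length, tube_area = A,
    pressure_drop = pressure_drop, viscosity = viscosity,
    flow_series = data.frame(time_s = times, mass_g = mass),
    strict = noise == 0)
}

#' Generate a fibrin-gel calibration panel
#'
#' For each fibrinogen concentration, builds the volume fraction from the
#' preparation volume balance ([fibrin_volume_fraction()], 1 g solvent per
#' mg-scale fibrinogen dose), assigns a permeability from a power law in phi
#' calibrated so the panel spans the measured decade range (1000 um^2 at
#' 0.2 mg/mL down to 6 um^2 at 4 mg/mL, the smallest permeability whose
#' derived radius stays in the observed band), and derives the fiber radius
#' by inverting the random-fibre relation
#' ([fiber_radius_from_permeability()]). Multiplicative jitter `1 + noise*N(0,1)`
#' is applied to the permeabilities.
#'
#' @param c_fg Fibrinogen concentrations, mg/mL, each within the preparable
#'   range \[0.2, 4.2\].
#' @param noise Permeability jitter fraction.
#' @param seed Integer seed.
#' @return A `data.frame` of class `gel_panel` with columns `c_fg`, `phi`,
#'   `r_f` (nm), `k_s` (um^2).
#' @examples
#' gen_gel_panel(c(0.5, 1, 2, 4))
#' @export
gen_gel_panel <- function(c_fg, noise = 0, seed = 1) {
  if (any(c_fg < 0.2 | c_fg > 4.2))
    stop("concentrations must lie in the preparable range [0.2, 4.2] mg/mL")
  if (noise < 0) stop("noise must be non-negative")
  phi_of <- function(c) fibrin_volume_fraction(m_f = c * 1e-3, m_w = 1)
  phi <- vapply(c_fg, phi_of, numeric(1))
  # power-law anchors: (phi(0.2), 1000 um^2) and (phi(4), 6 um^2)
  phi_lo <- phi_of(0.2); phi_hi <- phi_of(4)
  b <- log(1000 / 6) / log(phi_hi / phi_lo)
  k <- 1000 * (phi / phi_lo)^(-b)
  if (noise > 0)
    k <- .with_seed(seed, function()
      k * pmax(1 + stats::rnorm(length(k), sd = noise), 0.05))
  r_f <- fiber_radius_from_permeability(k, phi)
  structure(data.frame(c_fg = c_fg, phi = phi, r_f = r_f, k_s = k),
            class = c("gel_panel", "data.frame"))
}
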