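# Nondimensional axisymmetric advection-diffusion of thrombin through the
# composite-sphere flow. Lengths are scaled by the core radius R1, velocities
# by the far-field speed U, time by R1/U and concentration by its initial
# value, so the equation is  dc/dt + div(u c) = (1/Pe) lap(c).
#
# Finite-volume scheme on a spherical (r, theta) grid: cell-centered,
# geometrically stretched in r near the core, uniform in theta; second-order
# MUSCL reconstruction with a minmod limiter for advective face values,
# central differences for diffusion, explicit strong-stability-preserving
# two-stage Runge-Kutta (Heun) stepping under a combined advective/diffusive
# CFL bound (a convex combination of Euler steps, so the limiter's TVD and
# positivity properties carry over while restoring second-order accuracy in
# time). Exact cell volumes r^2 sin(theta) dr dtheta.

#' Transport configuration
#'
#' @param Pe Peclet number `U * R1 / D` (> 0).
#' @param h Initial thrombin shell thickness, um.
#' @param n_r,n_theta Grid resolution (radial cells, polar cells).
#' @param r_max Outer boundary in units of R1 (>= 5; default 10).
#' @param cfl Stability number in (0, 0.5].
#' @param stretch Radial geometric stretching ratio (>= 1; cells grow away
#'   from the core).
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(Pe, h = 2, n_r = 128, n_theta = 64,
                             r_max = 10, cfl = 0.4, stretch = 1.02) {
  if (!is.finite(Pe) || Pe <= 0) stop("Pe must be positive")
  if (!is.finite(h) || h <= 0) stop("h must be positive (um)")
  if (n_r < 4 || n_theta < 4) stop("grid must have at least 4x4 cells")
  if (r_max < 5) stop("r_max must be >= 5 core radii")
  if (cfl <= 0 || cfl > 0.5) stop("cfl must lie in (0, 0.5]")
  if (stretch < 1) stop("stretch must be >= 1")
  structure(list(Pe = Pe, h = h, n_r = as.integer(n_r),
                 n_theta = as.integer(n_theta), r_max = r_max,
                 cfl = cfl, stretch = stretch),
            class = "transport_config")
}

# Geometrically stretched radial faces on [1, r_max] (nondimensional).
.radial_faces <- function(n_r, r_max, stretch) {
  if (stretch == 1) {
    seq(1, r_max, length.out = n_r + 1)
  } else {
    d0 <- (r_max - 1) * (stretch - 1) / (stretch^n_r - 1)
    c(1, 1 + cumsum(d0 * stretch^(0:(n_r - 1))))
  }
}

#' Initial spherical thrombin shell
#'
#' Builds the computational grid and sets `c = 1` in the shell
#' `R1 <= r <= R1 + h` hugging the core and 0 elsewhere, projected onto the
#' grid by exact cell-volume fractions so the discrete mass equals the shell
#' volume to roundoff; the initial field is independent of theta.
#'
#' @param cfg A [transport_config()].
#' @param geom A [thrombus_geometry()]; sets the core radius R1 (length
#'   scale) and cap radius R2.
#' @return An object of class `concentration_field`: grid geometry, `values`
#'   (`n_r` x `n_theta` matrix), nondimensional `time`, total `mass`
#'   (volume integral of c, omitting the azimuthal 2*pi).
#' @export
initial_shell <- function(cfg, geom) {
  stopifnot(inherits(cfg, "transport_config"),
            inherits(geom, "thrombus_geometry"))
  h_nd <- cfg$h / geom$R1
  rf <- .radial_faces(cfg$n_r, cfg$r_max, cfg$stretch)
  if (h_nd < (rf[2] - rf[1]))
    stop(sprintf(paste(
      "shell thickness h = %g um is below the first radial cell (%g um);",
      "increase n_r or the stretching, or thicken the shell"),
      cfg$h, (rf[2] - rf[1]) * geom$R1))
  thf <- seq(0, pi, length.out = cfg$n_theta + 1)
  rc <- (rf[-1] + rf[-length(rf)]) / 2
  thc <- (thf[-1] + thf[-length(thf)]) / 2
  # volume fraction of each radial cell inside the shell [1, 1 + h]
  lo <- pmin(pmax(rf[-length(rf)], 1), 1 + h_nd)
  hi <- pmin(pmax(rf[-1], 1), 1 + h_nd)
  frac <- (hi^3 - lo^3) / diff(rf^3)
  vals <- matrix(frac, cfg$n_r, cfg$n_theta)
  fld <- structure(list(r_faces = rf, th_faces = thf,
                        r_centers = rc, th_centers = thc,
                        values = vals, time = 0,
                        Pe = cfg$Pe, cfg = cfg,
                        R1 = geom$R1, r2 = geom$R2 / geom$R1,
                        mass = NA_real_),
                   class = "concentration_field")
  fld$mass <- field_mass(fld)
  fld
}

#' Total solute content of a concentration field
#'
#' Volume integral of c over the grid (nondimensional, without the azimuthal
#' factor 2*pi).
#'
#' @param field A [initial_shell()] / [advance_transport()] field.
#' @return Nondimensional mass.
#' @export
field_mass <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  sum(.cell_volumes(field) * field$values)
}

.cell_volumes <- function(field) {
  rf <- field$r_faces; thf <- field$th_faces
  dr3 <- diff(rf^3) / 3
  dmu <- -diff(cos(thf))          # cos(th_j) - cos(th_j+1) > 0
  outer(dr3, dmu)
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("<concentration_field> %d x %d grid on r/R1 in [1, %g], t = %.4g, mass = %.6g\n",
              nrow(x$values), ncol(x$values), max(x$r_faces), x$time, field_mass(x)))
  cat(sprintf("  c in [%.3g, %.3g]\n", min(x$values), max(x$values)))
  invisible(x)
}

.minmod <- function(a, b) {
  0.5 * (sign(a) + sign(b)) * pmin(abs(a), abs(b))
}

# Scheme-verification driver: 1-D periodic advection at constant speed with
# the same minmod-limited MUSCL reconstruction and SSP-RK2 stepping used by
# the 2-D solver. Exposed (unexported) so the limiter's TVD and accuracy
# properties can be checked in isolation.
.advect_1d <- function(c0, u, dx, cfl = 0.4, t_end) {
  n <- length(c0)
  dt <- cfl * dx / abs(u)
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  rhs <- function(cv) {
    d <- (cv - cv[c(n, 1:(n - 1))]) / dx          # backward differences
    slope <- .minmod(d, d[c(2:n, 1)])
    cf <- if (u >= 0) cv + slope * dx / 2 else    # value at right face
      cv[c(2:n, 1)] - slope[c(2:n, 1)] * dx / 2
    flux <- u * cf                                 # right-face fluxes
    -(flux - flux[c(n, 1:(n - 1))]) / dx
  }
  cv <- c0
  for (s in seq_len(nsteps)) {                     # SSP-RK2 (Heun)
    c1 <- cv + dt * rhs(cv)
    cv <- 0.5 * (cv + c1 + dt * rhs(c1))
  }
  cv
}

#' Advance the thrombin field in time
#'
#' Explicit finite-volume integration to nondimensional time `t_end`.
#' Boundary conditions: zero normal flux at the core surface `r = R1`;
#' at the outer boundary, `c = 0` on inflow faces and zero-gradient on
#' outflow faces (`boundary = "open"`, the default), or no flux anywhere
#' (`boundary = "closed"`). Symmetry at the poles is automatic (the polar
#' face areas vanish).
#'
#' @param field A `concentration_field`.
#' @param flow A [solve_composite_sphere()] solution sharing the geometry, or
#'   `NULL` for pure diffusion.
#' @param cfg The [transport_config()] (for `cfl`).
#' @param t_end Target nondimensional time (must exceed `field$time`).
#' @param boundary `"open"` or `"closed"` outer boundary.
#' @param source Optional volumetric production term: an `n_r` x `n_theta`
#'   matrix of nondimensional rates added to `dc/dt` (default none; the
#'   baseline release is the initial shell only).
#' @return The advanced `concentration_field`; attribute `diagnostics` holds
#'   the step count, time step, accumulated boundary outflow and the largest
#'   per-step mass-budget residual.
#' @export
advance_transport <- function(field, flow, cfg, t_end,
                              boundary = c("open", "closed"),
                              source = NULL) {
  stopifnot(inherits(field, "concentration_field"),
            inherits(cfg, "transport_config"))
  boundary <- match.arg(boundary)
  if (t_end <= field$time) stop("t_end must exceed the field time")
  rf <- field$r_faces; thf <- field$th_faces
  rc <- field$r_centers; thc <- field$th_centers
  nr <- length(rc); nth <- length(thc)
  Pe <- field$Pe
  V <- .cell_volumes(field)
  dmu <- -diff(cos(thf))
  dth <- diff(thf)[1]
  # face areas (azimuthal 2*pi omitted consistently)
  Sr <- outer(rf^2, dmu)                       # (nr+1) x nth
  Sth <- outer(diff(rf^2) / 2, sin(thf))       # nr x (nth+1); 0 at poles
  # face velocities (nondimensional), steady
  if (is.null(flow)) {
    ur_f <- matrix(0, nr + 1, nth)
    ut_f <- matrix(0, nr, nth + 1)
  } else {
    stopifnot(inherits(flow, "flow_solution"))
    R1 <- field$R1; U <- flow$geometry$U
    ur_f <- matrix(flow_velocity(flow,
                                 rep(rf * R1, nth),
                                 rep(thc, each = nr + 1))[, "u_r"],
                   nr + 1, nth) / U
    ut_f <- matrix(flow_velocity(flow,
                                 rep(rc * R1, nth + 1),
                                 rep(thf, each = nr))[, "u_theta"],
                   nr, nth + 1) / U
  }
  ur_f[1, ] <- 0                                # no-slip core: exact zero
  if (boundary == "closed") ur_f[nr + 1, ] <- 0
  # cell spacings for gradients and CFL
  dr <- diff(rf)
  drc <- diff(rc)                               # between-center distances
  dr_ghost_out <- rf[nr + 1] - rc[nr]
  inv_drc <- 1 / drc
  # CFL bound from combined advective + diffusive stability
  ur_c <- (abs(ur_f[-1, , drop = FALSE]) + abs(ur_f[-(nr + 1), , drop = FALSE])) / 2
  ut_c <- (abs(ut_f[, -1, drop = FALSE]) + abs(ut_f[, -(nth + 1), drop = FALSE])) / 2
  rate <- sweep(ur_c, 1, dr, "/") + ut_c / (rc * dth) +
    (2 / Pe) * (outer(1 / dr^2, rep(1, nth)) + 1 / (rc * dth)^2)
  dt_stab <- cfg$cfl / max(rate)
  cvals <- field$values
  t_now <- field$time
  n_steps <- 0L
  outflow <- 0
  max_budget_resid <- 0
  if (!is.null(source)) {
    if (!is.matrix(source) || any(dim(source) != c(nr, nth)))
      stop("source must be an n_r x n_theta matrix of rates")
  }
  i_mid <- 2:nr
  j_mid <- 2:nth
  up_out <- ur_f[nr + 1, ] >= 0
  ur_int <- ur_f[i_mid, , drop = FALSE]
  up_r <- ur_int >= 0
  ut_int <- ut_f[, j_mid, drop = FALSE]
  up_t <- ut_int >= 0
  # net flux divergence (per cell) and outer boundary flux for a state
  flux_div <- function(cvals) {
    # --- radial direction ---
    d_lo <- (cvals[i_mid, , drop = FALSE] - cvals[i_mid - 1, , drop = FALSE]) * inv_drc
    slope_r <- matrix(0, nr, nth)
    slope_r[i_mid[-length(i_mid)], ] <- .minmod(d_lo[-nrow(d_lo), , drop = FALSE],
                                                d_lo[-1, , drop = FALSE])
    cf_up <- cvals[i_mid - 1, , drop = FALSE] +
      slope_r[i_mid - 1, , drop = FALSE] * (rf[i_mid] - rc[i_mid - 1])
    cf_dn <- cvals[i_mid, , drop = FALSE] +
      slope_r[i_mid, , drop = FALSE] * (rf[i_mid] - rc[i_mid])
    cface <- cf_dn
    cface[up_r] <- cf_up[up_r]
    Fr <- matrix(0, nr + 1, nth)
    Fr[i_mid, ] <- ur_int * cface * Sr[i_mid, , drop = FALSE] -
      (1 / Pe) * Sr[i_mid, , drop = FALSE] * d_lo
    if (boundary == "open") {
      c_last <- cvals[nr, ]
      # outflow: first-order upwind, zero-gradient diffusion; inflow: c = 0
      adv <- ifelse(up_out, ur_f[nr + 1, ] * c_last, 0) * Sr[nr + 1, ]
      dif <- ifelse(up_out, 0,
                    (1 / Pe) * Sr[nr + 1, ] * c_last / dr_ghost_out)
      Fr[nr + 1, ] <- adv + dif
    }
    # --- polar direction ---
    d_th <- (cvals[, j_mid, drop = FALSE] - cvals[, j_mid - 1, drop = FALSE]) / dth
    slope_t <- matrix(0, nr, nth)
    slope_t[, j_mid[-length(j_mid)]] <- .minmod(d_th[, -ncol(d_th), drop = FALSE],
                                                d_th[, -1, drop = FALSE])
    cf_up <- cvals[, j_mid - 1, drop = FALSE] +
      slope_t[, j_mid - 1, drop = FALSE] * (dth / 2)
    cf_dn <- cvals[, j_mid, drop = FALSE] -
      slope_t[, j_mid, drop = FALSE] * (dth / 2)
    cface_t <- cf_dn
    cface_t[up_t] <- cf_up[up_t]
    Ft <- matrix(0, nr, nth + 1)
    Ft[, j_mid] <- ut_int * cface_t * Sth[, j_mid, drop = FALSE] -
      (1 / Pe) * Sth[, j_mid, drop = FALSE] * d_th / rc
    list(div = (Fr[-1, , drop = FALSE] - Fr[-(nr + 1), , drop = FALSE]) +
           (Ft[, -1, drop = FALSE] - Ft[, -(nth + 1), drop = FALSE]),
         bflux = sum(Fr[nr + 1, ]))
  }
  while (t_now < t_end - 1e-14) {
    dt <- min(dt_stab, t_end - t_now)
    s1 <- flux_div(cvals)                      # SSP-RK2 (Heun)
    c1 <- cvals - dt * s1$div / V
    s2 <- flux_div(c1)
    cvals <- 0.5 * (cvals + c1 - dt * s2$div / V)
    if (!is.null(source)) cvals <- cvals + dt * source
    bflux <- (s1$bflux + s2$bflux) / 2
    outflow <- outflow + dt * bflux
    max_budget_resid <- max(max_budget_resid,
                            abs(sum(dt * (s1$div + s2$div) / 2) - dt * bflux) /
                              max(field$mass, .Machine$double.eps))
    # (the optional source adds dt * sum(V * source) of mass by construction)
    t_now <- t_now + dt
    n_steps <- n_steps + 1L
    if (n_steps %% 200L == 0L && min(cvals) < -1e-12)
      stop(sprintf("negative concentration %.3e: flux-limiter failure",
                   min(cvals)))
  }
  if (min(cvals) < -1e-12)
    stop(sprintf("negative concentration %.3e: flux-limiter failure",
                 min(cvals)))
  field$values <- cvals
  field$time <- t_now
  field$mass <- sum(V * cvals)
  attr(field, "diagnostics") <- list(n_steps = n_steps, dt = dt_stab,
                                     outflow = outflow,
                                     max_budget_resid = max_budget_resid)
  field
}

#' Diffusion-layer thickness near the thrombus core
#'
#' Depth d of the region where diffusion outruns advection, from the local
#' flux balance `u_t(R1 + d, theta) * d / D = 1` (local Peclet number equal
#' to one); the smallest positive root is returned.
#'
#' @param flow A [solve_composite_sphere()] solution, or a function
#'   `u_t(d)` giving tangential speed (um/s) at depth d um above the core.
#' @param D Protein diffusivity, um^2/s.
#' @param theta Polar angle, rad; must be away from the stagnation axis
#'   (margin `theta_margin`).
#' @param theta_margin Minimum distance from the poles, rad (default 0.05).
#' @param d_max Largest depth searched, um (default: up to the outer
#'   exterior, `4 * R2 - R1`, for a flow solution).
#' @return Depth delta in um; attribute `out_of_cap` is `TRUE` when delta
#'   exceeds the cap thickness `R2 - R1`.
#' @examples
#' # linear shear u_t = g*d has the closed form delta = sqrt(D/g)
#' diffusion_layer_thickness(function(d) 50 * d, D = 100, theta = pi/2)
#' @export
diffusion_layer_thickness <- function(flow, D, theta, theta_margin = 0.05,
                                      d_max = NULL) {
  if (D <= 0) stop("D must be positive")
  if (is.function(flow)) {
    u_t <- flow
    cap_thickness <- Inf
    if (is.null(d_max)) d_max <- 1e4
  } else {
    stopifnot(inherits(flow, "flow_solution"))
    g <- flow$geometry
    if (min(theta, pi - theta) < theta_margin)
      stop("theta is within the stagnation-axis margin")
    u_t <- function(d) abs(flow_velocity(flow, g$R1 + d, theta)[, "u_theta"])
    cap_thickness <- g$R2 - g$R1
    if (is.null(d_max)) d_max <- 4 * g$R2 - g$R1
  }
  bal <- function(d) u_t(d) * d / D - 1
  dgrid <- exp(seq(log(d_max * 1e-8), log(d_max), length.out = 400))
  vals <- vapply(dgrid, bal, numeric(1))
  ic <- which(vals[-1] * vals[-length(vals)] <= 0)[1]
  if (is.na(ic))
    stop("no balance point below d_max; flow may be too weak (raise d_max)")
  delta <- stats::uniroot(bal, c(dgrid[ic], dgrid[ic + 1]), tol = 1e-12)$root
  attr(delta, "out_of_cap") <- delta > cap_thickness
  delta
}
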