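# Creeping flow past a composite thrombus: impermeable spherical core of
# radius R1, Brinkman-permeable fibrin cap to radius R2, uniform stream U at
# infinity along the polar axis (theta = 0 downstream, theta = pi upstream).
#
# Axisymmetric stream functions (theta measured from the flow axis):
#   exterior (r > R2):  psi = U sin^2(theta) * (r^2/2 + A/r + B r)
#   cap (R1 < r < R2):  psi = U sin^2(theta) * (C r^2 + D/r + E bK(r) + G bI(r))
# where bK, bI are exponentially scaled combinations of the half-integer
# modified Bessel functions K_{3/2}, I_{3/2} (decaying/growing Brinkman
# modes), and sigma = sqrt(mu/(mu_eff * k_cap)) is the inverse screening
# length. The six coefficients follow from no-slip at R1 and continuity of
# both velocity components, tangential stress and pressure at R2.

#' Composite-thrombus geometry and flow parameters
#'
#' @param R1 Core radius, um.
#' @param R2 Thrombus (cap outer) radius, um; `R2 >= R1`.
#' @param k_cap Cap Darcy permeability, um^2.
#' @param mu Fluid viscosity, Pa*s.
#' @param U Far-field speed, um/s.
#' @param mu_eff Effective Brinkman viscosity in the cap, Pa*s (defaults to
#'   `mu`).
#' @return An object of class `thrombus_geometry`.
#' @examples
#' thrombus_geometry(R1 = 20, R2 = 40, k_cap = 1000)
#' @export
thrombus_geometry <- function(R1, R2, k_cap, mu = 1e-3, U = 1000,
                              mu_eff = mu) {
  if (!is.finite(R1) || R1 <= 0) stop("R1 must be positive (um)")
  if (!is.finite(R2) || R2 < R1) stop("R2 must satisfy R2 >= R1")
  if (!is.finite(k_cap) || k_cap <= 0) stop("k_cap must be positive (um^2)")
  if (mu <= 0 || mu_eff <= 0) stop("viscosities must be positive")
  if (!is.finite(U) || U <= 0) stop("U must be positive (um/s)")
  structure(list(R1 = R1, R2 = R2, k_cap = k_cap, mu = mu,
                 mu_eff = mu_eff, U = U),
            class = "thrombus_geometry")
}

#' @export
print.thrombus_geometry <- function(x, ...) {
  cat(sprintf("<thrombus_geometry> R1 = %g um, R2 = %g um, k_cap = %g um^2, mu = %g Pa.s, U = %g um/s\n",
              x$R1, x$R2, x$k_cap, x$mu, x$U))
  invisible(x)
}

# Scaled Brinkman radial modes and derivatives.
#   bK(r) = exp(sigma*R1) * r k1(sigma r)   (decaying; scaled about R1)
#   bI(r) = exp(-sigma*R2) * r i1(sigma r)  (growing;  scaled about R2)
# Both stay bounded on [R1, R2] for arbitrarily large sigma. Second
# derivatives come from the defining ODE f'' = sigma^2 f + 2 f / r^2.
.cap_basis <- function(r, sigma, R1, R2) {
  sr <- sigma * r
  eK <- exp(-sigma * (r - R1))
  bK <- eK * (1 + sr) / (sigma^2 * r)
  bKp <- -eK * (1 + 1 / sr + 1 / sr^2)
  e_up <- exp(-sigma * (R2 - r))    # <= 1 on the cap
  e_dn <- exp(-sigma * (R2 + r))
  bI <- ((sr - 1) * e_up + (sr + 1) * e_dn) / (2 * sigma^2 * r)
  bIp <- (e_up - e_dn) / 2 -
    ((sr - 1) * e_up + (sr + 1) * e_dn) / (2 * sr^2) * 1
  bKpp <- sigma^2 * bK + 2 * bK / r^2
  bIpp <- sigma^2 * bI + 2 * bI / r^2
  list(bK = bK, bKp = bKp, bKpp = bKpp, bI = bI, bIp = bIp, bIpp = bIpp)
}

#' Solve the composite-sphere Stokes-Brinkman flow
#'
#' Assembles and solves the 6x6 linear system for the stream-function
#' coefficients: no-slip at the core surface `r = R1`, continuity of radial
#' velocity, tangential velocity, tangential stress and pressure at the cap
#' surface `r = R2`, and a uniform stream at infinity. When `R2 == R1` the
#' classical Stokes solution past a solid sphere is returned in closed form.
#'
#' @param geom A [thrombus_geometry()].
#' @return An object of class `flow_solution`: the geometry, exterior
#'   coefficients `A` (um^3), `B` (um), cap coefficients `C`, `D`, `E`, `G`,
#'   inverse screening length `sigma` (1/um), and the maximum relative
#'   boundary-condition residual `bc_residual`.
#' @export
solve_composite_sphere <- function(geom) {
  stopifnot(inherits(geom, "thrombus_geometry"))
  R1 <- geom$R1; R2 <- geom$R2
  if (R2 == R1) {
    sol <- structure(list(geometry = geom,
                          A = R1^3 / 4, B = -3 * R1 / 4,
                          C = NA_real_, D = NA_real_, E = NA_real_,
                          G = NA_real_,
                          sigma = Inf, bc_residual = 0),
                     class = "flow_solution")
    return(sol)
  }
  lambda <- geom$mu_eff / geom$mu
  sigma <- sqrt(1 / (lambda * geom$k_cap))
  inv_k <- 1 / geom$k_cap
  b1 <- .cap_basis(R1, sigma, R1, R2)
  b2 <- .cap_basis(R2, sigma, R1, R2)
  # Unknowns x = (A, B, C, D, E, G); stress functional T(f) = r^2 f'' - 2 r f' + 2 f
  TK <- sigma^2 * R2^2 * b2$bK + 4 * b2$bK - 2 * R2 * b2$bKp
  TI <- sigma^2 * R2^2 * b2$bI + 4 * b2$bI - 2 * R2 * b2$bIp
  M <- rbind(
    c(0,        0,  R1^2,   1 / R1,    b1$bK,  b1$bI),   # u_r = 0 at R1
    c(0,        0,  2 * R1, -1 / R1^2, b1$bKp, b1$bIp),  # u_theta = 0 at R1
    c(-1 / R2,  -R2, R2^2,  1 / R2,    b2$bK,  b2$bI),   # u_r continuous at R2
    c(1 / R2^2, -1, 2 * R2, -1 / R2^2, b2$bKp, b2$bIp),  # u_theta continuous
    c(-6 / R2,  0,  0, lambda * 6 / R2, lambda * TK, lambda * TI),  # stress
    c(0, 2 / R2^2, 2 * inv_k * R2, -inv_k / R2^2, 0, 0)  # pressure
  )
  rhs <- c(0, 0, R2^2 / 2, R2, 0, 0)
  # column equilibration keeps the solve well-conditioned across extreme k_cap
  cs <- apply(abs(M), 2, max)
  cs[cs == 0] <- 1
  x <- tryCatch(solve(sweep(M, 2, cs, "/"), rhs) / cs,
                error = function(e)
                  stop("singular boundary-condition system (degenerate geometry)",
                       call. = FALSE))
  sol <- structure(list(geometry = geom,
                        A = x[1], B = x[2], C = x[3], D = x[4],
                        E = x[5], G = x[6],
                        sigma = sigma, bc_residual = NA_real_),
                   class = "flow_solution")
  sol$bc_residual <- .bc_residual(sol)
  if (!is.finite(sol$bc_residual) || sol$bc_residual > 1e-6)
    warning(sprintf("boundary-condition residual %.2e exceeds 1e-6",
                    sol$bc_residual))
  sol
}

# Stream-function radial profile f(r) and derivative for either branch.
.f_profile <- function(sol, r) {
  g <- sol$geometry
  f <- fp <- numeric(length(r))
  cap <- r <= g$R2 & is.finite(sol$sigma)
  if (any(cap)) {
    b <- .cap_basis(r[cap], sol$sigma, g$R1, g$R2)
    f[cap] <- sol$C * r[cap]^2 + sol$D / r[cap] +
      sol$E * b$bK + sol$G * b$bI
    fp[cap] <- 2 * sol$C * r[cap] - sol$D / r[cap]^2 +
      sol$E * b$bKp + sol$G * b$bIp
  }
  ext <- !cap
  if (any(ext)) {
    f[ext] <- r[ext]^2 / 2 + sol$A / r[ext] + sol$B * r[ext]
    fp[ext] <- r[ext] - sol$A / r[ext]^2 + sol$B
  }
  list(f = f, fp = fp)
}

# Max relative residual over the boundary conditions (velocity scale U):
# no-slip at R1 plus exact branch mismatch of f, f' at R2.
.bc_residual <- function(sol) {
  g <- sol$geometry
  u1 <- flow_velocity(sol, g$R1, pi / 3)
  b <- .cap_basis(g$R2, sol$sigma, g$R1, g$R2)
  f_cap <- sol$C * g$R2^2 + sol$D / g$R2 + sol$E * b$bK + sol$G * b$bI
  fp_cap <- 2 * sol$C * g$R2 - sol$D / g$R2^2 + sol$E * b$bKp + sol$G * b$bIp
  f_out <- g$R2^2 / 2 + sol$A / g$R2 + sol$B * g$R2
  fp_out <- g$R2 - sol$A / g$R2^2 + sol$B
  max(abs(c(u1 / g$U,
            (f_cap - f_out) / g$R2^2,
            (fp_cap - fp_out) / g$R2)))
}

#' @export
print.flow_solution <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<flow_solution> R1 = %g, R2 = %g um, k_cap = %g um^2 (sigma*R2 = %.3g)\n",
              g$R1, g$R2, g$k_cap,
              if (is.finite(x$sigma)) x$sigma * g$R2 else Inf))
  cat(sprintf("  exterior A = %.6g um^3, B = %.6g um; F_rel = %.4f\n",
              x$A, x$B, drag_force(x)$F_rel))
  invisible(x)
}

#' Velocity field of a composite-sphere flow solution
#'
#' `u_r = (1/(r^2 sin(theta))) dpsi/dtheta`,
#' `u_theta = -(1/(r sin(theta))) dpsi/dr`, with the cap or exterior branch
#' selected by radius. Polar axis along the far-field flow; `theta = 0` is
#' downstream.
#'
#' @param sol A [solve_composite_sphere()] result.
#' @param r Radii, um (recycled against `theta`); must be `>= R1`.
#' @param theta Polar angles, rad.
#' @return Matrix with columns `u_r`, `u_theta` in um/s.
#' @export
flow_velocity <- function(sol, r, theta) {
  stopifnot(inherits(sol, "flow_solution"))
  g <- sol$geometry
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  if (any(r < g$R1 * (1 - 1e-12))) stop("r must be >= R1")
  r <- pmax(r, g$R1)
  pr <- .f_profile(sol, r)
  cbind(u_r = 2 * g$U * cos(theta) * pr$f / r^2,
        u_theta = -g$U * sin(theta) * pr$fp / r)
}

#' Hydrodynamic drag force on the thrombus
#'
#' The net force follows from the Stokeslet coefficient of the exterior
#' stream function, `F = -8 pi mu U B`, equivalent to integrating the stress
#' tensor over the thrombus surface; the solid-sphere limit returns exactly
#' `6 pi mu U R`. `F_rel` divides by the Stokes drag on an impermeable sphere
#' of radius `R2`.
#'
#' @param sol A [solve_composite_sphere()] result.
#' @return An object of class `force_result`: list with `F` (N) and `F_rel`.
#' @examples
#' sol <- solve_composite_sphere(thrombus_geometry(20, 40, k_cap = 1000))
#' drag_force(sol)$F_rel   # ~0.5: the permeable cap halves the drag
#' @export
drag_force <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  g <- sol$geometry
  F_N <- -8 * pi * g$mu * (g$U * 1e-6) * (sol$B * 1e-6)
  F_rel <- -(4 / 3) * sol$B / g$R2
  structure(list(F = F_N, F_rel = F_rel), class = "force_result")
}

#' @export
print.force_result <- function(x, ...) {
  cat(sprintf("<force_result> F = %.4g N, F_rel = %.4f\n", x$F, x$F_rel))
  invisible(x)
}

#' Largest thrombus radius consistent with creeping flow
#'
#' The Stokes/Brinkman description requires a local Reynolds number below 1.
#' For a small wall-attached thrombus in a vessel with a parabolic velocity
#' profile, the near-wall velocity at height R is `u = gamma * R` with wall
#' shear rate `gamma = 4 * u_mean / R0`; setting
#' `Re = rho * u(R) * R / mu = 1` gives the bound
#' `R* = sqrt(mu * R0 / (4 * rho * u_mean))`.
#'
#' @param vessel_radius Vessel radius R0, um.
#' @param mean_velocity Axially averaged blood velocity, um/s.
#' @param density Blood density, kg/m^3 (default 1050).
#' @param viscosity Blood viscosity, Pa*s (default 3e-3).
#' @return Radius bound, um.
#' @examples
#' max_thrombus_radius(200, 1e4)   # exceeds the ~60 um of observed thrombi
#' @export
max_thrombus_radius <- function(vessel_radius, mean_velocity,
                                density = 1050, viscosity = 3e-3) {
  if (any(c(vessel_radius, mean_velocity, density, viscosity) <= 0))
    stop("all inputs must be positive")
  R0 <- vessel_radius * 1e-6
  u <- mean_velocity * 1e-6
  sqrt(viscosity * R0 / (4 * density * u)) * 1e6
}

#' Local Reynolds number at height R above the vessel wall
#'
#' Companion to [max_thrombus_radius()]: `Re = rho * (4 u_mean R / R0) * R / mu`
#' using the near-wall shear of the parabolic profile.
#'
#' @inheritParams max_thrombus_radius
#' @param R Height above the wall (thrombus radius), um.
#' @return Dimensionless local Reynolds number.
#' @export
local_reynolds <- function(R, vessel_radius, mean_velocity,
                           density = 1050, viscosity = 3e-3) {
  if (any(c(R, vessel_radius, mean_velocity, density, viscosity) <= 0))
    stop("all inputs must be positive")
  R_m <- R * 1e-6
  R0 <- vessel_radius * 1e-6
  u <- mean_velocity * 1e-6
  density * (4 * u * R_m / R0) * R_m / viscosity
}
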