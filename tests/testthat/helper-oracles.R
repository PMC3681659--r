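# Independent numerical oracles used by the test suite. Each one solves the
# same physical problem as the package by a different route (fine-grid
# finite-volume integration or ODE shooting), so agreement is evidence, not
# tautology.

# 1-D spherical pure-diffusion reference: uniform fine grid, conservative
# finite volumes, small explicit steps. Initial condition: unit shell
# [1, 1 + h] (volume-fraction projected). Closed boundaries.
oracle_spherical_diffusion <- function(n, r_max, h, D, t_end) {
  rf <- seq(1, r_max, length.out = n + 1)
  rc <- (rf[-1] + rf[-(n + 1)]) / 2
  lo <- pmin(pmax(rf[-(n + 1)], 1), 1 + h)
  hi <- pmin(pmax(rf[-1], 1), 1 + h)
  cv <- (hi^3 - lo^3) / diff(rf^3)
  V <- diff(rf^3) / 3
  S <- rf^2
  dr <- diff(rc)[1]
  dt <- 0.2 * dr^2 / D
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  for (s in seq_len(nsteps)) {
    Fv <- numeric(n + 1)
    Fv[2:n] <- -D * S[2:n] * diff(cv) / dr
    cv <- cv - dt * diff(Fv) / V
  }
  list(rc = rc, c = cv)
}

# Brute-force recovery of a uniformly bleached disk of radius w in 2-D
# (radial cylindrical diffusion): c0 = 0 inside the disk, 1 outside;
# returns mean concentration over the disk at the requested times.
oracle_disk_recovery <- function(times, w = 1, D = 1, r_max = 15 * w,
                                 n = 1500) {
  rf <- seq(0, r_max, length.out = n + 1)
  rc <- (rf[-1] + rf[-(n + 1)]) / 2
  cv <- as.numeric(rc > w)
  V <- diff(rf^2) / 2
  S <- rf
  dr <- diff(rc)[1]
  dt <- 0.2 * dr^2 / D
  inside <- rc <= w
  w_in <- V[inside]
  out <- numeric(length(times))
  t_now <- 0
  for (i in seq_along(sort(times))) {
    t_target <- sort(times)[i]
    nsteps <- ceiling((t_target - t_now) / dt)
    dts <- (t_target - t_now) / max(nsteps, 1)
    for (s in seq_len(nsteps)) {
      Fv <- numeric(n + 1)
      Fv[2:n] <- -D * S[2:n] * diff(cv) / dr
      cv <- cv - dts * diff(Fv) / V
    }
    t_now <- t_target
    out[i] <- sum(cv[inside] * w_in) / sum(w_in)
  }
  out[order(order(times))]
}

# Composite-sphere flow by linear shooting of the radial first-order system
#   f' = fp, fp' = g + 2 f/r^2, g' = q + s2(r) fp, q' = 2 (g - s2(r) f)/r^2
# (q = g' - sigma^2 f' is the pressure-continuous flux variable), with
# no-slip at R1 and far-field closure at R_far excluding the growing modes.
# Independent of the analytic coefficient solution.
oracle_flow_profile <- function(geom, r_eval, R_far_mult = 30) {
  R1 <- geom$R1; R2 <- geom$R2
  s2 <- 1 / geom$k_cap
  R_far <- R_far_mult * R2
  deriv <- function(r, y, parms) {
    sg <- if (r <= R2) s2 else 0
    list(c(y[2],
           y[3] + 2 * y[1] / r^2,
           y[4] + sg * y[2],
           2 * (y[3] - sg * y[1]) / r^2))
  }
  grid <- sort(unique(c(seq(R1, R_far, length.out = 2000), R2, r_eval)))
  s1 <- deSolve::ode(c(0, 0, 1, 0), grid, deriv, NULL,
                     rtol = 1e-11, atol = 1e-12)
  s2m <- deSolve::ode(c(0, 0, 0, 1), grid, deriv, NULL,
                      rtol = 1e-11, atol = 1e-12)
  n <- nrow(s1)
  A <- rbind(
    c(s1[n, 4] + R_far * s1[n, 5], s2m[n, 4] + R_far * s2m[n, 5]),
    c(s1[n, 4] + 2 * s1[n, 2] / R_far^2, s2m[n, 4] + 2 * s2m[n, 2] / R_far^2))
  ab <- solve(A, c(0, 1))
  f <- ab[1] * s1[, 2] + ab[2] * s2m[, 2]
  g <- ab[1] * s1[, 4] + ab[2] * s2m[, 4]
  idx <- match(r_eval, grid)
  list(r = r_eval, f = f[idx], B = -g[n] * R_far / 2)
}

# Truncated power-series evaluation of exp(-x) * (I0(x) + I1(x)),
# independent of base besselI; accurate for moderate x.
oracle_scaled_bessel_sum <- function(x, terms = 60) {
  k <- 0:terms
  I0 <- sum((x / 2)^(2 * k) / factorial(k)^2)
  I1 <- sum((x / 2)^(2 * k + 1) / (factorial(k) * factorial(k + 1)))
  exp(-x) * (I0 + I1)
}
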