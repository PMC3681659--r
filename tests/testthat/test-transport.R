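# Finite-volume thrombin transport: initial condition, conservation,
# positivity/TVD, accuracy against a fine 1-D oracle, open-boundary
# behaviour and the diffusion-layer balance.

geom_default <- thrombus_geometry(R1 = 20, R2 = 25, k_cap = 1000, U = 1000)

test_that("initial shell is theta-uniform with exact discrete mass", {
  cfg <- transport_config(Pe = 200, h = 2, n_r = 64, n_theta = 16)
  f0 <- initial_shell(cfg, geom_default)
  h_nd <- 2 / 20
  m_exact <- ((1 + h_nd)^3 - 1) / 3 * 2        # azimuthal 2*pi omitted
  expect_equal(f0$mass, m_exact, tolerance = 1e-12)
  expect_lt(abs(f0$mass - m_exact) / m_exact, 1 / 64)
  expect_true(all(apply(f0$values, 1, function(x) diff(range(x)) == 0)))
  # support confined to the first h um above the core
  nz <- which(rowSums(f0$values) > 0)
  expect_lt(max(f0$r_centers[nz]) - 1, h_nd + diff(f0$r_faces)[max(nz)])
  # shells thinner than the first cell are rejected with guidance
  expect_error(initial_shell(transport_config(Pe = 200, h = 0.05, n_r = 32),
                             geom_default), "n_r")
})

test_that("closed-box mass is conserved over many steps", {
  cfg <- transport_config(Pe = 200, h = 2, n_r = 48, n_theta = 16,
                          stretch = 1.05)
  f0 <- initial_shell(cfg, geom_default)
  f1 <- advance_transport(f0, NULL, cfg, t_end = 2, boundary = "closed")
  expect_lt(abs(f1$mass - f0$mass) / f0$mass, 1e-10)
  expect_gte(min(f1$values), 0)
  d <- attr(f1, "diagnostics")
  expect_lt(d$max_budget_resid, 1e-8)
  # optional volumetric source adds mass at the prescribed rate
  src <- matrix(0.01, nrow(f0$values), ncol(f0$values))
  f2 <- advance_transport(f0, NULL, cfg, t_end = 1, boundary = "closed",
                          source = src)
  V_tot <- sum(fibrincap:::.cell_volumes(f0))
  expect_equal(f2$mass - f0$mass, 0.01 * V_tot * 1, tolerance = 1e-10)
  expect_error(advance_transport(f0, NULL, cfg, 1, source = matrix(1, 2, 2)),
               "n_r x n_theta")
})

test_that("pure diffusion matches the fine-grid 1-D spherical oracle", {
  cfg <- transport_config(Pe = 50, h = 2, n_r = 96, n_theta = 8)
  f0 <- initial_shell(cfg, geom_default)
  f1 <- advance_transport(f0, NULL, cfg, t_end = 1, boundary = "closed")
  orc <- oracle_spherical_diffusion(960, 10, 0.1, 1 / 50, 1)
  cref <- stats::approx(orc$rc, orc$c, xout = f1$r_centers)$y
  # theta-independence is preserved exactly
  expect_true(all(apply(f1$values, 1, function(x) diff(range(x)) < 1e-13)))
  l2 <- sqrt(sum((f1$values[, 1] - cref)^2) / sum(cref^2))
  expect_lt(l2, 0.01)
})

test_that("1-D advection keeps square-pulse bounds (TVD) ", {
  n <- 200
  x <- (1:n - 0.5) / n
  c0 <- as.numeric(x > 0.25 & x < 0.5)
  c1 <- fibrincap:::.advect_1d(c0, u = 1, dx = 1 / n, t_end = 0.7)
  expect_gte(min(c1), -1e-12)
  expect_lte(max(c1), 1 + 1e-12)
  # and with the opposite wind
  c2 <- fibrincap:::.advect_1d(c0, u = -1, dx = 1 / n, t_end = 0.7)
  expect_gte(min(c2), -1e-12)
  expect_lte(max(c2), 1 + 1e-12)
})

test_that("observed convergence order on a smooth profile is near 2", {
  err <- vapply(c(200, 400, 800), function(n) {
    x <- (1:n - 0.5) / n
    c0 <- sin(2 * pi * x)^4
    c1 <- fibrincap:::.advect_1d(c0, 1, 1 / n, t_end = 1)
    sum(abs(c1 - c0)) / n
  }, numeric(1))
  orders <- log2(err[-length(err)] / err[-1])
  expect_gte(max(orders), 1.8)
  expect_true(all(orders > 1.5))
})

test_that("open-boundary mass budget closes against the outflow integral", {
  cfg <- transport_config(Pe = 200, h = 2, n_r = 48, n_theta = 24,
                          stretch = 1.05)
  flow <- solve_composite_sphere(geom_default)
  f0 <- initial_shell(cfg, geom_default)
  f1 <- advance_transport(f0, flow, cfg, t_end = 5)
  d <- attr(f1, "diagnostics")
  expect_lt(d$max_budget_resid, 1e-8)
  expect_equal(f0$mass - f1$mass, d$outflow, tolerance = 1e-8)
  expect_gte(min(f1$values), 0)
})

test_that("thrombin is washed downstream through a permeable cap", {
  cfg <- transport_config(Pe = 200, h = 2, n_r = 64, n_theta = 32)
  flow <- solve_composite_sphere(geom_default)
  f0 <- initial_shell(cfg, geom_default)
  f1 <- advance_transport(f0, flow, cfg, t_end = 1.5)
  surf <- f1$values[1, ]
  th <- f1$th_centers
  down <- surf[th < pi / 2]
  up <- rev(surf[th > pi / 2])     # mirrored angles
  expect_gt(mean(down), mean(up))
  expect_true(all(down >= up - 1e-12))
})

test_that("doubling the outer boundary hardly changes surface values", {
  flow <- solve_composite_sphere(geom_default)
  run <- function(r_max, n_r) {
    cfg <- transport_config(Pe = 200, h = 2, n_r = n_r, n_theta = 16,
                            r_max = r_max, stretch = 1.05)
    advance_transport(initial_shell(cfg, geom_default), flow, cfg, 1)
  }
  s10 <- run(10, 48)$values[1, ]
  s20 <- run(20, 72)$values[1, ]
  expect_lt(max(abs(s10 - s20)) / max(s10), 0.01)
})

test_that("diffusion-layer thickness balances local advection and diffusion", {
  flow <- solve_composite_sphere(geom_default)
  # defining identity at the returned depth
  D <- 95
  d <- diffusion_layer_thickness(flow, D, theta = pi / 2)
  g <- flow$geometry
  u_t <- abs(flow_velocity(flow, g$R1 + as.numeric(d), pi / 2)[, "u_theta"])
  expect_equal(unname(u_t) * as.numeric(d) / D, 1, tolerance = 1e-9)
  # halving diffusivity thins the layer; doubling thickens it
  expect_lt(as.numeric(diffusion_layer_thickness(flow, D / 2, pi / 2)),
            as.numeric(d))
  expect_gt(as.numeric(diffusion_layer_thickness(flow, 2 * D, pi / 2)),
            as.numeric(d))
  # closed form for a synthetic linear shear u_t = g d: delta = sqrt(D/g)
  dl <- diffusion_layer_thickness(function(x) 50 * x, D = 100, theta = pi / 2)
  expect_equal(as.numeric(dl), sqrt(100 / 50), tolerance = 1e-9)
})

test_that("layer is thin for permeable caps, thick for tight ones", {
  D <- 95                                     # thrombin-like diffusivity
  hi <- solve_composite_sphere(thrombus_geometry(20, 25, 1000, U = 1000))
  lo <- solve_composite_sphere(thrombus_geometry(20, 25, 3, U = 1000))
  d_hi <- as.numeric(diffusion_layer_thickness(hi, D, pi / 2))
  d_lo <- as.numeric(diffusion_layer_thickness(lo, D, pi / 2))
  expect_gt(d_lo, d_hi)
  # a few percent of the thrombus radius for the permeable cap,
  # 10-20% for the tight one
  expect_lt(d_hi / 25, 0.08)
  expect_gt(d_lo / 25, 0.08)
  expect_lt(d_lo / 25, 0.25)
  # the larger, slower probe has a thinner layer
  d_fab <- as.numeric(diffusion_layer_thickness(hi, D / 2, pi / 2))
  expect_lt(d_fab, d_hi)
})
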