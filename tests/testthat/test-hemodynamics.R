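test_that("Poiseuille pressure drop obeys its closed form and scalings", {
  expect_equal(poiseuille_dp(0, 0.0035, 0.05, 0.002), 0)
  # R^-4 scaling
  dp1 <- poiseuille_dp(2e-6, 0.0035, 0.05, 0.002)
  dp2 <- poiseuille_dp(2e-6, 0.0035, 0.05, 0.004)
  expect_equal(dp1 / dp2, 16)
  # independent hand evaluation: 8 mu L Q / (pi R^4)
  hand <- (8 * 0.0035 * 0.05 * 2e-6) / (pi * 0.002 * 0.002 * 0.002 * 0.002)
  expect_equal(dp1, hand)
  expect_error(poiseuille_dp(1e-6, 0.0035, 0.05, -1), "R")
})

test_that("stenosis loss vanishes for uniform tubes and scales as expected", {
  uni <- lumen_profile(vessel_geometry(L = 40, R0 = 2, d = 0), ds = 0.5)
  expect_equal(stenosis_loss(3e-6, 0.0035, 1060, uni), 0)

  # quadratic (expansion) coefficient ratio between d = 0.75 and d = 0.5:
  # ((1/(1-0.75)^2 - 1) / (1/(1-0.5)^2 - 1))^2, severities entering via A0/As
  quad_coef <- function(d) {
    prof <- lumen_profile(vessel_geometry(L = 40, R0 = 2, d = d, w = 4), ds = 0.25)
    q <- 5e-6
    (stenosis_loss(2 * q, 0.0035, 1060, prof) - 2 * stenosis_loss(q, 0.0035, 1060, prof)) /
      (2 * q^2)
  }
  ratio <- quad_coef(0.75) / quad_coef(0.5)
  # reference area is taken at the profile inlet, where the Gaussian bump
  # has a ~1e-6 residual: tolerance reflects that, not solver error
  expect_equal(ratio, ((1 / 0.25^2 - 1) / (1 / 0.5^2 - 1))^2, tolerance = 1e-4)

  # Q -> 0: the linear viscous term dominates
  prof <- lumen_profile(vessel_geometry(L = 40, R0 = 2, d = 0.5, w = 4), ds = 0.25)
  q_small <- 1e-12
  lin_coef <- stenosis_loss(q_small, 0.0035, 1060, prof) / q_small
  q_half <- q_small / 2
  expect_equal(stenosis_loss(q_half, 0.0035, 1060, prof) / q_half, lin_coef, tolerance = 1e-6)
  expect_gt(lin_coef, 0)
})

test_that("uniform-tube solves reproduce Poiseuille exactly and conserve mass", {
  grid <- expand.grid(
    mu = c(0.003, 0.0035, 0.004),
    L = c(20, 50, 100), # mm
    R = c(1, 1.5, 2, 3), # mm
    Q = c(1, 3, 5) # mL/s
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    prof <- tibble::tibble(s = seq(0, g$L, by = 1), r = g$R)
    sol <- solve_steady_flow(
      prof, fluid_model(mu = g$mu),
      flow_bc(inlet_pressure = 100, inlet_flow = g$Q)
    )
    analytic <- poiseuille_dp(g$Q * 1e-6, g$mu, g$L * 1e-3, g$R * 1e-3)
    expect_lt(abs(attr(sol, "dp_pa") - analytic) / analytic, 1e-3)
    # discrete continuity: v(s) A(s) constant = Q
    qs <- sol$velocity * sol$area * 1e-6
    expect_lt(max(abs(qs - attr(sol, "Q"))) / attr(sol, "Q"), 1e-10)
    # pressure linear in s
    fit <- lm(pressure_pa ~ s, data = sol)
    expect_lt(max(abs(residuals(fit))), 1e-6 * analytic + 1e-9)
  }
})

test_that("pressure-pressure conditions invert to the analytic flow", {
  prof <- tibble::tibble(s = seq(0, 50, by = 0.5), r = 1.5)
  mu <- 0.0035
  p_in <- 100
  p_out <- 92
  sol <- solve_steady_flow(
    prof, fluid_model(mu = mu),
    flow_bc(inlet_pressure = p_in, outlet_pressure = p_out)
  )
  dp <- (p_in - p_out) * 133.322387415
  q_analytic <- dp * pi * (1.5e-3)^4 / (8 * mu * 50e-3)
  expect_equal(attr(sol, "Q"), q_analytic, tolerance = 1e-6)
  expect_equal(sol$pressure_mmhg[nrow(sol)], p_out, tolerance = 1e-6)
})

test_that("outlet resistance closes the pressure field consistently", {
  prof <- lumen_profile(vessel_geometry(L = 40, R0 = 2, d = 0.4), ds = 0.5)
  Rd <- 25 # mmHg/(mL/s)
  sol <- solve_steady_flow(
    prof, fluid_model(),
    flow_bc(inlet_pressure = 100, outlet_resistance = Rd)
  )
  q <- attr(sol, "q_ml_s")
  expect_equal(sol$pressure_mmhg[nrow(sol)], Rd * q, tolerance = 1e-6)
  expect_lt(q, 100 / Rd) # the stenosis consumes some driving pressure
})

test_that("pressure drop is monotone in flow, viscosity and severity", {
  dp_of <- function(d, mu = 0.0035, q = 3) {
    prof <- lumen_profile(vessel_geometry(L = 40, R0 = 2, d = d, w = 4), ds = 0.25)
    attr(solve_steady_flow(
      prof, fluid_model(mu = mu),
      flow_bc(inlet_pressure = 100, inlet_flow = q)
    ), "dp_pa")
  }
  expect_true(all(diff(sapply(c(1, 2, 4), function(q) dp_of(0.5, q = q))) > 0))
  expect_true(all(diff(sapply(c(0.002, 0.0035, 0.007), function(m) dp_of(0.5, mu = m))) > 0))
  expect_true(all(diff(sapply(c(0, 0.3, 0.6), dp_of)) > 0))
})

test_that("mean pressure matches an independent quadrature", {
  expect_equal(mean_pressure(rep(100, 5)), 100)
  sine <- pressure_waveform(mean = 90, amplitude = 20, period = 0.8, n_cycles = 3)
  expect_equal(mean_pressure(sine), 90, tolerance = 1e-9)
  set.seed(8)
  t <- cumsum(runif(60, 0.01, 0.05))
  p <- 90 + cumsum(rnorm(60))
  expect_equal(mean_pressure(tibble::tibble(time = t, pressure = p)), oracle_trapz_mean(t, p))
  expect_error(mean_pressure(numeric(0)), "empty")
})

test_that("FFR is the ratio of mean distal to mean aortic pressure", {
  wf <- pressure_waveform(mean = 95, amplitude = 18, period = 0.8)
  expect_equal(compute_ffr(wf, wf)$ffr, 1)
  expect_equal(compute_ffr(80, 100)$ffr, 0.8)
  res <- compute_ffr(80, 100)
  expect_equal(tidy(res)$ps, 80)
  expect_error(compute_ffr(80, 0), "positive")
  expect_warning(compute_ffr(105, 100), "non-physical")
})

test_that("FFR decreases with severity and stays physical across the sweep", {
  sweep <- ffr_vs_severity(c(0, 0.3, 0.5, 0.7))
  expect_equal(which.max(sweep$ffr), 1L)
  expect_true(all(diff(sweep$ffr) < 0))
  expect_true(all(sweep$ffr > 0 & sweep$ffr <= 1 + 1e-9))

  # doubling viscosity lowers every FFR at fixed flow
  thick <- ffr_vs_severity(c(0, 0.3, 0.5, 0.7), fluid = fluid_model(mu = 0.007))
  expect_true(all(thick$ffr < sweep$ffr))

  # a short unobstructed vessel is hemodynamically transparent
  short <- ffr_vs_severity(0, L = 10, R0 = 2)
  expect_lt(abs(short$ffr - 1), 0.02)
})

test_that("boundary-condition constructor enforces its contract", {
  expect_error(flow_bc(), "inlet condition")
  expect_error(flow_bc(inlet_pressure = 100), "outlet condition")
  expect_error(
    flow_bc(inlet_pressure = 100, inlet_flow = 3, outlet_pressure = 90),
    "exactly one pressure condition"
  )
  expect_error(
    flow_bc(inlet_pressure = 90, outlet_pressure = 100),
    "must not exceed"
  )
  expect_s3_class(flow_bc(inlet_flow = 3, inlet_pressure = 100), "flow_bc")
  expect_s3_class(flow_bc(inlet_pressure = 100, outlet_resistance = 10), "flow_bc")
})
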