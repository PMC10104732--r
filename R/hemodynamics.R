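#' Blood as an incompressible Newtonian fluid
#'
#' @param rho Density, kg/m^3 (> 0). Default 1060 (whole blood).
#' @param mu Dynamic viscosity, Pa s (> 0). Default 0.0035.
#' @return A `fluid_model` list.
#' @export
fluid_model <- function(rho = 1060, mu = 0.0035) {
  check_scalar(rho, "rho", positive = TRUE)
  check_scalar(mu, "mu", positive = TRUE)
  structure(list(rho = rho, mu = mu), class = "fluid_model")
}

#' Boundary conditions for the steady vessel-flow solve
#'
#' Exactly one inlet condition (aortic pressure in mmHg, or flow in mL/s)
#' and one outlet condition (pressure in mmHg, or a distal resistance in
#' mmHg per mL/s) must be given. With a flow condition on either side the
#' pressure field follows by direct integration; with pressure on both
#' sides (or pressure + resistance) the flow is recovered by bisection on
#' the monotone flow-to-pressure-drop relation.
#'
#' When the flow is prescribed (hyperemic operating point), the aortic
#' `inlet_pressure` alone may anchor the absolute pressure level instead of
#' an outlet condition.
#'
#' @param inlet_pressure Mean aortic (inlet) pressure, mmHg.
#' @param inlet_flow Inlet flow, mL/s.
#' @param outlet_pressure Outlet pressure, mmHg.
#' @param outlet_resistance Distal resistance, mmHg/(mL/s); the outlet
#'   pressure is then `outlet_resistance * Q` above venous zero.
#' @return A `flow_bc` list.
#' @export
flow_bc <- function(inlet_pressure = NULL, inlet_flow = NULL,
                    outlet_pressure = NULL, outlet_resistance = NULL) {
  n_out <- (!is.null(outlet_pressure)) + (!is.null(outlet_resistance))
  if (n_out > 1L) abort("give at most one outlet condition (pressure or resistance).")
  if (is.null(inlet_flow)) {
    if (is.null(inlet_pressure)) abort("an inlet condition (pressure or flow) is required.")
    if (n_out != 1L) {
      abort("with a pressure inlet, exactly one outlet condition (pressure or resistance) is required.")
    }
  } else {
    # prescribed flow: exactly one pressure level must anchor the field
    n_anchor <- (!is.null(inlet_pressure)) + n_out
    if (n_anchor != 1L) {
      abort("with a prescribed flow, exactly one pressure condition (inlet or outlet) must anchor the level.")
    }
  }
  if (!is.null(inlet_pressure)) check_scalar(inlet_pressure, "inlet_pressure", positive = TRUE)
  if (!is.null(outlet_pressure)) check_scalar(outlet_pressure, "outlet_pressure", positive = TRUE)
  if (!is.null(inlet_flow)) check_scalar(inlet_flow, "inlet_flow", nonneg = TRUE)
  if (!is.null(outlet_resistance)) check_scalar(outlet_resistance, "outlet_resistance", nonneg = TRUE)
  if (!is.null(inlet_pressure) && !is.null(outlet_pressure) &&
    outlet_pressure > inlet_pressure) {
    abort("outlet pressure must not exceed inlet pressure for forward flow.")
  }
  structure(
    list(
      inlet_pressure = inlet_pressure, inlet_flow = inlet_flow,
      outlet_pressure = outlet_pressure, outlet_resistance = outlet_resistance
    ),
    class = "flow_bc"
  )
}

#' Poiseuille pressure drop in a straight tube
#'
#' The steady fully developed laminar limit of the incompressible momentum
#' balance in a rigid cylinder:
#' \deqn{\Delta p = \frac{8 \mu L Q}{\pi R^4}.}
#' SI units throughout. This closed form is both the solver's per-segment
#' viscous element and the oracle any correct 3-D solver must reproduce in
#' the uniform-tube limit.
#'
#' @param Q Flow rate, m^3/s (>= 0).
#' @param mu Dynamic viscosity, Pa s (> 0).
#' @param L Tube length, m (> 0).
#' @param R Tube radius, m (> 0).
#' @return Pressure drop, Pa.
#' @examples
#' poiseuille_dp(Q = 2e-6, mu = 0.0035, L = 0.05, R = 0.002)
#' @export
poiseuille_dp <- function(Q, mu, L, R) {
  check_scalar(Q, "Q", nonneg = TRUE)
  check_scalar(mu, "mu", positive = TRUE)
  check_scalar(L, "L", positive = TRUE)
  check_scalar(R, "R", positive = TRUE)
  8 * mu * L * Q / (pi * R^4)
}

#' Stenosis pressure loss (Young-Tsai empirical model)
#'
#' Additional pressure drop across a focal constriction in a tube, beyond
#' the fully developed Poiseuille drop of the unobstructed vessel:
#' \deqn{\Delta p_s = K_v \frac{\mu Q}{A_0 D_0}
#'   + K_t \frac{\rho}{2 A_0^2}\left(\frac{A_0}{A_s} - 1\right)^2 Q^2,}
#' with the viscous coefficient
#' \eqn{K_v = \frac{32 (0.83 L_a + 1.64 D_s)}{D_0} (A_0/A_s)^2}
#' (`La` the stenosis length, `Ds` the throat diameter) and the turbulent
#' expansion coefficient `Kt = 1.52`. `A0`/`D0` are the unobstructed lumen
#' area/diameter taken at the inlet of the profile; `As` is the throat
#' area. `La` is measured as the full width at half the radius deficit. The
#' loss is zero for a uniform profile, linear in `Q` as `Q -> 0`, and
#' quadratic at high flow.
#'
#' @param Q Flow rate, m^3/s.
#' @param mu Viscosity, Pa s.
#' @param rho Density, kg/m^3.
#' @param r_profile Tibble or data frame with columns `s`, `r` in mm (as
#'   from [lumen_profile()] or [extract_lumen_profile()]); must be strictly
#'   positive.
#' @return Pressure drop, Pa (>= 0).
#' @export
stenosis_loss <- function(Q, mu, rho, r_profile) {
  check_scalar(Q, "Q", nonneg = TRUE)
  p <- validate_profile(r_profile)
  st <- stenosis_descriptors(p)
  if (is.null(st)) return(0)
  Kv <- 32 * (0.83 * st$La + 1.64 * st$Ds) / st$D0 * (st$A0 / st$As)^2
  Kt <- 1.52
  Kv * mu * Q / (st$A0 * st$D0) + Kt * rho / (2 * st$A0^2) * (st$A0 / st$As - 1)^2 * Q^2
}

# geometric descriptors of the (single) stenosis in a radius profile, SI.
# NULL when the profile is uniform to within 0.1% of the reference radius.
stenosis_descriptors <- function(p) {
  r <- p$r_m
  s <- p$s_m
  r0 <- r[1] # unobstructed reference: proximal end
  i_min <- which.min(r)
  r_min <- r[i_min]
  if (r_min >= r0 * (1 - 1e-3)) return(NULL)
  half <- r0 - (r0 - r_min) / 2 # radius at half the deficit
  inlesion <- r < half
  La <- if (any(inlesion)) diff(range(s[inlesion])) else 0
  La <- max(La, diff(range(s)) / (length(s) * 2)) # at least ~one station
  list(
    A0 = pi * r0^2, As = pi * r_min^2,
    D0 = 2 * r0, Ds = 2 * r_min,
    La = La, i_throat = i_min
  )
}

validate_profile <- function(r_profile) {
  if (!is.data.frame(r_profile) || !all(c("s", "r") %in% names(r_profile))) {
    abort("`r_profile` must be a data frame with columns `s` and `r` (mm).")
  }
  s <- as.numeric(r_profile$s)
  r <- as.numeric(r_profile$r)
  if (length(s) < 2L) abort("`r_profile` needs at least 2 stations.")
  if (is.unsorted(s, strictly = TRUE)) abort("`s` must be strictly increasing.")
  if (any(!is.finite(r)) || any(r <= 0)) abort("radius profile must be strictly positive.")
  list(s_m = s * 1e-3, r_m = r * 1e-3)
}

#' Steady reduced-order flow solve over a lumen radius profile
#'
#' Solves the steady, axisymmetric reduction of the incompressible
#' continuity and momentum equations over a rigid vessel described by its
#' radius profile `r(s)`. Mass conservation holds exactly by construction
#' (`v(s) = Q / A(s)` with a single flow rate `Q`); the pressure field
#' integrates the distributed viscous gradient segment-by-segment with a
#' trapezoid rule on `8 mu Q / (pi r(s)^4)`, plus the turbulent
#' expansion loss of the Young-Tsai stenosis model applied across the
#' throat when a focal narrowing is present (the constriction's viscous
#' excess is already carried by the integrated Poiseuille term). With
#' pressure conditions on both ends the flow is recovered by bisection on
#' the monotone `Q -> dp(Q)` relation, bracketed by the zero-loss
#' Poiseuille bound.
#'
#' @param r_profile Stations tibble with `s`, `r` in mm.
#' @param fluid A [fluid_model()].
#' @param bc A [flow_bc()].
#' @param tol Relative tolerance of the bisection (on Q).
#' @return A `flow_solution`: tibble of stations (`s` mm, `r` mm,
#'   `area` mm^2, `pressure_pa`, `pressure_mmhg`, `velocity` m/s) with
#'   attributes `Q` (m^3/s), `q_ml_s`, and the achieved `dp_pa`.
#' @examples
#' prof <- lumen_profile(vessel_geometry(L = 40, R0 = 2, d = 0.5))
#' sol <- solve_steady_flow(prof, fluid_model(), flow_bc(inlet_pressure = 100, inlet_flow = 3))
#' glance(sol)
#' @export
solve_steady_flow <- function(r_profile, fluid = fluid_model(), bc, tol = 1e-12) {
  stopifnot(inherits(fluid, "fluid_model"), inherits(bc, "flow_bc"))
  p <- validate_profile(r_profile)
  s <- p$s_m
  r <- p$r_m
  n <- length(s)
  st <- stenosis_descriptors(p)

  # cumulative pressure drop (Pa) from inlet to each station at flow Q (m^3/s)
  drop_profile <- function(Q) {
    grad <- 8 * fluid$mu * Q / (pi * r^4) # dP/ds, Pa/m, at stations
    seg <- diff(s) * (head(grad, -1) + tail(grad, -1)) / 2
    dp <- c(0, cumsum(seg))
    if (!is.null(st)) {
      extra <- 1.52 * fluid$rho / (2 * st$A0^2) * (st$A0 / st$As - 1)^2 * Q^2
      k <- st$i_throat
      dp[seq(min(k + 1L, n), n)] <- dp[seq(min(k + 1L, n), n)] + extra
    }
    dp
  }
  total_drop <- function(Q) drop_profile(Q)[n]

  if (!is.null(bc$inlet_flow)) {
    Q <- bc$inlet_flow * 1e-6
  } else {
    p_in <- mmhg_to_pa(bc$inlet_pressure)
    target <- if (!is.null(bc$outlet_pressure)) {
      function(Q) total_drop(Q) - (p_in - mmhg_to_pa(bc$outlet_pressure))
    } else {
      Rd <- bc$outlet_resistance * MMHG_PA / 1e-6 # Pa per m^3/s
      function(Q) total_drop(Q) + Rd * Q - p_in
    }
    dp_max <- p_in
    r_max <- max(r)
    L_tot <- s[n] - s[1]
    q_hi <- dp_max * pi * r_max^4 / (8 * fluid$mu * L_tot) # zero-loss bound
    if (target(q_hi) < 0) abort("no flow satisfying the boundary conditions within the bracket.")
    lo <- 0
    hi <- q_hi
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (target(mid) > 0) hi <- mid else lo <- mid
      if ((hi - lo) <= tol * max(hi, 1e-30)) break
    }
    Q <- (lo + hi) / 2
  }

  dp <- drop_profile(Q)
  p_inlet <- if (!is.null(bc$inlet_pressure)) {
    mmhg_to_pa(bc$inlet_pressure)
  } else if (!is.null(bc$outlet_pressure)) {
    mmhg_to_pa(bc$outlet_pressure) + dp[n]
  } else {
    (bc$outlet_resistance * MMHG_PA / 1e-6) * Q + dp[n]
  }
  P <- p_inlet - dp
  area_si <- pi * r^2
  sol <- tibble(
    s = s * 1e3, r = r * 1e3, area = area_si * 1e6,
    pressure_pa = P, pressure_mmhg = pa_to_mmhg(P),
    velocity = Q / area_si
  )
  structure(sol,
    class = c("flow_solution", class(sol)),
    Q = Q, q_ml_s = Q * 1e6, dp_pa = dp[n]
  )
}

#' Time-mean of a pressure waveform
#'
#' Trapezoidal time integral divided by the duration — the mean pressure a
#' transducer reports over whole cardiac cycles.
#'
#' @param waveform A tibble with `time` and `pressure` columns (as from
#'   [pressure_waveform()]), or a numeric vector of uniformly sampled
#'   pressures.
#' @param time Sample times when `waveform` is a bare vector.
#' @return Scalar mean pressure (input units).
#' @export
mean_pressure <- function(waveform, time = NULL) {
  if (is.data.frame(waveform)) {
    if (!all(c("time", "pressure") %in% names(waveform))) {
      abort("waveform must have `time` and `pressure` columns.")
    }
    t <- waveform$time
    p <- waveform$pressure
  } else {
    p <- as.numeric(waveform)
    t <- if (is.null(time)) seq_along(p) - 1 else time
  }
  if (!length(p)) abort("empty waveform.")
  if (length(p) == 1L) return(p)
  if (length(t) != length(p)) abort("time and pressure lengths differ.")
  sum(diff(t) * (head(p, -1) + tail(p, -1)) / 2) / (t[length(t)] - t[1])
}

#' Fractional flow reserve
#'
#' `FFR = Ps / Pr`: the ratio of mean distal coronary pressure to mean
#' aortic pressure at maximal hyperemia. Arguments may be scalar mean
#' pressures or waveforms (tibbles with `time`/`pressure`), which are
#' averaged by [mean_pressure()]. Values above 1 are non-physical for a
#' passive stenosis and raise a warning.
#'
#' @param distal Distal pressure: scalar or waveform.
#' @param aortic Aortic (proximal reference) pressure: scalar or waveform.
#' @return An `ffr_result`: list with `ffr`, `ps`, `pr`.
#' @examples
#' compute_ffr(80, 100)$ffr # 0.8
#' @export
compute_ffr <- function(distal, aortic) {
  ps <- if (is.data.frame(distal)) mean_pressure(distal) else as.numeric(distal)
  pr <- if (is.data.frame(aortic)) mean_pressure(aortic) else as.numeric(aortic)
  check_scalar(ps, "distal")
  check_scalar(pr, "aortic")
  if (pr <= 0) abort("aortic mean pressure must be positive.")
  ffr <- ps / pr
  if (ffr > 1 + 1e-9) warn(sprintf("FFR = %.3f > 1: non-physical for a passive stenosis.", ffr))
  structure(list(ffr = ffr, ps = ps, pr = pr), class = "ffr_result")
}

#' @export
print.ffr_result <- function(x, ...) {
  cat(sprintf("<ffr_result> FFR = %.3f (Ps = %.4g, Pr = %.4g)\n", x$ffr, x$ps, x$pr))
  invisible(x)
}

#' FFR across a sweep of stenosis severities
#'
#' Runs the reduced-order solver over the analytic lumen profile of a
#' template vessel at each severity `d`, at a fixed hyperemic flow and
#' aortic pressure, and reports the FFR of each lesion. Hyperemia is
#' modelled as a prescribed hyperemic flow (default three times a 1 mL/s
#' resting flow).
#'
#' @param d Vector of severities in `[0, 1)`.
#' @param L,R0,w Template geometry (mm): length, baseline radius, stenosis
#'   width. The default is a proximal epicardial vessel (4 mm lumen
#'   diameter), for which the sweep stays inside the physical FFR range
#'   even at `d = 0.7` under hyperemic flow.
#' @param fluid A [fluid_model()].
#' @param p_aortic Aortic mean pressure, mmHg.
#' @param q_hyper Hyperemic flow, mL/s.
#' @param ds Station spacing for the analytic profile, mm.
#' @return An `ffr_sweep` tibble: `d`, `q_ml_s`, `pr_mmhg`, `ps_mmhg`,
#'   `dp_mmhg`, `ffr`.
#' @examples
#' ffr_vs_severity(c(0, 0.3, 0.5, 0.7))
#' @export
ffr_vs_severity <- function(d = c(0, 0.3, 0.5, 0.7), L = 40, R0 = 2,
                            w = 4, fluid = fluid_model(), p_aortic = 100,
                            q_hyper = 3, ds = 0.25) {
  if (any(d < 0 | d >= 1)) abort("severities `d` must lie in [0, 1).")
  rows <- purrr::map(d, function(di) {
    geom <- vessel_geometry(L = L, R0 = R0, d = di, w = w)
    prof <- lumen_profile(geom, ds = ds)
    sol <- solve_steady_flow(prof, fluid,
      flow_bc(inlet_pressure = p_aortic, inlet_flow = q_hyper)
    )
    ps <- sol$pressure_mmhg[nrow(sol)]
    tibble(
      d = di, q_ml_s = q_hyper, pr_mmhg = p_aortic, ps_mmhg = ps,
      dp_mmhg = p_aortic - ps, ffr = compute_ffr(ps, p_aortic)$ffr
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ffr_sweep", class(out))
  out
}
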