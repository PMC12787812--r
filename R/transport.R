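#' Soil column geometry and packing
#'
#' @param length_cm Column length (cm), positive. Default 15.
#' @param diameter_cm Inner diameter (cm), positive. Default 5.
#' @param bulk_density Dry bulk density rho (g/cm^3), positive. Default 1.34,
#'   a typical field packing density for sandy wetland soil.
#' @param theta Volumetric water content theta_v (cm^3/cm^3), in (0, 1).
#'   Default 0.42; see [theta_from_flow()] and [porosity_from_bulk_density()]
#'   for the two supported ways of deriving it.
#' @return An object of class `soil_column`.
#' @export
soil_column <- function(length_cm = 15, diameter_cm = 5,
                        bulk_density = 1.34, theta = 0.42) {
  if (length_cm <= 0 || diameter_cm <= 0 || bulk_density <= 0)
    stop("length_cm, diameter_cm and bulk_density must be positive",
         call. = FALSE)
  if (theta <= 0 || theta >= 1)
    stop("theta must lie strictly between 0 and 1", call. = FALSE)
  structure(list(length_cm = length_cm, diameter_cm = diameter_cm,
                 bulk_density = bulk_density, theta = theta),
            class = "soil_column")
}

#' @export
print.soil_column <- function(x, ...) {
  cat(sprintf("Soil column: L = %g cm, d = %g cm, rho = %g g/cm3, theta = %g\n",
              x$length_cm, x$diameter_cm, x$bulk_density, x$theta))
  invisible(x)
}

#' Water content from the metered flow and pore-water velocity
#'
#' In a saturated homogeneous column the Darcy flux is
#' `q = Q / A` and the volumetric water content follows from `theta = q / v`.
#' With Q = 0.6 mL/min through a 5 cm diameter column and v = 4.370 cm/h this
#' gives theta of about 0.42.
#'
#' @param flow_mL_per_min Pump flow rate Q (mL/min).
#' @param diameter_cm Column inner diameter (cm).
#' @param v Average pore-water velocity (cm/h).
#' @return Volumetric water content (dimensionless).
#' @export
theta_from_flow <- function(flow_mL_per_min, diameter_cm, v) {
  area <- pi * (diameter_cm / 2)^2
  q <- flow_mL_per_min * 60 / area  # cm/h
  q / v
}

#' Porosity estimated from bulk density
#'
#' `1 - rho / particle_density`, assuming the quartz-dominated particle
#' density of 2.65 g/cm^3 unless stated otherwise.
#'
#' @param bulk_density Dry bulk density (g/cm^3).
#' @param particle_density Particle density (g/cm^3), default 2.65.
#' @return Total porosity (dimensionless).
#' @export
porosity_from_bulk_density <- function(bulk_density, particle_density = 2.65) {
  1 - bulk_density / particle_density
}

#' Column hydraulics
#'
#' @param v Average pore-water velocity (cm/h), positive.
#' @param dispersivity Dispersivity lambda (cm), nonnegative.
#' @param d0 Molecular diffusion coefficient (cm^2/h), nonnegative.
#'   Default 0: molecular diffusion is negligible at typical column flow
#'   rates and the hydrodynamic dispersion coefficient is
#'   `D = lambda * v + d0`.
#' @return An object of class `hydraulics` with the derived `D`.
#' @export
hydraulics <- function(v, dispersivity, d0 = 0) {
  if (v <= 0) stop("v must be positive", call. = FALSE)
  if (dispersivity < 0 || d0 < 0)
    stop("dispersivity and d0 must be nonnegative", call. = FALSE)
  structure(list(v = v, dispersivity = dispersivity, d0 = d0,
                 D = dispersivity * v + d0),
            class = "hydraulics")
}

#' @export
print.hydraulics <- function(x, ...) {
  cat(sprintf("Hydraulics: v = %g cm/h, lambda = %g cm, D = %g cm2/h\n",
              x$v, x$dispersivity, x$D))
  invisible(x)
}

#' Two-site sorption parameters
#'
#' Sorption is split between type-1 sites at instantaneous equilibrium
#' (fraction `f` of the distribution coefficient `kd`) and type-2 sites that
#' approach equilibrium by first-order kinetics at rate `alpha`:
#' `s1 = f * kd * c^beta` and
#' `ds2/dt = alpha * ((1 - f) * kd * c^beta - s2)`.
#'
#' @param f Fraction of instantaneous (type-1) sites, in `[0, 1]`.
#' @param kd Sorption distribution coefficient (L/kg), nonnegative.
#' @param alpha First-order kinetic rate coefficient (1/h), nonnegative.
#' @param beta Sorption-isotherm exponent (dimensionless), positive.
#'   Default 1 (linear sorption); a batch Freundlich 1/n may be supplied.
#' @return An object of class `two_site_sorption`.
#' @export
two_site_sorption <- function(f, kd, alpha, beta = 1) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  if (kd < 0) stop("kd must be nonnegative", call. = FALSE)
  if (alpha < 0) stop("alpha must be nonnegative", call. = FALSE)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  structure(list(f = f, kd = kd, alpha = alpha, beta = beta),
            class = "two_site_sorption")
}

#' @export
print.two_site_sorption <- function(x, ...) {
  cat(sprintf("Two-site sorption: f = %g, Kd = %g L/kg, alpha = %g 1/h, beta = %g\n",
              x$f, x$kd, x$alpha, x$beta))
  invisible(x)
}

#' Solute pulse schedule
#'
#' @param c_in Input concentration during the pulse (mg/L), positive.
#' @param pulse_pv Duration of solute injection, in pore volumes.
#' @param total_pv Total simulated duration, in pore volumes; must exceed
#'   `pulse_pv`.
#' @return An object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(c_in = 1, pulse_pv, total_pv) {
  if (c_in <= 0) stop("c_in must be positive", call. = FALSE)
  if (pulse_pv <= 0 || pulse_pv >= total_pv)
    stop("need 0 < pulse_pv < total_pv", call. = FALSE)
  structure(list(c_in = c_in, pulse_pv = pulse_pv, total_pv = total_pv),
            class = "pulse_schedule")
}

#' Numerical grid for the column solver
#'
#' @param nx Number of spatial cells (>= 25). Default 150, i.e. 0.1 cm cells
#'   for a 15 cm column.
#' @param dt_max Maximum time step (h). Default 0.05 h; the solver subdivides
#'   each pulse leg into equal steps no longer than this, so pulse switching
#'   is exact in time.
#' @param scheme Spatial differencing for advection: `"central"`
#'   (second-order, requires grid Peclet number `v*dx/D <= 2`) or `"upwind"`
#'   (first-order, unconditionally non-oscillatory but with numerical
#'   dispersion of about `v*dx/2`, useful in the advection-dominated limit).
#' @return An object of class `transport_grid`.
#' @export
transport_grid <- function(nx = 150, dt_max = 0.05,
                           scheme = c("central", "upwind")) {
  scheme <- match.arg(scheme)
  if (nx < 25) stop("nx must be at least 25", call. = FALSE)
  if (dt_max <= 0) stop("dt_max must be positive", call. = FALSE)
  structure(list(nx = as.integer(nx), dt_max = dt_max, scheme = scheme),
            class = "transport_grid")
}

#' Retardation factor for linear equilibrium sorption
#'
#' `r = 1 + rho * kd / theta`. With kd in L/kg and rho in g/cm^3 the product
#' is dimensionless (1 L/kg = 1 cm^3/g).
#'
#' @param column A [soil_column()].
#' @param kd Distribution coefficient (L/kg), nonnegative.
#' @return The retardation factor (dimensionless, >= 1).
#' @export
retardation_factor <- function(column, kd) {
  stopifnot(inherits(column, "soil_column"))
  if (any(kd < 0)) stop("kd must be nonnegative", call. = FALSE)
  1 + column$bulk_density * kd / column$theta
}

#' Duration of one pore volume
#'
#' The mean travel time of one pore volume of water through the column,
#' `length / v` (hours per PV).
#'
#' @param column A [soil_column()].
#' @param hyd A [hydraulics()].
#' @return Hours per pore volume.
#' @export
pv_time_conversion <- function(column, hyd) {
  stopifnot(inherits(column, "soil_column"), inherits(hyd, "hydraulics"))
  column$length_cm / hyd$v
}

#' Breakthrough curve container
#'
#' A breakthrough curve: paired pore volumes and relative effluent
#' concentrations C/C0. Small negative values (numerical undershoot) are
#' tolerated in memory and clipped at zero on CSV export.
#'
#' @param pv Strictly increasing pore-volume values.
#' @param c_rel Relative concentrations, same length as `pv`.
#' @param hours_per_pv Optional duration of one pore volume (h), carried as
#'   metadata; needed to place observations on the time axis when fitting
#'   hydraulic parameters (it derives from the metered flow and water
#'   content, not from the fitted velocity).
#' @param tol Tolerated negative undershoot in `c_rel`.
#' @return A `data.frame` with columns `pv`, `c_rel`, class `btc`.
#' @export
btc <- function(pv, c_rel, hours_per_pv = NA_real_, tol = 1e-6) {
  if (length(pv) != length(c_rel))
    stop("pv and c_rel must have equal length", call. = FALSE)
  if (length(pv) >= 2L && any(diff(pv) <= 0))
    stop("pv must be strictly increasing", call. = FALSE)
  if (any(c_rel < -tol))
    stop("c_rel has negative values beyond numerical tolerance", call. = FALSE)
  structure(data.frame(pv = as.numeric(pv), c_rel = as.numeric(c_rel)),
            hours_per_pv = hours_per_pv,
            class = c("btc", "data.frame"))
}

#' @export
print.btc <- function(x, ...) {
  cat(sprintf("Breakthrough curve: %d points, pv in [%g, %g], peak C/C0 = %.3g\n",
              nrow(x), min(x$pv), max(x$pv), max(x$c_rel)))
  mb <- attr(x, "mass_balance")
  if (!is.null(mb))
    cat(sprintf("  mass balance: effluent %.4g + stored %.4g vs injected %.4g (PV units)\n",
                mb$effluent_pv, mb$stored_pv, mb$injected_pv))
  invisible(x)
}

# ---- core finite-volume / Crank-Nicolson solver -----------------------------

# Spatial operator A (nx x nx, dense) and unit inlet-source vector for the
# cell-centered finite-volume discretization of dc/dt = -d(vc - D dc/dx)/dx
# with a third-type (flux) inlet, v*c_in = v*c - D*dc/dx, and a zero
# dispersive gradient outlet. Row i of A gives the flux divergence for cell i;
# b_unit holds the inlet source for c_in = 1.
build_cde_operator <- function(nx, dx, v, D, scheme) {
  A <- matrix(0, nx, nx)
  dd <- D / dx
  if (scheme == "central") {
    # interior face i+1/2: J = v*(c_i + c_{i+1})/2 - D*(c_{i+1} - c_i)/dx
    for (i in seq_len(nx)) {
      if (i > 1L) {       # face i-1/2 inflow
        A[i, i - 1L] <- A[i, i - 1L] + (v / 2 + dd) / dx
        A[i, i] <- A[i, i] + (v / 2 - dd) / dx
      }
      if (i < nx) {       # face i+1/2 outflow
        A[i, i] <- A[i, i] - (v / 2 + dd) / dx
        A[i, i + 1L] <- A[i, i + 1L] - (v / 2 - dd) / dx
      }
    }
  } else {
    # upwind: J = v*c_i - D*(c_{i+1} - c_i)/dx
    for (i in seq_len(nx)) {
      if (i > 1L) {
        A[i, i - 1L] <- A[i, i - 1L] + (v + dd) / dx
        A[i, i] <- A[i, i] - dd / dx
      }
      if (i < nx) {
        A[i, i] <- A[i, i] - (v + dd) / dx
        A[i, i + 1L] <- A[i, i + 1L] + dd / dx
      }
    }
  }
  # outlet face: J = v*c_nx (zero dispersive gradient)
  A[nx, nx] <- A[nx, nx] - v / dx
  b_unit <- numeric(nx)
  b_unit[1L] <- v / dx
  list(A = A, b_unit = b_unit)
}

# One constant-coefficient theta-scheme leg (beta = 1): Crank-Nicolson
# (theta = 1/2, second order) for the central spatial scheme, backward Euler
# (theta = 1, L-stable, no ringing at sharp fronts) for the upwind scheme.
# State: aqueous c and kinetic-site s2 per cell. Returns states plus the
# effluent trace at every internal step.
run_linear_leg <- function(state, A, b_vec, n_steps, dt, r1, rho_th,
                           f, kd, alpha, theta_t = 0.5) {
  nx <- length(state$c)
  g <- if (alpha > 0) alpha / (1 + alpha * dt * theta_t) else 0
  kk <- rho_th * g * (1 - f) * kd
  M_L <- diag(r1 / dt + theta_t * kk, nx) - theta_t * A
  M_R <- diag(r1 / dt - (1 - theta_t) * kk, nx) + (1 - theta_t) * A
  M_inv <- solve(M_L)
  M_step <- M_inv %*% M_R          # constant per leg: one matvec per step
  b_step <- drop(M_inv %*% b_vec)
  c_cur <- state$c; s2 <- state$s2
  c_out <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    c_new <- drop(M_step %*% c_cur) + b_step
    if (alpha > 0) {
      c_new <- c_new + rho_th * g * drop(M_inv %*% s2)
      c_th <- (1 - theta_t) * c_cur + theta_t * c_new
      s2 <- s2 + dt * g * ((1 - f) * kd * c_th - s2)
    }
    c_cur <- c_new
    c_out[k] <- c_cur[nx]
  }
  list(c = c_cur, s2 = s2, c_out = c_out)
}

# Nonlinear (beta != 1) leg: Picard iteration on the frozen storage/source
# coefficients, implicit Euler in time for robustness near sharp fronts.
run_nonlinear_leg <- function(state, A, b_vec, n_steps, dt, rho_th,
                              f, kd, alpha, beta, c_eps = 1e-10) {
  nx <- length(state$c)
  c_cur <- state$c; s2 <- state$s2
  c_out <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    c_new <- c_cur
    for (it in 1:4) {
      cm <- pmax(c_new, c_eps)
      r1 <- 1 + f * rho_th * kd * beta * cm^(beta - 1)
      g <- if (alpha > 0) alpha / (1 + alpha * dt) else 0
      # implicit s2: s2_new = (s2 + alpha*dt*(1-f)*kd*c_new^beta)/(1+alpha*dt)
      # sink in c-eq: rho_th*(s2_new - s2)/dt, with c^beta ~ cm^(beta-1)*c_new
      kvec <- rho_th * g * (1 - f) * kd * cm^(beta - 1)
      M_L <- diag(r1 / dt + kvec, nx) - A
      rhs <- c_cur * r1 / dt + b_vec + rho_th * g * s2
      c_prev <- c_new
      c_new <- solve(M_L, rhs)
      if (max(abs(c_new - c_prev)) < 1e-10) break
    }
    cm <- pmax(c_new, c_eps)
    if (alpha > 0)
      s2 <- (s2 + alpha * dt * (1 - f) * kd * cm^(beta - 1) * c_new) /
        (1 + alpha * dt)
    c_cur <- c_new
    c_out[k] <- c_cur[nx]
  }
  list(c = c_cur, s2 = s2, c_out = c_out)
}

# Shared driver: simulate the pulse and elution legs in the time domain and
# interpolate the effluent to the requested output times. Times in hours.
solve_column <- function(column, hyd, sorb, t_pulse, t_end, c_in,
                         grid, t_out) {
  nx <- grid$nx
  dx <- column$length_cm / nx
  v <- hyd$v; D <- hyd$D
  if (D <= 0 && grid$scheme == "central")
    stop("central scheme requires D > 0; use the upwind scheme", call. = FALSE)
  if (grid$scheme == "central" && v * dx / D > 2 + 1e-12)
    stop(sprintf(paste0("grid Peclet number v*dx/D = %.3g exceeds 2; ",
                        "refine nx or use the upwind scheme"), v * dx / D),
         call. = FALSE)
  op <- build_cde_operator(nx, dx, v, D, grid$scheme)
  rho_th <- column$bulk_density / column$theta
  if (is.null(sorb)) sorb <- two_site_sorption(f = 0, kd = 0, alpha = 0)
  f <- sorb$f; kd <- sorb$kd; alpha <- sorb$alpha; beta <- sorb$beta
  linear <- abs(beta - 1) < 1e-12

  legs <- list(list(t0 = 0, t1 = t_pulse, c_in = c_in),
               list(t0 = t_pulse, t1 = t_end, c_in = 0))
  state <- list(c = numeric(nx), s2 = numeric(nx))
  t_trace <- 0; c_trace <- 0  # effluent trace, starts at c = 0
  for (leg in legs) {
    span <- leg$t1 - leg$t0
    if (span <= 0) next
    n_steps <- max(2L, as.integer(ceiling(span / grid$dt_max)))
    dt <- span / n_steps
    b_vec <- op$b_unit * leg$c_in
    if (linear) {
      r1 <- 1 + f * rho_th * kd
      res <- run_linear_leg(state, op$A, b_vec, n_steps, dt, r1, rho_th,
                            f, kd, alpha,
                            theta_t = if (grid$scheme == "upwind") 1 else 0.5)
    } else {
      res <- run_nonlinear_leg(state, op$A, b_vec, n_steps, dt, rho_th,
                               f, kd, alpha, beta)
    }
    state <- list(c = res$c, s2 = res$s2)
    t_trace <- c(t_trace, leg$t0 + dt * seq_len(n_steps))
    c_trace <- c(c_trace, res$c_out)
  }

  c_out <- stats::approx(t_trace, c_trace, xout = t_out, rule = 2)$y
  # mass balance in pore-volume-equivalent units of c_in
  hpp <- column$length_cm / v
  eff_pv <- sum(diff(t_trace) * (c_trace[-1] + c_trace[-length(c_trace)]) / 2) /
    (c_in * hpp)
  cm <- pmax(state$c, 0)
  s1 <- f * kd * cm^beta
  stored <- sum(column$theta * state$c + column$bulk_density * (s1 + state$s2)) *
    dx / (column$theta * column$length_cm * c_in)
  list(t = t_out, c_rel = c_out / c_in,
       state = state,
       mass_balance = list(effluent_pv = eff_pv, stored_pv = stored,
                           injected_pv = c_in * t_pulse / (c_in * hpp)))
}

#' Simulate a conservative-tracer breakthrough curve
#'
#' Forward-simulates the one-dimensional convection-dispersion equation for a
#' non-sorbing solute (retardation 1) in a saturated homogeneous column with
#' a third-type (flux) inlet boundary, a zero dispersive gradient at the
#' outlet, and a solute-free initial condition. A finite pulse of feed
#' concentration is applied for `pulse_pv` pore volumes and then switched
#' exactly (the time step is aligned to the pulse boundary) to solute-free
#' feed. The effluent concentration is the resident concentration in the
#' outlet cell, which under the zero-gradient outlet equals the flux
#' concentration leaving the column.
#'
#' @param column A [soil_column()].
#' @param hyd A [hydraulics()].
#' @param pulse A [pulse_schedule()].
#' @param grid A [transport_grid()].
#' @param pv_out Pore volumes at which to report the effluent; default a
#'   0.02-PV grid over the simulated duration.
#' @return A [btc()] with attributes `hours_per_pv` and `mass_balance` (the
#'   latter gives effluent, stored and injected mass in pore-volume units of
#'   the feed concentration).
#' @export
simulate_tracer <- function(column, hyd, pulse, grid = transport_grid(),
                            pv_out = NULL) {
  simulate_two_site(column, hyd, sorb = NULL, pulse = pulse, grid = grid,
                    pv_out = pv_out)
}

#' Simulate reactive transport with two-site equilibrium/kinetic sorption
#'
#' Solves the coupled system
#' \deqn{(1 + f \rho k_d \beta c^{\beta-1}/\theta)\,\partial c/\partial t +
#'   (\rho/\theta)\,\partial s_2/\partial t =
#'   D\,\partial^2 c/\partial x^2 - v\,\partial c/\partial x}
#' with instantaneous type-1 sites \eqn{s_1 = f k_d c^\beta} and kinetic
#' type-2 sites \eqn{\partial s_2/\partial t =
#' \alpha[(1-f) k_d c^\beta - s_2]}, with the same boundary and initial
#' conditions as [simulate_tracer()]. With `sorb = NULL` or `kd = 0` the
#' model reduces to the conservative tracer; with `f = 1` and `beta = 1` it
#' reduces to the equilibrium convection-dispersion equation with
#' retardation factor [retardation_factor()].
#'
#' @inheritParams simulate_tracer
#' @param sorb A [two_site_sorption()], or `NULL` for a conservative solute.
#' @return A [btc()]; see [simulate_tracer()].
#' @export
simulate_two_site <- function(column, hyd, sorb, pulse,
                              grid = transport_grid(), pv_out = NULL) {
  stopifnot(inherits(column, "soil_column"), inherits(hyd, "hydraulics"),
            inherits(pulse, "pulse_schedule"), inherits(grid, "transport_grid"))
  if (!is.null(sorb)) stopifnot(inherits(sorb, "two_site_sorption"))
  hpp <- pv_time_conversion(column, hyd)
  if (is.null(pv_out)) pv_out <- seq(0, pulse$total_pv, by = 0.02)
  res <- solve_column(column, hyd, sorb,
                      t_pulse = pulse$pulse_pv * hpp,
                      t_end = pulse$total_pv * hpp,
                      c_in = pulse$c_in, grid = grid,
                      t_out = pv_out * hpp)
  out <- btc(pv_out, res$c_rel, hours_per_pv = hpp)
  attr(out, "mass_balance") <- res$mass_balance
  out
}
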