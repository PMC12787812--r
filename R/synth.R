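#' Noise model for synthetic data
#'
#' @param kind One of `"none"`, `"additive_gaussian"` (sd in the units of the
#'   perturbed quantity) or `"multiplicative_gaussian"` (sd relative).
#' @param sd Standard deviation, nonnegative.
#' @param seed Integer seed; recorded in all generated outputs so datasets
#'   are reproducible. Mersenne-Twister is used throughout.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "additive_gaussian",
                                 "multiplicative_gaussian"),
                        sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (sd < 0) stop("sd must be nonnegative", call. = FALSE)
  structure(list(kind = kind, sd = sd, seed = seed), class = "noise_model")
}

# evaluate noise on x under a locally seeded RNG, restoring global RNG state
apply_noise <- function(x, noise) {
  if (is.null(noise) || noise$kind == "none" || noise$sd == 0) return(x)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (!is.null(noise$seed)) set.seed(noise$seed, kind = "Mersenne-Twister")
  eps <- stats::rnorm(length(x), sd = noise$sd)
  switch(noise$kind,
         additive_gaussian = x + eps,
         multiplicative_gaussian = x * (1 + eps))
}

#' Solve the closed-system batch equilibrium
#'
#' For each initial concentration C0 of a batch design, solves the
#' closed-system mass balance `Ce + (m/V) * q(Ce) = C0` for the equilibrium
#' solution concentration Ce (monotone scalar root-find bracketed on
#' `[0, C0]`), where `q(.)` is the sorption law of a converged isotherm fit,
#' and returns the paired `(Ce, qe = q(Ce))` records. By construction the
#' records satisfy the batch mass balance [compute_sorbed_amount()] to high
#' precision.
#'
#' @param design A [batch_design()].
#' @param fit A converged `freundlich_fit` or `langmuir_fit` (e.g. from
#'   [freundlich_params()]).
#' @param tol Root-finding tolerance on Ce.
#' @return An [isotherm_data()] with an extra column `c0`.
#' @export
solve_batch_equilibrium <- function(design, fit, tol = 1e-10) {
  stopifnot(inherits(design, "batch_design"))
  ratio <- design$soil_mass / design$solution_volume  # g/mL = kg/L
  ce <- vapply(design$initial_concentrations, function(c0) {
    if (c0 == 0) return(0)
    g <- function(x) x + ratio * predict_isotherm(fit, x) - c0
    if (g(c0) <= 0) return(c0)  # no sorption (e.g. kf = 0)
    stats::uniroot(g, c(0, c0), tol = tol)$root
  }, numeric(1))
  out <- isotherm_data(ce = ce, qe = predict_isotherm(fit, ce))
  out$c0 <- design$initial_concentrations
  out
}

#' Generate a synthetic batch isotherm dataset
#'
#' Solves the batch equilibrium for each initial concentration, perturbs the
#' *measured* equilibrium solution concentration Ce with the noise model, and
#' recomputes the sorbed amount from the batch mass balance
#' `qe = (C0 - Ce) * V / m` — so measurement noise propagates through the
#' mass balance exactly as it would in a real batch experiment (a noisy Ce
#' can therefore yield a negative qe, which downstream fits exclude).
#'
#' @inheritParams solve_batch_equilibrium
#' @param noise A [noise_model()].
#' @return An [isotherm_data()] with columns `c0`, `ce`, `qe` and attributes
#'   `seed` and `noise`.
#' @export
gen_isotherm_dataset <- function(design, fit, noise = noise_model()) {
  eq <- solve_batch_equilibrium(design, fit)
  ce <- apply_noise(eq$ce, noise)
  qe <- compute_sorbed_amount(eq$c0, ce, design$solution_volume,
                              design$soil_mass)
  out <- data.frame(c0 = eq$c0, ce = ce, qe = qe)
  class(out) <- c("isotherm_data", "data.frame")
  attr(out, "seed") <- noise$seed
  attr(out, "noise") <- noise
  out
}

#' Generate a synthetic breakthrough curve
#'
#' Forward-simulates the column experiment ([simulate_tracer()] or
#' [simulate_two_site()]), resamples the effluent to the fraction-collector
#' sampling grid, applies the noise model to C/C0 and clips negatives to
#' zero.
#'
#' @param column A [soil_column()].
#' @param hyd A [hydraulics()].
#' @param sorb A [two_site_sorption()], or `NULL` for a conservative tracer.
#' @param pulse A [pulse_schedule()].
#' @param grid A [transport_grid()].
#' @param noise A [noise_model()].
#' @param sampling_interval_pv Effluent sampling interval in pore volumes,
#'   emulating fraction collection. Default 0.1 PV.
#' @return A [btc()] with attributes `seed`, `noise` and `hours_per_pv`.
#' @export
gen_btc <- function(column, hyd, sorb = NULL, pulse,
                    grid = transport_grid(), noise = noise_model(),
                    sampling_interval_pv = 0.1) {
  pv_out <- seq(0, pulse$total_pv, by = sampling_interval_pv)
  sim <- simulate_two_site(column, hyd, sorb, pulse, grid, pv_out = pv_out)
  c_rel <- pmax(apply_noise(sim$c_rel, noise), 0)
  out <- btc(pv_out, c_rel, hours_per_pv = attr(sim, "hours_per_pv"))
  attr(out, "seed") <- noise$seed
  attr(out, "noise") <- noise
  out
}
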