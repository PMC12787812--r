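#' Batch experimental design
#'
#' Describes a batch equilibrium sorption experiment: a series of initial
#' solution concentrations shaken with a fixed soil mass and solution volume
#' until equilibrium.
#'
#' @param initial_concentrations Numeric vector of initial solute
#'   concentrations C0 (mg/L). Default is the five-level series
#'   10, 15, 20, 25, 30 mg/L used for sulfadiazine batch experiments.
#' @param solution_volume Solution volume V (mL). Must be positive.
#' @param soil_mass Soil mass m (g). Must be positive. The default 10 mL on
#'   5 g gives the 2:1 water-to-soil ratio (V/m).
#' @param temperature Temperature in degrees Celsius (metadata only).
#'
#' @return An object of class `batch_design`.
#' @export
batch_design <- function(initial_concentrations = c(10, 15, 20, 25, 30),
                         solution_volume = 10, soil_mass = 5,
                         temperature = 25) {
  if (!is.numeric(initial_concentrations) || any(initial_concentrations < 0))
    stop("initial_concentrations must be nonnegative", call. = FALSE)
  if (!is.numeric(solution_volume) || length(solution_volume) != 1L ||
      solution_volume <= 0)
    stop("solution_volume must be a single positive number", call. = FALSE)
  if (!is.numeric(soil_mass) || length(soil_mass) != 1L || soil_mass <= 0)
    stop("soil_mass must be a single positive number", call. = FALSE)
  structure(list(initial_concentrations = as.numeric(initial_concentrations),
                 solution_volume = as.numeric(solution_volume),
                 soil_mass = as.numeric(soil_mass),
                 temperature = as.numeric(temperature)),
            class = "batch_design")
}

#' @export
print.batch_design <- function(x, ...) {
  cat("Batch sorption design\n")
  cat("  C0 (mg/L):       ", paste(x$initial_concentrations, collapse = ", "), "\n")
  cat("  solution volume: ", x$solution_volume, "mL\n")
  cat("  soil mass:       ", x$soil_mass, "g\n")
  cat("  temperature:     ", x$temperature, "degC\n")
  invisible(x)
}

#' Equilibrium isotherm records
#'
#' A validated table of batch equilibrium points: equilibrium solution
#' concentration `ce` (mg/L) and sorbed amount `qe` (mg/kg).
#'
#' @param ce Equilibrium solution concentrations (mg/L), nonnegative.
#' @param qe Sorbed amounts (mg/kg), finite.
#' @return A `data.frame` with columns `ce` and `qe`, class `isotherm_data`.
#' @export
isotherm_data <- function(ce, qe) {
  if (length(ce) != length(qe))
    stop("ce and qe must have equal length", call. = FALSE)
  if (any(!is.finite(qe)) || any(!is.finite(ce)))
    stop("ce and qe must be finite", call. = FALSE)
  if (any(ce < 0))
    stop("ce must be nonnegative", call. = FALSE)
  structure(data.frame(ce = as.numeric(ce), qe = as.numeric(qe)),
            class = c("isotherm_data", "data.frame"))
}

#' Sorbed amount from batch mass balance
#'
#' Computes the sorbed amount per unit soil mass from the depletion of the
#' solution phase in a closed batch system,
#' `qe = (c0 - ct) * volume / mass`. With volume in mL, mass in g and
#' concentrations in mg/L the result is in mg/kg.
#'
#' @param c0 Initial solution concentration (mg/L).
#' @param ct Solution concentration at time t or at equilibrium (mg/L).
#' @param volume Solution volume (mL), positive.
#' @param mass Soil mass (g), positive.
#' @return Sorbed amount (mg/kg). Vectorized over `c0`/`ct`.
#' @examples
#' compute_sorbed_amount(30, 28, 10, 5) # 4 mg/kg
#' @export
compute_sorbed_amount <- function(c0, ct, volume, mass) {
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("volume must be a single positive number", call. = FALSE)
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0)
    stop("mass must be a single positive number", call. = FALSE)
  (c0 - ct) * volume / mass
}

# R-squared on the regression's own (transformed) scale, computed directly
# so that exactly collinear data do not trip summary.lm's perfect-fit warning
lm_r2 <- function(fit) {
  y <- stats::model.response(stats::model.frame(fit))
  sstot <- sum((y - mean(y))^2)
  ssres <- sum(stats::residuals(fit)^2)
  if (sstot == 0) return(if (ssres == 0) 1 else NA_real_)
  1 - ssres / sstot
}

# keep only records usable on the log/transformed scales; warn when dropping
drop_nonpositive_records <- function(records, need = 3L) {
  if (!is.data.frame(records) || !all(c("ce", "qe") %in% names(records)))
    stop("records must be a data.frame with columns ce and qe", call. = FALSE)
  keep <- is.finite(records$ce) & is.finite(records$qe) &
    records$ce > 0 & records$qe > 0
  if (any(!keep))
    warning(sum(!keep), " record(s) with ce <= 0 or qe <= 0 excluded from fit",
            call. = FALSE)
  out <- records[keep, c("ce", "qe"), drop = FALSE]
  if (nrow(out) < need)
    stop("fewer than ", need, " valid isotherm records", call. = FALSE)
  out
}

#' Fit a Freundlich isotherm by the linearized log-log regression
#'
#' Ordinary least squares of `ln(qe)` on `ln(ce)`: the slope estimates the
#' exponent 1/n and `exp(intercept)` the capacity constant Kf, the classical
#' linearization of `qe = Kf * ce^(1/n)`. R-squared is reported on the
#' transformed (ln-ln) scale, the scale the regression is performed on.
#'
#' Records with `ce <= 0` or `qe <= 0` (possible in noisy data) are excluded
#' with a warning; at least 3 valid records are required.
#'
#' @param records A data.frame with columns `ce` (mg/L) and `qe` (mg/kg),
#'   e.g. from [isotherm_data()].
#' @return An object of class `freundlich_fit` with elements `kf`
#'   ((mg/kg)(L/mg)^(1/n)), `inv_n` (dimensionless), `r2`, `n_obs`.
#' @seealso [fit_langmuir()], [predict_isotherm()], [classify_isotherm()]
#' @export
fit_freundlich <- function(records) {
  rec <- drop_nonpositive_records(records)
  fit <- stats::lm(log(qe) ~ log(ce), data = rec)
  co <- stats::coef(fit)
  structure(list(kf = unname(exp(co[1L])), inv_n = unname(co[2L]),
                 r2 = lm_r2(fit), n_obs = nrow(rec)),
            class = "freundlich_fit")
}

#' @export
print.freundlich_fit <- function(x, ...) {
  cat("Freundlich isotherm fit (linearized ln-ln regression)\n")
  cat(sprintf("  Kf   = %.4g (mg/kg)(L/mg)^(1/n)\n", x$kf))
  cat(sprintf("  1/n  = %.4g  [%s-type isotherm]\n", x$inv_n,
              classify_isotherm(x)))
  cat(sprintf("  R2   = %.4g (ln-ln scale), n = %d\n", x$r2, x$n_obs))
  invisible(x)
}

#' Fit a Langmuir isotherm by the linearized Ce/qe regression
#'
#' Ordinary least squares of `ce/qe` on `ce`: for
#' `qe = qmax * KL * ce / (1 + KL * ce)` the linearization
#' `ce/qe = ce/qmax + 1/(qmax*KL)` gives `qmax = 1/slope` and
#' `KL = slope/intercept`. R-squared is reported on the transformed
#' (`ce/qe` vs `ce`) scale.
#'
#' When the data are not Langmuir-like (e.g. generated by a Freundlich law
#' with exponent above 1) the regression can return a nonpositive slope or
#' intercept; the implied parameters are then non-physical and the fit is
#' flagged `converged = FALSE` with `kl`, `qmax`, `r2` set to `NA` (written
#' as the literal string "NA" in fit reports).
#'
#' @inheritParams fit_freundlich
#' @return An object of class `langmuir_fit` with elements `kl` (L/mg),
#'   `qmax` (mg/kg), `r2`, `converged`, `n_obs`.
#' @export
fit_langmuir <- function(records) {
  rec <- drop_nonpositive_records(records)
  fit <- stats::lm(I(ce / qe) ~ ce, data = rec)
  co <- stats::coef(fit)
  slope <- unname(co[2L]); intercept <- unname(co[1L])
  if (!is.finite(slope) || !is.finite(intercept) ||
      slope <= 0 || intercept <= 0) {
    out <- list(kl = NA_real_, qmax = NA_real_, r2 = NA_real_,
                converged = FALSE, n_obs = nrow(rec))
  } else {
    out <- list(kl = slope / intercept, qmax = 1 / slope,
                r2 = lm_r2(fit),
                converged = TRUE, n_obs = nrow(rec))
  }
  structure(out, class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat("Langmuir isotherm fit (linearized Ce/qe regression)\n")
  if (!x$converged) {
    cat("  did not converge: non-physical linearized slope/intercept (NA)\n")
  } else {
    cat(sprintf("  KL   = %.4g L/mg\n", x$kl))
    cat(sprintf("  qmax = %.4g mg/kg\n", x$qmax))
    cat(sprintf("  R2   = %.4g (Ce/qe scale), n = %d\n", x$r2, x$n_obs))
  }
  invisible(x)
}

#' Evaluate a fitted isotherm
#'
#' Forward evaluation of a converged isotherm fit:
#' Freundlich `qe = Kf * ce^(1/n)`; Langmuir
#' `qe = qmax * KL * ce / (1 + KL * ce)`.
#'
#' @param fit A `freundlich_fit` or `langmuir_fit` object.
#' @param ce Equilibrium concentration(s), mg/L, nonnegative.
#' @return Predicted sorbed amount(s), mg/kg.
#' @export
predict_isotherm <- function(fit, ce) {
  if (any(ce < 0)) stop("ce must be nonnegative", call. = FALSE)
  UseMethod("predict_isotherm")
}

#' @export
predict_isotherm.freundlich_fit <- function(fit, ce) {
  ifelse(ce == 0, 0, fit$kf * ce^fit$inv_n)
}

#' @export
predict_isotherm.langmuir_fit <- function(fit, ce) {
  if (!isTRUE(fit$converged))
    stop("cannot predict from a non-converged Langmuir fit", call. = FALSE)
  fit$qmax * fit$kl * ce / (1 + fit$kl * ce)
}

#' @export
predict.freundlich_fit <- function(object, ce, ...) predict_isotherm(object, ce)

#' @export
predict.langmuir_fit <- function(object, ce, ...) predict_isotherm(object, ce)

#' Construct isotherm fit objects from known parameters
#'
#' Convenience constructors used to evaluate or generate data from published
#' parameter values without refitting.
#'
#' @param kf,inv_n Freundlich capacity constant and exponent 1/n.
#' @param kl,qmax Langmuir affinity constant (L/mg) and capacity (mg/kg).
#' @param r2 Optional goodness-of-fit to carry along.
#' @return A `freundlich_fit` / `langmuir_fit` object.
#' @export
freundlich_params <- function(kf, inv_n, r2 = NA_real_) {
  if (kf < 0) stop("kf must be nonnegative", call. = FALSE)
  structure(list(kf = kf, inv_n = inv_n, r2 = r2, n_obs = NA_integer_),
            class = "freundlich_fit")
}

#' @rdname freundlich_params
#' @export
langmuir_params <- function(kl, qmax, r2 = NA_real_) {
  if (kl <= 0 || qmax <= 0)
    stop("kl and qmax must be positive", call. = FALSE)
  structure(list(kl = kl, qmax = qmax, r2 = r2, converged = TRUE,
                 n_obs = NA_integer_),
            class = "langmuir_fit")
}

#' Classify a Freundlich isotherm by its exponent
#'
#' The shape classification of sorption isotherms by the Freundlich exponent:
#' 1/n below 1 is an "L"-type (concave, high-affinity) isotherm, 1/n equal to
#' 1 (within tolerance) is "C"-type (constant partitioning), and 1/n above 1
#' is "S"-type.
#'
#' @param fit A `freundlich_fit`.
#' @param tol Tolerance around 1 for the "C" label.
#' @return One of `"L"`, `"C"`, `"S"`.
#' @export
classify_isotherm <- function(fit, tol = 1e-9) {
  stopifnot(inherits(fit, "freundlich_fit"))
  if (abs(fit$inv_n - 1) <= tol) "C" else if (fit$inv_n < 1) "L" else "S"
}
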