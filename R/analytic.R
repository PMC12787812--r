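#' Closed-form breakthrough curve for the equilibrium CDE
#'
#' Analytical effluent curve for a finite pulse of solute through a
#' semi-infinite homogeneous column under the convection-dispersion equation
#' with (optionally) linear equilibrium retardation. The flux-averaged
#' concentration for a third-type (flux) inlet is used, which is the
#' erfc-based expression
#' \deqn{c/c_0 = \tfrac12\,\mathrm{erfc}\!\left(\frac{x - \bar v t}
#'   {2\sqrt{\bar D t}}\right) + \tfrac12\, e^{\bar v x/\bar D}\,
#'   \mathrm{erfc}\!\left(\frac{x + \bar v t}{2\sqrt{\bar D t}}\right)}
#' with \eqn{\bar v = v/r}, \eqn{\bar D = D/r}, and the pulse handled by
#' superposition of two step responses. The exponentially weighted second
#' term is evaluated on the log scale to stay finite at large column Peclet
#' numbers.
#'
#' This closed form serves as an independent check on the numerical solver:
#' at high Peclet number the numerical effluent (resident concentration in
#' the outlet cell under a zero-gradient outlet) coincides with the
#' flux-averaged concentration.
#'
#' @param pv Pore volumes at which to evaluate the curve.
#' @param column A [soil_column()].
#' @param hyd A [hydraulics()].
#' @param pulse A [pulse_schedule()].
#' @param retardation Retardation factor r (>= 1), default 1 (tracer).
#' @return A [btc()].
#' @export
analytic_cde_btc <- function(pv, column, hyd, pulse, retardation = 1) {
  stopifnot(inherits(column, "soil_column"), inherits(hyd, "hydraulics"),
            inherits(pulse, "pulse_schedule"))
  if (retardation < 1) stop("retardation must be >= 1", call. = FALSE)
  L <- column$length_cm
  vr <- hyd$v / retardation
  Dr <- hyd$D / retardation
  hpp <- L / hyd$v
  step_response <- function(t) {
    out <- numeric(length(t))
    pos <- which(t > 0)
    if (length(pos)) {
      tt <- t[pos]
      den <- 2 * sqrt(Dr * tt)
      z1 <- (L - vr * tt) / den
      z2 <- (L + vr * tt) / den
      # erfc(z) = 2*pnorm(-z*sqrt(2)); second term on the log scale
      term1 <- stats::pnorm(-z1 * sqrt(2))
      log_term2 <- vr * L / Dr + log(2) +
        stats::pnorm(-z2 * sqrt(2), log.p = TRUE)
      out[pos] <- term1 + 0.5 * exp(log_term2)
    }
    out
  }
  t <- pv * hpp
  t0 <- pulse$pulse_pv * hpp
  c_rel <- step_response(t) - step_response(t - t0)
  btc(pv, pmin(pmax(c_rel, 0), 1.0000001), hours_per_pv = hpp)
}
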