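#' Modulation parameters for simulated working-memory states
#'
#' Parametric changes to the population tuning channels as a function of a
#' channel's distance to the remembered orientation: gain (`gamma`), width
#' (`mu`), preferred-orientation shift (`omega`), plus the memory-strength
#' scaling `phi_test` applied to the stimulus drive at test. `a` and `b`
#' are the slope and midpoint (degrees) of the shift sigmoid and are held
#' fixed.
#'
#' @param phi_test memory strength in `[0, 1]`.
#' @param gamma gain-modulation strength in `[-1, 1]`.
#' @param mu width-modulation strength in `[-1, 1]`.
#' @param omega shift strength in `[0, 1]`.
#' @param a shift-sigmoid slope (fixed at -0.1).
#' @param b shift-sigmoid midpoint in degrees (fixed at 20).
#' @return object of class `modulation_params`.
#' @export
modulation_params <- function(phi_test = 1, gamma = 0, mu = 0, omega = 0,
                              a = -0.1, b = 20) {
  chk <- function(x, lo, hi, nm) {
    if (!is.finite(x) || x < lo || x > hi) {
      stop(sprintf("`%s` must be in [%g, %g]", nm, lo, hi))
    }
  }
  chk(phi_test, 0, 1, "phi_test")
  chk(gamma, -1, 1, "gamma")
  chk(mu, -1, 1, "mu")
  chk(omega, 0, 1, "omega")
  structure(
    list(phi_test = phi_test, gamma = gamma, mu = mu, omega = omega,
         a = a, b = b),
    class = "modulation_params"
  )
}

#' @export
print.modulation_params <- function(x, ...) {
  cat(sprintf(
    "modulation_params: phi_test=%g gamma=%g mu=%g omega=%g (a=%g, b=%g)\n",
    x$phi_test, x$gamma, x$mu, x$omega, x$a, x$b
  ))
  invisible(x)
}

#' Per-channel gain, width and shift modulation terms
#'
#' For a channel whose center lies `theta` degrees (shortest arc, 0-90)
#' from the remembered orientation:
#' \itemize{
#'   \item gain scale `alpha = 1 - gamma * (1 + cos(2 theta))`: positive
#'     `gamma` suppresses channels near the remembered orientation (down to
#'     `1 - 2 gamma` at `theta = 0`, inverting their sign for
#'     `gamma > 0.5`) and leaves distant channels untouched.
#'   \item width exponent `beta`. The `"consistent"` variant,
#'     `beta = e0 * exp(-mu * (1 - 2 cos(2 theta)))`, equals the base
#'     tuning exponent `e0` when `mu = 0` and, for `mu > 0`, widens
#'     (lowers the exponent of) channels far from the remembered
#'     orientation. The `"printed"` variant multiplies an extra factor
#'     `e^1` into the exponent and is provided verbatim for comparison.
#'   \item center shift `delta = omega * d / (1 + exp(-a (d - b)))` degrees
#'     toward the remembered orientation, a sigmoidal function of the
#'     distance `d` with slope `a = -0.1` and midpoint `b = 20`.
#' }
#'
#' @param params a `modulation_params`.
#' @param theta distance(s) of channel center(s) to the remembered
#'   orientation, degrees on the 180-periodic circle.
#' @param base_exponent tuning exponent of the unmodulated channels.
#' @param width_variant `"consistent"` (default) or `"printed"`.
#' @return list with numeric vectors `alpha`, `beta`, `delta`.
#' @export
compute_modulations <- function(params, theta, base_exponent = 8,
                                width_variant = c("consistent", "printed")) {
  width_variant <- match.arg(width_variant)
  theta <- circ_dist180(theta, 0)
  c2 <- cospi(2 * theta / 180)
  alpha <- 1 - params$gamma * (1 + c2)
  wexp <- -params$mu * (1 - 2 * c2)
  if (width_variant == "printed") wexp <- 1 + wexp
  beta <- base_exponent * exp(wexp)
  delta <- params$omega * theta / (1 + exp(-params$a * (theta - params$b)))
  list(alpha = alpha, beta = beta, delta = delta)
}

#' Apply state modulations to a channel basis
#'
#' Produces the "biased" test basis for a given remembered orientation:
#' each channel's center is shifted toward the remembered orientation by
#' `delta`, its tuning curve raised to the `beta` power instead of the base
#' exponent, and the whole curve scaled by `alpha`. With
#' `gamma = mu = omega = 0` the result is identical to the unmodulated
#' basis matrix.
#'
#' @param basis a `channel_basis` (the simulator's tuning channels).
#' @param params a `modulation_params`.
#' @param theta_sample remembered orientation in degrees.
#' @param width_variant see [compute_modulations()].
#' @return `n_points x k` modulated channel matrix.
#' @export
modulate_basis <- function(basis, params, theta_sample,
                           width_variant = c("consistent", "printed")) {
  width_variant <- match.arg(width_variant)
  d_signed <- circ_diff180(theta_sample, basis$centers)
  mod <- compute_modulations(params, abs(d_signed),
    base_exponent = basis$exponent, width_variant = width_variant
  )
  centers <- (basis$centers + sign(d_signed) * mod$delta) %% 180
  n <- length(basis$grid)
  dmat <- circ_dist180(
    matrix(basis$grid, n, basis$k),
    matrix(centers, n, basis$k, byrow = TRUE)
  )
  base <- cospi(dmat / 180)
  M <- base^matrix(mod$beta, n, basis$k, byrow = TRUE)
  sweep(M, 2, mod$alpha, `*`)
}
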