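#' Exponential memory friction kernel
#'
#' Specifies a (multi-)exponential friction memory kernel
#' \deqn{\Gamma(t) = \sum_{i=1}^N (\gamma_i/\tau_i)\, e^{-|t|/\tau_i},}
#' where \eqn{\gamma_i} is the friction weight of component `i` (so that
#' \eqn{\int_0^\infty \Gamma(t)\,dt = \sum_i \gamma_i = \gamma}) and
#' \eqn{\tau_i} its memory time.  Components are stored sorted by
#' \eqn{\tau_i} for deterministic serialisation.
#'
#' @param gamma Friction weights, one per component (> 0).
#' @param tau Memory times, one per component (> 0); recycled against
#'   `gamma` if scalar.
#' @return An object of class `memory_kernel`.
#' @examples
#' k <- memory_kernel(gamma = c(1, 2), tau = c(0.1, 1))
#' kernel_value(k, 0)        # Gamma(0) = sum gamma_i / tau_i
#' @export
memory_kernel <- function(gamma, tau) {
  .check_finite_vec(gamma, "gamma")
  .check_finite_vec(tau, "tau")
  n <- max(length(gamma), length(tau))
  gamma <- rep_len(gamma, n)
  tau <- rep_len(tau, n)
  if (any(gamma <= 0) || any(tau <= 0)) {
    abort("All kernel components need gamma_i > 0 and tau_i > 0.",
          class = "memfpt_error_domain")
  }
  ord <- order(tau, gamma)
  structure(
    list(components = tibble(gamma = gamma[ord], tau = tau[ord]),
         gamma = sum(gamma)),
    class = "memory_kernel"
  )
}

#' @export
print.memory_kernel <- function(x, ...) {
  n <- nrow(x$components)
  cat(sprintf("Exponential memory kernel, %d component%s, total gamma = %g\n",
              n, if (n > 1) "s" else "", x$gamma))
  print(x$components)
  invisible(x)
}

#' Non-equilibrium exponential friction / noise pair
#'
#' Specifies the non-equilibrium generalisation in which the friction kernel
#' and the random-force autocorrelation are both single exponentials with the
#' same integrated friction \eqn{\gamma} but different decay times:
#' \deqn{\Gamma_V(t) = (\gamma/\tau_V) e^{-|t|/\tau_V}, \qquad
#'       \Gamma_R(t) = (\gamma/\tau_R) e^{-|t|/\tau_R}.}
#' Equilibrium (the fluctuation-dissipation relation) is recovered for
#' `tau_R == tau_V`; any mismatch makes the stationary state non-Boltzmann.
#'
#' @param gamma Total friction (> 0).
#' @param tau_V Friction-kernel decay time (> 0).
#' @param tau_R Random-force autocorrelation decay time (> 0).
#' @return An object of class `neq_kernel`.
#' @export
neq_kernel <- function(gamma, tau_V, tau_R) {
  .check_scalar(gamma, "gamma")
  .check_scalar(tau_V, "tau_V")
  .check_scalar(tau_R, "tau_R")
  structure(list(gamma = gamma, tau_V = tau_V, tau_R = tau_R),
            class = "neq_kernel")
}

#' @export
print.neq_kernel <- function(x, ...) {
  cat(sprintf(
    "Non-equilibrium kernel pair: gamma = %g, tau_V = %g, tau_R = %g (tau_R/tau_V = %g)\n",
    x$gamma, x$tau_V, x$tau_R, x$tau_R / x$tau_V))
  invisible(x)
}

#' Evaluate a friction kernel
#'
#' Returns \eqn{\Gamma(t)} (friction per unit time), an even function of `t`.
#' For a non-equilibrium pair, `which` selects the friction kernel
#' \eqn{\Gamma_V} or the noise autocorrelation kernel \eqn{\Gamma_R}.
#'
#' @param kernel A `memory_kernel` or `neq_kernel`.
#' @param t Time lags (numeric vector).
#' @param ... Method arguments, e.g. `which` for `neq_kernel`.
#' @return Numeric vector of kernel values.
#' @export
kernel_value <- function(kernel, t, ...) {
  UseMethod("kernel_value")
}

#' @export
kernel_value.memory_kernel <- function(kernel, t, ...) {
  .check_finite_vec(t, "t")
  comp <- kernel$components
  vapply(t, function(ti) sum(comp$gamma / comp$tau * exp(-abs(ti) / comp$tau)),
         numeric(1))
}

#' @rdname kernel_value
#' @param which For `neq_kernel`: `"friction"` (\eqn{\Gamma_V}) or
#'   `"noise"` (\eqn{\Gamma_R}).
#' @export
kernel_value.neq_kernel <- function(kernel, t,
                                    which = c("friction", "noise"), ...) {
  .check_finite_vec(t, "t")
  which <- match.arg(which)
  tau <- if (which == "friction") kernel$tau_V else kernel$tau_R
  kernel$gamma / tau * exp(-abs(t) / tau)
}

#' Characteristic timescales
#'
#' `inertial_time()` returns \eqn{\tau_m = m/\gamma}; `diffusion_time()`
#' returns \eqn{\tau_D = \beta L_L^2 \gamma}, with the left-well width
#' \eqn{L_L} as the characteristic length.  These non-dimensionalise the mass
#' and the memory time: simulations and sweeps are parameterised by
#' \eqn{\tau_m/\tau_D} and \eqn{\tau/\tau_D}.
#'
#' @param mass Reaction-coordinate mass (>= 0).
#' @param gamma Total friction (> 0).
#' @param beta Inverse thermal energy (> 0).
#' @param L_L Left-well width (> 0).
#' @return A single time.
#' @export
inertial_time <- function(mass, gamma) {
  .check_scalar(mass, "mass", zero_ok = TRUE)
  .check_scalar(gamma, "gamma")
  mass / gamma
}

#' @rdname inertial_time
#' @export
diffusion_time <- function(beta, L_L, gamma) {
  .check_scalar(beta, "beta")
  .check_scalar(L_L, "L_L")
  .check_scalar(gamma, "gamma")
  beta * L_L^2 * gamma
}
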