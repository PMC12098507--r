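#' Closed-form mean first-passage-time predictions
#'
#' Crossover formulas for barrier-crossing MFPTs of a reaction coordinate
#' with mass `mass`, single-exponential memory friction (total friction
#' `gamma`, memory time `tau`) in a quartic double well with barrier height
#' `U0` (or side-specific `U`) and well-minimum curvature
#' \eqn{K = 8U/L^2}.  Each prediction is the sum of three exposed terms:
#' an inertial (energy-diffusion) term \eqn{\propto m/\gamma + 2K\tau^2/
#' (3\gamma)}, an overdamped term \eqn{\propto \gamma/K} with the
#' memory-induced speed-up denominator \eqn{1 + K\beta U\tau/(4\gamma)}, and
#' a heuristic crossover term \eqn{4\sqrt{2m/K}} for the turnover regime.
#'
#' `mfpt_well_to_well()` is the symmetric well-to-well formula (overdamped
#' prefactor \eqn{2\sqrt{2}\pi\gamma/K}); `mfpt_well_to_top()` is the
#' well-to-barrier-top formula, whose overdamped prefactor is exactly half
#' (\eqn{\sqrt{2}\pi\gamma/K}) and which depends only on the chosen well's
#' parameters — the two wells decouple.  Unlike the simulator, `mass = 0`
#' and `tau = 0` are accepted: the limits are finite.
#'
#' @param U0,U Barrier height (energy; \eqn{\beta U} is the dimensionless
#'   barrier).
#' @param K Curvature at the well minimum (energy / length^2), see
#'   [curvature_at_minimum()].
#' @param gamma Total friction (> 0).
#' @param tau Memory time (>= 0).
#' @param mass Mass (>= 0).
#' @param beta Inverse thermal energy (> 0).
#' @return An object of class `mfpt_prediction` with fields `total`,
#'   `inertial`, `overdamped`, `crossover` (terms sum to `total`).
#' @examples
#' # overdamped Markovian limit: e^{beta U0} * 2 sqrt(2) pi gamma / K
#' mfpt_well_to_well(U0 = 5, K = 40)$total
#' @export
mfpt_well_to_well <- function(U0, K, gamma = 1, tau = 0, mass = 0, beta = 1) {
  .theory_core(U0, K, gamma, tau, mass, beta, od_prefactor = d2_const)
}

#' @rdname mfpt_well_to_well
#' @export
mfpt_well_to_top <- function(U, K, gamma = 1, tau = 0, mass = 0, beta = 1) {
  .theory_core(U, K, gamma, tau, mass, beta, od_prefactor = d2_const / 2)
}

# shared three-term evaluator; od_prefactor = 2*sqrt(2)*pi (well-to-well)
# or sqrt(2)*pi (well-to-top)
.theory_core <- function(U, K, gamma, tau, mass, beta, od_prefactor) {
  .check_scalar(U, "U")
  .check_scalar(K, "K")
  .check_scalar(gamma, "gamma")
  .check_scalar(tau, "tau", zero_ok = TRUE)
  .check_scalar(mass, "mass", zero_ok = TRUE)
  .check_scalar(beta, "beta")
  bU <- beta * U
  boltz <- exp(bU)
  inertial <- boltz * (1 / bU) * d1_const *
    (mass / gamma + 2 * K * tau^2 / (3 * gamma))
  overdamped <- boltz * (od_prefactor * gamma / K) /
    (1 + K * bU * tau / (4 * gamma))
  crossover <- boltz * 4 * sqrt(2 * mass / K)
  structure(
    list(total = inertial + overdamped + crossover, inertial = inertial,
         overdamped = overdamped, crossover = crossover,
         params = list(U = U, K = K, gamma = gamma, tau = tau, mass = mass,
                       beta = beta)),
    class = "mfpt_prediction"
  )
}

#' @export
print.mfpt_prediction <- function(x, ...) {
  cat(sprintf(
    "MFPT prediction: total = %.6g\n  inertial = %.4g  overdamped = %.4g  crossover = %.4g\n",
    x$total, x$inertial, x$overdamped, x$crossover))
  invisible(x)
}

#' Per-component contributions for multi-exponential memory
#'
#' Decomposition of the well-to-top formula used to handle multi-exponential
#' kernels: for each kernel component \eqn{(\gamma_i, \tau_i)},
#' `od_contribution()` is the overdamped part
#' \deqn{\tau_{OD_i} = e^{\beta U}\left[\frac{\sqrt{2}\pi\gamma_i/K}
#'   {1 + \beta U K \tau_i/(4\gamma_i)} + 2\sqrt{2m/K}\right]}
#' and `ed_contribution()` the energy-diffusion part
#' \deqn{\tau_{ED_i} = e^{\beta U}\left[\frac{1}{\beta U}\frac{3\pi}
#'   {8\sqrt{2}}\left(\frac{m}{\gamma_i} + \frac{2K\tau_i^2}{3\gamma_i}
#'   \right) + 2\sqrt{2m/K}\right].}
#'
#' @inheritParams mfpt_well_to_well
#' @param gamma_i,tau_i Friction weight and memory time of the component.
#' @return A single time.
#' @export
od_contribution <- function(U, K, gamma_i, tau_i, mass = 0, beta = 1) {
  .check_scalar(U, "U")
  .check_scalar(K, "K")
  .check_scalar(gamma_i, "gamma_i")
  .check_scalar(tau_i, "tau_i", zero_ok = TRUE)
  bU <- beta * U
  exp(bU) * ((d2_const / 2) * gamma_i / K / (1 + bU * K * tau_i /
                                               (4 * gamma_i)) +
               2 * sqrt(2 * mass / K))
}

#' @rdname od_contribution
#' @export
ed_contribution <- function(U, K, gamma_i, tau_i, mass = 0, beta = 1) {
  .check_scalar(U, "U")
  .check_scalar(K, "K")
  .check_scalar(gamma_i, "gamma_i")
  .check_scalar(tau_i, "tau_i", zero_ok = TRUE)
  bU <- beta * U
  exp(bU) * ((1 / bU) * d1_const * (mass / gamma_i +
                                      2 * K * tau_i^2 / (3 * gamma_i)) +
               2 * sqrt(2 * mass / K))
}

#' Well-to-top MFPT for a multi-exponential kernel
#'
#' Combination rule for `N` kernel components: the overdamped contributions
#' add in series while the energy-diffusion contributions add as parallel
#' rates,
#' \deqn{\tau_{MFP} = \sum_i \tau_{OD_i} +
#'   \left(\sum_i 1/\tau_{ED_i}\right)^{-1}.}
#' For `N = 1` this reduces algebraically to the single-exponential
#' well-to-top formula, and the reduction is evaluated through the same code
#' path so the equality is exact in floating point.
#'
#' @inheritParams mfpt_well_to_well
#' @param kernel A [memory_kernel()] supplying the components
#'   \eqn{(\gamma_i, \tau_i)}.
#' @return A list of class `mfpt_prediction_multi` with `total`, the
#'   per-component `contributions` tibble, and the two combined addends
#'   `od_total` and `ed_total`.
#' @export
multi_exponential_mfpt <- function(U, K, kernel, mass = 0, beta = 1) {
  stopifnot(inherits(kernel, "memory_kernel"))
  comp <- kernel$components
  od <- vapply(seq_len(nrow(comp)), function(i) {
    od_contribution(U, K, comp$gamma[i], comp$tau[i], mass, beta)
  }, numeric(1))
  ed <- vapply(seq_len(nrow(comp)), function(i) {
    ed_contribution(U, K, comp$gamma[i], comp$tau[i], mass, beta)
  }, numeric(1))
  total <- if (nrow(comp) == 1L) {
    # N = 1: the combination rule reduces to tau_OD1 + tau_ED1 exactly;
    # evaluating it this way avoids the double rounding of 1/(1/x) and makes
    # the documented reduction to the single-exponential formula bit-exact
    mfpt_well_to_top(U, K, comp$gamma[1], comp$tau[1], mass, beta)$total
  } else {
    sum(od) + 1 / sum(1 / ed)
  }
  structure(
    list(total = total,
         od_total = sum(od), ed_total = 1 / sum(1 / ed),
         contributions = tibble(gamma = comp$gamma, tau = comp$tau,
                                od = od, ed = ed)),
    class = "mfpt_prediction_multi"
  )
}

#' @export
print.mfpt_prediction_multi <- function(x, ...) {
  cat(sprintf("Multi-exponential MFPT prediction: total = %.6g\n", x$total))
  print(x$contributions)
  invisible(x)
}

#' Non-equilibrium effective inverse temperature
#'
#' For the exponential non-equilibrium kernel pair, the stationary state is
#' governed by the effective inverse temperature
#' \eqn{\beta_{NEQ} = \beta\,\tau_R^2/\tau_V^2}: a random force that decays
#' more slowly than the friction kernel (\eqn{\tau_R > \tau_V}) acts as a
#' colder effective bath (slower barrier crossing), and vice versa.
#'
#' @inheritParams mfpt_well_to_well
#' @param tau_R,tau_V Random-force and friction-kernel decay times (> 0).
#' @return The effective inverse temperature.
#' @export
neq_effective_beta <- function(beta, tau_R, tau_V) {
  .check_scalar(beta, "beta")
  .check_scalar(tau_R, "tau_R")
  .check_scalar(tau_V, "tau_V")
  # written as beta * (tau_R/tau_V)^2 so tau_R == tau_V gives beta exactly
  beta * (tau_R / tau_V)^2
}

#' Non-equilibrium well-to-top MFPT
#'
#' The harmonic-approximation prediction for the non-equilibrium kernel
#' pair: the equilibrium well-to-top formula with \eqn{\beta \to \beta_{NEQ}
#' = \beta\tau_R^2/\tau_V^2} everywhere \eqn{\beta} appears and
#' \eqn{\tau \to \tau_V}; the mass and crossover terms are unchanged.  At
#' `tau_R == tau_V` it coincides exactly with [mfpt_well_to_top()].
#'
#' @inheritParams mfpt_well_to_well
#' @param tau_V,tau_R Friction and random-force decay times (> 0).
#' @return An `mfpt_prediction`.
#' @export
neq_mfpt_well_to_top <- function(U, K, gamma = 1, tau_V, tau_R, mass = 0,
                                 beta = 1) {
  b_neq <- neq_effective_beta(beta, tau_R, tau_V)
  out <- mfpt_well_to_top(U, K, gamma, tau_V, mass, b_neq)
  out$params$beta <- beta
  out$params$beta_neq <- b_neq
  out$params$tau_V <- tau_V
  out$params$tau_R <- tau_R
  out
}

#' Theory prediction from a potential
#'
#' Convenience dispatcher: evaluates the appropriate closed form for a
#' [double_well()] and kernel — the well-to-top formula for a side with a
#' single-exponential [memory_kernel()], the multi-exponential combination
#' rule for `N > 1` components, the non-equilibrium formula for a
#' [neq_kernel()], or the symmetric well-to-well formula for
#' `side = "well"` (symmetric potentials only).
#'
#' @param potential A [double_well()].
#' @param side `"left"`, `"right"`, or `"well"` (well-to-well, symmetric).
#' @param kernel A [memory_kernel()] or [neq_kernel()].
#' @param mass,beta Mass and inverse thermal energy.
#' @return An `mfpt_prediction` (or `mfpt_prediction_multi`).
#' @export
predict_mfpt <- function(potential, side = c("left", "right", "well"),
                         kernel, mass = 0, beta = 1) {
  stopifnot(inherits(potential, "double_well"))
  side <- match.arg(side)
  if (side == "well") {
    sym <- isTRUE(all.equal(potential$U_L, potential$U_R)) &&
      isTRUE(all.equal(potential$L_L, potential$L_R))
    if (!sym) {
      abort("Well-to-well prediction requires a symmetric double well.",
            class = "memfpt_error_domain")
    }
    if (inherits(kernel, "neq_kernel") ||
        nrow(kernel$components) != 1L) {
      abort(paste0("Well-to-well prediction is available for ",
                   "single-exponential equilibrium kernels only."),
            class = "memfpt_error_domain")
    }
    return(mfpt_well_to_well(potential$U_L,
                             curvature_at_minimum(potential, "left"),
                             kernel$gamma, kernel$components$tau[1], mass,
                             beta))
  }
  U <- if (side == "left") potential$U_L else potential$U_R
  K <- curvature_at_minimum(potential, side)
  if (inherits(kernel, "neq_kernel")) {
    neq_mfpt_well_to_top(U, K, kernel$gamma, kernel$tau_V, kernel$tau_R,
                         mass, beta)
  } else if (nrow(kernel$components) == 1L) {
    mfpt_well_to_top(U, K, kernel$gamma, kernel$components$tau[1], mass, beta)
  } else {
    multi_exponential_mfpt(U, K, kernel, mass, beta)
  }
}

#' Exact overdamped Markovian MFPT by double quadrature
#'
#' Independent oracle for the overdamped Markovian limit: the classical
#' double integral
#' \deqn{\tau = \beta\gamma\int_{x_0}^{x_1} dy\, e^{\beta U(y)}
#'   \int_{-\infty}^{y} dz\, e^{-\beta U(z)},}
#' evaluated by adaptive quadrature.  The infinite lower limit is truncated
#' where the Boltzmann weight falls below \eqn{10^{-12}} of its maximum (or
#' replaced by a reflecting boundary via `lower`).  This routine shares no
#' code with the closed-form predictions and serves as their asymptotic
#' cross-check.
#'
#' @param potential A [double_well()], [harmonic_well()], or a plain
#'   function `U(x)`.
#' @param start,target Integration limits (`start < target`).
#' @param beta,gamma Inverse thermal energy and friction.
#' @param lower Lower limit of the inner integral: `-Inf` (default,
#'   truncated automatically) or a finite reflecting boundary.
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @return A single time.
#' @export
mfpt_quadrature <- function(potential, start, target, beta = 1, gamma = 1,
                            lower = -Inf, rel_tol = 1e-9) {
  .check_scalar(start, "start", positive = FALSE)
  .check_scalar(target, "target", positive = FALSE)
  .check_scalar(beta, "beta")
  .check_scalar(gamma, "gamma")
  if (start >= target) {
    abort("`start` must be below `target`.", class = "memfpt_error_domain")
  }
  Ufun <- if (is.function(potential)) {
    potential
  } else {
    function(x) potential_energy(potential, x)
  }
  z_lo <- if (is.finite(lower)) {
    lower
  } else {
    .truncation_point(Ufun, beta, start)
  }
  inner <- function(y) {
    integrate(function(z) exp(-beta * Ufun(z)), z_lo, y,
              rel.tol = rel_tol, stop.on.error = TRUE)$value
  }
  outer <- integrate(
    function(ys) vapply(ys, function(y) exp(beta * Ufun(y)) * inner(y),
                        numeric(1)),
    start, target, rel.tol = rel_tol, stop.on.error = FALSE)
  if (!identical(outer$message, "OK")) {
    abort(sprintf("Quadrature did not converge: %s", outer$message),
          class = "memfpt_error_quadrature")
  }
  beta * gamma * outer$value
}

# internal: point below `start` where the Boltzmann weight is 1e-12 of its
# maximum, found by doubling then bisection on beta*(U - U_min) = log(1e12)
.truncation_point <- function(Ufun, beta, start) {
  span <- 1
  u_min <- min(vapply(seq(start - 5, start + 5, length.out = 201), Ufun,
                      numeric(1)))
  thresh <- log(1e12) / beta + u_min
  lo <- start
  while (Ufun(lo) < thresh && span < 1e6) {
    lo <- lo - span
    span <- span * 2
  }
  if (Ufun(lo) < thresh) {
    abort("Could not truncate the inner integral: potential grows too slowly.",
          class = "memfpt_error_quadrature")
  }
  uniroot(function(x) Ufun(x) - thresh, c(lo, start))$root
}
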