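#' Simulation configuration
#'
#' Integrator settings for [simulate_gle()].  Massless configurations are
#' rejected: the simulator always propagates finite inertia, the
#' \eqn{m \to 0} limit lives in the theory module only.
#'
#' @param mass Reaction-coordinate mass (> 0).
#' @param beta Inverse thermal energy (> 0), default 1 (energies in
#'   \eqn{k_BT}).
#' @param n_steps Number of integration steps (after `burn_in`, positions are
#'   recorded every `sampling_stride` steps).
#' @param dt Time step.  `NULL` (default) picks
#'   `0.01 * min(tau_m, min(tau_i), sqrt(mass / K_max), tau_D)` at simulation
#'   time, see [gle_timestep()].  An explicit `dt` must satisfy the stability
#'   contract `dt <= 0.1 * min(tau_m, min(tau_i), sqrt(mass / K_max))`.
#' @param burn_in Discarded initial steps.  `NULL` (default) discards
#'   `10 * tau_D` worth of steps so the reported series starts from a
#'   stationary state.
#' @param seed Integer RNG seed; the compiled integrator uses a counter-based
#'   generator derived from it, so identical configurations replay exactly.
#' @param initial_position `"left-minimum"`, `"right-minimum"`, or a numeric
#'   starting position.
#' @param sampling_stride Output decimation factor for stored positions.
#'   First-passage statistics requested through the `passages` argument of
#'   [simulate_gle()] are always accumulated at full step resolution.
#' @param record_velocity Store the velocity series as well?
#' @param noise Logical; `FALSE` switches the random force off (deterministic
#'   dynamics, used for energy-conservation diagnostics only).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mass, beta = 1, n_steps, dt = NULL, burn_in = NULL,
                       seed = 1L, initial_position = "left-minimum",
                       sampling_stride = 1L, record_velocity = FALSE,
                       noise = TRUE) {
  .check_scalar(mass, "mass")
  .check_scalar(beta, "beta")
  .check_scalar(n_steps, "n_steps")
  if (!is.null(dt)) .check_scalar(dt, "dt")
  if (!is.null(burn_in)) .check_scalar(burn_in, "burn_in", zero_ok = TRUE)
  .check_scalar(sampling_stride, "sampling_stride")
  if (is.numeric(initial_position)) {
    .check_scalar(initial_position, "initial_position", positive = FALSE)
  } else if (!initial_position %in% c("left-minimum", "right-minimum")) {
    abort(paste0("`initial_position` must be numeric, \"left-minimum\" ",
                 "or \"right-minimum\"."),
          class = "memfpt_error_domain")
  }
  structure(
    list(mass = mass, beta = beta, n_steps = n_steps, dt = dt,
         burn_in = burn_in, seed = as.integer(seed),
         initial_position = initial_position,
         sampling_stride = as.integer(sampling_stride),
         record_velocity = isTRUE(record_velocity), noise = isTRUE(noise)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "GLE simulation config: mass = %g, beta = %g, n_steps = %g, dt = %s,\n",
    x$mass, x$beta, x$n_steps, if (is.null(x$dt)) "auto" else format(x$dt)))
  cat(sprintf("  burn_in = %s, stride = %d, seed = %d, start = %s\n",
              if (is.null(x$burn_in)) "auto (10 tau_D)" else
                format(x$burn_in),
              x$sampling_stride, x$seed,
              paste(format(x$initial_position), collapse = "")))
  invisible(x)
}

# internal: characteristic scales relevant for timestep selection
.time_scales <- function(potential, kernel, mass, beta) {
  gamma <- if (inherits(kernel, "neq_kernel")) kernel$gamma else kernel$gamma
  taus <- if (inherits(kernel, "neq_kernel")) {
    c(kernel$tau_V, kernel$tau_R)
  } else {
    kernel$components$tau
  }
  K_max <- if (inherits(potential, "double_well")) {
    max(curvature_at_minimum(potential, "left"),
        curvature_at_minimum(potential, "right"))
  } else if (inherits(potential, "harmonic_well")) {
    potential$K
  } else {
    NA_real_
  }
  tau_D <- if (inherits(potential, "double_well")) {
    diffusion_time(beta, potential$L_L, gamma)
  } else {
    beta * gamma  # unit length scale for harmonic / free runs
  }
  list(tau_m = mass / gamma, taus = taus, K_max = K_max, tau_D = tau_D,
       gamma = gamma)
}

#' Default integration timestep
#'
#' Returns `0.01 * min(tau_m, min(tau_i), sqrt(mass / K_max), tau_D)`, the
#' conservative default used when `sim_config(dt = NULL)`.  A coarser
#' explicit `dt` may be supplied up to the stability bound
#' `0.1 * min(tau_m, min(tau_i), sqrt(mass / K_max))`; a convergence check
#' (halving `dt` must move MFPTs by less than one standard error) is the
#' recommended validation for coarse custom steps.
#'
#' @inheritParams simulate_gle
#' @param mass,beta Mass and inverse thermal energy.
#' @export
gle_timestep <- function(potential, kernel, mass, beta = 1) {
  sc <- .time_scales(potential, kernel, mass, beta)
  cand <- c(sc$tau_m, sc$taus, if (is.finite(sc$K_max)) sqrt(mass / sc$K_max),
            sc$tau_D)
  0.01 * min(cand)
}

# internal: enforce the stability contract, naming the violated ratio
.check_stability <- function(dt, potential, kernel, mass, beta) {
  sc <- .time_scales(potential, kernel, mass, beta)
  lims <- c(tau_m = sc$tau_m, tau_min = min(sc$taus))
  if (is.finite(sc$K_max)) lims <- c(lims, osc = sqrt(mass / sc$K_max))
  bad <- lims[dt > 0.1 * lims]
  if (length(bad)) {
    abort(sprintf(
      paste0("dt = %g violates the stability contract dt <= 0.1 * %s = %g ",
             "(ratio dt/%s = %.3g)."),
      dt, names(bad)[1], 0.1 * bad[1], names(bad)[1], dt / bad[1]),
      class = "memfpt_error_stability")
  }
  invisible(TRUE)
}
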