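#' Draw a stationary initial state
#'
#' Samples the initial condition used by [simulate_gle()]: the position set
#' by the configuration, the velocity from the Maxwell distribution at
#' temperature \eqn{1/\beta}, and each auxiliary kernel variable from its
#' stationary Gaussian law (variance \eqn{\gamma_i/(\beta\tau_i)}).  Starting
#' the auxiliary/noise variables in their stationary laws removes the startup
#' transient of the memory integral's lower limit; the burn-in discards the
#' remainder.  Draws use R's RNG seeded from `config$seed`, so repeated calls
#' are bit-identical.
#'
#' @inheritParams simulate_gle
#' @param n Number of draws.
#' @return A tibble with columns `position`, `velocity` and one `z_i` column
#'   per auxiliary variable (`z_V` and `eta` for a non-equilibrium kernel).
#' @export
draw_initial_state <- function(potential, kernel, config, n = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  x0 <- if (is.numeric(config$initial_position)) {
    config$initial_position
  } else if (identical(config$initial_position, "right-minimum")) {
    if (!inherits(potential, "double_well")) 0 else potential$L_R
  } else {
    if (!inherits(potential, "double_well")) 0 else -potential$L_L
  }
  v <- rnorm(n, 0, sqrt(1 / (config$beta * config$mass)))
  out <- tibble(position = rep(x0, n), velocity = v)
  if (inherits(kernel, "neq_kernel")) {
    out$z_V <- rnorm(n, 0, sqrt(kernel$gamma / (config$beta * kernel$tau_V)))
    out$eta <- if (config$noise) {
      rnorm(n, 0, sqrt(kernel$gamma / (config$beta * kernel$tau_R)))
    } else {
      rep(0, n)
    }
  } else {
    comp <- kernel$components
    for (i in seq_len(nrow(comp))) {
      out[[paste0("z_", i)]] <- if (config$noise) {
        rnorm(n, 0, sqrt(comp$gamma[i] / (config$beta * comp$tau[i])))
      } else {
        rep(0, n)
      }
    }
  }
  out
}

# internal: derive a 64-bit-ish sub-seed for chunk j of a run (kept within
# double-exact integer range; distinct across seeds and chunks)
.sub_seed <- function(seed, chunk) {
  (as.numeric(seed) %% 2^31) * 2^20 + 1000003 * (chunk %% 1024) + 17
}

# internal: resolve dt/burn_in defaults and validate sizes
.resolve_config <- function(potential, kernel, config) {
  dt <- config$dt %||% gle_timestep(potential, kernel, config$mass,
                                    config$beta)
  .check_stability(dt, potential, kernel, config$mass, config$beta)
  sc <- .time_scales(potential, kernel, config$mass, config$beta)
  burn_in <- config$burn_in %||% ceiling(10 * sc$tau_D / dt)
  if (config$n_steps <= burn_in) {
    abort(sprintf("n_steps (%g) must exceed burn_in (%g).",
                  config$n_steps, burn_in),
          class = "memfpt_error_domain")
  }
  n_rec <- floor((config$n_steps - burn_in) / config$sampling_stride)
  if (n_rec > 5e7) {
    abort(sprintf(
      "Run would store %g samples; increase `sampling_stride`.", n_rec),
      class = "memfpt_error_domain")
  }
  list(dt = dt, burn_in = burn_in, n_rec = n_rec)
}

#' Simulate the generalized Langevin equation
#'
#' Integrates the GLE
#' \deqn{m\ddot x(t) = -\int_0^t \Gamma(t-t')\,\dot x(t')\,dt' - U'(x(t))
#'   + F_R(t)}
#' for a reaction coordinate in the supplied potential.  With a
#' [memory_kernel()], the random force obeys the fluctuation-dissipation
#' relation \eqn{\langle F_R(t)F_R(t')\rangle = \Gamma(t-t')/\beta}
#' component-wise, and the long-run statistics are Boltzmann.  With a
#' [neq_kernel()], friction decays with `tau_V` while the random force is an
#' independent stationary colored noise with decay `tau_R` and amplitude
#' \eqn{\gamma/(\beta\tau_R)}; for `tau_R != tau_V` the stationary state is
#' non-Boltzmann, and `tau_R == tau_V` recovers the equilibrium statistics.
#'
#' Each exponential component is realised exactly as a coupled auxiliary
#' Ornstein-Uhlenbeck process inside a velocity-Verlet splitting, so the
#' timestep is set by the potential and inertial scales, not by the smallest
#' memory time.
#'
#' @param potential A [double_well()], [harmonic_well()], or `NULL` for a
#'   free particle.
#' @param kernel A [memory_kernel()] (equilibrium) or [neq_kernel()]
#'   (non-equilibrium).
#' @param config A [sim_config()].
#' @param passages Optional two-column data frame / matrix of
#'   `(start, target)` level pairs.  For each pair, all-to-first-passage
#'   statistics are accumulated online at full step resolution (independent
#'   of `sampling_stride`) and attached to the result; retrieve them with
#'   [passage_groups()] or feed the trajectory to [mfpt_estimate()] via
#'   [all_to_first_passage()].
#' @return A tibble of class `gle_trajectory` with columns `time`,
#'   `position` (and `velocity` if requested), uniform spacing
#'   `dt * sampling_stride`, and metadata attributes (`dt`, `config`,
#'   `potential`, `kernel`, `passages`, `final_state`).
#' @examples
#' p <- double_well(U_L = 2, L_L = 1)
#' k <- memory_kernel(gamma = 1, tau = 0.05)
#' cfg <- sim_config(mass = 0.01, n_steps = 2e5, seed = 42)
#' traj <- simulate_gle(p, k, cfg)
#' @export
simulate_gle <- function(potential, kernel, config, passages = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(kernel, "memory_kernel") && !inherits(kernel, "neq_kernel")) {
    abort("`kernel` must be a `memory_kernel` or `neq_kernel`.",
          class = "memfpt_error_domain")
  }
  rc <- .resolve_config(potential, kernel, config)
  pot <- .pot_code(potential)
  init <- draw_initial_state(potential, kernel, config, n = 1)
  neq <- inherits(kernel, "neq_kernel")
  gammas <- if (neq) kernel$gamma else kernel$components$gamma
  taus <- if (neq) kernel$tau_V else kernel$components$tau
  z0 <- as.numeric(init[1, -(1:2)])
  if (neq) {
    eta0 <- init$eta[1]
    z0 <- init$z_V[1]
  } else {
    eta0 <- 0
  }
  pair_mat <- .as_pair_matrix(passages)

  res <- gle_simulate_cpp(
    pot$type, pot$par, config$mass, config$beta, rc$dt, config$n_steps,
    rc$burn_in, config$sampling_stride, init$position[1], init$velocity[1],
    z0, eta0, gammas, taus, neq, if (neq) kernel$tau_V else 0,
    if (neq) kernel$tau_R else 0, pair_mat, config$record_velocity,
    config$noise, .sub_seed(config$seed, 0), 0,
    numeric(0), numeric(0))

  .new_trajectory(res, rc, config, potential, kernel)
}

# internal: normalise the `passages` argument into a 2-column matrix
.as_pair_matrix <- function(passages) {
  if (is.null(passages)) return(matrix(numeric(0), ncol = 2))
  m <- as.matrix(as.data.frame(passages)[, 1:2])
  storage.mode(m) <- "double"
  if (any(m[, 1] == m[, 2])) {
    abort("Passage start and target levels must differ.",
          class = "memfpt_error_domain")
  }
  m
}

# internal: assemble the trajectory tibble + metadata from a compiled run
.new_trajectory <- function(res, rc, config, potential, kernel) {
  n_rec <- length(res$positions)
  dt_samp <- rc$dt * config$sampling_stride
  out <- tibble(
    time = (rc$burn_in * rc$dt) + dt_samp * seq_len(n_rec),
    position = res$positions
  )
  if (config$record_velocity) out$velocity <- res$velocities
  pass <- lapply(res$pairs, function(p) {
    tibble(arrival_time = p$arrival_time, n = p$n, sum = p$sum,
           start = p$start, target = p$target)
  })
  structure(
    out,
    class = c("gle_trajectory", class(out)),
    dt = rc$dt,
    dt_sample = dt_samp,
    config = config,
    potential = potential,
    kernel = kernel,
    passages = pass,
    final_state = list(x = res$x, v = res$v, z = res$z, eta = res$eta,
                       t_end = res$t_end)
  )
}

#' Passage statistics attached to a trajectory
#'
#' Returns the list of per-pair all-to-first-passage group tables accumulated
#' online during [simulate_gle()] (one tibble per requested `(start, target)`
#' pair, columns `arrival_time`, `n`, `sum`).
#'
#' @param traj A `gle_trajectory`.
#' @export
passage_groups <- function(traj) {
  attr(traj, "passages")
}

#' Simulate a Markovian Langevin reference trajectory
#'
#' Underdamped Langevin dynamics with memoryless friction `gamma`, integrated
#' with the BAOAB splitting.  This is an independent reference implementation
#' (it shares no propagation code with [simulate_gle()]) used to validate the
#' GLE engine in the Markovian limit \eqn{\tau/\tau_D \to 0}.
#'
#' @inheritParams simulate_gle
#' @param gamma Friction coefficient (> 0).
#' @return A `gle_trajectory` tibble (see [simulate_gle()]).
#' @export
simulate_langevin <- function(potential, gamma, config, passages = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .check_scalar(gamma, "gamma")
  kernel <- memory_kernel(gamma, tau = 1e-12)  # only for scale resolution
  dt <- config$dt %||% {
    sc <- .time_scales(potential, kernel, config$mass, config$beta)
    0.01 * min(sc$tau_m, if (is.finite(sc$K_max)) sqrt(config$mass / sc$K_max),
               sc$tau_D)
  }
  sc <- .time_scales(potential, kernel, config$mass, config$beta)
  burn_in <- config$burn_in %||% ceiling(10 * sc$tau_D / dt)
  if (config$n_steps <= burn_in) {
    abort("n_steps must exceed burn_in.", class = "memfpt_error_domain")
  }
  rc <- list(dt = dt, burn_in = burn_in)
  pot <- .pot_code(potential)
  init <- draw_initial_state(potential, kernel, config, n = 1)
  res <- langevin_simulate_cpp(
    pot$type, pot$par, config$mass, config$beta, gamma, dt, config$n_steps,
    burn_in, config$sampling_stride, init$position[1], init$velocity[1],
    .as_pair_matrix(passages), config$record_velocity,
    .sub_seed(config$seed, 0))
  .new_trajectory(res, rc, config, potential, kernel)
}

#' Generate a stationary colored-noise stream
#'
#' Samples the stationary random force consistent with a kernel: for a
#' [memory_kernel()] the sum of independent Ornstein-Uhlenbeck components
#' with autocorrelation \eqn{\sum_i (\gamma_i/(\beta\tau_i)) e^{-|\Delta
#' t|/\tau_i}}; for a [neq_kernel()] the single component with decay `tau_R`
#' and amplitude \eqn{\gamma/(\beta\tau_R)}.  Used to verify the realized
#' fluctuation-dissipation statistics of the integrator's noise.
#'
#' @inheritParams simulate_gle
#' @param n Number of samples.
#' @param dt Sampling interval.
#' @param beta Inverse thermal energy.
#' @param seed Integer seed.
#' @return A tibble with columns `time` and `force`.
#' @export
simulate_noise <- function(kernel, n, dt, beta = 1, seed = 1L) {
  .check_scalar(n, "n")
  .check_scalar(dt, "dt")
  .check_scalar(beta, "beta")
  if (inherits(kernel, "neq_kernel")) {
    gammas <- kernel$gamma
    taus <- kernel$tau_R
  } else if (inherits(kernel, "memory_kernel")) {
    gammas <- kernel$components$gamma
    taus <- kernel$components$tau
  } else {
    abort("`kernel` must be a `memory_kernel` or `neq_kernel`.",
          class = "memfpt_error_domain")
  }
  f <- noise_stream_cpp(gammas, taus, beta, dt, n, .sub_seed(seed, 0))
  tibble(time = dt * seq_len(n), force = f)
}

# ---------------------------------------------------------------------------
# Chunked passage-statistics runner used by the sweep module: accumulates
# per-pair arrival-group statistics over successive compiled chunks (each
# chunk reseeded from a derived counter seed) until every pair has
# `events_target` arrivals or `max_steps` is exhausted.  Only sufficient
# statistics cross the C++/R boundary, so arbitrarily long effective runs
# stay in O(#arrivals) memory.
# ---------------------------------------------------------------------------
.run_passages <- function(potential, kernel, config, pairs,
                          events_target = 300, max_steps = 2e9,
                          chunk_steps = 2.5e8, min_time = 0) {
  # nothing is stored, so resolve dt/burn-in directly without the
  # trajectory-size guard of .resolve_config()
  dt <- config$dt %||% gle_timestep(potential, kernel, config$mass,
                                    config$beta)
  .check_stability(dt, potential, kernel, config$mass, config$beta)
  sc <- .time_scales(potential, kernel, config$mass, config$beta)
  rc <- list(dt = dt,
             burn_in = config$burn_in %||% ceiling(10 * sc$tau_D / dt))
  pot <- .pot_code(potential)
  neq <- inherits(kernel, "neq_kernel")
  gammas <- if (neq) kernel$gamma else kernel$components$gamma
  taus <- if (neq) kernel$tau_V else kernel$components$tau
  init <- draw_initial_state(potential, kernel, config, n = 1)
  z <- if (neq) init$z_V[1] else as.numeric(init[1, -(1:2)])
  eta <- if (neq) init$eta[1] else 0
  x <- init$position[1]
  v <- init$velocity[1]
  pair_mat <- .as_pair_matrix(pairs)

  acc <- lapply(seq_len(nrow(pair_mat)), function(i) {
    list(n = numeric(0), sum = numeric(0), arrival_time = numeric(0))
  })
  pend_n <- numeric(nrow(pair_mat))
  pend_tsum <- numeric(nrow(pair_mat))
  total_steps <- 0
  t_off <- 0
  chunk <- 0
  first <- TRUE
  repeat {
    n_arr <- vapply(acc, function(a) length(a$n), numeric(1))
    # arrival counts alone can be inflated by correlated recrossing bursts
    # at long memory times, so a run additionally has to cover `min_time`
    # (sized upstream from the predicted means) before it may stop early
    if ((all(n_arr >= events_target) && t_off >= min_time) ||
        total_steps >= max_steps) break
    todo <- min(chunk_steps, max_steps - total_steps,
                config$n_steps - total_steps)
    if (todo <= 0) break
    res <- gle_simulate_cpp(
      pot$type, pot$par, config$mass, config$beta, rc$dt,
      todo + if (first) rc$burn_in else 0,
      if (first) rc$burn_in else 0, todo + rc$burn_in + 1,  # store nothing
      x, v, z, eta, gammas, taus, neq,
      if (neq) kernel$tau_V else 0, if (neq) kernel$tau_R else 0,
      pair_mat, FALSE, config$noise, .sub_seed(config$seed, chunk), t_off,
      pend_n, pend_tsum)
    for (i in seq_along(acc)) {
      p <- res$pairs[[i]]
      acc[[i]]$n <- c(acc[[i]]$n, p$n)
      acc[[i]]$sum <- c(acc[[i]]$sum, p$sum)
      acc[[i]]$arrival_time <- c(acc[[i]]$arrival_time, p$arrival_time)
      pend_n[i] <- p$pending_n      # open passages continue into next chunk
      pend_tsum[i] <- p$pending_tsum
    }
    x <- res$x
    v <- res$v
    z <- res$z
    eta <- res$eta
    t_off <- res$t_end
    total_steps <- total_steps + todo
    chunk <- chunk + 1
    first <- FALSE
    if (total_steps >= config$n_steps) break
  }

  groups <- lapply(seq_along(acc), function(i) {
    tibble(arrival_time = acc[[i]]$arrival_time, n = acc[[i]]$n,
           sum = acc[[i]]$sum, start = pair_mat[i, 1],
           target = pair_mat[i, 2])
  })
  list(groups = groups, total_steps = total_steps, dt = rc$dt,
       total_time = t_off)
}
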