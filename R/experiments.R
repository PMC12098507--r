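#' alpha3D-like free-energy fixture
#'
#' Builds the double-well potential with the published fast-folder profile
#' parameters (unfolded well on the left: barrier height 1.7 k_BT, width
#' 0.15; folded well on the right: 3.2 k_BT, width 0.08, in fraction-of-
#' native-contacts units) and samples it on a grid for fit round-trip tests.
#' This is a synthetic stand-in constructed from the published fit
#' parameters, not molecular-dynamics data.
#'
#' @param n Number of profile points (default 200).
#' @return A list with elements `potential` (a [double_well()]) and
#'   `profile` (a free-energy-profile tibble).
#' @export
alpha3d_fixture <- function(n = 200) {
  p <- double_well(U_L = 1.7, U_R = 3.2, L_L = 0.15, L_R = 0.08)
  x <- seq(-1.3 * p$L_L, 1.3 * p$L_R, length.out = n)
  list(potential = p,
       profile = tibble(position = x, energy = potential_energy(p, x)))
}

#' Deterministic piecewise-linear test trajectory
#'
#' Interpolates scripted `(time, position)` waypoints onto a uniform grid,
#' producing a trajectory object for deterministic passage-time unit tests.
#'
#' @param times Strictly increasing waypoint times.
#' @param positions Matched waypoint positions.
#' @param dt Grid spacing.
#' @return A `gle_trajectory` tibble (metadata attributes minimal).
#' @export
make_test_trajectory <- function(times, positions, dt) {
  .check_finite_vec(times, "times")
  .check_finite_vec(positions, "positions")
  .check_scalar(dt, "dt")
  if (length(times) != length(positions)) {
    abort("`times` and `positions` must have equal length.",
          class = "memfpt_error_domain")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("Waypoint times must be strictly increasing.",
          class = "memfpt_error_domain")
  }
  grid <- seq(times[1], times[length(times)], by = dt)
  pos <- approx(times, positions, xout = grid)$y
  out <- tibble(time = grid, position = pos)
  structure(out, class = c("gle_trajectory", class(out)), dt = dt,
            dt_sample = dt)
}

# internal: observable bookkeeping for sweeps -------------------------------

.sweep_pairs <- function(potential, observables) {
  rows <- list()
  if ("left" %in% observables) {
    rows$left <- c(-potential$L_L, 0)
  }
  if ("right" %in% observables) {
    rows$right <- c(potential$L_R, 0)
  }
  if ("well" %in% observables) {
    rows$left_to_right <- c(-potential$L_L, potential$L_R)
    rows$right_to_left <- c(potential$L_R, -potential$L_L)
  }
  do.call(rbind, rows)
}

.sweep_theory <- function(potential, observable, kernel, mass, beta) {
  sym <- isTRUE(all.equal(potential$U_L, potential$U_R)) &&
    isTRUE(all.equal(potential$L_L, potential$L_R))
  if (observable %in% c("left", "right")) {
    predict_mfpt(potential, observable, kernel, mass, beta)$total
  } else if (sym && !inherits(kernel, "neq_kernel") &&
             nrow(kernel$components) == 1L) {
    predict_mfpt(potential, "well", kernel, mass, beta)$total
  } else {
    NA_real_
  }
}

# one sweep point: chunked run + estimates for every observable
.sweep_point <- function(potential, kernel, mass, beta, observables,
                         events_target, max_steps, chunk_steps, dt, seed,
                         boot_seed = 1L) {
  pair_mat <- .sweep_pairs(potential, observables)
  config <- sim_config(mass = mass, beta = beta, n_steps = max_steps,
                       dt = dt, seed = seed,
                       initial_position = "left-minimum")
  # size the run from the predicted means so it holds ~events_target
  # independent events: raw arrival counts overcount during recrossing
  # bursts and would stop long-memory runs far too early
  th <- vapply(rownames(pair_mat), function(o) {
    .sweep_theory(potential, o, kernel, mass, beta)
  }, numeric(1))
  min_time <- if (all(is.na(th))) 0 else events_target * max(th, na.rm = TRUE)
  run <- .run_passages(potential, kernel, config, pair_mat,
                       events_target = events_target, max_steps = max_steps,
                       chunk_steps = chunk_steps, min_time = min_time)
  obs_names <- rownames(pair_mat)
  purrr::map_dfr(seq_along(obs_names), function(i) {
    g <- run$groups[[i]]
    est <- if (nrow(g) > 0) {
      mfpt_estimate(structure(g, grouped = TRUE), seed = boot_seed)
    } else {
      NULL
    }
    tibble(
      observable = obs_names[i],
      mean = if (is.null(est)) NA_real_ else est$mean,
      sem = if (is.null(est)) NA_real_ else est$sem,
      n_events = if (is.null(est)) 0 else est$n_events,
      n_arrivals = if (is.null(est)) 0 else est$n_arrivals,
      theory = .sweep_theory(potential, obs_names[i], kernel, mass, beta),
      total_steps = run$total_steps,
      sim_time = run$total_time,
      dt = run$dt,
      seed = seed
    )
  })
}

#' Memory-time sweep: simulation vs closed-form theory
#'
#' For each rescaled memory time in `tau_grid` (units of the diffusion time
#' \eqn{\tau_D = \beta L_L^2\gamma}), simulates the equilibrium GLE in the
#' requested double well and extracts well-to-barrier-top (and optionally
#' well-to-well) mean all-to-first-passage times, tabulated against the
#' closed-form predictions.  The working frame is dimensionless:
#' `beta = gamma = L_L = 1`, so points are specified by
#' \eqn{(\beta U_L, \beta U_R, L_R/L_L, \tau_m/\tau_D, \tau/\tau_D)}.
#'
#' Runs are chunked and stop once every observable has `events_target`
#' target arrivals *and* the simulated time covers `events_target` times the
#' largest predicted mean (arrival counts alone overcount during correlated
#' recrossing bursts at long memory), or at the `max_steps` budget; achieved
#' event counts and SEMs are recorded per row so downstream tolerance checks
#' are self-calibrating at reduced statistics.  Identical arguments
#' (including seeds) reproduce identical tables.
#'
#' @param tau_grid Sorted vector of memory times in units of \eqn{\tau_D}.
#' @param U_L,U_R Barrier heights in \eqn{k_BT} (`beta = 1` frame).
#' @param L_ratio Width ratio \eqn{L_R/L_L}.
#' @param tau_m Rescaled mass \eqn{\tau_m/\tau_D}.
#' @param observables Subset of `"left"`, `"right"` (well-to-top) and
#'   `"well"` (adds both well-to-well directions).
#' @param events_target Per-point target number of target arrivals.
#' @param max_steps Per-point step budget.
#' @param chunk_steps Steps per compiled chunk.
#' @param dt Timestep override (`NULL` = conservative default, see
#'   [gle_timestep()]).
#' @param seed Base seed; point `i` uses `seed + i`.
#' @return A tibble of class `mfpt_sweep` with one row per (grid point,
#'   observable).
#' @export
run_memory_sweep <- function(tau_grid, U_L = 3, U_R = U_L, L_ratio = 1,
                             tau_m = 0.01,
                             observables = c("left", "right"),
                             events_target = 300, max_steps = 2e9,
                             chunk_steps = 2.5e8, dt = NULL, seed = 1L) {
  .check_finite_vec(tau_grid, "tau_grid")
  if (is.unsorted(tau_grid, strictly = TRUE)) {
    abort("`tau_grid` must be strictly increasing.",
          class = "memfpt_error_domain")
  }
  observables <- match.arg(observables, c("left", "right", "well"),
                           several.ok = TRUE)
  potential <- double_well(U_L = U_L, U_R = U_R, L_L = 1, L_R = L_ratio)
  rows <- purrr::imap(tau_grid, function(tau, i) {
    kernel <- memory_kernel(gamma = 1, tau = tau)
    dt_i <- dt %||% gle_timestep(potential, kernel, mass = tau_m, beta = 1)
    point <- tryCatch(
      .sweep_point(potential, kernel, mass = tau_m, beta = 1, observables,
                   events_target, max_steps, chunk_steps, dt_i,
                   seed = seed + i),
      error = function(e) {
        tibble(observable = observables, mean = NA_real_, sem = NA_real_,
               n_events = 0, n_arrivals = 0, theory = NA_real_,
               total_steps = 0, sim_time = 0, dt = dt_i, seed = seed + i,
               status = conditionMessage(e))
      })
    if (!"status" %in% names(point)) point$status <- "ok"
    point$tau_over_tauD <- tau
    point
  })
  out <- dplyr::relocate(dplyr::bind_rows(rows), "tau_over_tauD")
  structure(out, class = c("mfpt_sweep", class(out)),
            params = list(U_L = U_L, U_R = U_R, L_ratio = L_ratio,
                          tau_m = tau_m, events_target = events_target,
                          kind = "memory"))
}

#' Non-equilibrium sweep over the noise/friction timescale ratio
#'
#' Fig.-style non-equilibrium experiment: at fixed friction decay time
#' `tau_V` (units of \eqn{\tau_D}), sweeps the ratio \eqn{\tau_R/\tau_V} of
#' the random-force to friction decay times, simulating the non-equilibrium
#' GLE and tabulating well-to-top MFPTs against the effective-temperature
#' prediction ([neq_mfpt_well_to_top()]).
#'
#' The default `tau_V = 1` keeps the experiment inside the validity regime
#' of the effective-temperature mapping: \eqn{\beta_{NEQ} =
#' \beta\tau_R^2/\tau_V^2} is the high-frequency limit of the per-mode
#' effective temperature \eqn{T_{eff}(\omega)/T =
#' (1+\omega^2\tau_V^2)/(1+\omega^2\tau_R^2)}, so it requires
#' \eqn{\omega_0\tau_{V,R} \gg 1} at the well frequency
#' \eqn{\omega_0 = \sqrt{K/m}}; with the default rescaled mass this needs
#' \eqn{\tau_V/\tau_D \gtrsim 1} (see the methods vignette for the exact
#' harmonic-well check).
#'
#' @inheritParams run_memory_sweep
#' @param ratio_grid Sorted vector of \eqn{\tau_R/\tau_V} values.
#' @param tau_V Friction decay time in units of \eqn{\tau_D}.
#' @return A tibble of class `mfpt_sweep` with one row per (ratio,
#'   observable).
#' @export
run_neq_sweep <- function(ratio_grid, tau_V = 1, U_L = 3, U_R = 4,
                          L_ratio = 1, tau_m = 0.1,
                          observables = c("left", "right"),
                          events_target = 300, max_steps = 2e9,
                          chunk_steps = 2.5e8, dt = NULL, seed = 1L) {
  .check_finite_vec(ratio_grid, "ratio_grid")
  if (is.unsorted(ratio_grid, strictly = TRUE)) {
    abort("`ratio_grid` must be strictly increasing.",
          class = "memfpt_error_domain")
  }
  observables <- match.arg(observables, c("left", "right"),
                           several.ok = TRUE)
  potential <- double_well(U_L = U_L, U_R = U_R, L_L = 1, L_R = L_ratio)
  rows <- purrr::imap(ratio_grid, function(r, i) {
    kernel <- neq_kernel(gamma = 1, tau_V = tau_V, tau_R = r * tau_V)
    dt_i <- dt %||% gle_timestep(potential, kernel, mass = tau_m, beta = 1)
    point <- tryCatch(
      .sweep_point(potential, kernel, mass = tau_m, beta = 1, observables,
                   events_target, max_steps, chunk_steps, dt_i,
                   seed = seed + i),
      error = function(e) {
        tibble(observable = observables, mean = NA_real_, sem = NA_real_,
               n_events = 0, n_arrivals = 0, theory = NA_real_,
               total_steps = 0, sim_time = 0, dt = dt_i, seed = seed + i,
               status = conditionMessage(e))
      })
    if (!"status" %in% names(point)) point$status <- "ok"
    point$tau_R_over_tau_V <- r
    point
  })
  out <- dplyr::relocate(dplyr::bind_rows(rows), "tau_R_over_tau_V")
  structure(out, class = c("mfpt_sweep", class(out)),
            params = list(U_L = U_L, U_R = U_R, L_ratio = L_ratio,
                          tau_m = tau_m, tau_V = tau_V,
                          events_target = events_target, kind = "neq"))
}
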