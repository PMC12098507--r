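#' Asymmetric piecewise-quartic double-well potential
#'
#' Constructs the four-parameter double-well potential used throughout the
#' package.  The barrier top sits at `x = 0`, the left minimum at `-L_L` with
#' energy 0, and the right minimum at `+L_R` with energy `U_L - U_R`:
#' \deqn{U(x) = U_L[(x/L_L)^2 - 1]^2 \;(x \le 0), \quad
#'       U(x) = U_R[(x/L_R)^2 - 1]^2 + (U_L - U_R) \;(x > 0).}
#' `U_L` and `U_R` are the barrier heights seen from the left and right wells
#' (in units of \eqn{k_BT} when `beta = 1`), `L_L` and `L_R` the distances
#' from each minimum to the barrier top.  The potential and its first
#' derivative are continuous at the barrier top; the second derivative is
#' discontinuous there for asymmetric parameters.
#'
#' @param U_L,U_R Barrier heights of the left and right wells (energy, > 0).
#'   `U_R` defaults to `U_L` (symmetric well).
#' @param L_L,L_R Distances from the left and right minima to the barrier top
#'   (length, > 0).  `L_R` defaults to `L_L`.
#' @return An object of class `double_well`.
#' @examples
#' p <- double_well(U_L = 3, U_R = 5, L_L = 1, L_R = 0.5)
#' potential_energy(p, c(-1, 0, 0.5))
#' @export
double_well <- function(U_L, U_R = U_L, L_L = 1, L_R = L_L) {
  .check_scalar(U_L, "U_L")
  .check_scalar(U_R, "U_R")
  .check_scalar(L_L, "L_L")
  .check_scalar(L_R, "L_R")
  structure(list(U_L = U_L, U_R = U_R, L_L = L_L, L_R = L_R),
            class = "double_well")
}

#' @export
print.double_well <- function(x, ...) {
  cat("Asymmetric double-well potential\n")
  cat(sprintf("  left : U_L = %g, L_L = %g  (minimum at x = %g, energy 0)\n",
              x$U_L, x$L_L, -x$L_L))
  cat(sprintf("  right: U_R = %g, L_R = %g  (minimum at x = %g, energy %g)\n",
              x$U_R, x$L_R, x$L_R, x$U_L - x$U_R))
  cat(sprintf("  barrier top at x = 0, energy %g\n", x$U_L))
  invisible(x)
}

#' Harmonic well
#'
#' Single harmonic well \eqn{U(x) = K x^2 / 2}, used for integrator
#' validation (equipartition checks) rather than barrier-crossing work.
#'
#' @param K Curvature (energy / length^2, > 0).
#' @return An object of class `harmonic_well`.
#' @export
harmonic_well <- function(K) {
  .check_scalar(K, "K")
  structure(list(K = K), class = "harmonic_well")
}

#' @export
print.harmonic_well <- function(x, ...) {
  cat(sprintf("Harmonic well, curvature K = %g\n", x$K))
  invisible(x)
}

# internal: map a potential object to the compiled (type, parameter) pair
.pot_code <- function(potential) {
  if (is.null(potential)) {
    list(type = 0L, par = numeric(4))
  } else if (inherits(potential, "harmonic_well")) {
    list(type = 1L, par = c(potential$K, 0, 0, 0))
  } else if (inherits(potential, "double_well")) {
    list(type = 2L,
         par = c(potential$U_L, potential$U_R, potential$L_L, potential$L_R))
  } else {
    abort("`potential` must be NULL, a `harmonic_well` or a `double_well`.",
          class = "memfpt_error_domain")
  }
}

#' Evaluate a potential
#'
#' `potential_energy()` returns \eqn{U(x)}; `potential_force()` returns
#' \eqn{-U'(x)}.  Both are vectorised over `x` and reject non-finite input.
#'
#' @param potential A `double_well` or `harmonic_well` object.
#' @param x Positions (finite numeric vector).
#' @return Numeric vector of the same length as `x`.
#' @export
potential_energy <- function(potential, x) {
  UseMethod("potential_energy")
}

#' @export
potential_energy.double_well <- function(potential, x) {
  .check_finite_vec(x, "x")
  left <- x <= 0
  U <- ifelse(left, potential$U_L, potential$U_R)
  L <- ifelse(left, potential$L_L, potential$L_R)
  off <- ifelse(left, 0, potential$U_L - potential$U_R)
  q <- (x / L)^2 - 1
  U * q^2 + off
}

#' @export
potential_energy.harmonic_well <- function(potential, x) {
  .check_finite_vec(x, "x")
  0.5 * potential$K * x^2
}

#' @rdname potential_energy
#' @export
potential_force <- function(potential, x) {
  UseMethod("potential_force")
}

#' @export
potential_force.double_well <- function(potential, x) {
  .check_finite_vec(x, "x")
  left <- x <= 0
  U <- ifelse(left, potential$U_L, potential$U_R)
  L <- ifelse(left, potential$L_L, potential$L_R)
  -4 * (U / L^2) * x * ((x / L)^2 - 1)
}

#' @export
potential_force.harmonic_well <- function(potential, x) {
  .check_finite_vec(x, "x")
  -potential$K * x
}

#' Curvatures of the double well
#'
#' `curvature_at_minimum()` returns \eqn{K_{L,R} = U''(\mp L_{L,R}) =
#' 8 U_{L,R} / L_{L,R}^2}, the curvature at the requested well minimum.
#' `barrier_curvature()` returns the one-sided second derivative at the
#' barrier top, \eqn{-4 U_{L,R} / L_{L,R}^2}; the two sides differ for
#' asymmetric parameters because the second derivative is discontinuous at
#' `x = 0`.
#'
#' @param potential A `double_well` object.
#' @param side `"left"` or `"right"`.
#' @return A single curvature (energy / length^2).
#' @export
curvature_at_minimum <- function(potential, side = c("left", "right")) {
  stopifnot(inherits(potential, "double_well"))
  side <- match.arg(side)
  if (side == "left") 8 * potential$U_L / potential$L_L^2
  else 8 * potential$U_R / potential$L_R^2
}

#' @rdname curvature_at_minimum
#' @export
barrier_curvature <- function(potential, side = c("left", "right")) {
  stopifnot(inherits(potential, "double_well"))
  side <- match.arg(side)
  if (side == "left") -4 * potential$U_L / potential$L_L^2
  else -4 * potential$U_R / potential$L_R^2
}

#' Validate a tabulated free-energy profile
#'
#' A free-energy profile is a two-column table (position, energy in
#' \eqn{k_BT}) with strictly increasing positions and at least 5 rows.
#'
#' @param profile A data frame whose first two columns are position and
#'   energy (any column names; `position`/`energy` preferred).
#' @return A validated tibble with columns `position` and `energy`.
#' @export
as_free_energy_profile <- function(profile) {
  if (!is.data.frame(profile) || ncol(profile) < 2L) {
    abort("`profile` must be a data frame with at least two columns.",
          class = "memfpt_error_domain")
  }
  cols <- if (all(c("position", "energy") %in% names(profile))) {
    profile[c("position", "energy")]
  } else {
    setNames(profile[1:2], c("position", "energy"))
  }
  out <- as_tibble(cols)
  .check_finite_vec(out$position, "position")
  .check_finite_vec(out$energy, "energy")
  if (nrow(out) < 5L) {
    abort("A free-energy profile needs at least 5 points.",
          class = "memfpt_error_domain")
  }
  if (any(diff(out$position) <= 0)) {
    abort("Profile positions must be strictly increasing.",
          class = "memfpt_error_domain")
  }
  out
}

# internal: locate the two-minima / one-maximum topology of a profile.
# Noisy profiles are smoothed (cross-validated smoothing spline) before
# extremum location; the smoothed extrema only seed the nonlinear fit.
.locate_extrema <- function(profile) {
  x <- profile$position
  y <- profile$energy
  ys <- if (nrow(profile) >= 30) {
    tryCatch(stats::predict(stats::smooth.spline(x, y), x)$y,
             error = function(e) y)
  } else {
    y
  }
  d <- diff(ys)
  s <- sign(d)
  s[s == 0] <- 1
  turns <- which(diff(s) != 0) + 1L
  minima <- turns[s[turns - 1L] < 0 & s[turns] > 0]
  maxima <- turns[s[turns - 1L] > 0 & s[turns] < 0]
  if (length(minima) < 2L || length(maxima) < 1L) {
    abort(paste0("Profile does not have a two-minima / one-maximum ",
                 "double-well shape."),
          class = "memfpt_error_shape")
  }
  # two deepest minima, then the highest maximum between them
  minima <- minima[order(ys[minima])][1:2]
  minima <- sort(minima)
  between <- maxima[maxima > minima[1] & maxima < minima[2]]
  if (length(between) < 1L) {
    abort(paste0("Profile does not have a two-minima / one-maximum ",
                 "double-well shape."),
          class = "memfpt_error_shape")
  }
  barrier <- between[which.max(ys[between])]
  tibble(
    role = c("left_minimum", "barrier_top", "right_minimum"),
    position = x[c(minima[1], barrier, minima[2])],
    energy = y[c(minima[1], barrier, minima[2])]
  )
}

#' Fit the double-well form to a free-energy profile
#'
#' Least-squares fit of the piecewise-quartic double well to a tabulated
#' profile.  The profile is first scanned for its two-minima / one-maximum
#' topology (on a lightly smoothed copy when the profile is noisy); profiles
#' without that shape are rejected.  The located extrema initialise the four
#' well parameters plus a horizontal shift of the barrier top to `x = 0` and
#' a vertical shift of the left-minimum energy to 0, and all six quantities
#' are refined by bound-constrained nonlinear least squares (`nls`, `"port"`
#' algorithm).  The applied translation is reported in the fit object.
#'
#' @param profile A free-energy profile (see [as_free_energy_profile()]).
#' @param ... Passed to [stats::nls.control()].
#' @return An object of class `double_well_fit` with elements `potential`
#'   (the fitted [double_well()]), `x_shift`, `energy_shift`, `extrema`,
#'   `rss`, `residuals`, `fitted`, `data`, `converged`.  Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' p <- double_well(3, 5, 1, 0.5)
#' prof <- tibble::tibble(position = seq(-1.4, 0.8, length.out = 200))
#' prof$energy <- potential_energy(p, prof$position)
#' fit <- fit_double_well(prof)
#' tidy(fit)
#' @export
fit_double_well <- function(profile, ...) {
  profile <- as_free_energy_profile(profile)
  ext <- .locate_extrema(profile)

  x_b <- ext$position[ext$role == "barrier_top"]
  e_l <- ext$energy[ext$role == "left_minimum"]
  start <- list(
    U_L = max(ext$energy[2] - ext$energy[1], 1e-3),
    U_R = max(ext$energy[2] - ext$energy[3], 1e-3),
    L_L = max(x_b - ext$position[1], 1e-6),
    L_R = max(ext$position[3] - x_b, 1e-6),
    x0 = x_b,
    e0 = e_l
  )

  model <- function(position, U_L, U_R, L_L, L_R, x0, e0) {
    potential_energy(double_well(U_L, U_R, L_L, L_R), position - x0) + e0
  }

  span <- diff(range(profile$position))
  # "false convergence" from the port solver near a flat optimum is benign;
  # the `converged` flag still reports genuine failures
  fit <- suppressWarnings(nls(
    energy ~ model(position, U_L, U_R, L_L, L_R, x0, e0),
    data = profile,
    start = start,
    algorithm = "port",
    lower = c(U_L = 1e-8, U_R = 1e-8, L_L = 1e-8, L_R = 1e-8,
              x0 = min(profile$position), e0 = -Inf),
    upper = c(U_L = Inf, U_R = Inf, L_L = span, L_R = span,
              x0 = max(profile$position), e0 = Inf),
    control = nls.control(maxiter = 500, warnOnly = TRUE, ...)
  ))

  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  structure(
    list(
      potential = double_well(cf[["U_L"]], cf[["U_R"]],
                              cf[["L_L"]], cf[["L_R"]]),
      x_shift = cf[["x0"]],
      energy_shift = cf[["e0"]],
      extrema = ext,
      rss = sum(res^2),
      residual_norm = sqrt(sum(res^2)),
      residuals = as.numeric(res),
      fitted = as.numeric(stats::fitted(fit)),
      data = profile,
      converged = fit$convInfo$isConv,
      nls = fit
    ),
    class = "double_well_fit"
  )
}

#' @export
print.double_well_fit <- function(x, ...) {
  cat("Double-well fit\n")
  print(x$potential)
  cat(sprintf("  translation: x0 = %.6g, e0 = %.6g; residual norm = %.4g\n",
              x$x_shift, x$energy_shift, x$residual_norm))
  invisible(x)
}
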