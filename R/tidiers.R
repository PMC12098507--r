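#' Tidy a double-well fit
#'
#' @param x A `double_well_fit`.
#' @param ... Unused.
#' @return One row per parameter (`U_L`, `U_R`, `L_L`, `L_R`, `x0`, `e0`)
#'   with `estimate` and `std.error` from the nonlinear least-squares fit.
#' @export
tidy.double_well_fit <- function(x, ...) {
  est <- stats::coef(x$nls)
  # standard errors are undefined for a perfect (zero-residual) fit
  se <- tryCatch(summary(x$nls)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  tibble(term = names(est), estimate = as.numeric(est),
         std.error = as.numeric(se))
}

#' @rdname tidy.double_well_fit
#' @return `glance()`: a one-row tibble with fit-level summaries.
#' @export
glance.double_well_fit <- function(x, ...) {
  tibble(rss = x$rss, residual_norm = x$residual_norm,
         sigma = sqrt(x$rss / max(1, nrow(x$data) - 6)),
         n = nrow(x$data), converged = x$converged,
         x_shift = x$x_shift, energy_shift = x$energy_shift)
}

#' Tidy a double-well potential
#'
#' @param x A `double_well`.
#' @param ... Unused.
#' @return One row per parameter with derived quantities (well curvatures).
#' @export
tidy.double_well <- function(x, ...) {
  tibble(
    term = c("U_L", "U_R", "L_L", "L_R", "K_L", "K_R"),
    estimate = c(x$U_L, x$U_R, x$L_L, x$L_R,
                 curvature_at_minimum(x, "left"),
                 curvature_at_minimum(x, "right"))
  )
}

#' Tidy an MFPT estimate
#'
#' @param x An `mfpt_estimate`.
#' @param ... Unused.
#' @return A one-row tibble (`mean`, `sem`, `n_events`, `n_arrivals`,
#'   `reliable`, `start`, `target`).
#' @export
tidy.mfpt_estimate <- function(x, ...) {
  tibble(mean = x$mean, sem = x$sem, n_events = x$n_events,
         n_arrivals = x$n_arrivals, reliable = x$reliable,
         start = x$start %||% NA_real_, target = x$target %||% NA_real_)
}

#' Tidy a closed-form MFPT prediction
#'
#' @param x An `mfpt_prediction`.
#' @param ... Unused.
#' @return One row per term (`inertial`, `overdamped`, `crossover`, `total`).
#' @export
tidy.mfpt_prediction <- function(x, ...) {
  tibble(term = c("inertial", "overdamped", "crossover", "total"),
         value = c(x$inertial, x$overdamped, x$crossover, x$total))
}
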