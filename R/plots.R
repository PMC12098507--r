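#' Plot a GLE trajectory
#'
#' Position versus time; when the trajectory was generated in a double well,
#' dashed guides mark the two minima and the barrier top.
#'
#' @param object A `gle_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gle_trajectory <- function(object, ...) {
  g <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                            y = .data$position)) +
    ggplot2::geom_line(linewidth = 0.25, colour = "grey25") +
    ggplot2::labs(x = "time", y = "reaction coordinate x(t)")
  p <- attr(object, "potential")
  if (inherits(p, "double_well")) {
    g <- g + ggplot2::geom_hline(yintercept = c(-p$L_L, 0, p$L_R),
                                 linetype = "dashed", colour = "steelblue")
  }
  g
}

#' Plot a double-well potential
#'
#' @param object A `double_well`.
#' @param from,to Plot range (defaults bracket both minima).
#' @param n Curve resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.double_well <- function(object, from = -1.6 * object$L_L,
                                 to = 1.6 * object$L_R, n = 400, ...) {
  x <- seq(from, to, length.out = n)
  df <- tibble(position = x, energy = potential_energy(object, x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate", y = "energy (kBT)")
}

#' Plot a double-well fit against its profile
#'
#' @param object A `double_well_fit`.
#' @param ... Unused.
#' @return A ggplot object: profile points and the fitted curve.
#' @export
autoplot.double_well_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$energy), size = 0.8,
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "reaction coordinate", y = "energy (kBT)")
}

#' Plot a simulation-versus-theory sweep
#'
#' Simulated MFPTs (points with 1-SEM error bars) against the closed-form
#' predictions (lines), on log-log axes for memory sweeps.
#'
#' @param object An `mfpt_sweep` from [run_memory_sweep()] or
#'   [run_neq_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mfpt_sweep <- function(object, ...) {
  xvar <- if ("tau_over_tauD" %in% names(object)) {
    "tau_over_tauD"
  } else {
    "tau_R_over_tau_V"
  }
  xlab <- if (xvar == "tau_over_tauD") "tau / tau_D" else "tau_R / tau_V"
  g <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[xvar]], y = .data$mean,
                                    colour = .data$observable)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.05) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$theory), linetype = "solid",
                       na.rm = TRUE) +
    ggplot2::labs(x = xlab, y = "MFPT / tau_D",
                  colour = "observable")
  if (xvar == "tau_over_tauD") {
    g <- g + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  g
}

#' @importFrom ggplot2 .data
NULL
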