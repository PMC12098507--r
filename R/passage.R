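#' Detect level crossings in a trajectory
#'
#' Finds the times at which the position series crosses `level`, refining
#' each crossing below sample resolution by linear interpolation between the
#' bracketing samples.  A crossing is any sign change of `position - level`
#' between consecutive samples; samples exactly on the level do not by
#' themselves create a crossing (the convention is documented and applied
#' consistently throughout the package).
#'
#' @param traj A data frame with `time` and `position` columns (e.g. a
#'   `gle_trajectory`).
#' @param level Crossing level (position).
#' @param direction `"both"`, `"up"` (position increasing through the
#'   level) or `"down"`.
#' @return A tibble with columns `time` and `direction`.
#' @export
detect_crossings <- function(traj, level, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  .check_scalar(level, "level", positive = FALSE)
  if (!is.data.frame(traj) || nrow(traj) == 0L) {
    abort("`traj` must be a non-empty data frame with time and position.",
          class = "memfpt_error_domain")
  }
  x <- traj$position
  tt <- traj$time
  n <- length(x)
  if (n < 2L) return(tibble(time = numeric(0), direction = character(0)))
  d <- x - level
  s <- sign(d)
  # samples exactly on the level inherit the preceding sign, so a touch
  # without a sign change is not a crossing while an exact hit followed by
  # the opposite sign registers once, at the sample time
  nz <- which(s != 0)
  if (length(nz) == 0L) {
    return(tibble(time = numeric(0), direction = character(0)))
  }
  s <- approx(nz, s[nz], xout = seq_len(n), method = "constant",
              rule = 2, f = 0)$y
  idx <- which(s[-n] != s[-1])
  tc <- tt[idx] + (tt[idx + 1] - tt[idx]) * (level - x[idx]) /
    (x[idx + 1] - x[idx])
  dir <- ifelse(x[idx + 1] > x[idx], "up", "down")
  out <- tibble(time = tc, direction = dir)
  if (direction != "both") out <- out[out$direction == direction, ]
  out
}

#' All-to-first-passage ensemble
#'
#' Implements the mean all-to-first-passage-time convention: every crossing
#' of the `start` level opens a passage, and each open passage ends at the
#' *next* crossing of the `target` level.  Start visits after the last target
#' arrival are discarded.  Durations are grouped by the shared target arrival
#' because passages ending at the same arrival are strongly correlated; the
#' groups drive the block bootstrap in [mfpt_estimate()].
#'
#' If `traj` carries full-resolution passage statistics for this exact
#' `(start, target)` pair (from the `passages` argument of
#' [simulate_gle()]), those are used; otherwise crossings are computed from
#' the stored (possibly decimated) series.
#'
#' @param traj A data frame with `time`/`position` columns, typically a
#'   `gle_trajectory`.
#' @param start,target Start and target levels (must differ).
#' @return An object of class `passage_ensemble`: a tibble with one row per
#'   passage (`start_time`, `duration`, `arrival`, `arrival_time`), or a
#'   grouped form with one row per arrival (`arrival_time`, `n`, `sum`) when
#'   built from online statistics.  Attributes `start`, `target`, `grouped`.
#' @export
all_to_first_passage <- function(traj, start, target) {
  .check_scalar(start, "start", positive = FALSE)
  .check_scalar(target, "target", positive = FALSE)
  if (start == target) {
    abort("`start` and `target` must differ.", class = "memfpt_error_domain")
  }
  pre <- .find_recorded_pair(traj, start, target)
  if (!is.null(pre)) {
    return(structure(pre, class = c("passage_ensemble", class(pre)),
                     start = start, target = target, grouped = TRUE))
  }
  S <- detect_crossings(traj, start)$time
  Tt <- detect_crossings(traj, target)$time
  if (length(Tt) == 0L || length(S) == 0L) {
    out <- tibble(start_time = numeric(0), duration = numeric(0),
                  arrival = integer(0), arrival_time = numeric(0))
    return(structure(out, class = c("passage_ensemble", class(out)),
                     start = start, target = target, grouped = FALSE))
  }
  j <- findInterval(S, Tt) + 1L
  keep <- j <= length(Tt)
  out <- tibble(
    start_time = S[keep],
    duration = Tt[j[keep]] - S[keep],
    arrival = j[keep],
    arrival_time = Tt[j[keep]]
  )
  structure(out, class = c("passage_ensemble", class(out)),
            start = start, target = target, grouped = FALSE)
}

# internal: online-accumulated group table matching this pair, if any
.find_recorded_pair <- function(traj, start, target) {
  pass <- attr(traj, "passages")
  if (is.null(pass)) return(NULL)
  for (p in pass) {
    if (nrow(p) == 0L) next
    if (isTRUE(all.equal(p$start[1], start)) &&
        isTRUE(all.equal(p$target[1], target))) {
      return(p[c("arrival_time", "n", "sum")])
    }
  }
  NULL
}

#' Mean first-passage-time estimate
#'
#' Averages an all-to-first-passage ensemble into a mean first-passage time
#' with a standard error.  Because many passages share a target arrival (and
#' are therefore correlated), the SEM comes from a seeded block bootstrap
#' over target-arrival groups rather than an i.i.d. formula.  Estimates with
#' fewer than 100 target arrivals are flagged unreliable.
#'
#' @param ensemble A `passage_ensemble` (from [all_to_first_passage()]) or a
#'   grouped tibble with columns `n` and `sum`.
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed Integer seed for the bootstrap.
#' @param n_blocks Number of contiguous blocks of arrival groups resampled
#'   by the bootstrap (default `min(40, #groups)`).  Blocks are contiguous
#'   in arrival order because at long memory times consecutive arrival
#'   groups (recrossing bursts) are themselves correlated; resampling
#'   individual groups would understate the error.
#' @return An object of class `mfpt_estimate` with fields `mean`, `sem`,
#'   `n_events`, `n_arrivals`, `reliable`, `start`, `target`.
#' @export
mfpt_estimate <- function(ensemble, n_boot = 200, seed = 1L,
                          n_blocks = NULL) {
  g <- .ensemble_groups(ensemble)
  if (nrow(g) == 0L) {
    abort(paste0("Empty passage ensemble: no target arrival was observed; ",
                 "extend the run."),
          class = "memfpt_error_empty")
  }
  m <- sum(g$sum) / sum(g$n)
  nb <- min(n_blocks %||% 40L, nrow(g))
  sem <- if (nb > 1L) {
    blk <- cut(seq_len(nrow(g)), breaks = nb, labels = FALSE)
    bn <- as.numeric(tapply(g$n, blk, sum))
    bs <- as.numeric(tapply(g$sum, blk, sum))
    set.seed(seed)
    idx <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = n_boot)
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- idx[b, ]
      sum(bs[i]) / sum(bn[i])
    }, numeric(1))
    sd(reps)
  } else {
    0
  }
  structure(
    list(mean = m, sem = sem, n_events = sum(g$n), n_arrivals = nrow(g),
         reliable = nrow(g) >= 100,
         start = attr(ensemble, "start"), target = attr(ensemble, "target")),
    class = "mfpt_estimate"
  )
}

# internal: reduce any ensemble representation to per-arrival (n, sum)
.ensemble_groups <- function(ensemble) {
  if (isTRUE(attr(ensemble, "grouped")) ||
      all(c("n", "sum") %in% names(ensemble))) {
    tibble(n = ensemble$n, sum = ensemble$sum)
  } else {
    if (nrow(ensemble) == 0L) return(tibble(n = numeric(0), sum = numeric(0)))
    agg <- tapply(ensemble$duration, ensemble$arrival, sum)
    cnt <- tapply(ensemble$duration, ensemble$arrival, length)
    tibble(n = as.numeric(cnt), sum = as.numeric(agg))
  }
}

#' @export
print.mfpt_estimate <- function(x, ...) {
  cat(sprintf(
    "MFPT %s -> %s: %.6g +/- %.3g  (%g passages, %g arrivals%s)\n",
    format(x$start %||% NA), format(x$target %||% NA), x$mean, x$sem,
    x$n_events, x$n_arrivals,
    if (!x$reliable) "; < 100 arrivals, flagged unreliable" else ""))
  invisible(x)
}

#' Well-to-well mean first-passage times
#'
#' Applies the all-to-first-passage convention between the two well minima:
#' start at one minimum (`-L_L` or `+L_R`), target the other.  Both
#' directions are returned.
#'
#' @param traj A trajectory covering both wells.
#' @param potential The [double_well()] the trajectory was generated in.
#' @param ... Passed to [mfpt_estimate()].
#' @return A list with elements `left_to_right` and `right_to_left`, each an
#'   `mfpt_estimate`.
#' @export
well_to_well_mfpt <- function(traj, potential, ...) {
  stopifnot(inherits(potential, "double_well"))
  list(
    left_to_right = mfpt_estimate(
      all_to_first_passage(traj, -potential$L_L, potential$L_R), ...),
    right_to_left = mfpt_estimate(
      all_to_first_passage(traj, potential$L_R, -potential$L_L), ...)
  )
}

#' Well-to-barrier-top mean first-passage time
#'
#' All-to-first-passage from a well minimum (`-L_L` or `+L_R`) to the
#' barrier top at `x = 0`; the quantities \eqn{\tau^L_{MFP}} and
#' \eqn{\tau^R_{MFP}} that the closed-form theory predicts.
#'
#' @inheritParams well_to_well_mfpt
#' @param side `"left"` or `"right"` well.
#' @return An `mfpt_estimate`.
#' @export
well_to_barrier_mfpt <- function(traj, potential, side = c("left", "right"),
                                 ...) {
  stopifnot(inherits(potential, "double_well"))
  side <- match.arg(side)
  start <- if (side == "left") -potential$L_L else potential$L_R
  mfpt_estimate(all_to_first_passage(traj, start, 0), ...)
}
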