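#' Read and write free-energy profiles
#'
#' Profiles are exchanged as two-column delimited text (position, energy in
#' \eqn{k_BT}) with `#` comment lines.
#'
#' @param file Path to a two-column text file.
#' @return `read_profile()`: a validated profile tibble.
#' @export
read_profile <- function(file) {
  df <- read.table(file, comment.char = "#", header = FALSE,
                   col.names = c("position", "energy"))
  as_free_energy_profile(df)
}

#' @rdname read_profile
#' @param profile A free-energy profile (data frame, first two columns
#'   position and energy).
#' @param comment Optional comment string written to the header.
#' @export
write_profile <- function(profile, file, comment = NULL) {
  profile <- as_free_energy_profile(profile)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# free-energy profile: position  energy(kBT)", con)
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(profile, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Serialize a double-well potential as JSON
#'
#' Parameters are written with explicit unit fields (energies in
#' \eqn{k_BT}, lengths in reaction-coordinate units).
#'
#' @param potential A [double_well()].
#' @param file Path to write.
#' @export
write_potential_json <- function(potential, file) {
  stopifnot(inherits(potential, "double_well"))
  jsonlite::write_json(
    list(type = "double_well",
         parameters = list(U_L = potential$U_L, U_R = potential$U_R,
                           L_L = potential$L_L, L_R = potential$L_R),
         units = list(energy = "kBT", length = "reaction coordinate")),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_potential_json
#' @export
read_potential_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  p <- obj$parameters
  double_well(p$U_L, p$U_R, p$L_L, p$L_R)
}

#' Read and write trajectories as delimited text
#'
#' Small trajectories are exchanged as tab-separated text with a
#' `#`-comment header carrying the sampling interval.  (Binary columnar
#' containers are intentionally not used: the toolchain is text-only.)
#'
#' @param traj A `gle_trajectory` (or any data frame with `time` /
#'   `position` columns).
#' @param file Path.
#' @export
write_trajectory <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# gle trajectory; dt_sample = %.17g",
                     attr(traj, "dt_sample") %||%
                       (if (nrow(traj) > 1) diff(traj$time[1:2]) else NA)),
             con)
  writeLines(paste0("# columns: ", paste(names(traj), collapse = "\t")), con)
  utils::write.table(as.data.frame(traj), con, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  hdr <- readLines(file, n = 2L)
  cols <- if (length(hdr) >= 2 && grepl("^# columns:", hdr[2])) {
    strsplit(sub("^# columns: ", "", hdr[2]), "\t")[[1]]
  } else {
    c("time", "position")
  }
  df <- read.table(file, comment.char = "#", header = FALSE,
                   col.names = cols)
  dt_samp <- if (grepl("dt_sample = ", hdr[1])) {
    as.numeric(sub(".*dt_sample = ", "", hdr[1]))
  } else if (nrow(df) > 1) {
    diff(df$time[1:2])
  } else {
    NA_real_
  }
  out <- as_tibble(df)
  structure(out, class = c("gle_trajectory", class(out)),
            dt_sample = dt_samp)
}
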