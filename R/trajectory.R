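TRAJ_COLS <- c("time", "id", "x", "y", "z", "r", "vx", "vy", "vz", "n_np",
               "fmx", "fmy", "fmz", "fgz", "fhx", "fhy", "fhz")

#' Construct a trajectory object
#'
#' One row per spheroid per snapshot. Snapshot times must be
#' non-decreasing down the table and, when `I_out` is known, multiples of
#' it (to rounding).
#'
#' @param data a data.frame/data.table with columns
#'   `r toString(TRAJ_COLS)`.
#' @param I_out snapshot interval (s), stored as an attribute; `NA` if
#'   unknown.
#' @return An object of class `mba_trajectory` (a data.table).
#' @export
trajectory <- function(data, I_out = NA_real_) {
  dt <- data.table::as.data.table(data)
  missing_cols <- setdiff(TRAJ_COLS, names(dt))
  if (length(missing_cols))
    stop("trajectory format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (is.unsorted(dt$time))
    stop("trajectory validation error: snapshot times must be non-decreasing")
  if (!is.na(I_out)) {
    ut <- unique(dt$time)
    if (any(abs(ut / I_out - round(ut / I_out)) > 1e-9))
      stop("trajectory validation error: snapshot times are not multiples of I_out")
    if (any(diff(ut) <= 0))
      stop("trajectory validation error: snapshot times must strictly increase")
  }
  data.table::setattr(dt, "I_out", I_out)
  data.table::setattr(dt, "class",
                      c("mba_trajectory", class(data.table::data.table())))
  dt
}

#' Number of snapshots in a trajectory
#' @param traj an `mba_trajectory`.
#' @return integer count of distinct snapshot times.
#' @export
n_snapshots <- function(traj) length(unique(traj$time))

#' Snapshot times of a trajectory
#' @param traj an `mba_trajectory`.
#' @return numeric vector of distinct times (s).
#' @export
snapshot_times <- function(traj) unique(traj$time)

#' Extract one snapshot as a population state
#'
#' @param traj an `mba_trajectory`.
#' @param time snapshot time; defaults to the last one.
#' @return an `mba_population` with `velocities` and force columns
#'   attached as attributes `forces` (list of matrices).
#' @export
snapshot_state <- function(traj, time = NULL) {
  ts <- snapshot_times(traj)
  if (is.null(time)) time <- ts[length(ts)]
  if (!any(abs(ts - time) < 1e-12))
    stop("no snapshot at time ", time)
  sn <- traj[abs(traj$time - time) < 1e-12, ]
  pop <- list(n = nrow(sn),
              positions = cbind(sn$x, sn$y, sn$z),
              radii = sn$r,
              np_counts = sn$n_np,
              velocities = cbind(sn$vx, sn$vy, sn$vz))
  class(pop) <- "mba_population"
  attr(pop, "forces") <- list(
    F_mag = cbind(sn$fmx, sn$fmy, sn$fmz),
    F_grav = cbind(0, 0, sn$fgz),
    F_hertz = cbind(sn$fhx, sn$fhy, sn$fhz))
  pop
}

#' Write a trajectory to CSV
#'
#' @param traj an `mba_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mba_trajectory"))
  data.table::fwrite(traj, path)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' Round-trips [write_trajectory()] output to full stored precision.
#' Missing columns raise a format error; non-monotone snapshot times raise
#' a validation error.
#'
#' @param path CSV file.
#' @param I_out optional snapshot interval for validation.
#' @return an `mba_trajectory`.
#' @export
read_trajectory <- function(path, I_out = NA_real_) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  trajectory(data.table::fread(path), I_out = I_out)
}
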