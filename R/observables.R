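#' Area coverage of the assembling construct
#'
#' Fraction of the circular region of interest (default: the magnet
#' footprint) covered by the union of the spheroids' equatorial disks
#' projected onto the floor plane, computed by rasterization.
#'
#' @param state an `mba_population`.
#' @param roi_radius ROI radius (m).
#' @param px rasterization pixel size (m); default one tenth of the
#'   smallest radius.
#' @return coverage fraction in \[0, 1\].
#' @export
area_coverage <- function(state, roi_radius = 2.5e-3, px = NULL) {
  if (state$n == 0) return(0)
  if (is.null(px)) px <- max(min(state$radii) / 10, 1e-6)
  cpp_coverage(state$positions[, 1], state$positions[, 2], state$radii,
               roi_radius, px)
}

#' Coverage kinetics from a stored trajectory
#'
#' @param traj an `mba_trajectory`.
#' @param roi_radius ROI radius (m).
#' @param px rasterization pixel (m).
#' @return data.frame with `time` and `coverage`.
#' @export
coverage_series <- function(traj, roi_radius = 2.5e-3, px = NULL) {
  ts <- snapshot_times(traj)
  cov <- vapply(ts, function(t)
    area_coverage(snapshot_state(traj, t), roi_radius, px), numeric(1))
  data.frame(time = ts, coverage = cov)
}

#' Assembly time of a coverage series
#'
#' Time at which the coverage first reaches `threshold` times its final
#' plateau value, linearly interpolated between samples. If the series is
#' already at or above the threshold at its first sample the assembly time
#' is 0. When the coverage is still visibly growing at the end of the
#' series (final slope above 1% of the plateau per sample interval) the
#' end time is returned with attribute `reached = FALSE`.
#'
#' With `method = "exp_fit"` the series is instead fit to
#' a + b (1 - exp(-t / tau)) and `tau` is returned (the time-coefficient
#' candidate).
#'
#' @param series data.frame with columns `time` and `coverage`.
#' @param threshold plateau fraction in (0, 1).
#' @param method `"plateau"` (default) or `"exp_fit"`.
#' @return assembly time (s) with attribute `reached`, or the exponential
#'   time constant for `method = "exp_fit"`.
#' @export
assembly_time <- function(series, threshold = 0.95,
                          method = c("plateau", "exp_fit")) {
  method <- match.arg(method)
  stopifnot(nrow(series) >= 1, threshold > 0, threshold < 1)
  t <- series$time
  a <- series$coverage
  if (method == "exp_fit") {
    if (nrow(series) < 4 || diff(range(a)) == 0) return(NA_real_)
    fit <- try(suppressWarnings(
      stats::nls(a ~ a0 + b0 * (1 - exp(-t / tau)),
                 start = list(a0 = a[1], b0 = max(a) - a[1],
                              tau = max(t[length(t)] / 5,
                                        .Machine$double.eps)),
                 control = stats::nls.control(warnOnly = TRUE))),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    return(unname(stats::coef(fit)["tau"]))
  }
  plateau <- a[length(a)]
  target <- threshold * plateau
  hit <- which(a >= target)
  if (!length(hit)) {
    out <- t[length(t)]
    attr(out, "reached") <- FALSE
    return(out)
  }
  k <- hit[1]
  out <- if (k == 1) t[1]
  else t[k - 1] + (target - a[k - 1]) / (a[k] - a[k - 1]) * (t[k] - t[k - 1])
  reached <- TRUE
  if (length(a) >= 3) {
    final_slope <- abs(a[length(a)] - a[length(a) - 1])
    if (plateau > 0 && final_slope > 0.01 * plateau) reached <- FALSE
  }
  attr(out, "reached") <- reached
  out
}

#' Radius-normalized movement-rate profile
#'
#' For every pair of consecutive snapshots and every spheroid, the speed
#' divided by the spheroid radius (s^-1) is assigned to the radial bin of
#' the spheroid's distance from the magnet axis at the interval start;
#' bin means are returned.
#'
#' @param traj an `mba_trajectory` with at least 2 snapshots.
#' @param n_bins number of radial bins.
#' @param r_max outer radius of the binning (m); defaults to the largest
#'   observed radial distance.
#' @return data.frame with `bin_center` (m), `rate` (s^-1; NA for empty
#'   bins) and `count`.
#' @export
rate_profile <- function(traj, n_bins = 20, r_max = NULL) {
  ts <- snapshot_times(traj)
  if (length(ts) < 2) stop("rate_profile needs at least 2 snapshots")
  dist0 <- numeric(0); rate <- numeric(0)
  for (k in seq_len(length(ts) - 1)) {
    s0 <- snapshot_state(traj, ts[k])
    s1 <- snapshot_state(traj, ts[k + 1])
    dt <- ts[k + 1] - ts[k]
    disp <- sqrt(rowSums((s1$positions - s0$positions)^2))
    dist0 <- c(dist0, sqrt(rowSums(s0$positions[, 1:2, drop = FALSE]^2)))
    rate <- c(rate, disp / dt / s0$radii)
  }
  if (is.null(r_max)) r_max <- max(dist0) * (1 + 1e-9)
  edges <- seq(0, r_max, length.out = n_bins + 1)
  bin <- findInterval(dist0, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
  means <- tapply(rate, factor(bin, levels = seq_len(n_bins)), mean)
  counts <- tabulate(bin, n_bins)
  data.frame(bin_center = (edges[-1] + edges[-length(edges)]) / 2,
             rate = as.numeric(means), count = counts)
}

#' Radial and vertical stress profiles
#'
#' Converts the forces acting on each spheroid to radial and vertical
#' stresses and bins them by the spheroid's distance from the magnet axis.
#' Negative values are compressive (toward the axis, or downward).
#'
#' Three stress components are available:
#' \describe{
#'   \item{`"body"`}{the body force F = F_mag (+ F_grav) over the spheroid
#'     cross-section: sigma_rad = (F . rho_hat)/(pi r_i^2), sigma_vert =
#'     F_z/(pi r_i^2). This is the direct per-spheroid force-per-area
#'     measure; its radial component vanishes on the axis by symmetry.}
#'   \item{`"transmitted"`}{the standard per-particle Cauchy stress built
#'     from the Hertzian contact forces, sigma_i = (1/V_i) sum_c b_c (x)
#'     F_c with branch vector b_c from the spheroid centre to the contact
#'     and V_i = (4/3) pi r_i^3 — the load actually carried through the
#'     tissue, which peaks at the construct centre and decays outward.}
#'   \item{`"total"`}{the sum of both.}
#' }
#'
#' @param state an `mba_population` with `np_counts` assigned.
#' @param magnet,np,params model specification objects.
#' @param n_bins number of radial bins.
#' @param r_max outer binning radius (m); defaults to the largest radial
#'   distance present.
#' @param include_gravity include the net gravitational force in the body
#'   component (default TRUE).
#' @param component which stress measure to profile (see Details).
#' @param well well geometry; required for the contact-based components
#'   (defaults to [well_geometry()]).
#' @return An object of class `mba_stress_profile`: data.frame with
#'   `bin_center` (m), `radial_stress`, `vertical_stress` (N m^-2, NA for
#'   empty bins) and `count`.
#' @export
stress_profiles <- function(state, magnet, np, params, n_bins = 10,
                            r_max = NULL, include_gravity = TRUE,
                            component = c("body", "transmitted", "total"),
                            well = well_geometry()) {
  component <- match.arg(component)
  rho <- sqrt(rowSums(state$positions[, 1:2, drop = FALSE]^2))
  rho_hat <- cbind(ifelse(rho > 0, state$positions[, 1] / rho, 0),
                   ifelse(rho > 0, state$positions[, 2] / rho, 0))
  area <- pi * state$radii^2
  sig_rad <- sig_vert <- numeric(state$n)
  if (component %in% c("body", "total")) {
    Fm <- magnetic_force(state, magnet, np, params)
    Fg <- gravity_buoyancy(state, params)
    Ft <- if (include_gravity) Fm + Fg else Fm
    sig_rad <- (Ft[, 1] * rho_hat[, 1] + Ft[, 2] * rho_hat[, 2]) / area
    sig_vert <- Ft[, 3] / area
  }
  if (component %in% c("transmitted", "total")) {
    cs <- particle_contact_stress(state, params, well)
    for (i in seq_len(state$n)) {
      rh <- c(rho_hat[i, ], 0)
      sig_rad[i] <- sig_rad[i] + drop(t(rh) %*% cs[, , i] %*% rh)
      sig_vert[i] <- sig_vert[i] + cs[3, 3, i]
    }
  }
  if (is.null(r_max)) r_max <- max(rho) * (1 + 1e-9)
  if (r_max <= 0) r_max <- 1e-9
  edges <- seq(0, r_max, length.out = n_bins + 1)
  bin <- findInterval(rho, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
  lev <- factor(bin, levels = seq_len(n_bins))
  out <- data.frame(
    bin_center = (edges[-1] + edges[-length(edges)]) / 2,
    radial_stress = as.numeric(tapply(sig_rad, lev, mean)),
    vertical_stress = as.numeric(tapply(sig_vert, lev, mean)),
    count = tabulate(bin, n_bins))
  class(out) <- c("mba_stress_profile", "data.frame")
  out
}

#' Per-particle Cauchy stress tensors from contact forces
#'
#' sigma_i = (1/V_i) sum over contacts of (branch vector) (x) (contact
#' force on i), with the branch vector -r_i n_hat from the spheroid centre
#' to the contact point and V_i = (4/3) pi r_i^3. Wall contacts are
#' included. Compressive normal loads give negative diagonal entries.
#'
#' @param state an `mba_population`.
#' @param params an [sim_params()] object.
#' @param well an [well_geometry()] object.
#' @return a 3 x 3 x n array (N m^-2).
#' @export
particle_contact_stress <- function(state, params, well = well_geometry()) {
  con <- hertz_forces(detect_contacts(state, well), params)
  S <- array(0, c(3, 3, state$n))
  for (k in seq_len(nrow(con))) {
    i <- con$i[k]; j <- con$j[k]
    nv <- c(con$nx[k], con$ny[k], con$nz[k])
    fv <- c(con$fx[k], con$fy[k], con$fz[k])
    S[, , i] <- S[, , i] + outer(-state$radii[i] * nv, fv)
    if (j != WALL) S[, , j] <- S[, , j] + outer(state$radii[j] * nv, -fv)
  }
  for (i in seq_len(state$n)) S[, , i] <- S[, , i] / (4 / 3 * pi * state$radii[i]^3)
  S
}
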