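#' Assemble the overdamped mobility system C v = F
#'
#' Diagonal 3x3 blocks are the Stokes drag 6 pi eta r_i I plus, for every
#' contact of spheroid i, the contact-damping block
#' S (c_n n n^T + c_t (I - n n^T)); off-diagonal blocks of a contacting
#' pair are the negated damping block, so C is symmetric. Wall contacts
#' contribute to the diagonal only (the wall does not move). The right-hand
#' side collects the body and potential forces
#' F_i = F_mag_i + F_grav_i + F_hertz_i.
#'
#' @param pop an `mba_population`.
#' @param forces output of [force_decomposition()].
#' @param contacts contact table (with damping areas `S`); defaults to the
#'   table inside `forces`.
#' @param params an [sim_params()] object.
#' @param lam_dt optional `lambda * dt` weight: adds the Hertz stiffness
#'   blocks `k n n^T` of the semi-implicit operator (requires column `k`
#'   from [hertz_forces()]).
#' @return list with sparse symmetric `C` (3n x 3n, dgCMatrix), numeric
#'   `F` (3n) and the `contacts` table.
#' @export
assemble_system <- function(pop, forces, contacts = forces$contacts,
                            params, lam_dt = 0) {
  n <- pop$n
  if (nrow(forces$F_mag) != n || length(forces$gamma) != n)
    stop("force decomposition inconsistent with population size")
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  add_block <- function(bi, bj, block) {
    idx <- expand.grid(1:3, 1:3)
    trip_i <<- c(trip_i, (bi - 1) * 3 + idx[, 1])
    trip_j <<- c(trip_j, (bj - 1) * 3 + idx[, 2])
    trip_x <<- c(trip_x, as.vector(block))
  }
  for (i in seq_len(n)) add_block(i, i, forces$gamma[i] * diag(3))
  m <- nrow(contacts)
  for (k in seq_len(m)) {
    nrm <- c(contacts$nx[k], contacts$ny[k], contacts$nz[k])
    B <- contacts$S[k] * (params$c_t * diag(3) +
                            (params$c_n - params$c_t) * tcrossprod(nrm))
    if (lam_dt > 0 && !is.null(contacts$k))
      B <- B + lam_dt * contacts$k[k] * tcrossprod(nrm)
    i <- contacts$i[k]; j <- contacts$j[k]
    add_block(i, i, B)
    if (j != WALL) {
      add_block(j, j, B)
      add_block(i, j, -B)
      add_block(j, i, -B)
    }
  }
  C <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(3 * n, 3 * n))
  Fv <- as.vector(t(forces$F_mag + forces$F_grav + forces$F_hertz))
  sys <- list(C = C, F = Fv, contacts = contacts)
  class(sys) <- "mba_system"
  sys
}

#' Solve the mobility system by conjugate gradients
#'
#' Jacobi-preconditioned conjugate gradients on the symmetric positive
#' definite mobility matrix; converged when the relative residual
#' ||Cv - F|| / ||F|| drops below `tol`.
#'
#' @param sys an `mba_system` from [assemble_system()].
#' @param tol relative residual tolerance.
#' @param max_iter iteration cap (default 10 * system size).
#' @param v0 optional warm-start velocities (3n vector).
#' @return n x 3 matrix of velocities (m s^-1).
#' @export
solve_velocities <- function(sys, tol = 1e-10, max_iter = NULL, v0 = NULL) {
  C <- sys$C; Fv <- sys$F
  nd <- length(Fv)
  if (is.null(max_iter)) max_iter <- max(100L, 10L * nd)
  nF <- sqrt(sum(Fv^2))
  if (nF == 0) return(matrix(0, nd / 3, 3, byrow = TRUE))
  v <- if (is.null(v0)) numeric(nd) else v0
  Dinv <- 1 / Matrix::diag(C)
  r <- Fv - as.vector(C %*% v)
  z <- Dinv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(r^2)) / nF <= tol) break
    Cp <- as.vector(C %*% p)
    alpha <- rz / sum(p * Cp)
    v <- v + alpha * p
    r <- r - alpha * Cp
    z <- Dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (sqrt(sum(r^2)) / nF > tol)
    stop("conjugate gradient failed to converge: relative residual ",
         signif(sqrt(sum(r^2)) / nF, 3), " after ", max_iter, " iterations")
  matrix(v, ncol = 3, byrow = TRUE)
}

#' Advance the state by one timestep (reference implementation)
#'
#' Computes all forces at the current state, solves the mobility system
#' (with the semi-implicit Hertz-stiffness correction when `lam > 0`) and
#' advances positions by x <- x + dt v, plus a sqrt(2 D) Wiener increment
#' when the thermal diffusivity D is positive. Radii and nanoparticle
#' counts are unchanged. This dense/R path is the reference oracle for the
#' compiled production engine.
#'
#' @param state an `mba_population` (optionally with a `velocities`
#'   element).
#' @param params,magnet,np,well model specification objects.
#' @param np_force optional function `(positions) -> n x 3` giving the
#'   per-nanoparticle magnetic force; defaults to the exact
#'   [single_np_force()]. Used to share the tabulated field with the
#'   compiled engine in equivalence checks.
#' @return the state with updated `positions` and `velocities`.
#' @export
step_state <- function(state, params, magnet, np, well, np_force = NULL) {
  forces <- if (is.null(np_force)) {
    force_decomposition(state, magnet, np, params, well)
  } else {
    fd <- force_decomposition(state, magnet, np, params, well)
    fd$F_mag <- state$np_counts * np_force(state$positions)
    fd
  }
  sys <- assemble_system(state, forces, params = params,
                         lam_dt = params$lam * params$dt)
  v <- solve_velocities(sys)
  state$positions <- state$positions + params$dt * v
  if (params$D > 0)
    state$positions <- state$positions +
      matrix(stats::rnorm(3 * state$n, 0, sqrt(2 * params$D * params$dt)),
             state$n, 3)
  state$velocities <- v
  state
}

#' Run a full bioassembly simulation
#'
#' Iterates the overdamped step from t = 0 to `t_end`, snapshotting the
#' full state (positions, velocities, per-spheroid force decomposition)
#' every `I_out` seconds and the area-coverage observable every
#' `kin_interval` seconds. The compiled engine evaluates the magnet field
#' through a precomputed axisymmetric lookup table (bilinear interpolation
#' on a 400 x 400 (rho, z) grid spanning the well) and detects contacts
#' with a uniform cell grid; velocities are solved by Jacobi-preconditioned
#' conjugate gradients warm-started from the previous step. An adaptive
#' sub-stepping guard splits any step whose largest displacement would
#' exceed 10% of the smallest radius.
#'
#' @param params,magnet,np,well model specification objects.
#' @param pop optional pre-built population; by default one is sampled
#'   with [sample_population()] and nanoparticle counts are allocated with
#'   [allocate_nanoparticles()] using `params$seed`.
#' @param n population size when `pop` is not supplied.
#' @param radius_mean,radius_cv radius distribution when sampling.
#' @param kin_interval coverage-sampling interval (s).
#' @param roi_radius coverage ROI radius (m); default the magnet footprint.
#' @param coverage_px coverage rasterization pixel (m); default r_min/10.
#' @param cg_tol conjugate-gradient relative tolerance.
#' @param substepping enable the adaptive sub-stepping stability guard.
#' @param verbose log per-snapshot progress.
#' @return list with `trajectory` (an `mba_trajectory`), `kinetics`
#'   (data.frame `time`, `coverage`), `final` (final state) and `params`.
#' @export
run_simulation <- function(params = sim_params(), magnet = magnet_spec(),
                           np = nanoparticle_spec(), well = well_geometry(),
                           pop = NULL, n = 1200, radius_mean = 100e-6,
                           radius_cv = 0.1, kin_interval = 0.05,
                           roi_radius = magnet$diameter / 2,
                           coverage_px = NULL, cg_tol = 1e-10,
                           substepping = TRUE, verbose = FALSE) {
  if (is.null(pop)) {
    pop <- sample_population(n, radius_mean, radius_cv, well,
                             seed = params$seed)
    if (params$m_NPtot > 0)
      pop <- allocate_nanoparticles(pop, params, np, seed = params$seed)
  }
  if (pop$n == 0) stop("cannot simulate an empty population")
  tab <- field_table(magnet, np, well, params)
  if (is.null(coverage_px)) coverage_px <- max(min(pop$radii) / 10, 1e-6)
  res <- cpp_run_simulation(
    pop$positions, pop$radii, as.numeric(pop$np_counts),
    tab,
    list(dt = params$dt, t_end = params$t_end, I_out = params$I_out,
         kin_interval = kin_interval, lam = params$lam, D = params$D,
         eta_m = params$eta_m, rho_s = params$rho_s, rho_m = params$rho_m,
         g = params$g, c_t = params$c_t, c_n = params$c_n,
         E_spheroid = params$E_spheroid, E_well = params$E_well,
         well_radius = well$radius, floor_z = well$floor_z,
         roi_radius = roi_radius, coverage_px = coverage_px,
         cg_tol = cg_tol, substep = as.numeric(substepping)),
    verbose)
  traj <- snapshots_to_trajectory(res$snapshots, res$times, pop,
                                  I_out = params$I_out)
  final <- pop
  final$positions <- res$snapshots[[length(res$snapshots)]]$positions
  final$velocities <- res$snapshots[[length(res$snapshots)]]$velocities
  list(trajectory = traj,
       kinetics = data.frame(time = res$kin_times,
                             coverage = res$kin_coverage),
       final = final, params = params)
}

#' Build the tabulated magnet field used by the compiled engine
#'
#' Precomputes the per-nanoparticle force ingredients (|H| and half the
#' gradient of |H|^2) of the axisymmetric cylinder field on a regular
#' (rho, z) grid covering the well, for bilinear interpolation at run
#' time.
#'
#' @param magnet,np,well,params model specification objects.
#' @param nr,nz grid resolution.
#' @return an opaque list consumed by the compiled engine and by
#'   [field_table_np_force()].
#' @export
field_table <- function(magnet, np, well, params, nr = 400, nz = 400) {
  if (magnet$Br <= 0 || params$m_NPtot == 0) {
    # null field: zero-force table
    return(cpp_field_table(magnet$diameter / 2, magnet$height / 2, 0,
                           params$mu0, np$V_NP, np$M_NP,
                           well$radius * 1.05, well$floor_z,
                           well$floor_z + well$height * 1.05,
                           8L, 8L, -magnet$gap - magnet$height / 2))
  }
  cpp_field_table(magnet$diameter / 2, magnet$height / 2, magnet$Br,
                  params$mu0, np$V_NP, np$M_NP,
                  well$radius * 1.05, well$floor_z,
                  well$floor_z + well$height * 1.05,
                  as.integer(nr), as.integer(nz),
                  -magnet$gap - magnet$height / 2)
}

#' Per-nanoparticle magnetic force from the tabulated field
#'
#' @param tab table from [field_table()].
#' @param positions n x 3 matrix of points (m).
#' @return n x 3 matrix of per-nanoparticle forces (N).
#' @export
field_table_np_force <- function(tab, positions) {
  cpp_field_np_force(tab, as.matrix(positions))
}

# convert compiled-engine snapshots into an mba_trajectory
snapshots_to_trajectory <- function(snapshots, times, pop, I_out) {
  rows <- lapply(seq_along(snapshots), function(s) {
    sn <- snapshots[[s]]
    data.table::data.table(
      time = times[s], id = seq_len(pop$n),
      x = sn$positions[, 1], y = sn$positions[, 2], z = sn$positions[, 3],
      r = pop$radii,
      vx = sn$velocities[, 1], vy = sn$velocities[, 2],
      vz = sn$velocities[, 3],
      n_np = as.numeric(pop$np_counts),
      fmx = sn$F_mag[, 1], fmy = sn$F_mag[, 2], fmz = sn$F_mag[, 3],
      fgz = sn$F_grav_z,
      fhx = sn$F_hertz[, 1], fhy = sn$F_hertz[, 2], fhz = sn$F_hertz[, 3])
  })
  trajectory(data.table::rbindlist(rows), I_out = I_out)
}
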