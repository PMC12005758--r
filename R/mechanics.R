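#' Magnetic body force on each spheroid
#'
#' The per-spheroid force scales the single-nanoparticle force at the
#' spheroid centre by its nanoparticle count:
#' F_m_i = N_NP_i * mu0 * V_NP * f(|H|) * (H.grad)H.
#'
#' @param pop an `mba_population` with `np_counts` assigned.
#' @param magnet an [magnet_spec()] object.
#' @param np an [nanoparticle_spec()] object.
#' @param params an [sim_params()] object.
#' @return n x 3 matrix of forces (N).
#' @export
magnetic_force <- function(pop, magnet, np, params) {
  if (pop$n == 0) return(matrix(numeric(0), 0, 3))
  f1 <- single_np_force(pop$positions, magnet, np, params)
  pop$np_counts * f1
}

#' Net gravitational force (weight minus buoyancy)
#'
#' F_g_i = (4/3) pi r_i^3 (rho_s - rho_m) g along -z.
#'
#' @param pop an `mba_population`.
#' @param params an [sim_params()] object.
#' @return n x 3 matrix of forces (N); only the z column is nonzero.
#' @export
gravity_buoyancy <- function(pop, params) {
  fz <- -4 / 3 * pi * pop$radii^3 * (params$rho_s - params$rho_m) * params$g
  cbind(0, 0, fz, deparse.level = 0)
}

#' Stokes drag coefficients
#'
#' gamma_i = 6 pi eta_m r_i; the drag force entering the mobility system
#' is -gamma_i v_i, opposing the motion.
#'
#' @param pop an `mba_population`.
#' @param params an [sim_params()] object.
#' @return numeric vector of length n (N s m^-1).
#' @export
stokes_drag_coefficient <- function(pop, params) {
  6 * pi * params$eta_m * pop$radii
}

# sentinel for wall contacts in the j column
WALL <- 0L

#' Detect sphere-sphere and sphere-wall contacts
#'
#' Sphere-sphere overlap delta_ij = r_i + r_j - |x_i - x_j| with contact
#' normal (x_i - x_j)/|x_i - x_j| (from j toward i); sphere-wall overlap
#' delta_iw = r_i - (x_i - x_w).n_w against the analytic cylinder (floor
#' plane and lateral wall), with the contact normal equal to the wall
#' normal pointing into the well. Pairs with delta >= 0 are returned.
#' Candidate sphere pairs come from a uniform cell grid (cell size twice
#' the largest radius), so the cost is near-linear in n.
#'
#' @param pop an `mba_population`.
#' @param well an [well_geometry()] object.
#' @return data.frame with columns `i`, `j` (`j = 0` denotes the wall),
#'   `delta` (m), `nx`, `ny`, `nz` (unit contact normal), `r_eff` (m) and
#'   `S` (contact area, m^2, pi * delta * r_eff).
#' @export
detect_contacts <- function(pop, well) {
  out <- list()
  n <- pop$n
  if (n > 0) {
    cell <- 2 * max(pop$radii)
    key <- floor(pop$positions / cell)
    kstr <- paste(key[, 1], key[, 2], key[, 3])
    buckets <- split(seq_len(n), kstr)
    lookup <- new.env(hash = TRUE, parent = emptyenv())
    for (k in names(buckets)) assign(k, buckets[[k]], envir = lookup)
    ii <- integer(0); jj <- integer(0)
    for (i in seq_len(n)) {
      kx <- key[i, 1]; ky <- key[i, 2]; kz <- key[i, 3]
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        k <- paste(kx + dx, ky + dy, kz + dz)
        cand <- if (exists(k, envir = lookup, inherits = FALSE))
          get(k, envir = lookup) else integer(0)
        cand <- cand[cand > i]
        if (length(cand)) { ii <- c(ii, rep(i, length(cand))); jj <- c(jj, cand) }
      }
    }
    if (length(ii)) {
      d <- pop$positions[ii, , drop = FALSE] - pop$positions[jj, , drop = FALSE]
      dist <- sqrt(rowSums(d^2))
      delta <- pop$radii[ii] + pop$radii[jj] - dist
      keep <- delta >= 0 & dist > 0
      if (any(keep)) {
        nrm <- d[keep, , drop = FALSE] / dist[keep]
        r_eff <- pop$radii[ii[keep]] * pop$radii[jj[keep]] /
          (pop$radii[ii[keep]] + pop$radii[jj[keep]])
        out$pairs <- data.frame(i = ii[keep], j = jj[keep],
                                delta = delta[keep],
                                nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
                                r_eff = r_eff)
      }
    }
    # floor: outward (into the well) normal +z
    dfloor <- pop$radii - (pop$positions[, 3] - well$floor_z)
    wf <- which(dfloor >= 0)
    if (length(wf))
      out$floor <- data.frame(i = wf, j = WALL, delta = dfloor[wf],
                              nx = 0, ny = 0, nz = 1,
                              r_eff = pop$radii[wf])
    # lateral wall: normal points toward the axis
    rho <- sqrt(pop$positions[, 1]^2 + pop$positions[, 2]^2)
    dlat <- pop$radii - (well$radius - rho)
    wl <- which(dlat >= 0 & rho > 0)
    if (length(wl))
      out$lateral <- data.frame(i = wl, j = WALL, delta = dlat[wl],
                                nx = -pop$positions[wl, 1] / rho[wl],
                                ny = -pop$positions[wl, 2] / rho[wl],
                                nz = 0, r_eff = pop$radii[wl])
  }
  res <- if (length(out)) do.call(rbind, unname(out))
  else data.frame(i = integer(0), j = integer(0), delta = numeric(0),
                  nx = numeric(0), ny = numeric(0), nz = numeric(0),
                  r_eff = numeric(0))
  res$S <- pi * res$delta * res$r_eff
  rownames(res) <- NULL
  res
}

# effective Hertz modulus: 1/E* = (1-nu^2)/E_a + (1-nu^2)/E_b, nu = 0.5
hertz_estar <- function(params, wall) {
  nu2 <- 0.25
  if (wall) 1 / ((1 - nu2) / params$E_spheroid + (1 - nu2) / params$E_well)
  else 1 / (2 * (1 - nu2) / params$E_spheroid)
}

#' Hertzian repulsion forces for a contact set
#'
#' F_H_ij = (4/3) E* sqrt(r_eff) delta^(3/2) n_ij acting on spheroid `i`
#' (and with opposite sign on `j`). The wall is treated as a body of
#' infinite radius, so r_eff = r_i there, with the well modulus entering
#' the effective stiffness.
#'
#' @param contacts contact table from [detect_contacts()].
#' @param params an [sim_params()] object.
#' @return the contact table with added columns `fx`, `fy`, `fz` (force on
#'   `i`, N) and `k` (contact stiffness dF/ddelta, N m^-1).
#' @export
hertz_forces <- function(contacts, params) {
  if (any(contacts$delta < 0)) stop("negative overlap in contact table")
  estar <- ifelse(contacts$j == WALL, hertz_estar(params, TRUE),
                  hertz_estar(params, FALSE))
  fmag <- 4 / 3 * estar * sqrt(contacts$r_eff) * contacts$delta^1.5
  contacts$fx <- fmag * contacts$nx
  contacts$fy <- fmag * contacts$ny
  contacts$fz <- fmag * contacts$nz
  contacts$k <- 2 * estar * sqrt(contacts$r_eff * pmax(contacts$delta, 0))
  contacts
}

#' Contact-damping tensors
#'
#' For each contact, B = S * (c_t I + (c_n - c_t) n n^T), so that the
#' contact drag force is F_c = -B v_rel. Symmetric positive semidefinite
#' for non-negative damping coefficients, with eigenvalues
#' {S c_n, S c_t, S c_t}.
#'
#' @param contacts contact table from [detect_contacts()] (column `S`
#'   required).
#' @param params an [sim_params()] object.
#' @return a 3 x 3 x n_contacts array.
#' @export
contact_damping_blocks <- function(contacts, params) {
  m <- nrow(contacts)
  out <- array(0, c(3, 3, m))
  for (k in seq_len(m)) {
    nrm <- c(contacts$nx[k], contacts$ny[k], contacts$nz[k])
    out[, , k] <- contacts$S[k] *
      (params$c_t * diag(3) +
         (params$c_n - params$c_t) * tcrossprod(nrm))
  }
  out
}

#' Full force decomposition for a population state
#'
#' @param pop an `mba_population` with `np_counts` assigned.
#' @param magnet,np,params,well model specification objects.
#' @param contacts optional precomputed contact table.
#' @return list with `F_mag`, `F_grav`, `F_hertz` (n x 3 matrices, N),
#'   `gamma` (Stokes coefficients) and the augmented `contacts` table.
#' @export
force_decomposition <- function(pop, magnet, np, params, well,
                                contacts = NULL) {
  if (is.null(contacts)) contacts <- detect_contacts(pop, well)
  contacts <- hertz_forces(contacts, params)
  Fh <- matrix(0, pop$n, 3)
  for (k in seq_len(nrow(contacts))) {
    f <- c(contacts$fx[k], contacts$fy[k], contacts$fz[k])
    i <- contacts$i[k]; j <- contacts$j[k]
    Fh[i, ] <- Fh[i, ] + f
    if (j != WALL) Fh[j, ] <- Fh[j, ] - f
  }
  list(F_mag = magnetic_force(pop, magnet, np, params),
       F_grav = gravity_buoyancy(pop, params),
       F_hertz = Fh,
       gamma = stokes_drag_coefficient(pop, params),
       contacts = contacts)
}
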