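#' @useDynLib magassembly, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Bulirsch's generalized complete elliptic integral cel(kc, p, a, b).
# Scalar, kc != 0. Used by the axisymmetric cylinder-field evaluation.
cel_r <- function(kc, p, a, b) {
  if (kc == 0) return(NaN)
  errtol <- 1e-12
  k <- abs(kc); pp <- p; aa <- a; bb <- b; em <- 1.0
  if (p > 0) {
    pp <- sqrt(p); bb <- b / pp
  } else {
    f <- kc * kc; q <- 1 - f; g <- 1 - pp
    f <- f - pp; q <- q * (b - a * pp)
    pp <- sqrt(f / g); aa <- (a - b) / g
    bb <- -q / (g * g * pp) + aa * pp
  }
  f <- aa; aa <- aa + bb / pp; g <- k / pp
  bb <- 2 * (bb + f * g); pp <- g + pp
  g <- em; em <- k + em; kk <- k
  while (abs(g - k) > g * errtol) {
    k <- 2 * sqrt(kk)
    kk <- k * em
    f <- aa; aa <- aa + bb / pp
    g <- kk / pp; bb <- 2 * (bb + f * g)
    pp <- g + pp; g <- em; em <- k + em
  }
  (pi / 2) * (bb + aa * em) / (em * (em + pp))
}

# (B_rho, B_z) of a uniformly axially magnetized cylinder in its own frame:
# radius a, half-length hb, centered at the origin, remanence Br.
cyl_B_axisym <- function(rho, z, a, hb, Br) {
  rho <- abs(rho)
  zp <- z + hb; zm <- z - hb
  rp <- sqrt(zp^2 + (rho + a)^2); rm <- sqrt(zm^2 + (rho + a)^2)
  gam <- (a - rho) / (a + rho)
  kp <- sqrt((zp^2 + (a - rho)^2)) / rp
  km <- sqrt((zm^2 + (a - rho)^2)) / rm
  B0 <- Br / pi
  Brho <- B0 * ((a / rp) * cel_r(kp, 1, 1, -1) -
                (a / rm) * cel_r(km, 1, 1, -1))
  Bz <- B0 * a / (a + rho) * ((zp / rp) * cel_r(kp, gam^2, 1, gam) -
                              (zm / rm) * cel_r(km, gam^2, 1, gam))
  c(Brho, Bz)
}

# transform a lab-frame point into the magnet frame -> list(rho, zr, rho_hat)
magnet_frame <- function(point, magnet) {
  center <- magnet$top_face_center - magnet$axis * magnet$height / 2
  d <- point - center
  zr <- sum(d * magnet$axis)
  perp <- d - zr * magnet$axis
  rho <- sqrt(sum(perp^2))
  rho_hat <- if (rho > 0) perp / rho else c(0, 0, 0)
  list(rho = rho, zr = zr, rho_hat = rho_hat)
}

inside_magnet <- function(rho, zr, magnet) {
  rho < magnet$diameter / 2 & abs(zr) < magnet$height / 2
}

#' Magnetic field of the cylindrical permanent magnet
#'
#' Evaluates the field of a uniformly axially magnetized cylinder at one or
#' more points, using the generalized complete elliptic integral form of
#' the equivalent-solenoid field. Returns the field strength `H` (A m^-1),
#' the flux density `B` (T) and the gradient term `gradH_H` = (H.grad)H
#' (A^2 m^-3). In the current-free exterior (H.grad)H equals half the
#' gradient of |H|^2, and the latter is what is evaluated, by central
#' finite differences of |H|^2 in the axisymmetric (rho, z) plane with
#' step 1e-7 m.
#'
#' @param point numeric 3-vector, or an n x 3 matrix of points (m), in
#'   well-floor coordinates.
#' @param magnet an [magnet_spec()] object.
#' @param mu0 vacuum permeability used to convert B to H (N A^-2).
#' @return For a single point, a list with 3-vectors `H`, `gradH_H`, `B`;
#'   for a matrix of points, a list of n x 3 matrices.
#' @export
cylinder_field <- function(point, magnet, mu0 = 1.256e-6) {
  single <- is.null(dim(point))
  pts <- if (single) matrix(point, 1, 3) else as.matrix(point)
  stopifnot(ncol(pts) == 3)
  a <- magnet$diameter / 2
  hb <- magnet$height / 2
  n <- nrow(pts)
  H <- matrix(0, n, 3); B <- matrix(0, n, 3); G <- matrix(0, n, 3)
  h <- 1e-7  # finite-difference step (m); field varies on the mm scale
  U <- function(rho, z) {  # |B|^2 in the magnet frame
    b2 <- cyl_B_axisym(rho, z, a, hb, magnet$Br)
    b2[1]^2 + b2[2]^2
  }
  for (i in seq_len(n)) {
    fr <- magnet_frame(pts[i, ], magnet)
    if (inside_magnet(fr$rho, fr$zr, magnet))
      stop("point ", i, " lies inside the magnet volume")
    bv <- cyl_B_axisym(fr$rho, fr$zr, a, hb, magnet$Br)
    Bvec <- bv[1] * fr$rho_hat + bv[2] * magnet$axis
    B[i, ] <- Bvec
    H[i, ] <- Bvec / mu0
    dU_drho <- (U(fr$rho + h, fr$zr) - U(fr$rho - h, fr$zr)) / (2 * h)
    dU_dz <- (U(fr$rho, fr$zr + h) - U(fr$rho, fr$zr - h)) / (2 * h)
    # 0.5 * grad|H|^2 = 0.5 * grad|B|^2 / mu0^2
    G[i, ] <- 0.5 * (dU_drho * fr$rho_hat + dU_dz * magnet$axis) / mu0^2
  }
  if (single) list(H = H[1, ], gradH_H = G[1, ], B = B[1, ])
  else list(H = H, gradH_H = G, B = B)
}

#' Magnetization factor of a superparamagnetic nanoparticle
#'
#' Piecewise model of the effective susceptibility entering the single-MNP
#' force: f(H) = 3 below saturation (|H| < M_NP/3, the high-susceptibility
#' sphere limit) and M_NP/|H| above it, so that f(H) * H saturates at the
#' volumetric saturation magnetization M_NP. Continuous at the branch
#' point.
#'
#' @param H_mag field strength magnitude(s), A m^-1, >= 0.
#' @param np an [nanoparticle_spec()] object.
#' @return dimensionless factor(s), same length as `H_mag`.
#' @export
magnetization_factor <- function(H_mag, np) {
  if (any(H_mag < 0)) stop("H_mag must be >= 0")
  ifelse(H_mag < np$M_NP / 3, 3, np$M_NP / pmax(H_mag, .Machine$double.xmin))
}

#' Magnetic force on a single nanoparticle
#'
#' F = mu0 * V_NP * f(|H|) * (H.grad)H, evaluated through the
#' half-grad-|H|^2 identity valid in the current-free exterior of the
#' magnet. Zero where H vanishes; in the saturated region the magnitude is
#' mu0 * V_NP * M_NP * |grad|H|| independent of further field growth.
#'
#' @param point 3-vector or n x 3 matrix of evaluation points (m).
#' @param magnet an [magnet_spec()] object.
#' @param np an [nanoparticle_spec()] object.
#' @param params an [sim_params()] object (supplies mu0).
#' @return force 3-vector (N), or n x 3 matrix.
#' @export
single_np_force <- function(point, magnet, np, params) {
  fs <- cylinder_field(point, magnet, mu0 = params$mu0)
  if (is.null(dim(fs$H))) {
    Hmag <- sqrt(sum(fs$H^2))
    params$mu0 * np$V_NP * magnetization_factor(Hmag, np) * fs$gradH_H
  } else {
    Hmag <- sqrt(rowSums(fs$H^2))
    params$mu0 * np$V_NP * magnetization_factor(Hmag, np) * fs$gradH_H
  }
}
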