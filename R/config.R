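#' Simulation parameters
#'
#' Bundles every physical and numerical constant of the overdamped
#' bioassembly model. Defaults reproduce the published model-parameter table:
#' a 5e-5 s timestep, water-like medium (viscosity 1.2e-3 Pa s, density
#' 1000 kg m^-3), spheroid density 1014 kg m^-3, soft Hertzian contacts
#' (spheroid modulus 120 Pa, well modulus 1000 Pa), contact damping
#' c_t = c_n = 0.6 Pa s m^-1, a 60 s simulated window with 1 s output
#' cadence, fully explicit integration (lam = 0) and nanoparticle absorption
#' fraction alpha = 0.75.
#'
#' @param dt timestep (s).
#' @param mu0 vacuum permeability (N A^-2).
#' @param mu_r relative permeability of the medium (water = 1).
#' @param g gravitational acceleration (m s^-2).
#' @param eta_m medium dynamic viscosity (Pa s).
#' @param rho_m medium density (kg m^-3).
#' @param rho_s spheroid density (kg m^-3).
#' @param E_well elastic modulus of the well material (Pa).
#' @param sigma_adh spheroid-well adhesion energy density (N m^-1). Stored
#'   for fidelity with the published parameter table; no adhesion force is
#'   applied (the value is numerically negligible and the force law is not
#'   part of the model equations).
#' @param c_t tangential contact damping (Pa s m^-1).
#' @param c_n normal contact damping (Pa s m^-1).
#' @param E_spheroid spheroid elastic modulus (Pa).
#' @param t_end simulated time (s).
#' @param m_NPtot total nanoparticle mass added to the well (kg). The two
#'   published loading conditions ("30" and "60" ug Fe per mL incubation)
#'   correspond to 10 ug and 20 ug total added mass; see [mnp_total_mass()].
#' @param I_out trajectory snapshot interval (s).
#' @param lam degree of implicitness of the semi-implicit integrator, in
#'   \[0, 1\]; 0 = fully explicit.
#' @param alpha fraction of added nanoparticles absorbed onto spheroid
#'   surfaces, in \[0, 1\].
#' @param D thermal diffusivity of the spheroids (m^2 s^-1); thermal forces
#'   are negligible for radii above 100 um, so the default is 0 and the
#'   Wiener increment in the position update is inert.
#' @param seed integer RNG seed.
#' @return An object of class `mba_params` (named list).
#' @export
sim_params <- function(dt = 5e-5, mu0 = 1.256e-6, mu_r = 1, g = 9.807,
                       eta_m = 1.2e-3, rho_m = 1000, rho_s = 1014,
                       E_well = 1000, sigma_adh = 1e-20, c_t = 0.6,
                       c_n = 0.6, E_spheroid = 120, t_end = 60,
                       m_NPtot = 10e-9, I_out = 1, lam = 0, alpha = 0.75,
                       D = 0, seed = 1L) {
  p <- list(dt = dt, mu0 = mu0, mu_r = mu_r, g = g, eta_m = eta_m,
            rho_m = rho_m, rho_s = rho_s, E_well = E_well,
            sigma_adh = sigma_adh, c_t = c_t, c_n = c_n,
            E_spheroid = E_spheroid, t_end = t_end, m_NPtot = m_NPtot,
            I_out = I_out, lam = lam, alpha = alpha, D = D,
            seed = as.integer(seed))
  class(p) <- "mba_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid parameter '", field, "': ", why,
                          call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in setdiff(names(p), "seed")) chk(num1(p[[f]]), f, "must be a finite number")
  chk(p$dt > 0, "dt", "timestep must be > 0")
  chk(p$eta_m > 0, "eta_m", "viscosity must be > 0")
  chk(p$rho_m > 0, "rho_m", "medium density must be > 0")
  chk(p$rho_s > 0, "rho_s", "spheroid density must be > 0")
  chk(p$mu0 > 0, "mu0", "must be > 0")
  chk(p$E_well > 0, "E_well", "must be > 0")
  chk(p$E_spheroid > 0, "E_spheroid", "must be > 0")
  chk(p$c_t >= 0, "c_t", "must be >= 0")
  chk(p$c_n >= 0, "c_n", "must be >= 0")
  chk(p$alpha >= 0 && p$alpha <= 1, "alpha", "must lie in [0, 1]")
  chk(p$lam >= 0 && p$lam <= 1, "lam", "must lie in [0, 1]")
  chk(p$I_out >= p$dt, "I_out", "output interval must be >= dt")
  chk(p$t_end >= 0, "t_end", "must be >= 0")
  chk(p$m_NPtot >= 0, "m_NPtot", "must be >= 0")
  chk(p$D >= 0, "D", "must be >= 0")
  invisible(p)
}

#' Total MNP mass for a named loading condition
#'
#' The loading conditions are named by incubation concentration (30 or
#' 60 ug Fe per mL) but the model uses the total added masses from the
#' parameter table: 10 ug and 20 ug respectively.
#'
#' @param condition `"30"` or `"60"` (character or numeric).
#' @return total added MNP mass in kg.
#' @export
mnp_total_mass <- function(condition) {
  key <- as.character(condition)
  masses <- c("30" = 10e-9, "60" = 20e-9)
  if (!key %in% names(masses))
    stop("unknown MNP loading condition '", key, "' (expected \"30\" or \"60\")")
  unname(masses[key])
}

#' Nanoparticle specification
#'
#' @param r_NP nanoparticle radius (m); default 3e-9 (6 nm diameter
#'   magnetite cores).
#' @param M_sat_mass saturation magnetization per unit mass (emu g^-1,
#'   i.e. A m^2 kg^-1); default 60.
#' @param rho_NP nanoparticle material density (kg m^-3); default 5180
#'   (magnetite).
#' @return An object of class `mba_np` with derived fields `V_NP`
#'   (particle volume, m^3) and `M_NP` (volumetric saturation
#'   magnetization, A m^-1).
#' @export
nanoparticle_spec <- function(r_NP = 3e-9, M_sat_mass = 60, rho_NP = 5180) {
  if (!is.numeric(r_NP) || r_NP <= 0) stop("invalid parameter 'r_NP': must be > 0")
  if (!is.numeric(M_sat_mass) || M_sat_mass <= 0)
    stop("invalid parameter 'M_sat_mass': must be > 0")
  if (!is.numeric(rho_NP) || rho_NP <= 0)
    stop("invalid parameter 'rho_NP': must be > 0")
  np <- list(r_NP = r_NP, M_sat_mass = M_sat_mass, rho_NP = rho_NP,
             V_NP = 4 / 3 * pi * r_NP^3,
             # emu g^-1 == A m^2 kg^-1, so volumetric M [A m^-1] = Msat * rho
             M_NP = M_sat_mass * rho_NP)
  class(np) <- "mba_np"
  np
}

#' Cylindrical permanent-magnet specification
#'
#' Default geometry is the 5 mm x 5 mm NdFeB magnet with remanence
#' 1.48 T (14800 Gauss). The magnet sits below the well floor with its
#' axis through the well centre; `gap` is the distance from the magnet's
#' top face to the well floor (plate-bottom thickness), which is not a
#' published quantity. When `gap = NULL` it is calibrated so that the
#' on-axis flux density at the well floor equals `floor_B` (0.4 T, the
#' measured maximum at the bottom of the well). Alternatively, fix the gap
#' and set `calibrate = "remanence"` to rescale Br to meet `floor_B`.
#'
#' @param diameter magnet diameter (m).
#' @param height magnet height (m).
#' @param Br remanent flux density (T).
#' @param gap magnet top face to well floor distance (m), or `NULL` to
#'   calibrate it from `floor_B`.
#' @param floor_B target on-axis flux density at the well floor (T) used
#'   for calibration; set `NULL` to skip calibration (requires `gap`).
#' @param calibrate `"gap"` (default) or `"remanence"`.
#' @param axis unit magnetization axis (default +z).
#' @return An object of class `mba_magnet`. `top_face_center` is derived
#'   as `c(0, 0, -gap)` in well-floor coordinates (origin at the floor
#'   centre, z up).
#' @export
magnet_spec <- function(diameter = 5e-3, height = 5e-3, Br = 1.48,
                        gap = NULL, floor_B = 0.4,
                        calibrate = c("gap", "remanence"),
                        axis = c(0, 0, 1)) {
  calibrate <- match.arg(calibrate)
  if (!is.numeric(diameter) || diameter <= 0)
    stop("invalid parameter 'diameter': must be > 0")
  if (!is.numeric(height) || height <= 0)
    stop("invalid parameter 'height': must be > 0")
  if (!is.numeric(Br) || Br <= 0) stop("invalid parameter 'Br': must be > 0")
  if (length(axis) != 3 || sqrt(sum(axis^2)) == 0)
    stop("invalid parameter 'axis': must be a nonzero 3-vector")
  axis <- axis / sqrt(sum(axis^2))
  a <- diameter / 2
  onaxis <- function(d, br) {
    # flux density a distance d above the top face, on axis
    br / 2 * ((d + height) / sqrt((d + height)^2 + a^2) - d / sqrt(d^2 + a^2))
  }
  if (is.null(gap)) {
    if (is.null(floor_B))
      stop("either 'gap' or 'floor_B' must be given")
    if (floor_B >= onaxis(1e-9, Br))
      stop("floor_B unreachable: exceeds the field at the magnet face")
    gap <- stats::uniroot(function(d) onaxis(d, Br) - floor_B,
                          c(1e-9, 50 * height), tol = 1e-14)$root
  } else if (calibrate == "remanence" && !is.null(floor_B)) {
    Br <- Br * floor_B / onaxis(gap, Br)
  }
  m <- list(diameter = diameter, height = height, Br = Br, gap = gap,
            top_face_center = c(0, 0, -gap), axis = axis)
  class(m) <- "mba_magnet"
  m
}

#' Cylindrical well geometry
#'
#' The well interior is `{rho < radius, floor_z <= z <= floor_z + height}`
#' with the axis coincident with the magnet axis. Default radius 7.8 mm
#' (nominal 24-well plate) and 5 mm medium fill height; the simulation well
#' radius is not a published quantity.
#'
#' @param radius well radius (m).
#' @param height medium fill height (m).
#' @param floor_z floor elevation (m); the coordinate convention puts the
#'   origin at the floor centre, so the default is 0.
#' @return An object of class `mba_well`.
#' @export
well_geometry <- function(radius = 7.8e-3, height = 5e-3, floor_z = 0) {
  if (!is.numeric(radius) || radius <= 0)
    stop("invalid parameter 'radius': must be > 0")
  if (!is.numeric(height) || height <= 0)
    stop("invalid parameter 'height': must be > 0")
  w <- list(radius = radius, height = height, floor_z = floor_z)
  class(w) <- "mba_well"
  w
}

#' Load a simulation configuration
#'
#' Reads a YAML key-value file with optional sections `params`,
#' `nanoparticle`, `magnet` and `well`. Every missing key takes its
#' documented default (the published parameter table for `params`); every
#' present key overrides it. `params$condition` ("30"/"60") may be given
#' instead of `m_NPtot` and is mapped through [mnp_total_mass()]. All
#' quantities are SI (masses in kg, lengths in m, fields in T).
#'
#' @param path path to the configuration file. An empty or missing-section
#'   file yields the full default bundle.
#' @return A list with elements `params`, `np`, `magnet`, `well`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config parse error: top level must be a mapping")
  take <- function(section, fn, extra_ok = character()) {
    args <- cfg[[section]]
    if (is.null(args)) args <- list()
    known <- c(names(formals(fn)), extra_ok)
    bad <- setdiff(names(args), known)
    if (length(bad))
      stop("unknown key(s) in section '", section, "': ",
           paste(bad, collapse = ", "))
    args
  }
  pa <- take("params", sim_params, "condition")
  if (!is.null(pa$condition)) {
    if (is.null(pa$m_NPtot)) pa$m_NPtot <- mnp_total_mass(pa$condition)
    pa$condition <- NULL
  }
  params <- do.call(sim_params, pa)
  np <- do.call(nanoparticle_spec, take("nanoparticle", nanoparticle_spec))
  magnet <- do.call(magnet_spec, take("magnet", magnet_spec))
  well <- do.call(well_geometry, take("well", well_geometry))
  list(params = params, np = np, magnet = magnet, well = well)
}

#' Write a configuration bundle back to YAML
#'
#' Inverse of [load_config()]: `load_config(dump_config(b, f))` is the
#' identity on all fields.
#'
#' @param bundle a list as returned by [load_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(bundle, path) {
  strip <- function(x, drop = character()) {
    x <- unclass(x)
    x[setdiff(names(x), drop)]
  }
  out <- list(
    params = strip(bundle$params),
    nanoparticle = strip(bundle$np, drop = c("V_NP", "M_NP")),
    # gap is persisted explicitly so a re-load does not re-calibrate
    magnet = c(strip(bundle$magnet, drop = "top_face_center")["diameter"],
               strip(bundle$magnet)["height"],
               strip(bundle$magnet)["Br"],
               strip(bundle$magnet)["gap"],
               list(floor_B = NULL),
               strip(bundle$magnet)["axis"]),
    well = strip(bundle$well))
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}
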