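#' Sample a spheroid population in a cylindrical well
#'
#' Radii are drawn from a lognormal with the requested arithmetic mean and
#' coefficient of variation; centres are uniform in the well interior with
#' full-sphere containment and rejection of any pairwise overlap beyond
#' `overlap_tol`. Defaults mirror the experimental well loading: ~1200
#' microtissues (300,000 cells per well at ~250 cells per microtissue) of
#' mean radius 100 um.
#'
#' @param n number of spheroids (>= 0).
#' @param radius_mean arithmetic mean radius (m).
#' @param radius_cv coefficient of variation of the radius, in \[0, 1).
#' @param well an [well_geometry()] object.
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   populations.
#' @param overlap_tol maximum tolerated pairwise overlap at initialisation
#'   (m); candidate positions violating it are re-drawn.
#' @param max_tries rejection-sampling attempts per spheroid before giving
#'   up.
#' @return An object of class `mba_population`: list with `n`, `positions`
#'   (n x 3, m), `radii` (n, m), `np_counts` (n, integer, initially 0).
#' @export
sample_population <- function(n, radius_mean = 100e-6, radius_cv = 0.1,
                              well = well_geometry(), seed = 1L,
                              overlap_tol = 0, max_tries = 2000L) {
  stopifnot(n >= 0, radius_mean > 0, radius_cv >= 0, radius_cv < 1)
  if (n == 0) {
    pop <- list(n = 0L, positions = matrix(numeric(0), 0, 3),
                radii = numeric(0), np_counts = integer(0))
    class(pop) <- "mba_population"
    return(pop)
  }
  sphere_vol <- n * 4 / 3 * pi * radius_mean^3
  well_vol <- pi * well$radius^2 * well$height
  if (sphere_vol / well_vol > 0.5)
    stop("packing infeasible: requested volume fraction ",
         signif(sphere_vol / well_vol, 3), " exceeds 0.5")
  set.seed(seed)
  sdlog <- sqrt(log(1 + radius_cv^2))
  meanlog <- log(radius_mean) - sdlog^2 / 2
  radii <- stats::rlnorm(n, meanlog, sdlog)
  pos <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      # uniform over the disk by sqrt-radius, uniform in z; full containment
      rmax <- well$radius - radii[i]
      if (rmax <= 0) stop("spheroid ", i, " larger than the well radius")
      rho <- rmax * sqrt(stats::runif(1))
      phi <- stats::runif(1, 0, 2 * pi)
      z <- stats::runif(1, well$floor_z + radii[i],
                        well$floor_z + well$height - radii[i])
      cand <- c(rho * cos(phi), rho * sin(phi), z)
      if (i == 1) ok <- TRUE
      else {
        d2 <- colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - cand)^2)
        ok <- all(sqrt(d2) >= radii[seq_len(i - 1)] + radii[i] - overlap_tol)
      }
      if (ok) { pos[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop("packing failed for spheroid ", i, " after ",
                      max_tries, " attempts")
  }
  pop <- list(n = as.integer(n), positions = pos, radii = radii,
              np_counts = integer(n))
  class(pop) <- "mba_population"
  pop
}

#' Total number of nanoparticles added to the well
#'
#' N_NPtot = m_NPtot / (V_NP * rho_NP); real-valued, rounding is deferred
#' to the per-spheroid allocation.
#'
#' @param params an [sim_params()] object (`m_NPtot` in kg).
#' @param np an [nanoparticle_spec()] object.
#' @return real-valued particle count.
#' @export
total_np_count <- function(params, np) {
  if (params$m_NPtot <= 0) stop("m_NPtot must be > 0")
  params$m_NPtot / (np$V_NP * np$rho_NP)
}

#' Allocate nanoparticles to spheroid surfaces
#'
#' Each spheroid's expected count is the absorbed total scaled by its share
#' of the population surface area, mu_i = alpha * N_NPtot * A_i / A_tot
#' with A_i = 4 pi r_i^2. The realised count is drawn from
#' Normal(mu_i, sd = mu_i / 2) — the standard deviation equals half the
#' mean — truncated at zero and rounded to an integer.
#'
#' @param pop an `mba_population`.
#' @param params an [sim_params()] object (`alpha`, `m_NPtot`).
#' @param np an [nanoparticle_spec()] object.
#' @param seed integer RNG seed.
#' @return the population with `np_counts` filled in.
#' @export
allocate_nanoparticles <- function(pop, params, np, seed = 1L) {
  if (pop$n == 0) stop("population is empty")
  if (params$alpha < 0 || params$alpha > 1) stop("alpha must lie in [0, 1]")
  A <- 4 * pi * pop$radii^2
  mu <- params$alpha * total_np_count(params, np) * A / sum(A)
  set.seed(seed)
  draws <- stats::rnorm(pop$n, mean = mu, sd = mu / 2)
  pop$np_counts <- round(pmax(draws, 0))
  pop
}

#' Synthetic SQUID hysteresis curve
#'
#' Moment(H) = fe_mass * reference_Msat * L(H / H_scale) with L the
#' Langevin function, plus iid Gaussian noise. A zero iron mass yields the
#' flat (noise-only) curve of a control sample; the noiseless curve has
#' odd symmetry m(-H) = -m(H) and saturates at fe_mass * reference_Msat.
#'
#' @param fe_mass Fe3O4 mass in the sample (g, >= 0).
#' @param reference_Msat reference saturation magnetization (emu g^-1).
#' @param field_grid applied-field grid (T); must be non-empty.
#' @param noise_sd Gaussian noise on the moment (emu).
#' @param seed integer RNG seed.
#' @param sample_mass dry sample mass (g), carried for per-mass reporting.
#' @param H_scale Langevin field scale (T); a fixture shape parameter, not
#'   a measured quantity.
#' @param label curve label.
#' @return An object of class `mba_hysteresis`: list with `field`,
#'   `moment`, `sample_mass`, `label`.
#' @export
synth_hysteresis <- function(fe_mass, reference_Msat = 60,
                             field_grid = seq(-7, 7, length.out = 141),
                             noise_sd = 0, seed = 1L, sample_mass = 0.01,
                             H_scale = 0.05, label = "synthetic") {
  if (fe_mass < 0) stop("fe_mass must be >= 0")
  if (length(field_grid) == 0) stop("field_grid must be non-empty")
  langevin <- function(x) {
    out <- numeric(length(x))
    big <- abs(x) > 1e-4
    out[big] <- 1 / tanh(x[big]) - 1 / x[big]
    out[!big] <- x[!big] / 3  # series limit, avoids 0/0 at H = 0
    out
  }
  moment <- fe_mass * reference_Msat * langevin(field_grid / H_scale)
  if (noise_sd > 0) {
    set.seed(seed)
    moment <- moment + stats::rnorm(length(field_grid), 0, noise_sd)
  }
  hysteresis_curve(field_grid, moment, sample_mass, label)
}

#' Construct a hysteresis curve object
#'
#' @param field applied field (T); must span negative and positive values.
#' @param moment magnetic moment (emu), same length as `field`.
#' @param sample_mass dry sample mass (g), > 0.
#' @param label curve label.
#' @return An object of class `mba_hysteresis`.
#' @export
hysteresis_curve <- function(field, moment, sample_mass = 0.01,
                             label = "") {
  if (length(field) != length(moment))
    stop("field and moment must have equal length")
  if (length(field) >= 3 && (min(field) >= 0 || max(field) <= 0))
    stop("field grid must span negative and positive values")
  if (sample_mass <= 0) stop("sample_mass must be > 0")
  h <- list(field = as.numeric(field), moment = as.numeric(moment),
            sample_mass = sample_mass, label = label)
  class(h) <- "mba_hysteresis"
  h
}

#' Synthetic oriented-fiber image
#'
#' A sinusoidal stripe texture at a prescribed orientation plus Gaussian
#' noise, used as ground truth for the FFT directionality analysis. The
#' angle follows the image-analysis convention: the fiber direction in
#' degrees on \[0, 180), measured from the +x axis.
#'
#' @param size image side length (pixels).
#' @param angle fiber angle (degrees in \[0, 180)).
#' @param wavelength stripe wavelength (pixels).
#' @param contrast stripe amplitude (gray levels); 0 gives pure noise.
#' @param noise_sd Gaussian noise SD (gray levels).
#' @param seed integer RNG seed.
#' @return `size` x `size` numeric matrix.
#' @export
synth_fiber_image <- function(size = 256, angle = 45, wavelength = 12,
                              contrast = 1, noise_sd = 0, seed = 1L) {
  if (angle < 0 || angle >= 180) stop("angle must lie in [0, 180)")
  if (size < 8) stop("size too small")
  th <- angle * pi / 180
  # stripes along the fiber direction: intensity varies perpendicular to it
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), times = size), size, size)
  phase <- (-sin(th) * xs + cos(th) * ys) * 2 * pi / wavelength
  img <- contrast * sin(phase)
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(size^2, 0, noise_sd), size, size)
  }
  img
}
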