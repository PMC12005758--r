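#' Saturation moment of a hysteresis curve
#'
#' Mean of the absolute moments linearly interpolated at the positive and
#' negative read-off fields (default +/-7 T, the edge of the measured
#' range).
#'
#' @param curve an `mba_hysteresis` object.
#' @param at_field read-off field magnitude (T); must lie within the
#'   measured range on both sides.
#' @return saturation moment (emu).
#' @export
saturation_moment <- function(curve, at_field = 7) {
  rng <- range(curve$field)
  if (at_field > rng[2] || -at_field < rng[1])
    stop("read-off field ", at_field, " T outside the measured range [",
         rng[1], ", ", rng[2], "]")
  ord <- order(curve$field)
  f <- curve$field[ord]; m <- curve$moment[ord]
  mp <- stats::approx(f, m, xout = at_field, ties = mean)$y
  mm <- stats::approx(f, m, xout = -at_field, ties = mean)$y
  (abs(mp) + abs(mm)) / 2
}

# odd-symmetric saturation read-off (m(+f) - m(-f))/2: exactly invariant
# to any additive baseline shared by sample and control
saturation_moment_odd <- function(curve, at_field = 7) {
  rng <- range(curve$field)
  if (at_field > rng[2] || -at_field < rng[1])
    stop("read-off field ", at_field, " T outside the measured range")
  ord <- order(curve$field)
  f <- curve$field[ord]; m <- curve$moment[ord]
  mp <- stats::approx(f, m, xout = at_field, ties = mean)$y
  mm <- stats::approx(f, m, xout = -at_field, ties = mean)$y
  (mp - mm) / 2
}

#' Fe3O4 content of a sample from hysteresis curves
#'
#' The sample's background-corrected saturation moment (sample minus
#' control, each read off as the odd-symmetric moment at the saturation
#' field) is converted to mass through the reference-powder saturation
#' magnetization. The odd-symmetric read-off makes the result exactly
#' invariant to any additive background curve shared by sample and
#' control. Negative corrected moments are clipped to 0 with a warning.
#'
#' @param sample,control `mba_hysteresis` objects; their field grids need
#'   not match (each is interpolated at the read-off fields).
#' @param reference_Msat reference-powder saturation magnetization
#'   (emu g^-1).
#' @param at_field read-off field (T).
#' @return Fe3O4 mass in micrograms.
#' @export
fe_content <- function(sample, control, reference_Msat = 60, at_field = 7) {
  if (reference_Msat <= 0) stop("reference_Msat must be > 0")
  dm <- saturation_moment_odd(sample, at_field) -
    saturation_moment_odd(control, at_field)
  if (dm < 0) {
    warning("corrected saturation moment is negative; clipping mass to 0")
    dm <- 0
  }
  dm / reference_Msat * 1e6  # g -> ug
}

#' Percent reduction between two mass measurements
#'
#' 100 * (1 - after/before), rounded to the nearest integer percent for
#' reporting.
#'
#' @param mass_before mass at the earlier timepoint (> 0), ug.
#' @param mass_after mass at the later timepoint (>= 0), ug.
#' @param digits rounding digits (0 = integer percent, the reporting
#'   convention).
#' @return percent reduction.
#' @export
percent_reduction <- function(mass_before, mass_after, digits = 0) {
  if (mass_before <= 0) stop("mass_before must be > 0")
  if (mass_after < 0) stop("mass_after must be >= 0")
  round(100 * (1 - mass_after / mass_before), digits)
}

#' Read a hysteresis curve from a two-column CSV
#'
#' Expected columns: `field_T`, `moment_emu` (header required).
#'
#' @param path CSV file.
#' @param sample_mass dry sample mass (g).
#' @param label curve label (defaults to the file name).
#' @return an `mba_hysteresis` object.
#' @export
read_hysteresis <- function(path, sample_mass = 0.01, label = NULL) {
  if (!file.exists(path)) stop("hysteresis file not found: ", path)
  d <- utils::read.csv(path)
  need <- c("field_T", "moment_emu")
  if (!all(need %in% names(d)))
    stop("hysteresis format error: expected columns ",
         paste(need, collapse = ", "))
  hysteresis_curve(d$field_T, d$moment_emu, sample_mass,
                   label %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a hysteresis curve to CSV
#' @param curve an `mba_hysteresis`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hysteresis <- function(curve, path) {
  utils::write.csv(data.frame(field_T = curve$field,
                              moment_emu = curve$moment),
                   path, row.names = FALSE)
  invisible(path)
}
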