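#' Grid collimator geometry
#'
#' Describes one hole of a hexagonal-pattern grid block: the hole diameter,
#' the centre-to-centre spacing between neighbouring holes, and (as metadata)
#' the block thickness. The circular tissue region attributed to a single hole
#' extends to `r_max = spacing / 2`, half the centre-to-centre distance.
#'
#' @param hole_diameter Hole diameter in cm. Must be positive and smaller than
#'   `spacing`.
#' @param spacing Centre-to-centre hole distance in cm.
#' @param pattern Hole lattice pattern label; only `"hexagonal"` is used.
#' @param block_thickness Block thickness in cm (metadata only; the dose model
#'   does not use it).
#'
#' @return An object of class `grid_geometry` with fields `hole_diameter`,
#'   `spacing`, `pattern`, `block_thickness` (cm) and the derived `r_max_mm`
#'   (mm).
#' @examples
#' grid_geometry(1.0, 1.8)
#' @export
grid_geometry <- function(hole_diameter, spacing, pattern = "hexagonal",
                          block_thickness = 7.5) {
  stopifnot(is.numeric(hole_diameter), length(hole_diameter) == 1L,
            is.numeric(spacing), length(spacing) == 1L)
  if (!is.finite(hole_diameter) || hole_diameter <= 0)
    stop("`hole_diameter` must be a positive length in cm", call. = FALSE)
  if (!is.finite(spacing) || spacing <= hole_diameter)
    stop("`spacing` must exceed `hole_diameter` (holes cannot overlap)",
         call. = FALSE)
  structure(
    list(hole_diameter = hole_diameter, spacing = spacing, pattern = pattern,
         block_thickness = block_thickness,
         r_max_mm = spacing * 10 / 2),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf(
    "Grid geometry: %.2f cm holes, %.2f cm centre-to-centre (%s pattern)\n",
    x$hole_diameter, x$spacing, x$pattern))
  cat(sprintf("  r_max = %.1f mm, block thickness %.1f cm\n",
              x$r_max_mm, x$block_thickness))
  invisible(x)
}

#' Parameters of the surrogate single-hole profile model
#'
#' The surrogate radial dose model is a plateau at the peak dose inside the
#' hole, an error-function penumbra centred on the hole edge, and a flat
#' valley at `valley_fraction` of the peak between holes. It is the minimal
#' shape consistent with the quantities a treatment-planning report states
#' about a megavoltage grid field at depth: the peak dose, a finite penumbra,
#' and a valley-to-peak ratio (about 22% at 5 cm depth for the reference
#' 1.0 cm / 1.8 cm block).
#'
#' @param valley_fraction Valley-to-peak dose ratio, in (0, 1]. Default 0.22.
#' @param penumbra_sigma Gaussian width (mm) of the error-function penumbra.
#'   Default 1.5 mm, a typical 6 MV collimated-edge scale.
#' @param radial_step Radial sampling step in mm. Default 0.1 mm.
#'
#' @return An object of class `profile_model_params`.
#' @export
profile_model_params <- function(valley_fraction = 0.22,
                                 penumbra_sigma = 1.5,
                                 radial_step = 0.1) {
  if (!is.numeric(valley_fraction) || valley_fraction <= 0 ||
      valley_fraction > 1)
    stop("`valley_fraction` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(penumbra_sigma) || penumbra_sigma < 0)
    stop("`penumbra_sigma` must be >= 0 mm", call. = FALSE)
  if (!is.numeric(radial_step) || radial_step <= 0)
    stop("`radial_step` must be > 0 mm", call. = FALSE)
  structure(list(valley_fraction = valley_fraction,
                 penumbra_sigma = penumbra_sigma,
                 radial_step = radial_step),
            class = "profile_model_params")
}

new_dose_profile <- function(radii, doses) {
  radii <- as.numeric(radii)
  doses <- as.numeric(doses)
  if (length(radii) < 2L || length(radii) != length(doses))
    stop("a dose profile needs at least two (radius, dose) samples",
         call. = FALSE)
  if (radii[1L] != 0)
    stop("profile radii must start at 0 mm", call. = FALSE)
  dr <- diff(radii)
  if (any(dr <= 0)) {
    i <- which(dr <= 0)[1L] + 1L
    stop(sprintf("profile radii must be strictly increasing (row %d, r = %g mm)",
                 i, radii[i]), call. = FALSE)
  }
  bad <- which(!is.finite(doses) | doses < 0)
  if (length(bad))
    stop(sprintf("doses must be finite and >= 0 Gy (row %d, dose = %g)",
                 bad[1L], doses[bad[1L]]), call. = FALSE)
  structure(
    list(radii = radii, doses = doses,
         peak_dose = max(doses),
         valley_fraction = doses[length(doses)] / max(doses)),
    class = "dose_profile"
  )
}

#' Generate the surrogate radial dose profile under one grid hole
#'
#' Samples the surrogate dose model (see [profile_model_params()]) every
#' `model$radial_step` mm from the hole centre (r = 0) out to
#' `r_max = spacing / 2`. The dose is
#' \deqn{D(r) = P\,[v + (1 - v)\,\mathrm{erfc}((r - a)/(\sigma\sqrt2))/2],}
#' where `P` is the nominal peak dose, `v` the valley fraction, `a` the hole
#' radius and `sigma` the penumbra width; at the hole edge the dose is exactly
#' `P (1 + v) / 2`. With `valley_fraction = 1` the field is uniform.
#'
#' @param geometry A [grid_geometry()].
#' @param peak_dose Nominal dose at the hole centre, Gy (> 0).
#' @param model A [profile_model_params()]; defaults to the canonical model
#'   (valley 0.22, sigma 1.5 mm, step 0.1 mm).
#'
#' @return A `dose_profile` with fields `radii` (mm), `doses` (Gy),
#'   `peak_dose` (the maximum sampled dose) and `valley_fraction`
#'   (dose at `r_max` over peak).
#' @examples
#' p <- make_single_hole_profile(grid_geometry(1.0, 1.8), peak_dose = 15)
#' p$valley_fraction
#' @export
make_single_hole_profile <- function(geometry, peak_dose,
                                     model = profile_model_params()) {
  stopifnot(inherits(geometry, "grid_geometry"),
            inherits(model, "profile_model_params"))
  if (!is.numeric(peak_dose) || length(peak_dose) != 1L || peak_dose <= 0)
    stop("`peak_dose` must be a positive dose in Gy", call. = FALSE)
  r_max <- geometry$r_max_mm
  if (model$radial_step > r_max)
    stop("`radial_step` exceeds r_max; nothing to sample", call. = FALSE)
  radii <- seq(0, r_max, by = model$radial_step)
  if (radii[length(radii)] < r_max) radii <- c(radii, r_max)
  hole_radius <- geometry$hole_diameter * 10 / 2  # mm
  doses <- surrogate_dose(radii, peak_dose, hole_radius,
                          model$valley_fraction, model$penumbra_sigma)
  new_dose_profile(radii, doses)
}

# erf-penumbra surrogate; sigma = 0 degenerates to a step at the hole edge
surrogate_dose <- function(r, peak, hole_radius, valley, sigma) {
  if (valley == 1) return(rep(peak, length(r)))
  if (sigma == 0) {
    shoulder <- ifelse(r < hole_radius, 1, ifelse(r == hole_radius, 0.5, 0))
  } else {
    # erfc(x)/2 via the normal CDF: pnorm(-x * sqrt(2))
    shoulder <- stats::pnorm(-(r - hole_radius) / sigma)
  }
  peak * (valley + (1 - valley) * shoulder)
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf(
    "Single-hole dose profile: %d samples on [0, %.1f] mm\n",
    length(x$radii), x$radii[length(x$radii)]))
  cat(sprintf("  peak %.3f Gy, valley-to-peak %.3f\n",
              x$peak_dose, x$valley_fraction))
  invisible(x)
}

#' Read or write a tabulated radial dose profile
#'
#' Profiles are exchanged as UTF-8 CSV with header `r_mm,dose_Gy`, one sample
#' per row, radii strictly increasing from 0. `read_profile_csv()` validates
#' on the way in and names the offending row on failure.
#'
#' @param path Path to the CSV file.
#' @param profile A `dose_profile` to write.
#' @return `read_profile_csv()` returns a `dose_profile`;
#'   `write_profile_csv()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_profile_csv(make_single_hole_profile(grid_geometry(1, 1.8), 15), f)
#' read_profile_csv(f)
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stop("no such profile file: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(path, header = TRUE, colClasses = "numeric"),
    error = function(e) stop("malformed profile CSV: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(tab) == 0L)
    stop("empty profile CSV: ", path, call. = FALSE)
  if (!all(c("r_mm", "dose_Gy") %in% names(tab)))
    stop("profile CSV must have columns `r_mm` and `dose_Gy`", call. = FALSE)
  new_dose_profile(tab$r_mm, tab$dose_Gy)
}

#' @rdname read_profile_csv
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "dose_profile"))
  utils::write.csv(
    data.frame(r_mm = profile$radii, dose_Gy = profile$doses),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
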