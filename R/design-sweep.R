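#' Peak dose that delivers a target EUD through a given grid geometry
#'
#' For a fixed geometry and profile model the EUD is strictly increasing in
#' the peak dose, so the peak dose delivering a prescribed tumour EUD is
#' found by bracketed root-finding over (0, 100] Gy and verified by a
#' forward EUD recomputation to 1e-6 Gy.
#'
#' @param geometry A [grid_geometry()].
#' @param target_eud Target tumour EUD in Gy (> 0).
#' @param tumor [lq_params] of the tumour.
#' @param model `"LQ"` or `"HK"`.
#' @param profile_model A [profile_model_params()].
#' @param ring_thickness Ring thickness in mm.
#' @return The peak dose in Gy.
#' @examples
#' semi <- derive_lq_params(0.4, 10)
#' g <- grid_geometry(1.0, 1.8)
#' match_peak_dose_to_eud(g, target_eud = 4.7, tumor = semi)
#' @export
match_peak_dose_to_eud <- function(geometry, target_eud, tumor,
                                   model = c("LQ", "HK"),
                                   profile_model = profile_model_params(),
                                   ring_thickness = 0.1) {
  stopifnot(inherits(geometry, "grid_geometry"),
            inherits(tumor, "lq_params"))
  model <- match.arg(model)
  if (!is.numeric(target_eud) || target_eud <= 0)
    stop("`target_eud` must be a positive dose in Gy", call. = FALSE)
  eud_of_peak <- function(P) {
    therapeutic_ratio(make_single_hole_profile(geometry, P, profile_model),
                      tumor, model = model,
                      ring_thickness = ring_thickness)$eud
  }
  f <- function(P) eud_of_peak(P) - target_eud
  lo <- 1e-3; hi <- 100
  if (f(hi) < 0)
    stop("`target_eud` not reachable with peak dose <= 100 Gy", call. = FALSE)
  if (f(lo) > 0)
    stop("`target_eud` below the EUD of the minimum peak dose", call. = FALSE)
  peak <- stats::uniroot(f, interval = c(lo, hi), tol = 1e-9)$root
  stopifnot(abs(eud_of_peak(peak) - target_eud) < 1e-6)
  peak
}

sweep_point <- function(geometry, target_eud, tumor, normal, model,
                        profile_model, ring_thickness) {
  peak <- match_peak_dose_to_eud(geometry, target_eud, tumor, model = model,
                                 profile_model = profile_model,
                                 ring_thickness = ring_thickness)
  res <- therapeutic_ratio(
    make_single_hole_profile(geometry, peak, profile_model),
    tumor, normal, model = model, ring_thickness = ring_thickness)
  data.frame(hole_diameter = geometry$hole_diameter,
             spacing = geometry$spacing,
             adjusted_peak_dose = peak,
             eud = res$eud, tr = res$tr)
}

#' EUD-matched sweep over grid-hole diameters
#'
#' Evaluates the therapeutic ratio for a set of hole diameters at fixed
#' centre-to-centre spacing, rescaling each geometry's peak dose so that the
#' tumour EUD equals `target_eud` in every design. The valley fraction and
#' penumbra width of the profile model are held constant across geometries (a
#' modelling assumption; a transport calculation would give each geometry its
#' own valley and penumbra).
#'
#' @param diameters Hole diameters in cm (all `< spacing`).
#' @param spacing Centre-to-centre spacing in cm.
#' @param target_eud Tumour EUD held fixed across the sweep, Gy.
#' @param tumor,normal [lq_params]; the tumour defaults to the
#'   radioresistant class, the normal tissue to SF2 = 0.4 at
#'   alpha/beta = 2.5 Gy.
#' @param model `"LQ"` or `"HK"`.
#' @param profile_model A [profile_model_params()].
#' @param ring_thickness Ring thickness in mm.
#' @return A data.frame of design points (`hole_diameter`, `spacing`,
#'   `adjusted_peak_dose`, `eud`, `tr`), with attribute `"optimal"` holding
#'   every diameter whose TR is within 1% of the maximum.
#' @examples
#' \donttest{
#' sweep_hole_diameters(c(0.5, 1.0, 1.25), spacing = 1.8, target_eud = 5)
#' }
#' @export
sweep_hole_diameters <- function(diameters, spacing, target_eud,
                                 tumor = derive_lq_params(0.5, 10,
                                                          "radioresistant"),
                                 normal = derive_lq_params(0.4, 2.5,
                                                           "normal tissue"),
                                 model = c("LQ", "HK"),
                                 profile_model = profile_model_params(),
                                 ring_thickness = 0.1) {
  model <- match.arg(model)
  if (any(diameters >= spacing))
    stop("every hole diameter must be smaller than the spacing",
         call. = FALSE)
  pts <- do.call(rbind, lapply(diameters, function(d)
    sweep_point(grid_geometry(d, spacing), target_eud, tumor, normal,
                model, profile_model, ring_thickness)))
  attr(pts, "optimal") <- pts$hole_diameter[pts$tr >= max(pts$tr) * 0.99]
  pts
}

#' EUD-matched sweep over centre-to-centre spacings
#'
#' As [sweep_hole_diameters()], but varying the spacing at fixed hole
#' diameter; `r_max = spacing / 2` varies with each design.
#'
#' @param diameter Hole diameter in cm.
#' @param spacings Centre-to-centre spacings in cm (all `> diameter`).
#' @inheritParams sweep_hole_diameters
#' @return A data.frame of design points with attribute `"optimal"` holding
#'   every spacing whose TR is within 1% of the maximum.
#' @examples
#' \donttest{
#' sweep_spacings(1.25, c(1.6, 1.8, 2.0), target_eud = 5)
#' }
#' @export
sweep_spacings <- function(diameter, spacings, target_eud,
                           tumor = derive_lq_params(0.5, 10,
                                                    "radioresistant"),
                           normal = derive_lq_params(0.4, 2.5,
                                                     "normal tissue"),
                           model = c("LQ", "HK"),
                           profile_model = profile_model_params(),
                           ring_thickness = 0.1) {
  model <- match.arg(model)
  if (any(spacings <= diameter))
    stop("every spacing must exceed the hole diameter", call. = FALSE)
  pts <- do.call(rbind, lapply(spacings, function(s)
    sweep_point(grid_geometry(diameter, s), target_eud, tumor, normal,
                model, profile_model, ring_thickness)))
  attr(pts, "optimal") <- pts$spacing[pts$tr >= max(pts$tr) * 0.99]
  pts
}

#' Therapeutic ratio over a grid of SF2 values and peak doses
#'
#' Tabulates TR for tumours spanning a range of radiosensitivities (SF2 at a
#' common alpha/beta ratio) and several peak doses on one fixed profile
#' shape. For peak doses of 10 Gy and above, TR increases with SF2:
#' radioresistant tumours benefit most from spatial fractionation.
#'
#' @param sf2_values Tumour SF2 values in (0, 1).
#' @param alpha_beta Tumour alpha/beta ratio in Gy (default 10).
#' @param peak_doses Peak doses in Gy.
#' @param profile A `dose_profile` whose doses are rescaled to each peak.
#' @param model `"LQ"` or `"HK"`.
#' @param normal Normal-tissue [lq_params].
#' @param ring_thickness Ring thickness in mm.
#' @return A data.frame with one row per SF2 and one `tr_<dose>Gy` column per
#'   peak dose.
#' @examples
#' p <- make_single_hole_profile(grid_geometry(1.0, 1.8), 15)
#' tr_vs_sf2_table(c(0.28, 0.4, 0.55), peak_doses = c(10, 15), profile = p)
#' @export
tr_vs_sf2_table <- function(sf2_values, alpha_beta = 10, peak_doses,
                            profile, model = c("LQ", "HK"),
                            normal = derive_lq_params(0.4, 2.5,
                                                      "normal tissue"),
                            ring_thickness = 0.1) {
  model <- match.arg(model)
  stopifnot(inherits(profile, "dose_profile"))
  if (any(sf2_values <= 0 | sf2_values >= 1))
    stop("all `sf2_values` must lie strictly in (0, 1)", call. = FALSE)
  out <- data.frame(sf2 = sf2_values)
  for (P in peak_doses) {
    scaled <- new_dose_profile(profile$radii,
                               profile$doses * P / profile$peak_dose)
    out[[sprintf("tr_%gGy", P)]] <- vapply(sf2_values, function(s2) {
      therapeutic_ratio(scaled, derive_lq_params(s2, alpha_beta),
                        normal, model = model,
                        ring_thickness = ring_thickness)$tr
    }, numeric(1))
  }
  out
}
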