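#' Bundled clinical grid-therapy response records
#'
#' Joins the two bundled tables shipped with the package: per-study total
#' clinical response rates of grid therapy by tumour histology or site, and
#' published SF2 values by histology. Histologies reported in several studies
#' keep one record per study (fits use all rows). Join key is the normalised
#' histology name; "SCC of H&N" joins to SCC. Records missing either field
#' (parotid's response rate is not reported; maxillary sinus has no published
#' SF2) carry `NA` and are excluded from fits. Responses reported only as
#' lower bounds ("more than X%") are stored as X with `qualifier = ">"`.
#'
#' @return A data.frame with columns `histology`, `sf2`, `response`
#'   (percent), `qualifier` (`""` or `">"`), `source` (citation key) and
#'   `delivery` (`"block"` or `"MLC"`).
#' @examples
#' head(load_clinical_table())
#' @export
load_clinical_table <- function() {
  dir <- system.file("extdata", package = "gridtr", mustWork = TRUE)
  resp <- utils::read.delim(file.path(dir, "clinical_response.tsv"),
                            na.strings = "NA")
  sf2 <- utils::read.delim(file.path(dir, "histology_sf2.tsv"),
                           na.strings = "NA")
  out <- merge(resp, sf2[, c("histology", "sf2")],
               by = "histology", all.x = TRUE, sort = FALSE)
  out$qualifier[is.na(out$qualifier)] <- ""
  out[, c("histology", "sf2", "response", "qualifier", "source", "delivery")]
}

#' Least-squares fit of clinical response against a radiobiological predictor
#'
#' Ordinary least-squares regression of the reported total clinical response
#' (percent) on either the histology SF2 or the model-predicted therapeutic
#' ratio. With `predictor = "tr"` and no `tr` column present, TR is computed
#' for each record from its SF2 (alpha/beta = 10 Gy) on the canonical
#' 1.0 cm / 1.8 cm profile at a 15 Gy peak with the LQ model. Both
#' predictors are expected to carry a positive slope: tumours with higher
#' SF2 (more radioresistant) respond better to grid therapy.
#'
#' @param records A data.frame from [load_clinical_table()] (or any frame
#'   with `response` and the predictor column).
#' @param predictor `"sf2"` or `"tr"`.
#' @param peak_dose Peak dose (Gy) used when TR must be computed; default 15.
#' @return A list with `slope`, `intercept`, `r` (Pearson correlation),
#'   `n` (records used) and the fitted `lm` object as `fit`.
#' @examples
#' fit_linear_response(load_clinical_table(), "sf2")
#' @export
fit_linear_response <- function(records, predictor = c("sf2", "tr"),
                                peak_dose = 15) {
  predictor <- match.arg(predictor)
  if (predictor == "tr" && !"tr" %in% names(records)) {
    prof <- make_single_hole_profile(grid_geometry(1.0, 1.8), peak_dose)
    records$tr <- vapply(records$sf2, function(s2) {
      if (is.na(s2)) return(NA_real_)
      therapeutic_ratio(prof, derive_lq_params(s2, 10))$tr
    }, numeric(1))
  }
  keep <- stats::complete.cases(records[, c(predictor, "response")])
  usable <- records[keep, ]
  if (nrow(usable) < 3L)
    stop("need at least 3 records with both `", predictor,
         "` and `response`", call. = FALSE)
  fit <- stats::lm(stats::reformulate(predictor, "response"), data = usable)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(usable[[predictor]], usable$response),
       n = nrow(usable),
       fit = fit)
}
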