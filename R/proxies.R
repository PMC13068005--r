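#' Composite delay-proxy ratio: CRP over neutrophils
#'
#' Cross-sectional structural analogue of a delayed inflammatory response:
#' `tau_composite = crp / (neutrophils + 1)`.  High values indicate
#' amplification of the downstream acute-phase signal (CRP) relative to the
#' upstream innate response (neutrophils).
#'
#' @param crp Nonnegative CRP concentrations (assay units).
#' @param neutrophils Nonnegative neutrophil counts (assay units).
#' @return `crp / (neutrophils + 1)`, elementwise.
#' @export
#' @examples
#' tau_composite(2, 3)   # 0.5
tau_composite <- function(crp, neutrophils) {
  if (any(crp < 0, na.rm = TRUE) || any(neutrophils < 0, na.rm = TRUE))
    stop("'crp' and 'neutrophils' must be nonnegative", call. = FALSE)
  crp / (neutrophils + 1)
}

#' Regulatory-imbalance delay proxy: CRP over albumin
#'
#' `delta_ratio = crp / albumin`; high values indicate inflammation
#' outpacing the negative acute-phase (regulatory) response.
#'
#' @param crp Nonnegative CRP concentrations.
#' @param albumin Strictly positive albumin concentrations.
#' @return `crp / albumin`, elementwise.
#' @export
#' @examples
#' delta_ratio(4, 40)   # 0.1
delta_ratio <- function(crp, albumin) {
  if (any(crp < 0, na.rm = TRUE))
    stop("'crp' must be nonnegative", call. = FALSE)
  if (any(albumin <= 0, na.rm = TRUE))
    stop("'albumin' must be strictly positive", call. = FALSE)
  crp / albumin
}

#' Augment a biomarker table with delay-proxy ratios and tertiles
#'
#' Appends `tau_composite`, `delta_ratio` and their tertile labels to a
#' per-subject biomarker table.  Rows with missing inputs are excluded
#' per ratio (not listwise): a row missing albumin still contributes to the
#' `tau_composite` tertiles.  All input rows are retained in the output;
#' exclusions are `NA` in the affected columns and counted in the
#' `"exclusions"` attribute.
#'
#' @param records Data.frame with columns `crp`, `neutrophils`, `albumin`
#'   (and optionally `subject_id`, `event`, `time`).
#' @return The augmented data.frame, with attribute `"exclusions"` giving
#'   per-ratio counts of excluded rows.
#' @export
proxy_table <- function(records) {
  req <- c("crp", "neutrophils", "albumin")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  complete_tau <- !is.na(records$crp) & !is.na(records$neutrophils)
  complete_delta <- !is.na(records$crp) & !is.na(records$albumin) &
    !is.na(records$albumin)
  if (!any(complete_tau) && !any(complete_delta))
    stop("no record with complete biomarkers", call. = FALSE)

  records$tau_composite <- NA_real_
  records$tau_composite[complete_tau] <-
    tau_composite(records$crp[complete_tau],
                  records$neutrophils[complete_tau])
  records$delta_ratio <- NA_real_
  records$delta_ratio[complete_delta] <-
    delta_ratio(records$crp[complete_delta], records$albumin[complete_delta])

  records$tau_composite_tertile <- NA_integer_
  if (any(complete_tau))
    records$tau_composite_tertile[complete_tau] <-
      tertile_split(records$tau_composite[complete_tau])
  records$delta_ratio_tertile <- NA_integer_
  if (any(complete_delta))
    records$delta_ratio_tertile[complete_delta] <-
      tertile_split(records$delta_ratio[complete_delta])

  attr(records, "exclusions") <- c(tau_composite = sum(!complete_tau),
                                   delta_ratio = sum(!complete_delta))
  records
}
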