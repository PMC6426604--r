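#' Derive a purification table
#'
#' Standard enzyme-purification bookkeeping: per step, total protein
#' (volume x protein concentration), total activity (activity x volume),
#' purification fold (specific activity relative to the first step) and
#' yield (total activity relative to the first step). The first row is the
#' reference (crude extract) by construction.
#'
#' When a `specific_activity` column is supplied it is used for the fold
#' calculation (assay-volume conversions often make it non-derivable from
#' the printed columns); otherwise it is derived as
#' `total_activity / total_protein`.
#'
#' @param steps Data frame with columns `step`, `volume_ml`,
#'   `protein_mg_per_ml`, `activity` (per-assay rate, uM/min) and optionally
#'   `specific_activity` (umol/min/mg).
#' @return The input with derived columns added: `total_protein_mg`,
#'   `total_activity`, `specific_activity`, exact `fold` and `yield_pct`,
#'   and presentation-rounded `fold_rounded` (1 decimal) and
#'   `yield_rounded` (integer).
#' @examples
#' derive_table(data.frame(
#'   step = c("Crude extract", "Ni2+ chromatography"),
#'   volume_ml = c(6.0, 7.0), protein_mg_per_ml = c(15.9, 4.5),
#'   activity = c(1.578, 0.823), specific_activity = c(0.595, 1.087)
#' ))
#' @export
derive_table <- function(steps) {
  req <- c("step", "volume_ml", "protein_mg_per_ml", "activity")
  missing_cols <- setdiff(req, names(steps))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(nrow(steps) >= 1, all(steps$volume_ml > 0),
            all(steps$protein_mg_per_ml >= 0))
  out <- steps
  out$total_protein_mg <- out$volume_ml * out$protein_mg_per_ml
  out$total_activity <- out$activity * out$volume_ml
  if (is.null(out$specific_activity)) {
    out$specific_activity <- out$total_activity / out$total_protein_mg
  }
  if (out$total_activity[1] <= 0) stop("zero reference activity")
  if (out$specific_activity[1] <= 0) stop("zero reference specific activity")
  out$fold <- out$specific_activity / out$specific_activity[1]
  out$yield_pct <- 100 * out$total_activity / out$total_activity[1]
  out$fold_rounded <- round(out$fold, 1)
  out$yield_rounded <- round(out$yield_pct)
  out
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' Betalamic acid is quantified at 424 nm with a molar extinction
#' coefficient of 24,000 1/M/cm; the yellow pigments share similar
#' absorptivities.
#'
#' @param absorbance Absorbance units (>= 0).
#' @param epsilon Molar extinction coefficient, 1/M/cm (> 0).
#' @param path_cm Optical path length, cm (> 0).
#' @return Concentration in uM.
#' @examples
#' beer_lambert_conc(0.24) # 10 uM
#' @export
beer_lambert_conc <- function(absorbance, epsilon = 24000, path_cm = 1) {
  if (any(absorbance < 0)) stop("negative absorbance")
  if (epsilon <= 0 || path_cm <= 0) stop("epsilon and path must be positive")
  absorbance / (epsilon * path_cm) * 1e6
}
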