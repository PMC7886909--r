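#' Aggregate region-of-interest cell densities
#'
#' Multiplex-IHC quantification samples up to six regions of interest (ROIs)
#' of 0.36 mm2 per tissue section; each ROI reports a phenotype's cell
#' density in cells/mm2. This aggregates to the per patient x timepoint x
#' compartment x phenotype arithmetic mean over the ROIs that were actually
#' imaged (absence of an image is not absence of cells, so missing ROIs are
#' averaged over, not imputed as zero), with the ROI count reported.
#'
#' @param records Tibble with `patient_id`, `timepoint`, `compartment`
#'   (tumor/stroma), `phenotype`, `roi_index`, `density` (cells/mm2, >= 0).
#' @return Tibble with one row per group: `mean_density`, `n_roi`.
#' @export
roi_aggregate <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("patient_id", "timepoint", "compartment", "phenotype", "density")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("ROI table is missing column(s): ", paste(missing, collapse = ", ")),
          class = "tilmonitor_bad_format")
  }
  if (any(records$density < 0, na.rm = TRUE)) {
    abort("ROI densities must be non-negative", class = "tilmonitor_bad_value")
  }
  records |>
    dplyr::filter(!is.na(density)) |>
    dplyr::group_by(patient_id, timepoint, compartment, phenotype) |>
    dplyr::summarise(mean_density = mean(density), n_roi = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(patient_id, timepoint, compartment, phenotype)
}

#' Convert raw ROI cell counts to densities
#'
#' @param counts Cell counts per ROI.
#' @param roi_area ROI area in mm2 (default 0.36).
#' @return Densities in cells/mm2.
#' @export
counts_to_density <- function(counts, roi_area = 0.36) {
  stopifnot(roi_area > 0)
  if (any(counts < 0, na.rm = TRUE)) {
    abort("cell counts must be non-negative", class = "tilmonitor_bad_value")
  }
  counts / roi_area
}

#' Compartment fold change of aggregated densities
#'
#' Same floored-ratio contract as [fold_change()], applied to pre/post mean
#' densities within a compartment (e.g. the tumor vs stroma contrast of
#' proliferating CD103+ CD8+ cells).
#'
#' @param pre_mean,post_mean Mean densities (cells/mm2), non-negative.
#' @param floor Positive floor (default 0.01).
#' @return Fold change(s) with a `"floored"` attribute.
#' @export
compartment_fold_change <- function(pre_mean, post_mean, floor = 0.01) {
  fold_change(pre_mean, post_mean, floor = floor)
}

#' Concordance between flow percentages and IHC densities
#'
#' Ordinary least-squares fit of IHC density on flow percentage over paired
#' per-patient observations; R-squared is the squared Pearson correlation,
#' the statistic used to ask whether flow frequencies of a subset agree with
#' intratumoral (vs stromal) IHC counts of the same phenotype.
#'
#' @param flow_pct Flow percentages, one per patient.
#' @param ihc_density Matched IHC mean densities (cells/mm2).
#' @return A list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
flow_ihc_concordance <- function(flow_pct, ihc_density) {
  stopifnot(length(flow_pct) == length(ihc_density))
  keep <- stats::complete.cases(flow_pct, ihc_density)
  x <- flow_pct[keep]
  y <- ihc_density[keep]
  if (length(x) < 3) {
    abort("concordance needs at least 3 complete pairs",
          class = "tilmonitor_bad_value")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("R-squared undefined: zero variance in one of the vectors",
          class = "tilmonitor_undefined_r2")
  }
  fit <- stats::lm(y ~ x)
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = unname(stats::cor(x, y)^2),
    n = length(x)
  )
}

#' Call ELISpot well positivity
#'
#' A well is positive when its spot-forming cell (SFC) count strictly exceeds
#' the cutoff (default 100 SFC per 1e5 cells). Background subtraction is not
#' applied by default; pass `mock_sfc` to subtract a matched mock/negative
#' well first.
#'
#' @param sfc Integer SFC counts (vectorized).
#' @param cutoff Non-negative cutoff, strict inequality (default 100).
#' @param mock_sfc Optional matched negative-control SFC to subtract
#'   (floored at 0) before calling.
#' @return Logical vector of positivity calls.
#' @export
elispot_call <- function(sfc, cutoff = 100, mock_sfc = NULL) {
  stopifnot(cutoff >= 0)
  if (any(sfc < 0, na.rm = TRUE)) {
    abort("SFC counts must be non-negative", class = "tilmonitor_bad_value")
  }
  if (!is.null(mock_sfc)) {
    if (any(mock_sfc < 0, na.rm = TRUE)) {
      abort("SFC counts must be non-negative", class = "tilmonitor_bad_value")
    }
    sfc <- pmax(sfc - mock_sfc, 0)
  }
  sfc > cutoff
}
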