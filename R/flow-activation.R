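#' Floored fold change between two percentages
#'
#' `FC = max(post, floor) / max(pre, floor)`. The floor (default 0.01
#' percentage points) keeps fold changes finite when a subset is undetectable
#' at one timepoint; floored comparisons are flagged rather than dropped.
#' Vectorized over `pre`/`post`.
#'
#' @param pre,post Percentages (0-100 scale), non-negative.
#' @param floor Positive floor applied to both values before division.
#' @return A numeric vector of fold changes with a logical attribute
#'   `"floored"` marking entries where either input was below the floor.
#' @export
#' @examples
#' fold_change(2, 6.8) # 3.4
fold_change <- function(pre, post, floor = 0.01) {
  if (any(pre < 0, na.rm = TRUE) || any(post < 0, na.rm = TRUE)) {
    abort("percentages must be non-negative", class = "tilmonitor_bad_value")
  }
  stopifnot(floor > 0)
  fc <- pmax(post, floor) / pmax(pre, floor)
  attr(fc, "floored") <- (pre < floor) | (post < floor)
  fc
}

required_index_fields <- c("pct_cd8_of_t", "pct_dp_of_cd8", "pct_ki67_of_dp")

check_panel <- function(panel, label) {
  missing <- required_index_fields[
    !required_index_fields %in% names(panel) |
      vapply(required_index_fields, function(f)
        f %in% names(panel) && is.na(panel[[f]][1]), logical(1))
  ]
  if (length(missing) > 0) {
    abort(paste0("panel '", label, "' is missing required subset field(s): ",
                 paste(missing, collapse = ", ")),
          class = "tilmonitor_missing_subset")
  }
  invisible(panel)
}

#' CD8 TIL activation index for one patient
#'
#' Combines the baseline-to-day-of-surgery fold changes of three CD8 TIL
#' measurements — percentage of CD8+ cells among T cells, percentage of
#' CD103+CD39+ (DP) cells among CD8+, and percentage of Ki-67+ cells among DP
#' — into a single index. The default index is the geometric mean of the
#' three fold changes, and the default responder rule (`"geom_gate"`)
#' additionally requires every component to exceed 1, i.e. a concordant
#' increase in all three categories; `"geom_only"` thresholds the composite
#' alone. Both the rule and the threshold are configurable because the exact
#' published combination is not fully specified.
#'
#' @param panel_pre,panel_post One-row data frames (or named lists) with the
#'   same `patient_id` and the three required percentage fields, at baseline
#'   and day of surgery respectively.
#' @param rule `"geom_gate"` (default) or `"geom_only"`.
#' @param threshold Responder threshold on the composite index (default 1).
#' @param floor Detection floor passed to [fold_change()].
#' @return A one-row tibble: `patient_id`, `fc_cd8`, `fc_dp`, `fc_ki67dp`,
#'   `index`, `responder`, `floored`.
#' @export
activation_index <- function(panel_pre, panel_post,
                             rule = c("geom_gate", "geom_only"),
                             threshold = 1, floor = 0.01) {
  rule <- match.arg(rule)
  panel_pre <- as.list(panel_pre)
  panel_post <- as.list(panel_post)
  if (!identical(as.character(panel_pre$patient_id),
                 as.character(panel_post$patient_id))) {
    abort("pre and post panels belong to different patients",
          class = "tilmonitor_bad_value")
  }
  check_panel(panel_pre, "baseline")
  check_panel(panel_post, "DOS")
  fcs <- vapply(required_index_fields, function(f) {
    as.numeric(fold_change(panel_pre[[f]], panel_post[[f]], floor = floor))
  }, numeric(1))
  floored <- any(vapply(required_index_fields, function(f) {
    attr(fold_change(panel_pre[[f]], panel_post[[f]], floor = floor), "floored")
  }, logical(1)))
  ai <- exp(mean(log(fcs)))
  resp <- switch(rule,
    geom_gate = ai > threshold && min(fcs) > 1,
    geom_only = ai > threshold
  )
  tibble::tibble(
    patient_id = as.character(panel_pre$patient_id),
    fc_cd8 = fcs[["pct_cd8_of_t"]],
    fc_dp = fcs[["pct_dp_of_cd8"]],
    fc_ki67dp = fcs[["pct_ki67_of_dp"]],
    index = ai,
    responder = resp,
    floored = floored
  )
}

#' Activation index for a whole cohort of panels
#'
#' @param panels Tibble of subset panels (one row per patient x timepoint)
#'   with columns `patient_id`, `timepoint` and the three required percentage
#'   fields. Baseline and DOS rows must exist per patient.
#' @param pre_timepoint,post_timepoint Labels of the two timepoints compared.
#' @inheritParams activation_index
#' @return One [activation_index()] row per patient.
#' @export
activation_index_cohort <- function(panels, pre_timepoint = "baseline",
                                    post_timepoint = "DOS",
                                    rule = "geom_gate", threshold = 1,
                                    floor = 0.01) {
  ids <- sort(unique(as.character(panels$patient_id)))
  purrr::map_dfr(ids, function(id) {
    pre <- panels[panels$patient_id == id & panels$timepoint == pre_timepoint, ]
    post <- panels[panels$patient_id == id & panels$timepoint == post_timepoint, ]
    if (nrow(pre) != 1 || nrow(post) != 1) {
      abort(paste0("patient ", id, " needs exactly one '", pre_timepoint,
                   "' and one '", post_timepoint, "' panel"),
            class = "tilmonitor_bad_value")
    }
    activation_index(pre, post, rule = rule, threshold = threshold, floor = floor)
  })
}

#' Summarise responder classification over a cohort
#'
#' @param results Tibble of [activation_index()] rows, one per patient.
#' @return A list with `labels` (per-patient tibble ordered by `patient_id`),
#'   `n_responders`, `n_non_responders` and `n_total`.
#' @export
classify_cohort <- function(results) {
  stopifnot(nrow(results) >= 1)
  if (anyDuplicated(results$patient_id)) {
    dup <- unique(results$patient_id[duplicated(results$patient_id)])
    abort(paste0("duplicate patient_id in activation results: ",
                 paste(dup, collapse = ", ")),
          class = "tilmonitor_bad_value")
  }
  labels <- dplyr::arrange(results, patient_id)
  list(
    labels = labels,
    n_responders = sum(labels$responder),
    n_non_responders = sum(!labels$responder),
    n_total = nrow(labels)
  )
}

#' Per-subset fold-change time course versus baseline
#'
#' Computes each patient's fold change versus their own baseline for every
#' percentage column, then the mean and SD per subset per timepoint, and the
#' timepoint at which each subset's mean fold change peaks — the summary used
#' to locate the peak of peripheral immune activation (e.g. proliferation
#' peaking about two weeks after dosing).
#'
#' @param panels Tibble with `patient_id`, `timepoint` and one or more
#'   `pct_*` percentage columns; a `baseline` row must exist per patient.
#' @param baseline_timepoint Label of the baseline timepoint.
#' @param floor Detection floor passed to [fold_change()].
#' @return A list with `summary` (subset x timepoint tibble: `mean_fc`,
#'   `sd_fc`, `n`) and `peak` (per-subset argmax timepoint tibble).
#' @export
timecourse_summary <- function(panels, baseline_timepoint = "baseline",
                               floor = 0.01) {
  pct_cols <- grep("^pct_", names(panels), value = TRUE)
  stopifnot(length(pct_cols) > 0)
  long <- panels |>
    dplyr::select(patient_id, timepoint, dplyr::all_of(pct_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(pct_cols),
                        names_to = "subset", values_to = "value")
  base <- long |>
    dplyr::filter(timepoint == baseline_timepoint) |>
    dplyr::select(patient_id, subset, baseline = value)
  if (!all(unique(long$patient_id) %in% base$patient_id)) {
    abort("every patient needs a baseline panel", class = "tilmonitor_bad_value")
  }
  fc_tbl <- long |>
    dplyr::inner_join(base, by = c("patient_id", "subset")) |>
    dplyr::mutate(fold_change = as.numeric(fold_change(baseline, value, floor = floor)))
  # preserve the timepoint order as given in the input
  tp_levels <- unique(as.character(panels$timepoint))
  summary <- fc_tbl |>
    dplyr::group_by(subset, timepoint) |>
    dplyr::summarise(mean_fc = mean(fold_change), sd_fc = stats::sd(fold_change),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(timepoint = factor(timepoint, levels = tp_levels)) |>
    dplyr::arrange(subset, timepoint)
  peak <- summary |>
    dplyr::filter(timepoint != baseline_timepoint) |>
    dplyr::group_by(subset) |>
    dplyr::slice_max(mean_fc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(subset, peak_timepoint = timepoint, peak_mean_fc = mean_fc)
  list(summary = summary, peak = peak)
}

#' Read subset panels from CSV (wide or long layout)
#'
#' Wide layout: one row per patient x timepoint with `pct_*` columns. Long
#' layout: columns `patient_id`, `timepoint`, `subset`, `value`, pivoted to
#' wide on read.
#'
#' @param path CSV path.
#' @return A wide panels tibble.
#' @export
read_subset_panels <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("subset", "value") %in% names(raw))) {
    raw <- tidyr::pivot_wider(raw, names_from = "subset", values_from = "value")
  }
  bad <- setdiff(c("patient_id", "timepoint"), names(raw))
  if (length(bad) > 0) {
    abort(paste0("panel CSV is missing column(s): ", paste(bad, collapse = ", ")),
          class = "tilmonitor_bad_format")
  }
  pct <- grep("^pct_", names(raw), value = TRUE)
  for (col in pct) {
    if (any(raw[[col]] < 0 | raw[[col]] > 100, na.rm = TRUE)) {
      abort(paste0("column ", col, " contains values outside [0, 100]"),
            class = "tilmonitor_bad_value")
    }
  }
  tibble::as_tibble(raw)
}
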