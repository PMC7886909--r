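check_survival_records <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(c("time", "event"), names(records))
  if (length(missing) > 0) {
    abort(paste0("survival table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tilmonitor_bad_format")
  }
  if (any(records$time < 0, na.rm = TRUE)) {
    abort("survival times must be non-negative", class = "tilmonitor_bad_value")
  }
  records$event <- as.logical(records$event)
  records
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct event times, with the standard tie convention that events precede
#' censorings at the same time (censored subjects count as at risk for that
#' event). Backed by [survival::survfit()].
#'
#' @param records Tibble with `time` (months from surgery, >= 0) and `event`
#'   (TRUE = event observed, FALSE = censored).
#' @param conf_type Confidence-interval transform passed to survfit
#'   (default "log-log").
#' @return A list: `table` (tibble of `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `lower`, `upper`), `fit` (the survfit object) and
#'   `median` (median survival time, NA if the curve never reaches 0.5).
#' @export
km_estimate <- function(records, conf_type = "log-log") {
  records <- check_survival_records(records)
  stopifnot(nrow(records) >= 1)
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ 1,
    conf.type = conf_type
  )
  tab <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv,
    lower = fit$lower,
    upper = fit$upper
  )
  med <- unname(summary(fit)$table["median"])
  list(table = tab, fit = fit, median = med)
}

#' Survival probability at given times
#'
#' Right-continuous step-function evaluation of a [km_estimate()] curve;
#' S(t) = 1 before the first event.
#'
#' @param km A [km_estimate()] result.
#' @param times Times at which to evaluate.
#' @return Numeric survival probabilities.
#' @export
km_surv_at <- function(km, times) {
  s <- summary(km$fit, times = times, extend = TRUE)
  s$surv
}

#' Number of patients at risk at given times
#'
#' The at-risk row conventionally printed beneath a survival curve.
#'
#' @param km A [km_estimate()] result.
#' @param times Times at which to report the at-risk count.
#' @return Tibble with `time` and `n_risk`.
#' @export
km_at_risk <- function(km, times) {
  s <- summary(km$fit, times = times, extend = TRUE)
  tibble::tibble(time = s$time, n_risk = s$n.risk)
}

#' Log-rank (Mantel-Cox) comparison of two groups
#'
#' Standard Mantel-Cox statistic on the pooled event times, with p from a
#' chi-square with 1 degree of freedom. Backed by [survival::survdiff()].
#'
#' @param records Tibble with `time`, `event` and `group` (exactly two
#'   levels), or pass the two groups as `a` and `b`.
#' @param a,b Alternative interface: two survival tibbles.
#' @return A list: `chisq`, `p_value`, `n` (per-group sizes),
#'   `observed`/`expected` event counts per group.
#' @export
logrank_test <- function(records = NULL, a = NULL, b = NULL) {
  if (is.null(records)) {
    stopifnot(!is.null(a), !is.null(b))
    a <- check_survival_records(a)
    b <- check_survival_records(b)
    records <- dplyr::bind_rows(
      dplyr::mutate(a, group = "a"),
      dplyr::mutate(b, group = "b")
    )
  }
  records <- check_survival_records(records)
  if (!"group" %in% names(records)) {
    abort("log-rank needs a `group` column (or the a/b interface)",
          class = "tilmonitor_bad_format")
  }
  groups <- unique(records$group)
  if (length(groups) != 2 || any(table(records$group) == 0)) {
    abort("log-rank compares exactly two non-empty groups",
          class = "tilmonitor_bad_value")
  }
  if (sum(records$event) == 0) {
    abort("log-rank undefined: no events in the pooled data",
          class = "tilmonitor_no_events")
  }
  sd <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ records$group
  )
  chisq <- unname(sd$chisq)
  list(
    chisq = chisq,
    p_value = unname(pchisq(chisq, df = 1, lower.tail = FALSE)),
    n = setNames(as.integer(sd$n), sub("^records\\$group=", "", names(sd$n))),
    observed = unname(sd$obs),
    expected = unname(sd$exp)
  )
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Applies the product-limit estimator with the censoring indicator treated
#' as the event (and events censored), so the "survival" curve describes
#' follow-up; the median follow-up is the smallest time at which it drops to
#' 0.5 or below. The 95% CI uses the Greenwood variance with a log-log
#' transform.
#'
#' @param records Tibble with `time` and `event`.
#' @return A list: `median_followup`, `ci_lower`, `ci_upper`, `km` (the
#'   reverse-KM [km_estimate()] result). If the curve never reaches 0.5 the
#'   median is NA and a warning of class
#'   `tilmonitor_undefined_median` is signalled.
#' @export
reverse_km_followup <- function(records) {
  records <- check_survival_records(records)
  flipped <- dplyr::mutate(records, event = !event)
  km <- km_estimate(flipped, conf_type = "log-log")
  q <- stats::quantile(km$fit, probs = 0.5)
  med <- unname(q$quantile)
  if (is.na(med)) {
    warn("reverse-KM curve never reaches 0.5; median follow-up undefined",
         class = "tilmonitor_undefined_median")
  }
  list(
    median_followup = med,
    ci_lower = unname(q$lower),
    ci_upper = unname(q$upper),
    km = km
  )
}

#' Read a survival table from CSV
#'
#' Expects columns `time` (months from the day of surgery), `event`
#' (logical/0-1) and optionally `patient_id` and `group`. Times are assumed
#' to already be on the surgery origin; negative times are rejected.
#'
#' @param path CSV path.
#' @return A validated survival tibble.
#' @export
read_survival <- function(path) {
  check_survival_records(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
}
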