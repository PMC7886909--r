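surv_tbl <- function(time, event, group = NULL) {
  out <- tibble::tibble(time = time, event = event)
  if (!is.null(group)) out$group <- group
  out
}

test_that("KM product-limit matches hand calculations", {
  # no events: flat at 1
  km0 <- km_estimate(surv_tbl(c(3, 6, 9), c(FALSE, FALSE, FALSE)))
  expect_equal(km_surv_at(km0, c(0, 5, 10)), rep(1, 3))

  # 17 subjects, 3 events before t, no prior censoring: S = 14/17
  km17 <- km_estimate(surv_tbl(c(1, 2, 3, rep(50, 14)),
                               c(rep(TRUE, 3), rep(FALSE, 14))))
  expect_equal(km_surv_at(km17, 10), 14 / 17, tolerance = 1e-12)

  # censoring at an event time: censored subject still at risk for the event
  km_tie <- km_estimate(surv_tbl(c(2, 2, 5), c(TRUE, FALSE, FALSE)))
  expect_equal(km_surv_at(km_tie, 3), 2 / 3, tolerance = 1e-12)

  # all-events data equals the empirical survival function
  times <- c(1, 2, 3, 4, 5)
  km_all <- km_estimate(surv_tbl(times, rep(TRUE, 5)))
  expect_equal(km_surv_at(km_all, times), 1 - seq(0.2, 1, 0.2),
               tolerance = 1e-12)

  expect_error(km_estimate(surv_tbl(-1, TRUE)), class = "tilmonitor_bad_value")
})

test_that("KM curve is a proper non-increasing step function with at-risk counts", {
  surv <- gen_survival(80, 2, censor_rate = 0.02, seed = 14)
  km <- km_estimate(surv)
  expect_true(all(diff(km$table$surv) <= 1e-12))
  expect_true(all(km$table$surv >= 0 & km$table$surv <= 1))
  expect_true(all(diff(km$table$n_risk) <= 0))
  expect_equal(km_surv_at(km, 0), 1)
  ar <- km_at_risk(km, c(0, 12, 24))
  expect_equal(ar$n_risk[1], nrow(surv))
  expect_true(all(diff(ar$n_risk) <= 0))
})

test_that("KM on exponential data hits 0.5 near the distribution median", {
  surv <- gen_survival(1000, 1, censor_rate = 0, seed = 19, base_hazard = 0.05)
  one_group <- surv[surv$group == "responder", ]
  km <- km_estimate(one_group)
  med_true <- log(2) / 0.05
  expect_equal(km_surv_at(km, med_true), 0.5, tolerance = 0.05)
})

test_that("log-rank matches identical-group null and hand arithmetic", {
  a <- surv_tbl(c(1, 3, 5, 8), c(TRUE, TRUE, FALSE, TRUE))
  same <- logrank_test(a = a, b = a)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  b <- surv_tbl(c(2, 4, 6, 9), c(TRUE, FALSE, TRUE, TRUE))
  out <- logrank_test(a = a, b = b)
  naive <- naive_logrank_chisq(c(a$time, b$time), c(a$event, b$event),
                               rep(c("a", "b"), each = 4))
  expect_equal(out$chisq, naive, tolerance = 1e-9)

  # symmetric in group order, invariant under common time rescaling
  expect_equal(logrank_test(a = b, b = a)$chisq, out$chisq, tolerance = 1e-12)
  expect_equal(logrank_test(a = dplyr::mutate(a, time = time * 7),
                            b = dplyr::mutate(b, time = time * 7))$chisq,
               out$chisq, tolerance = 1e-12)

  expect_error(logrank_test(a = surv_tbl(1:3, rep(FALSE, 3)),
                            b = surv_tbl(1:3, rep(FALSE, 3))),
               class = "tilmonitor_no_events")
})

test_that("large-sample planted hazard ratio is detected", {
  surv <- gen_survival(500, 3, censor_rate = 0.005, seed = 3)
  out <- logrank_test(surv)
  expect_lt(out$p_value, 0.001)
  # null case: HR = 1 without censoring gives a small statistic on average
  stats <- vapply(1:10, function(s) {
    logrank_test(gen_survival(60, 1, censor_rate = 0, seed = 100 + s))$chisq
  }, numeric(1))
  expect_lt(mean(stats), 3) # chi-square(1) mean is 1
})

test_that("reverse KM equals KM on flipped indicators and finds follow-up", {
  rec <- surv_tbl(c(2, 4, 7, 9, 12, 15),
                  c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  fu <- reverse_km_followup(rec)
  flipped <- dplyr::mutate(rec, event = !event)
  km_flip <- km_estimate(flipped)
  expect_equal(fu$km$table, km_flip$table)
  # hand product-limit on flipped indicators:
  # censorings (events after flip) at 4, 7, 12, 15 with at-risk 5, 4, 2, 1
  # S: 4/5 = 0.8 at t=4; 0.8*3/4 = 0.6 at t=7; 0.6*1/2 = 0.3 at t=12
  expect_equal(km_surv_at(km_flip, c(4, 7, 12)), c(0.8, 0.6, 0.3),
               tolerance = 1e-12)
  expect_equal(fu$median_followup, 12) # smallest time with S <= 0.5

  # all censored at time T: median follow-up is T
  allc <- reverse_km_followup(surv_tbl(rep(39, 8), rep(FALSE, 8)))
  expect_equal(allc$median_followup, 39)

  # all events: reverse curve never reaches 0.5
  expect_warning(
    und <- reverse_km_followup(surv_tbl(c(1, 2, 3), rep(TRUE, 3))),
    class = "tilmonitor_undefined_median"
  )
  expect_true(is.na(und$median_followup))
})

test_that("survival CSV reader validates and preserves groups", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(gen_survival(10, 2, seed = 44), path)
  back <- read_survival(path)
  expect_equal(nrow(back), 20)
  expect_true(is.logical(back$event))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("time,event\n-3,1", bad)
  expect_error(read_survival(bad), class = "tilmonitor_bad_value")
})
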