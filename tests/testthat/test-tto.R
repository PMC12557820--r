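# Time-to-onset computation, binning, Kaplan-Meier, log-rank.

make_tto_db <- function(rows) {
  # rows: list of c(primaryid, start_dt, event_dt)
  reports <- data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(primaryid = r[1], caseid = r[1], fda_dt = "20230601",
                           event_dt = r[3], age = NA_real_, sex = NA_character_,
                           wt = NA_real_, reporter = "", country = "US")))
  drugs <- data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(primaryid = r[1], drug_seq = 1L, name = "AVACOPAN",
                           role = "PS", start_dt = r[2])))
  srsignal:::new_report_db(reports, drugs,
                           data.table::data.table(primaryid = character(),
                                                  pt = character()),
                           data.table::data.table(primaryid = character(),
                                                  outcome = character()))
}

test_that("onset days are differenced only on full-precision dates", {
  db <- make_tto_db(list(
    c("1", "20230101", "20230131"),   # 30 days
    c("2", "20230215", "20230210"),   # negative
    c("3", "202301", "20230131"),     # partial start
    c("4", "20230101", "202303"),     # partial event
    c("5", "", "20230131"),           # missing start
    c("6", "20230101", "")))          # missing event
  tto <- compute_tto(db, "AVACOPAN")
  expect_equal(tto[tto$primaryid == "1"]$tto_days, 30L)
  expect_equal(tto[tto$primaryid == "2"]$reason, "negative")
  expect_equal(tto[tto$primaryid == "3"]$reason, "partial_date")
  expect_equal(tto[tto$primaryid == "4"]$reason, "partial_date")
  expect_equal(tto[tto$primaryid == "5"]$reason, "missing_start")
  expect_equal(tto[tto$primaryid == "6"]$reason, "missing_event")
  expect_true(all(is.na(tto$tto_days[tto$reason != "ok"])))
  # same-day onset is day 0, a valid value
  db0 <- make_tto_db(list(c("7", "20230101", "20230101")))
  expect_equal(compute_tto(db0, "AVACOPAN")$tto_days, 0L)
})

test_that("the earliest full-precision start anchors multi-row therapy", {
  db <- make_tto_db(list(c("1", "20230110", "20230131")))
  db$drugs <- rbind(db$drugs,
                    data.table::data.table(primaryid = "1", drug_seq = 2L,
                                           name = "AVACOPAN", role = "PS",
                                           start_dt = "20230101"))
  expect_equal(compute_tto(db, "AVACOPAN")$tto_days, 30L)
})

test_that("bins are closed on both printed endpoints", {
  bins <- bin_tto(c(0, 30, 31, 360, 361))
  expect_equal(bins$count, c(2L, 1L, 0L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(sum(bins$count), 5L)
})

test_that("bin shares reproduce the descriptive onset distribution", {
  counts <- c(202, 119, 58, 36, 16, 19, 68, 44)
  reps <- c(0, 31, 61, 91, 121, 151, 181, 361)
  values <- rep(reps, counts)
  bins <- bin_tto(values)
  expect_equal(bins$count, as.integer(counts))
  expect_equal(bins$pct[1], 35.9)
  expect_equal(round(sum(bins$count[4:8]) / sum(counts) * 100, 1), 32.6)
  expect_lt(abs(sum(bins$pct) - 100), 0.3)
})

test_that("the product-limit estimator matches hand computation", {
  km <- km_estimate(c(1, 2, 3))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$cuminc, 1 - km$surv)
  expect_true(all(diff(km$surv) <= 0))
  # all censored: survival stays at 1
  kmc <- km_estimate(c(1, 2, 3), events = c(0, 0, 0))
  expect_true(all(kmc$surv == 1))
  expect_error(km_estimate(numeric(0)), "empty")
})

test_that("without censoring the KM survival equals 1 - ECDF", {
  set.seed(4)
  x <- round(rweibull(500, 0.8, 76))
  km <- km_estimate(x)
  F <- ecdf(x)
  expect_equal(km$surv, 1 - F(km$time), tolerance = 1e-12)
  # interpolated quantiles back the median/IQR summary
  expect_equal(attr(km, "median"), unname(quantile(x, 0.5)))
})

test_that("log-rank is zero for identical groups and matches a naive oracle", {
  t0 <- c(3, 5, 8, 13, 21, 34)
  res0 <- logrank_test(c(t0, t0), rep(c("a", "b"), each = 6))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
  # hand-worked 6-subject two-group example
  time <- c(1, 3, 4, 5, 8, 9)
  group <- c("x", "y", "x", "y", "x", "y")
  event <- c(1, 1, 1, 0, 1, 1)
  res <- logrank_test(time, group, event)
  expect_equal(res$statistic, naive_logrank2(time, event, group),
               tolerance = 1e-10)
  expect_equal(res$df, 1L)
  # invariant to group label order
  res2 <- logrank_test(time, ifelse(group == "x", "y", "x"), event)
  expect_equal(res$statistic, res2$statistic, tolerance = 1e-12)
  expect_error(logrank_test(1:3, c("a", "a", "a")), "two groups")
})
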