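# Case/non-case risk-factor analysis.

test_that("univariate odds ratios reproduce the printed 2x2 margins", {
  rtx <- univariate_or(53, 90, 164, 1494)
  expect_equal(round(rtx$or, 2), 5.36)
  expect_equal(round(rtx$lo, 2), 3.68)
  expect_equal(round(rtx$hi, 2), 7.81)
  expect_lt(rtx$p, 0.001)
  male <- univariate_or(44, 99, 694, 964)
  expect_equal(round(male$or, 2), 0.62)
  expect_equal(round(male$lo, 2), 0.43)
  expect_equal(round(male$hi, 2), 0.89)
  expect_equal(round(male$p, 3), 0.010)
  null <- univariate_or(10, 10, 10, 10)
  expect_equal(null$or, 1)
  expect_equal(round(null$p, 3), 1)
  z <- univariate_or(0, 10, 10, 10)
  expect_true(is.na(z$or) && z$reason == "zero cell")
})

test_that("exposure flags match drug rows and spare the target PS entry", {
  dir <- write_toy_quarter()
  # add rituximab as concomitant on 1011 and avacopan PS on 1031
  cat("1011$101$2$C$Rituximab\n", file = file.path(dir, "DRUG.txt"),
      append = TRUE)
  db <- parse_quarter_files(dir)
  fl <- exposure_flags(db, target = "AVACOPAN")
  expect_true(fl[fl$primaryid == "1011"]$RTX)
  expect_false(any(fl[fl$primaryid == "1031", c("RTX", "CTX", "PPI", "STATIN")] == TRUE))
  # avacopan's own PS row never defines an exposure even if listed as a class
  fl2 <- exposure_flags(db, classes = list(AVA = "AVACOPAN"),
                        target = "AVACOPAN")
  expect_false(fl2[fl2$primaryid == "1011"]$AVA)  # PS entry excluded
  expect_true(fl2[fl2$primaryid == "1021"]$AVA)   # C role counts
})

test_that("risk rows are complete-case and outcome follows the SOC", {
  b <- simulate_reports(sim_config(n_reports = 1500, seed = 61))
  m <- meddra_map(default_event_catalog()$pt, default_event_catalog()$soc)
  db <- map_pt_to_soc(as_report_db(b), m)
  rows <- build_risk_rows(db, target = "AVACOPAN")
  r <- db$reports
  expect_equal(nrow(rows), sum(!is.na(r$age) & !is.na(r$sex)))
  case_ids <- unique(db$reactions[db$reactions$soc == "Hepatobiliary disorders"]$primaryid)
  expect_setequal(rows$primaryid[rows$outcome],
                  intersect(case_ids, rows$primaryid))
  expect_true(all(levels(rows$age_band) == c("<45", "45-65", "65-75", ">75")))
})

test_that("exposure prevalences on synthetic data match the catalog", {
  b <- simulate_reports(sim_config(n_reports = 8000, seed = 62))
  db <- as_report_db(b)
  fl <- exposure_flags(db, target = "AVACOPAN")
  cc <- default_concomitant_catalog()
  for (i in seq_len(nrow(cc))) {
    cl <- if (cc$class[i] == "PPI") "PPI" else cc$class[i]
    col <- c(RTX = "RTX", CTX = "CTX", PPI = "PPI", STATIN = "STATIN")[[cc$class[i]]]
    expect_lt(abs(mean(fl[[col]]) - cc$prev[i]),
              4 * sqrt(cc$prev[i] * (1 - cc$prev[i]) / nrow(fl)))
  }
})

test_that("a single binary covariate matches the collapsed 2x2 odds ratio", {
  set.seed(5)
  n <- 4000
  x <- runif(n) < 0.3
  y <- runif(n) < plogis(-2 + 1.2 * x)
  rows <- data.frame(outcome = y, RTX = x)
  f <- fit_logistic(rows, covariates = "RTX")
  u <- univariate_or(sum(x & y), sum(!x & y), sum(x & !y), sum(!x & !y))
  expect_equal(f$coefficients[f$coefficients$term == "RTXTRUE"]$or, u$or,
               tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("rank deficiency and separation raise named errors", {
  rows <- data.frame(outcome = c(TRUE, FALSE, TRUE, FALSE),
                     RTX = c(TRUE, TRUE, TRUE, TRUE))
  expect_error(fit_logistic(rows, covariates = "RTX"), "rank-deficient")
  sep <- data.frame(outcome = rep(c(TRUE, FALSE), each = 50),
                    RTX = rep(c(TRUE, FALSE), each = 50))
  expect_error(fit_logistic(sep, covariates = "RTX"), "separation")
  expect_error(fit_logistic(data.frame(outcome = rep(TRUE, 5),
                                       RTX = rep(FALSE, 5))),
               "at least one case")
})

test_that("multivariable fit recovers known coefficients on one cohort", {
  rows <- simulate_risk_cohort(50000, seed = 71)
  truth <- attr(rows, "coefs")
  f <- fit_logistic(rows)
  cf <- setNames(f$coefficients$coef, f$coefficients$term)
  se <- setNames(f$coefficients$se, f$coefficients$term)
  for (pair in list(c("RTXTRUE", "RTX"), c("PPITRUE", "PPI"),
                    c("sexmale", "male"), c("age_band>75", "age_gt75"))) {
    # within 3.5 standard errors of the generating coefficient
    expect_lt(abs(cf[[pair[1]]] - truth[[pair[2]]]), 3.5 * se[[pair[1]]])
  }
})
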