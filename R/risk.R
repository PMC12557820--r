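# Case/non-case analysis of hepatobiliary risk factors: outcome and
# exposure definition, univariate 2x2 odds ratios with Wald inference,
# and the multivariable logistic model.

#' Default concomitant drug-class synonym lists
#'
#' Editable lists matching normalized FAERS drug names to the exposure
#' classes of the risk model: rituximab (RTX), cyclophosphamide (CTX),
#' proton-pump inhibitors (PPIs) and statins.
#'
#' @return named list of character vectors.
#' @export
default_drug_classes <- function() {
  list(
    RTX = c("RITUXIMAB", "RITUXAN", "MABTHERA", "TRUXIMA", "RUXIENCE"),
    CTX = c("CYCLOPHOSPHAMIDE", "CYTOXAN", "ENDOXAN"),
    PPI = c("OMEPRAZOLE", "PANTOPRAZOLE", "ESOMEPRAZOLE", "LANSOPRAZOLE",
            "RABEPRAZOLE", "DEXLANSOPRAZOLE"),
    STATIN = c("ATORVASTATIN", "SIMVASTATIN", "ROSUVASTATIN", "PRAVASTATIN",
               "LOVASTATIN", "PITAVASTATIN", "FLUVASTATIN"))
}

#' Read drug-class synonym lists from a TSV file
#'
#' @param path TSV with columns `class` and `name`.
#' @return named list of normalized synonym vectors.
#' @export
read_drug_classes <- function(path) {
  m <- data.table::fread(path, sep = "\t", colClasses = "character")
  names(m) <- tolower(names(m))
  stopifnot(all(c("class", "name") %in% names(m)))
  split(normalize_name(m$name), m$class)
}

#' Exposure flags per report
#'
#' A class flag is true iff any drug entry of the report matches the class
#' synonym list, in any role other than the target drug's own
#' primary-suspect entry (configurable to non-suspect roles only).
#'
#' @param db a `report_db`.
#' @param classes named list of synonym vectors, see
#'   [default_drug_classes()].
#' @param target synonym list for the target drug (its PS rows are never
#'   counted as exposures).
#' @param roles drug roles eligible to define exposure; default all four.
#' @return data.table: `primaryid` plus one logical column per class.
#' @export
exposure_flags <- function(db, classes = default_drug_classes(),
                           target = NULL, roles = c("PS", "SS", "C", "I")) {
  stopifnot(inherits(db, "report_db"))
  dr <- db$drugs[role %in% roles]
  if (!is.null(target)) {
    syn <- normalize_name(target)
    dr <- dr[!(role == "PS" & name %in% syn)]
  }
  out <- data.table::data.table(primaryid = db$reports$primaryid)
  for (cl in names(classes)) {
    ids <- unique(dr[name %in% normalize_name(classes[[cl]]), primaryid])
    out[[cl]] <- out$primaryid %in% ids
  }
  out
}

#' Assemble case/non-case rows for the risk model
#'
#' A report is a case when at least one of its PTs maps to the outcome
#' SOC. Age is banded `<45, 45-65, 65-75, >75`; reports with unknown age
#' or sex are excluded (complete-case analysis).
#'
#' @param db a deduplicated, SOC-annotated, primary-suspect filtered
#'   `report_db`.
#' @param outcome_soc SOC defining cases (default
#'   `"Hepatobiliary disorders"`).
#' @param classes exposure synonym lists.
#' @param target target-drug synonyms (excluded from exposures).
#' @return data.table `primaryid`, `outcome`, `age_band`, `sex`, one
#'   logical column per exposure class.
#' @export
build_risk_rows <- function(db, outcome_soc = "Hepatobiliary disorders",
                            classes = default_drug_classes(), target = NULL) {
  stopifnot(inherits(db, "report_db"))
  if (!"soc" %in% names(db$reactions))
    stop_invalid("risk rows require a SOC-annotated database")
  case_ids <- unique(db$reactions[soc == outcome_soc, primaryid])
  r <- db$reports[!is.na(age) & !is.na(sex)]
  fl <- exposure_flags(db, classes, target)
  rows <- data.table::data.table(
    primaryid = r$primaryid,
    outcome = r$primaryid %in% case_ids,
    age_band = cut(r$age, breaks = c(-Inf, 45, 65, 75, Inf),
                   labels = c("<45", "45-65", "65-75", ">75"), right = FALSE),
    sex = factor(data.table::fifelse(r$sex == "M", "male", "female"),
                 levels = c("female", "male")))
  rows <- fl[rows, on = "primaryid"]
  data.table::setcolorder(rows, c("primaryid", "outcome", "age_band", "sex"))
  rows[]
}

#' Univariate odds ratio from a 2x2 exposure table
#'
#' `OR = (exposed cases x unexposed controls) / (unexposed cases x exposed
#' controls)` with Wald interval `exp(ln OR +/- 1.96 SE)`,
#' `SE = sqrt(sum 1/count)`, and a two-sided normal p-value for
#' `z = ln OR / SE`.
#'
#' @param exposed_cases,unexposed_cases,exposed_controls,unexposed_controls
#'   the four counts; all must be positive for the statistic to be
#'   defined.
#' @return list `or`, `lo`, `hi`, `p` (full precision), `display` (OR and
#'   CI to 2 decimals, p to 3), `reason`.
#' @export
univariate_or <- function(exposed_cases, unexposed_cases,
                          exposed_controls, unexposed_controls) {
  cells <- c(exposed_cases, unexposed_cases, exposed_controls,
             unexposed_controls)
  if (any(cells < 0)) stop_invalid("counts must be non-negative")
  if (any(cells == 0))
    return(list(or = NA_real_, lo = NA_real_, hi = NA_real_, p = NA_real_,
                display = NULL, reason = "zero cell"))
  or <- (exposed_cases * unexposed_controls) /
    (unexposed_cases * exposed_controls)
  se <- sqrt(sum(1 / cells))
  z <- log(or) / se
  p <- 2 * pnorm(-abs(z))
  list(or = or, lo = exp(log(or) - 1.96 * se), hi = exp(log(or) + 1.96 * se),
       p = p,
       display = sprintf("%.2f (%.2f-%.2f, p = %.3f)", round(or, 2),
                         round(exp(log(or) - 1.96 * se), 2),
                         round(exp(log(or) + 1.96 * se), 2), round(p, 3)),
       reason = NA_character_)
}

#' Fit the multivariable case/non-case logistic model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) of the case indicator on age band, sex and the exposure
#' classes, with reference levels age `<45`, `female`, unexposed. Errors
#' on rank deficiency and on separation (any coefficient diverging beyond
#' 15 in absolute value).
#'
#' @param rows data from [build_risk_rows()] or [simulate_risk_cohort()]:
#'   must contain `outcome`, `age_band`, `sex` and logical exposure
#'   columns.
#' @param covariates character vector of right-hand-side terms; default
#'   all covariate columns present.
#' @return object of class `logistic_fit`: coefficient table with odds
#'   ratios, Wald 95% intervals and p-values, plus `converged`,
#'   `iterations`, `loglik`.
#' @export
fit_logistic <- function(rows, covariates = NULL) {
  rows <- as.data.frame(rows)
  stopifnot("outcome" %in% names(rows))
  if (is.null(covariates))
    covariates <- setdiff(names(rows), c("outcome", "primaryid"))
  if (sum(rows$outcome) == 0L || sum(!rows$outcome) == 0L)
    stop_invalid("need at least one case and one non-case")
  fml <- as.formula(paste("outcome ~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(
    glm(fml, data = rows, family = binomial(),
        control = stats::glm.control(epsilon = 1e-10, maxit = 50)))
  cf <- coef(fit)
  if (anyNA(cf))
    stop_invalid("rank-deficient design; drop term(s): ",
                 paste(names(cf)[is.na(cf)], collapse = ", "))
  big <- abs(cf[-1]) > 15
  if (any(big))
    stop_invalid("separation detected for term(s): ",
                 paste(names(cf[-1])[big], collapse = ", "))
  se <- sqrt(diag(vcov(fit)))
  tab <- data.table::data.table(
    term = names(cf), coef = unname(cf), se = unname(se),
    or = exp(unname(cf)),
    or_lo = exp(unname(cf) - 1.96 * unname(se)),
    or_hi = exp(unname(cf) + 1.96 * unname(se)),
    p = 2 * pnorm(-abs(unname(cf) / unname(se))))
  structure(list(coefficients = tab, converged = fit$converged,
                 iterations = fit$iter, loglik = as.numeric(logLik(fit)),
                 model = fml, n = nrow(rows), n_cases = sum(rows$outcome)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>", x$n, "rows,", x$n_cases, "cases;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations; logLik", round(x$loglik, 2), "\n")
  print(x$coefficients[, .(term, or = round(or, 2), or_lo = round(or_lo, 2),
                           or_hi = round(or_hi, 2), p = signif(p, 3))])
  invisible(x)
}
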