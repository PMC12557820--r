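# Synthetic spontaneous-reporting-system generator.
#
# Emulates a FAERS-style quarterly extract (DEMO/DRUG/REAC/OUTC/THER/INDI)
# with planted drug-event associations, report duplication, and realistic
# missingness, so every downstream stage can be exercised and calibrated
# without access to the real database.

#' Adjust an event probability to plant a target odds ratio
#'
#' Inverts the odds-ratio definition: given a background probability `p0`
#' and a target odds ratio `target_or`, returns the probability `p1` whose
#' odds are `target_or` times the background odds,
#' `p1 = OR * p0 / (1 - p0 + OR * p0)`.
#'
#' @param p0 background probability, strictly inside (0, 1).
#' @param target_or non-negative target odds ratio.
#' @return adjusted probability in `[0, 1)`.
#' @examples
#' plant_association(0.3, 1)   # unchanged
#' plant_association(0.01, 5)  # 0.048077
#' @export
plant_association <- function(p0, target_or) {
  if (!is.numeric(p0) || any(is.na(p0)) || any(p0 <= 0) || any(p0 >= 1))
    stop_invalid("`p0` must lie strictly inside (0, 1)")
  if (!is.numeric(target_or) || any(is.na(target_or)) || any(target_or < 0))
    stop_invalid("`target_or` must be non-negative")
  target_or * p0 / (1 - p0 + target_or * p0)
}

#' Default drug catalog for the synthetic generator
#'
#' One target drug plus a background of comparator drugs with sampling
#' weights for the primary-suspect slot of each report.
#'
#' @param target name of the target drug.
#' @return data.table with columns `name` and `weight`.
#' @export
default_drug_catalog <- function(target = "AVACOPAN") {
  data.table::data.table(
    name = c(target, sprintf("COMPARATOR_%02d", 1:12)),
    weight = c(0.15, rep(0.85 / 12, 12))
  )
}

#' Default adverse-event (PT) catalog for the synthetic generator
#'
#' Toy MedDRA-like vocabulary spanning the organ classes the analysis
#' exercises (hepatobiliary terms, infections, gastrointestinal terms, ...).
#' `prob` is the approximate per-report presence probability; probabilities
#' sum to about 2.3 so the default event load matches the events-per-report
#' mean of the study conditions.
#'
#' @return data.table with columns `pt`, `soc`, `prob`.
#' @export
default_event_catalog <- function() {
  heb <- "Hepatobiliary disorders"
  inf <- "Infections and infestations"
  gis <- "Gastrointestinal disorders"
  gen <- "General disorders and administration site conditions"
  nrv <- "Nervous system disorders"
  inv <- "Investigations"
  ren <- "Renal and urinary disorders"
  rsp <- "Respiratory, thoracic and mediastinal disorders"
  skn <- "Skin and subcutaneous tissue disorders"
  vas <- "Vascular disorders"
  msk <- "Musculoskeletal and connective tissue disorders"
  data.table::data.table(rbind(
    data.frame(pt = c("Hepatic function abnormal", "Liver disorder",
                      "Drug-induced liver injury", "Jaundice", "Cholestasis",
                      "Hepatitis acute", "Vanishing bile duct syndrome"),
               soc = heb,
               prob = c(0.030, 0.025, 0.020, 0.012, 0.008, 0.004, 0.002)),
    data.frame(pt = c("Pneumonia", "COVID-19", "Infection", "Sepsis",
                      "Cytomegalovirus infection", "Urinary tract infection"),
               soc = inf,
               prob = c(0.060, 0.050, 0.040, 0.020, 0.010, 0.030)),
    data.frame(pt = c("Diarrhoea", "Nausea", "Vomiting", "Abdominal discomfort"),
               soc = gis, prob = c(0.160, 0.150, 0.090, 0.060)),
    data.frame(pt = c("Fatigue", "Illness", "Condition aggravated", "Pyrexia"),
               soc = gen, prob = c(0.180, 0.080, 0.050, 0.060)),
    data.frame(pt = c("Headache", "Dizziness"), soc = nrv,
               prob = c(0.130, 0.080)),
    data.frame(pt = c("Hepatic enzyme increased",
                      "Alanine aminotransferase increased",
                      "Blood creatinine increased"),
               soc = inv, prob = c(0.030, 0.020, 0.030)),
    data.frame(pt = c("Renal impairment", "Renal failure"), soc = ren,
               prob = c(0.040, 0.025)),
    data.frame(pt = c("Dyspnoea", "Cough"), soc = rsp, prob = c(0.090, 0.070)),
    data.frame(pt = c("Rash", "Alopecia"), soc = skn, prob = c(0.100, 0.045)),
    data.frame(pt = "Hypertension", soc = vas, prob = 0.080),
    data.frame(pt = c("Arthralgia", "Myalgia"), soc = msk,
               prob = c(0.090, 0.050))
  ))
}

#' Default concomitant-medication catalog
#'
#' Drug classes used by the risk-factor module, with per-report sampling
#' prevalences calibrated to the overall exposure margins of the study
#' population (rituximab about 12%, cyclophosphamide 4%, proton-pump
#' inhibitors 7%, statins 4%).
#'
#' @return data.table with columns `class`, `name`, `prev`.
#' @export
default_concomitant_catalog <- function() {
  data.table::data.table(
    class = c("RTX", "CTX", "PPI", "STATIN"),
    name = c("RITUXIMAB", "CYCLOPHOSPHAMIDE", "OMEPRAZOLE", "ATORVASTATIN"),
    prev = c(0.12, 0.04, 0.07, 0.04)
  )
}

#' Configuration for the synthetic report generator
#'
#' Validates and assembles the generator settings. Defaults encode the
#' study conditions: 2.3 distinct events per report, 42.1% unknown age,
#' 35.8% unknown sex, onset dates on 17.8% of reports, a Weibull onset
#' delay with median near 48 days, and report-level outcome frequencies
#' (hospitalization 23.3%, death 7.5%, ...).
#'
#' @param n_reports number of unique (pre-duplication) reports.
#' @param drug_catalog data.frame `name`, `weight` for the PS drug.
#' @param event_catalog data.frame `pt`, `soc`, `prob`.
#' @param planted_signals data.frame `drug`, `pt`, `or` of target odds
#'   ratios planted for reports whose PS drug matches.
#' @param events_per_report_mean mean number of distinct PTs per report
#'   (zero-truncated Poisson event load).
#' @param outcome_probs named probabilities over outcome codes
#'   `HO, DE, LT, DS, OT, RI, unknown`; must sum to 1.
#' @param missing_age_rate,missing_sex_rate proportion of reports with
#'   unknown age / sex.
#' @param onset_date_rate proportion of reports carrying full therapy-start
#'   and event dates (the time-to-onset denominator).
#' @param partial_date_rate proportion of the carried onset dates degraded
#'   to `YYYYMM`/`YYYY` precision, to exercise partial-date handling.
#' @param duplicate_rate proportion of reports later duplicated by
#'   [inject_duplicates()] when the pipeline requests it.
#' @param concomitant_catalog data.frame `class`, `name`, `prev` of
#'   co-medications sampled into non-PS roles.
#' @param tto_shape,tto_scale Weibull shape/scale of the onset delay, days.
#' @param date_range character `YYYYMMDD` bounds for FDA receipt dates.
#' @param seed integer seed; equal configurations with equal seeds give
#'   byte-identical bundles.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_reports = 3150L,
                       drug_catalog = default_drug_catalog(),
                       event_catalog = default_event_catalog(),
                       planted_signals = NULL,
                       events_per_report_mean = 2.3,
                       outcome_probs = c(HO = 0.233, DE = 0.075, LT = 0.011,
                                         DS = 0.001, OT = 0.177, RI = 0.0003,
                                         unknown = 0.5027),
                       missing_age_rate = 0.421,
                       missing_sex_rate = 0.358,
                       onset_date_rate = 0.178,
                       partial_date_rate = 0,
                       duplicate_rate = 0,
                       concomitant_catalog = default_concomitant_catalog(),
                       tto_shape = 0.8,
                       tto_scale = 76,
                       date_range = c("20220101", "20241231"),
                       seed = 1L) {
  n_reports <- as.integer(n_reports)
  if (is.na(n_reports) || n_reports < 0L)
    stop_invalid("`n_reports` must be a non-negative integer")
  drug_catalog <- data.table::as.data.table(drug_catalog)
  event_catalog <- data.table::as.data.table(event_catalog)
  if (n_reports > 0L && (nrow(drug_catalog) == 0L || nrow(event_catalog) == 0L))
    stop_invalid("drug and event catalogs must be non-empty when n_reports > 0")
  if (nrow(event_catalog) &&
      (any(event_catalog$prob <= 0) || any(event_catalog$prob >= 1)))
    stop_invalid("event catalog probabilities must lie in (0, 1)")
  if (nrow(drug_catalog) && any(drug_catalog$weight < 0))
    stop_invalid("drug weights must be non-negative")
  if (!is.null(planted_signals)) {
    planted_signals <- data.table::as.data.table(planted_signals)
    stopifnot(all(c("drug", "pt", "or") %in% names(planted_signals)))
    if (any(planted_signals$or < 0))
      stop_invalid("planted target odds ratios must be non-negative")
    if (!all(planted_signals$pt %in% event_catalog$pt))
      stop_invalid("planted PTs must appear in the event catalog")
    if (!all(planted_signals$drug %in% drug_catalog$name))
      stop_invalid("planted drugs must appear in the drug catalog")
  }
  if (abs(sum(outcome_probs) - 1) > 1e-9)
    stop_invalid("`outcome_probs` must sum to 1")
  if (any(outcome_probs < 0) || any(outcome_probs > 1))
    stop_invalid("`outcome_probs` must lie in [0, 1]")
  for (r in c(missing_age_rate, missing_sex_rate, onset_date_rate,
              partial_date_rate, duplicate_rate))
    if (!is_prob(r)) stop_invalid("rates must be proportions in [0, 1]")
  if (events_per_report_mean <= 1)
    stop_invalid("`events_per_report_mean` must exceed 1 (zero-truncated load)")
  if (tto_shape <= 0 || tto_scale <= 0)
    stop_invalid("Weibull onset-delay parameters must be positive")
  structure(list(
    n_reports = n_reports, drug_catalog = drug_catalog,
    event_catalog = event_catalog, planted_signals = planted_signals,
    events_per_report_mean = events_per_report_mean,
    outcome_probs = outcome_probs, missing_age_rate = missing_age_rate,
    missing_sex_rate = missing_sex_rate, onset_date_rate = onset_date_rate,
    partial_date_rate = partial_date_rate, duplicate_rate = duplicate_rate,
    concomitant_catalog = data.table::as.data.table(concomitant_catalog),
    tto_shape = tto_shape, tto_scale = tto_scale, date_range = date_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Zero-truncated Poisson draw via inverse CDF conditional on K >= 1.
rztpois <- function(n, lambda) {
  u <- runif(n, min = ppois(0, lambda), max = 1)
  qpois(u, lambda)
}

# Expected number of *distinct* PTs per report when K event slots are drawn
# with replacement from shares v and deduplicated, K ~ ZTP(lambda).
ztp_distinct_mean <- function(lambda, v) {
  kmax <- max(2L, qpois(1 - 1e-12, lambda) + 2L)
  k <- seq_len(kmax)
  pk <- dpois_zt <- exp(k * log(lambda) - lambda - lgamma(k + 1)) / (1 - exp(-lambda))
  distinct_k <- vapply(k, function(kk) sum(1 - (1 - v)^kk), numeric(1))
  sum(pk * distinct_k)
}

# Solve for the ZTP rate whose deduplicated event load matches the target.
calibrate_event_load <- function(target_mean, v) {
  uniroot(function(l) ztp_distinct_mean(l, v) - target_mean,
          lower = 1e-3, upper = 60, tol = 1e-10)$root
}

random_dates <- function(n, range) {
  lo <- as.Date(range[1], "%Y%m%d")
  hi <- as.Date(range[2], "%Y%m%d")
  d <- lo + floor(runif(n) * (as.numeric(hi - lo) + 1))
  format(d, "%Y%m%d")
}

degrade_date <- function(x, which_partial) {
  # which_partial: logical; degraded half to YYYYMM, half to YYYY
  if (!any(which_partial)) return(x)
  idx <- which(which_partial)
  to_month <- idx[seq_along(idx) %% 2L == 1L]
  to_year <- setdiff(idx, to_month)
  x[to_month] <- substr(x[to_month], 1, 6)
  x[to_year] <- substr(x[to_year], 1, 4)
  x
}

#' Simulate a spontaneous-reporting bundle
#'
#' Generates the six FAERS-style tables for `n_reports` unique reports.
#' Each report has one primary-suspect (PS) drug drawn from the drug
#' catalog; its distinct reaction terms are drawn by sampling a
#' zero-truncated Poisson number of event slots from the catalog's
#' normalized probability shares (deduplicated within report), with the
#' shares of planted (drug, PT) pairs boosted through [plant_association()]
#' when the report's PS drug matches. The slot-share construction makes the
#' report-level event-versus-other-events odds ratio of a planted pair equal
#' its target, so the downstream reporting odds ratio is calibrated.
#'
#' The attached `truth` attribute records what downstream stages should
#' recover: the deduplication survivor list, PS report counts per drug, and
#' the total report-PT pair count.
#'
#' @param config a [sim_config()] object.
#' @return object of class `srs_bundle`: a list of data.tables
#'   `demo`, `drug`, `reac`, `outc`, `ther`, `indi` with attributes
#'   `truth` and `config`.
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  empty <- function(cols) {
    dt <- data.table::as.data.table(setNames(rep(list(character()), length(cols)), cols))
    dt
  }
  if (n == 0L) {
    b <- structure(list(
      demo = empty(c("primaryid", "caseid", "fda_dt", "event_dt", "age",
                     "sex", "wt", "reporter", "occr_country")),
      drug = empty(c("primaryid", "caseid", "drug_seq", "role_cod", "drugname")),
      reac = empty(c("primaryid", "caseid", "pt")),
      outc = empty(c("primaryid", "caseid", "outc_cod")),
      ther = empty(c("primaryid", "caseid", "dsg_drug_seq", "start_dt")),
      indi = empty(c("primaryid", "caseid", "indi_drug_seq", "indi_pt"))
    ), class = "srs_bundle")
    attr(b, "truth") <- list(
      survivors = data.table::data.table(caseid = character(),
                                         primaryid = character()),
      ps_counts = data.table::data.table(drug = character(), n = integer()),
      n_event_pairs = 0L)
    attr(b, "config") <- config
    return(b)
  }

  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")
  fda_dt <- random_dates(n, config$date_range)

  # demographics: age ~ N(60.8, 17) truncated to [1, 99]; sex 59.1% female
  # among known (both calibrated to the study's descriptive table)
  age <- round(pmin(99, pmax(1, rnorm(n, 60.8, 17))))
  age[runif(n) < config$missing_age_rate] <- NA
  sex <- ifelse(runif(n) < 0.591, "F", "M")
  sex[runif(n) < config$missing_sex_rate] <- ""
  wt <- round(rnorm(n, 75, 15), 1)
  wt[runif(n) < 0.91] <- NA
  reporter <- sample(c("CN", "MD", "OT", "PH", ""), n, TRUE,
                     prob = c(0.52, 0.22, 0.13, 0.06, 0.07))
  country <- sample(c("US", "JP", "GB", "CA", "FR", "DE"), n, TRUE,
                    prob = c(0.763, 0.127, 0.032, 0.030, 0.015, 0.033))

  # PS drug per report
  dc <- config$drug_catalog
  ps_idx <- sample.int(nrow(dc), n, TRUE, prob = dc$weight)
  ps_drug <- dc$name[ps_idx]

  # reaction slot shares: background and per planted drug
  ec <- config$event_catalog
  v0 <- ec$prob / sum(ec$prob)
  share_for_drug <- function(drug) {
    ps <- config$planted_signals
    if (is.null(ps)) return(v0)
    ps <- ps[ps$drug == drug, ]
    if (nrow(ps) == 0L) return(v0)
    v <- v0
    j <- match(ps$pt, ec$pt)
    v[j] <- ifelse(ps$or == 0, 0, plant_association(v0[j], ps$or))
    # rescale the unplanted mass so shares still sum to one; this preserves
    # the planted event-vs-rest odds exactly
    rest <- setdiff(seq_along(v), j)
    v[rest] <- v[rest] * (1 - sum(v[j])) / (1 - sum(v0[j]))
    v
  }
  planted_drugs <- if (is.null(config$planted_signals)) character() else
    unique(config$planted_signals$drug)
  lambda <- calibrate_event_load(config$events_per_report_mean, v0)
  k <- rztpois(n, lambda)
  slot_report <- rep(seq_len(n), k)
  slot_pt <- integer(length(slot_report))
  grp <- ifelse(ps_drug %in% planted_drugs, ps_drug, "")
  for (g in unique(grp)) {
    v <- if (g == "") v0 else share_for_drug(g)
    sel <- grp[slot_report] == g
    slot_pt[sel] <- sample.int(nrow(ec), sum(sel), TRUE, prob = v)
  }
  reac <- unique(data.table::data.table(rid = slot_report, pt = ec$pt[slot_pt]))

  # outcomes: one sampled report-level outcome; "unknown" emits no OUTC row
  oc <- sample(names(config$outcome_probs), n, TRUE, prob = config$outcome_probs)

  # onset dates: event_dt = therapy start + Weibull delay for ~onset_date_rate
  # of reports; a further slice carries a start date only
  has_onset <- runif(n) < config$onset_date_rate
  event_dt <- rep("", n)
  start_dt <- rep("", n)
  delay <- round(rweibull(n, config$tto_shape, config$tto_scale))
  ev <- as_date8(fda_dt) - rpois(n, 30)
  start_known_only <- !has_onset & runif(n) < 0.3
  start_dt[has_onset] <- format(ev[has_onset] - delay[has_onset], "%Y%m%d")
  event_dt[has_onset] <- format(ev[has_onset], "%Y%m%d")
  start_dt[start_known_only] <- format(ev[start_known_only] - delay[start_known_only], "%Y%m%d")
  if (config$partial_date_rate > 0) {
    deg <- has_onset & runif(n) < config$partial_date_rate
    start_dt <- degrade_date(start_dt, deg)
  }

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    event_dt = event_dt, age = ifelse(is.na(age), "", as.character(age)),
    sex = sex, wt = ifelse(is.na(wt), "", as.character(wt)),
    reporter = reporter, occr_country = country)

  drug <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, drug_seq = 1L,
    role_cod = "PS", drugname = ps_drug)
  ther <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, dsg_drug_seq = 1L,
    start_dt = start_dt)[start_dt != ""]

  # concomitant co-medications in non-PS roles
  cc <- config$concomitant_catalog
  if (nrow(cc)) {
    con <- list()
    for (i in seq_len(nrow(cc))) {
      take <- which(runif(n) < cc$prev[i])
      if (!length(take)) next
      con[[length(con) + 1L]] <- data.table::data.table(
        primaryid = primaryid[take], caseid = caseid[take],
        drug_seq = 1L + i,
        role_cod = sample(c("SS", "C", "I"), length(take), TRUE,
                          prob = c(0.25, 0.65, 0.10)),
        drugname = cc$name[i])
    }
    if (length(con)) drug <- data.table::rbindlist(c(list(drug), con))
  }
  data.table::setorder(drug, primaryid, drug_seq)

  reac_out <- data.table::data.table(
    primaryid = primaryid[reac$rid], caseid = caseid[reac$rid], pt = reac$pt)
  outc <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, outc_cod = oc)[outc_cod != "unknown"]
  indi <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, indi_drug_seq = 1L,
    indi_pt = "ANCA associated vasculitis")

  b <- structure(list(demo = demo, drug = drug, reac = reac_out, outc = outc,
                      ther = ther, indi = indi), class = "srs_bundle")
  attr(b, "truth") <- list(
    survivors = data.table::data.table(caseid = caseid, primaryid = primaryid),
    ps_counts = data.table::data.table(drug = ps_drug)[, .(n = .N), by = "drug"],
    n_event_pairs = nrow(reac_out))
  attr(b, "config") <- config
  b
}

#' @export
print.srs_bundle <- function(x, ...) {
  cat("<srs_bundle>", nrow(x$demo), "DEMO rows,",
      nrow(x$drug), "DRUG rows,", nrow(x$reac), "REAC rows\n")
  tr <- attr(x, "truth")
  if (!is.null(tr))
    cat("  ground truth:", nrow(tr$survivors), "survivor reports,",
        tr$n_event_pairs, "report-PT pairs\n")
  invisible(x)
}

#' Inject duplicate report versions into a bundle
#'
#' A fraction `rate` of reports gains one or more extra versions that share
#' the caseid, carry a strictly larger primaryid and a later-or-equal FDA
#' receipt date, and replicate all child rows. The returned bundle's
#' `truth$survivors` attribute records, per caseid, the primaryid that the
#' deduplication rule (latest `fda_dt`, then largest primaryid) must retain.
#'
#' @param bundle an `srs_bundle`.
#' @param rate proportion of reports to duplicate, in `[0, 1]`.
#' @param seed integer seed for the injection.
#' @return a new `srs_bundle` with duplicates and updated ground truth.
#' @export
inject_duplicates <- function(bundle, rate, seed = 1L) {
  stopifnot(inherits(bundle, "srs_bundle"))
  if (!is_prob(rate)) stop_invalid("`rate` must be a proportion in [0, 1]")
  if (rate == 0 || nrow(bundle$demo) == 0L) return(bundle)
  set.seed(as.integer(seed))
  demo <- bundle$demo
  pick <- which(runif(nrow(demo)) < rate)
  if (!length(pick)) return(bundle)
  truth <- attr(bundle, "truth")
  surv <- data.table::copy(truth$survivors)
  extra <- list(demo = list(), drug = list(), reac = list(), outc = list(),
                ther = list(), indi = list())
  child_tabs <- c("drug", "reac", "outc", "ther", "indi")
  n_extra <- 1L + rpois(length(pick), 0.3)
  for (ii in seq_along(pick)) {
    i <- pick[ii]
    cid <- demo$caseid[i]
    base_pid <- demo$primaryid[i]
    fda <- as_date8(demo$fda_dt[i])
    for (v in seq_len(n_extra[ii])) {
      new_pid <- paste0(cid, as.character(1L + v))
      fda <- fda + rpois(1, 20)  # later or equal receipt date
      d <- demo[i]
      d[, `:=`(primaryid = new_pid, fda_dt = format(fda, "%Y%m%d"))]
      extra$demo[[length(extra$demo) + 1L]] <- d
      for (tb in child_tabs) {
        ch <- bundle[[tb]][caseid == cid & primaryid == base_pid]
        if (nrow(ch)) {
          ch <- data.table::copy(ch)[, primaryid := new_pid]
          extra[[tb]][[length(extra[[tb]]) + 1L]] <- ch
        }
      }
      # the newest version always wins the (fda_dt, primaryid) rule
      surv[caseid == cid, primaryid := new_pid]
    }
  }
  out <- bundle
  for (tb in names(extra)) {
    if (length(extra[[tb]]))
      out[[tb]] <- data.table::rbindlist(c(list(bundle[[tb]]), extra[[tb]]))
  }
  truth$survivors <- surv
  attr(out, "truth") <- truth
  attr(out, "config") <- attr(bundle, "config")
  class(out) <- "srs_bundle"
  out
}

#' Write a bundle as '$'-delimited FAERS-style tables
#'
#' @param bundle an `srs_bundle`.
#' @param dir output directory (one simulated quarter); created if needed.
#' @param truth also write the ground-truth survivor list as TSV.
#' @return invisibly, the paths written (named by table).
#' @export
write_srs_tables <- function(bundle, dir, truth = TRUE) {
  stopifnot(inherits(bundle, "srs_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names_up <- c(demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
                outc = "OUTC.txt", ther = "THER.txt", indi = "INDI.txt")
  paths <- character()
  for (tb in names(names_up)) {
    p <- file.path(dir, names_up[[tb]])
    data.table::fwrite(bundle[[tb]], p, sep = "$", quote = FALSE, na = "")
    paths[[tb]] <- p
  }
  tr <- attr(bundle, "truth")
  if (truth && !is.null(tr)) {
    p <- file.path(dir, "ground_truth_survivors.tsv")
    data.table::fwrite(tr$survivors, p, sep = "\t")
    paths[["truth"]] <- p
  }
  invisible(paths)
}

#' Simulate a case/non-case cohort from a known logistic model
#'
#' Direct covariate-level simulator used to validate the risk-factor
#' module by parameter recovery: age band, sex and four exposure classes
#' are drawn from study-calibrated margins and the hepatobiliary outcome
#' from the logistic model with the supplied coefficients.
#'
#' @param n cohort size.
#' @param coefs named log-odds coefficients: `intercept`, `age45_65`,
#'   `age65_75`, `age_gt75`, `male`, `RTX`, `CTX`, `PPI`, `STATIN`.
#' @param seed integer seed.
#' @return data.frame with factor covariates, logical exposures and a
#'   logical `outcome`; the generating coefficients are attached as
#'   attribute `coefs`.
#' @export
simulate_risk_cohort <- function(n,
                                 coefs = c(intercept = -3.2, age45_65 = 0,
                                           age65_75 = 1.0, age_gt75 = 1.2,
                                           male = -0.5, RTX = 1.06, CTX = 0.3,
                                           PPI = 1.5, STATIN = 0.4),
                                 seed = 1L) {
  set.seed(as.integer(seed))
  age_band <- sample(c("<45", "45-65", "65-75", ">75"), n, TRUE,
                     prob = c(0.179, 0.364, 0.226, 0.231))
  sex <- sample(c("female", "male"), n, TRUE, prob = c(0.581, 0.419))
  rtx <- runif(n) < 0.12
  ctx <- runif(n) < 0.04
  ppi <- runif(n) < 0.07
  statin <- runif(n) < 0.04
  eta <- coefs[["intercept"]] +
    coefs[["age45_65"]] * (age_band == "45-65") +
    coefs[["age65_75"]] * (age_band == "65-75") +
    coefs[["age_gt75"]] * (age_band == ">75") +
    coefs[["male"]] * (sex == "male") +
    coefs[["RTX"]] * rtx + coefs[["CTX"]] * ctx +
    coefs[["PPI"]] * ppi + coefs[["STATIN"]] * statin
  out <- data.frame(
    age_band = factor(age_band, levels = c("<45", "45-65", "65-75", ">75")),
    sex = factor(sex, levels = c("female", "male")),
    RTX = rtx, CTX = ctx, PPI = ppi, STATIN = statin,
    outcome = runif(n) < plogis(eta))
  attr(out, "coefs") <- coefs
  out
}
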