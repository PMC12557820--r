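# Pipeline orchestration: configuration, staged execution with count
# logging, and publication-shaped TSV outputs.

#' Assemble a pipeline configuration
#'
#' @param quarter_dirs character vector of directories holding the
#'   '$'-delimited quarterly tables.
#' @param target character synonym list for the target drug.
#' @param meddra_map_path TSV `pt`, `soc`.
#' @param ime_path,dme_path designation-list files.
#' @param drug_classes_path TSV `class`, `name` of exposure synonyms
#'   (NULL uses [default_drug_classes()]).
#' @param outcome_soc SOC defining the risk-model cases.
#' @param thresholds signal-positivity thresholds.
#' @param yates Yates-correct the PRR chi-square.
#' @param stratify optional `"sex"` or `"age"`: rerun the PT-level
#'   disproportionality within the strata as a subgroup analysis.
#' @param out_dir output directory for the TSV tables.
#' @param seed integer seed recorded in the run manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(quarter_dirs, target, meddra_map_path,
                            ime_path = NULL, dme_path = NULL,
                            drug_classes_path = NULL,
                            outcome_soc = "Hepatobiliary disorders",
                            thresholds = signal_thresholds(), yates = TRUE,
                            stratify = NULL, out_dir = tempfile("srsignal_"),
                            seed = 1L) {
  for (p in c(quarter_dirs, meddra_map_path, ime_path, dme_path,
              drug_classes_path))
    if (!is.null(p) && !file.exists(p))
      stop_invalid("configured path does not exist: ", p)
  if (!is.null(stratify)) stratify <- match.arg(stratify, c("sex", "age"))
  structure(list(quarter_dirs = quarter_dirs, target = target,
                 meddra_map_path = meddra_map_path, ime_path = ime_path,
                 dme_path = dme_path, drug_classes_path = drug_classes_path,
                 outcome_soc = outcome_soc, thresholds = thresholds,
                 yates = yates, stratify = stratify, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Plain-text key/value configuration mirroring the arguments of
#' [pipeline_config()]; relative paths are resolved against the file's
#' directory.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  pipeline_config(
    quarter_dirs = resolve(unlist(y$quarter_dirs)),
    target = unlist(y$target),
    meddra_map_path = resolve(y$meddra_map),
    ime_path = resolve(y$ime_list), dme_path = resolve(y$dme_list),
    drug_classes_path = resolve(y$drug_classes),
    outcome_soc = y$outcome_soc %||% "Hepatobiliary disorders",
    thresholds = utils::modifyList(signal_thresholds(),
                                   as.list(y$thresholds %||% list())),
    yates = y$yates %||% TRUE, stratify = y$stratify,
    out_dir = y$out_dir %||% tempfile("srsignal_"),
    seed = y$seed %||% 1L)
}

#' Descriptive characteristics table
#'
#' Report-level tabulations of sex, age bands, outcomes and the
#' time-to-onset bins, with percentages against the stated denominators:
#' reports for demographics and outcomes, non-missing onset records for
#' the bins.
#'
#' @param db primary-suspect filtered `report_db`.
#' @param target target synonyms (onset anchoring).
#' @return data.table `section`, `characteristic`, `count`, `pct`.
#' @export
descriptive_table <- function(db, target = NULL) {
  n <- n_reports(db)
  row <- function(section, characteristic, count, denom) {
    data.table::data.table(section = section, characteristic = characteristic,
                           count = count,
                           pct = if (denom > 0) round(100 * count / denom, 1)
                                 else NA_real_)
  }
  r <- db$reports
  out <- list(
    row("Sex", "Female", sum(r$sex == "F", na.rm = TRUE), n),
    row("Sex", "Male", sum(r$sex == "M", na.rm = TRUE), n),
    row("Sex", "Unknown", sum(is.na(r$sex)), n))
  age_bands <- cut(r$age, c(-Inf, 18, 65, 85, Inf),
                   labels = c("<18", "18-65", "65-85", ">=85"), right = FALSE)
  for (lv in levels(age_bands))
    out <- c(out, list(row("Age (years)", lv,
                           sum(age_bands == lv, na.rm = TRUE), n)))
  out <- c(out, list(row("Age (years)", "Unknown", sum(is.na(r$age)), n)))
  oc_label <- c(HO = "Hospitalization", DE = "Death", LT = "Life Threatening",
                DS = "Disability", OT = "Other Serious",
                RI = "Required intervention")
  with_outcome <- character(0)
  for (code in names(oc_label)) {
    ids <- unique(db$outcomes[outcome == code, primaryid])
    with_outcome <- union(with_outcome, ids)
    out <- c(out, list(row("Outcomes", oc_label[[code]], length(ids), n)))
  }
  out <- c(out, list(row("Outcomes", "Unknown", n - length(with_outcome), n)))
  tto <- compute_tto(db, target)
  bins <- bin_tto(tto$tto_days)
  out <- c(out, list(data.table::data.table(
    section = "Time-to-onset (days)", characteristic = bins$bin,
    count = bins$count, pct = bins$pct)))
  data.table::rbindlist(out)
}

stage <- function(name, expr) {
  res <- tryCatch(expr, error = function(e)
    stop_invalid("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  res
}

#' Run the full analysis pipeline
#'
#' Stages: ingest -> deduplicate -> primary-suspect filter -> SOC mapping
#' -> disproportionality (SOC and PT) -> clinical prioritization ->
#' time-to-onset -> risk models. Every stage logs its input/output record
#' counts; all result tables are written as TSV under the configured
#' output directory together with a run manifest (configuration hash and
#' seed).
#'
#' @param config a [pipeline_config()] object or path to a YAML file.
#' @return invisibly, a list with the result tables (`descriptive`,
#'   `soc_signals`, `pt_signals`, `priority`, `tto_bins`, `km`,
#'   `risk_univariate`, `risk_multivariable`, and per-stratum signal
#'   tables when stratified) and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  log_n <- function(...) message("[srsignal] ", ...)

  db <- stage("ingest", {
    dbs <- lapply(config$quarter_dirs, parse_quarter_files)
    db <- if (length(dbs) == 1L) dbs[[1]] else
      new_report_db(
        data.table::rbindlist(lapply(dbs, `[[`, "reports")),
        data.table::rbindlist(lapply(dbs, `[[`, "drugs")),
        data.table::rbindlist(lapply(dbs, `[[`, "reactions")),
        data.table::rbindlist(lapply(dbs, `[[`, "outcomes")))
    log_n("ingest: ", n_reports(db), " raw reports")
    db
  })
  db <- stage("deduplicate", {
    out <- deduplicate(db)
    log_n("deduplicate: ", n_reports(db), " -> ", n_reports(out), " reports")
    out
  })
  full_db <- stage("soc_map", {
    m <- read_meddra_map(config$meddra_map_path)
    map_pt_to_soc(db, m, unmapped = "bucket")
  })
  ps_db <- stage("ps_filter", filter_primary_suspect(full_db, config$target))

  signals_soc <- stage("signals_soc", {
    s <- signal_table(full_db, config$target, level = "SOC",
                      thresholds = config$thresholds, yates = config$yates)
    log_n("signals: ", nrow(s), " SOC terms")
    s
  })
  mgps_h <- attr(signals_soc, "mgps_hyper")
  signals_pt <- stage("signals_pt", {
    s <- signal_table(full_db, config$target, level = "PT",
                      thresholds = config$thresholds, yates = config$yates,
                      mgps_h = mgps_h)
    log_n("signals: ", nrow(s), " PT terms, ", sum(s$overall),
          " positive in all four algorithms")
    s
  })

  priority <- stage("prioritization", {
    lists <- if (!is.null(config$ime_path) && !is.null(config$dme_path))
      read_designation_lists(config$ime_path, config$dme_path)
    else designation_lists()
    p <- prioritize_signals(signals_pt, ps_db, lists)
    log_n("prioritization: ", nrow(p), " terms assessed")
    p
  })

  tto_res <- stage("tto", {
    tto <- compute_tto(ps_db, config$target)
    ok <- tto[reason == "ok"]
    log_n("tto: ", nrow(ok), " of ", nrow(tto), " reports with onset data")
    km <- if (nrow(ok)) km_estimate(ok$tto_days) else NULL
    list(tto = tto, bins = bin_tto(tto$tto_days), km = km)
  })

  risk <- stage("risk_models", {
    classes <- if (!is.null(config$drug_classes_path))
      read_drug_classes(config$drug_classes_path) else default_drug_classes()
    rows <- build_risk_rows(ps_db, config$outcome_soc, classes, config$target)
    log_n("risk: ", nrow(rows), " complete-case rows, ",
          sum(rows$outcome), " cases")
    uni <- risk_univariate_table(rows, names(classes))
    multi <- tryCatch(fit_logistic(rows), error = function(e) {
      log_n("risk: multivariable fit unavailable (", conditionMessage(e), ")")
      NULL
    })
    list(rows = rows, univariate = uni, multivariable = multi)
  })

  strata <- NULL
  if (!is.null(config$stratify)) {
    strata <- stage("stratified_signals",
                    stratified_signals(full_db, config$target,
                                       config$stratify, config$thresholds,
                                       config$yates))
  }

  desc <- descriptive_table(ps_db, config$target)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) {
    p <- file.path(config$out_dir, f)
    if (!is.null(x)) data.table::fwrite(x, p, sep = "\t")
    p
  }
  paths <- c(
    descriptive = w(desc, "descriptive.tsv"),
    soc_signals = w(signals_soc, "soc_signals.tsv"),
    pt_signals = w(signals_pt, "pt_signals.tsv"),
    forest = w(signals_pt[, .(term, ror, ror_lo, ror_hi)], "forest_ror.tsv"),
    priority = w(priority, "priority.tsv"),
    tto_bins = w(tto_res$bins, "tto_bins.tsv"),
    km = w(if (!is.null(tto_res$km)) as.data.frame(tto_res$km) else NULL,
           "km_curve.tsv"),
    risk_univariate = w(risk$univariate, "risk_univariate.tsv"),
    risk_multivariable = w(if (!is.null(risk$multivariable))
      risk$multivariable$coefficients else NULL, "risk_multivariable.tsv"))
  manifest <- data.table::data.table(
    item = c("seed", "target", "config_hash", "n_reports", "n_event_pairs"),
    value = c(config$seed, paste(config$target, collapse = "|"),
              config_hash(config), n_reports(ps_db), n_event_pairs(ps_db)))
  w(manifest, "manifest.tsv")

  invisible(list(descriptive = desc, soc_signals = signals_soc,
                 pt_signals = signals_pt, priority = priority,
                 tto = tto_res, risk = risk, strata = strata,
                 paths = paths, db = ps_db))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}

#' Univariate odds-ratio table for the risk factors
#'
#' One 2x2 [univariate_or()] row per age band (against the reference
#' `<45`), for male sex (against female), and per exposure class.
#'
#' @param rows output of [build_risk_rows()].
#' @param classes character names of the exposure columns.
#' @return data.table `variable`, `factor`, counts and OR columns.
#' @export
risk_univariate_table <- function(rows, classes = c("RTX", "CTX", "PPI",
                                                    "STATIN")) {
  rows <- data.table::as.data.table(rows)
  res <- list()
  add <- function(variable, factor_, ec, uc, ect, uct) {
    u <- univariate_or(ec, uc, ect, uct)
    res[[length(res) + 1L]] <<- data.table::data.table(
      variable = variable, factor = factor_, exposed_cases = ec,
      unexposed_cases = uc, exposed_controls = ect, unexposed_controls = uct,
      or = u$or, or_lo = u$lo, or_hi = u$hi, p = u$p)
  }
  ref <- rows$age_band == "<45"
  for (lv in c("45-65", "65-75", ">75")) {
    sel <- rows$age_band == lv
    add("Age", lv, sum(sel & rows$outcome), sum(ref & rows$outcome),
        sum(sel & !rows$outcome), sum(ref & !rows$outcome))
  }
  add("Sex", "male", sum(rows$sex == "male" & rows$outcome),
      sum(rows$sex == "female" & rows$outcome),
      sum(rows$sex == "male" & !rows$outcome),
      sum(rows$sex == "female" & !rows$outcome))
  for (cl in intersect(classes, names(rows))) {
    e <- rows[[cl]]
    add("Concomitant drug", cl, sum(e & rows$outcome), sum(!e & rows$outcome),
        sum(e & !rows$outcome), sum(!e & !rows$outcome))
  }
  data.table::rbindlist(res)
}

#' Subgroup (stratified) disproportionality analysis
#'
#' Reruns the PT-level signal table within sex strata (F/M) or age strata
#' (<18, 18-65, >=65); no computation beyond filtering the database.
#'
#' @param db full SOC-annotated `report_db`.
#' @param target target synonyms.
#' @param by `"sex"` or `"age"`.
#' @param thresholds,yates as in [signal_table()].
#' @return named list of signal tables, one per stratum.
#' @export
stratified_signals <- function(db, target, by = c("sex", "age"),
                               thresholds = signal_thresholds(),
                               yates = TRUE) {
  by <- match.arg(by)
  r <- db$reports
  strata <- if (by == "sex") {
    list(female = r$primaryid[!is.na(r$sex) & r$sex == "F"],
         male = r$primaryid[!is.na(r$sex) & r$sex == "M"])
  } else {
    list(`<18` = r$primaryid[!is.na(r$age) & r$age < 18],
         `18-65` = r$primaryid[!is.na(r$age) & r$age >= 18 & r$age < 65],
         `>=65` = r$primaryid[!is.na(r$age) & r$age >= 65])
  }
  lapply(strata, function(ids) {
    sub <- new_report_db(db$reports[primaryid %in% ids],
                         db$drugs[primaryid %in% ids],
                         db$reactions[primaryid %in% ids],
                         db$outcomes[primaryid %in% ids])
    if (nrow(sub$reactions) == 0L) return(NULL)
    signal_table(sub, target, level = "PT", thresholds = thresholds,
                 yates = yates)
  })
}
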