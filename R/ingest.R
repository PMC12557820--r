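# Ingestion of FAERS-style quarterly extracts: parse the '$'-delimited
# tables into a relational report database, deduplicate cases, filter to
# primary-suspect reports for a target drug, annotate PTs with their SOC.

new_report_db <- function(reports, drugs, reactions, outcomes) {
  structure(list(reports = reports, drugs = drugs,
                 reactions = reactions, outcomes = outcomes),
            class = "report_db")
}

#' @export
print.report_db <- function(x, ...) {
  cat("<report_db>", nrow(x$reports), "reports |",
      nrow(x$drugs), "drug entries |",
      nrow(x$reactions), "report-PT pairs |",
      nrow(x$outcomes), "outcome rows\n")
  invisible(x)
}

#' Number of reports in a report database
#' @param db a `report_db`.
#' @return integer count.
#' @export
n_reports <- function(db) nrow(db$reports)

#' Number of report-PT pairs (the counting unit of the analysis)
#'
#' One report contributes each distinct PT at most once, so several
#' adverse events per report are counted but repeats of the same term are
#' not; this is the event-counting convention used throughout the
#' disproportionality and prioritization stages.
#'
#' @param db a `report_db`.
#' @return integer count of (report, distinct PT) pairs.
#' @export
n_event_pairs <- function(db) nrow(db$reactions)

read_faers_table <- function(path, required = character()) {
  dt <- data.table::fread(path, sep = "$", colClasses = "character",
                          quote = "", na.strings = NULL, header = TRUE)
  names(dt) <- tolower(names(dt))
  miss <- setdiff(required, names(dt))
  if (length(miss))
    stop_invalid("file '", basename(path), "' is missing mandatory column(s): ",
                 paste(miss, collapse = ", "))
  dt
}

drop_orphans <- function(child, demo_ids, what) {
  orphan <- !(child$primaryid %in% demo_ids)
  if (any(orphan)) {
    warning(sum(orphan), " orphan ", what,
            " row(s) reference no DEMO report; dropped", call. = FALSE)
    child <- child[!orphan]
  }
  child
}

#' Parse one quarter of FAERS-style tables into a report database
#'
#' @param paths named character vector or list with elements `demo`,
#'   `drug`, `reac`, and optionally `outc`, `ther`, `indi`, pointing to
#'   '$'-delimited files with headers. A single directory path may be given
#'   instead, in which case `DEMO.txt`, `DRUG.txt`, ... are read from it.
#' @return a `report_db` (pre-deduplication): `reports` one row per DEMO
#'   row, `drugs` with therapy start dates joined by drug sequence,
#'   `reactions` as distinct (report, PT) pairs with case-normalized
#'   whitespace-trimmed terms, and `outcomes`. Unknown fields stay
#'   explicitly unknown (`NA`/empty), never defaulted to a number.
#' @export
parse_quarter_files <- function(paths) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- list(demo = file.path(paths, "DEMO.txt"),
                  drug = file.path(paths, "DRUG.txt"),
                  reac = file.path(paths, "REAC.txt"),
                  outc = file.path(paths, "OUTC.txt"),
                  ther = file.path(paths, "THER.txt"),
                  indi = file.path(paths, "INDI.txt"))
    paths <- paths[vapply(paths, file.exists, logical(1))]
  }
  paths <- as.list(paths)
  stopifnot(all(c("demo", "drug", "reac") %in% names(paths)))

  demo <- read_faers_table(paths$demo, c("primaryid", "caseid", "fda_dt"))
  for (col in c("event_dt", "age", "sex", "wt", "reporter", "occr_country"))
    if (!col %in% names(demo)) demo[[col]] <- ""
  reports <- demo[, .(primaryid, caseid, fda_dt, event_dt,
                      age = suppressWarnings(as.numeric(age)),
                      sex = data.table::fifelse(sex %in% c("F", "M"), sex, NA_character_),
                      wt = suppressWarnings(as.numeric(wt)),
                      reporter, country = occr_country)]

  drug <- read_faers_table(paths$drug, c("primaryid", "drugname", "role_cod"))
  if (!"drug_seq" %in% names(drug)) drug$drug_seq <- "1"
  drug <- drop_orphans(drug, reports$primaryid, "DRUG")
  drugs <- drug[, .(primaryid, drug_seq = as.integer(drug_seq),
                    name = normalize_name(drugname),
                    role = toupper(trimws(role_cod)))]
  bad_role <- !drugs$role %in% c("PS", "SS", "C", "I")
  if (any(bad_role)) {
    warning(sum(bad_role), " drug row(s) with unknown role code dropped",
            call. = FALSE)
    drugs <- drugs[!bad_role]
  }

  if (!is.null(paths$ther)) {
    ther <- read_faers_table(paths$ther, c("primaryid", "start_dt"))
    if (!"dsg_drug_seq" %in% names(ther)) ther$dsg_drug_seq <- "1"
    ther <- drop_orphans(ther, reports$primaryid, "THER")
    ther <- ther[, .(primaryid, drug_seq = as.integer(dsg_drug_seq), start_dt)]
    drugs <- ther[drugs, on = c("primaryid", "drug_seq")]
    data.table::setcolorder(drugs, c("primaryid", "drug_seq", "name", "role", "start_dt"))
  } else drugs[, start_dt := NA_character_]
  drugs[is.na(start_dt), start_dt := ""]

  reac <- read_faers_table(paths$reac, c("primaryid", "pt"))
  reac <- drop_orphans(reac, reports$primaryid, "REAC")
  reactions <- unique(reac[, .(primaryid, pt = normalize_name(pt))])[pt != ""]

  if (!is.null(paths$outc)) {
    outc <- read_faers_table(paths$outc, c("primaryid", "outc_cod"))
    outc <- drop_orphans(outc, reports$primaryid, "OUTC")
    outcomes <- unique(outc[, .(primaryid, outcome = toupper(trimws(outc_cod)))])
    outcomes <- outcomes[outcome %in% c("HO", "DE", "LT", "DS", "RI", "OT", "CA")]
  } else {
    outcomes <- data.table::data.table(primaryid = character(),
                                       outcome = character())
  }
  new_report_db(reports, drugs, reactions, outcomes)
}

#' Convert a simulated bundle directly to a report database
#'
#' Fast in-memory path equivalent to writing the bundle with
#' [write_srs_tables()] and re-reading it with [parse_quarter_files()].
#'
#' @param bundle an `srs_bundle`.
#' @return a `report_db`.
#' @export
as_report_db <- function(bundle) {
  stopifnot(inherits(bundle, "srs_bundle"))
  d <- bundle$demo
  reports <- data.table::data.table(
    primaryid = as.character(d$primaryid), caseid = as.character(d$caseid),
    fda_dt = as.character(d$fda_dt), event_dt = as.character(d$event_dt),
    age = suppressWarnings(as.numeric(d$age)),
    sex = data.table::fifelse(d$sex %in% c("F", "M"), d$sex, NA_character_),
    wt = suppressWarnings(as.numeric(d$wt)),
    reporter = as.character(d$reporter), country = as.character(d$occr_country))
  ther <- bundle$ther[, .(primaryid = as.character(primaryid),
                          drug_seq = as.integer(dsg_drug_seq),
                          start_dt = as.character(start_dt))]
  drugs <- bundle$drug[, .(primaryid = as.character(primaryid),
                           drug_seq = as.integer(drug_seq),
                           name = normalize_name(drugname),
                           role = as.character(role_cod))]
  drugs <- ther[drugs, on = c("primaryid", "drug_seq")]
  drugs[is.na(start_dt), start_dt := ""]
  data.table::setcolorder(drugs, c("primaryid", "drug_seq", "name", "role", "start_dt"))
  reactions <- unique(bundle$reac[, .(primaryid = as.character(primaryid),
                                      pt = normalize_name(pt))])
  outcomes <- unique(bundle$outc[, .(primaryid = as.character(primaryid),
                                     outcome = as.character(outc_cod))])
  new_report_db(reports, drugs, reactions, outcomes)
}

#' Two-round case deduplication
#'
#' Round one keeps, within each caseid, the report with the most recent
#' FDA receipt date, breaking ties by the larger primaryid (compared
#' numerically when both ids parse as numbers, lexicographically
#' otherwise). Round two removes any residual duplicate primaryids,
#' keeping the last record in (receipt date, input order). Unparseable or
#' partial receipt dates sort earliest, so a dated report always survives
#' over an undated rival. The operation is idempotent.
#'
#' @param db a `report_db`.
#' @return deduplicated `report_db` (child tables subset accordingly).
#' @export
deduplicate <- function(db) {
  stopifnot(inherits(db, "report_db"))
  r <- data.table::copy(db$reports)
  if (nrow(r) == 0L) return(db)
  pid <- primaryid_order_keys(r$primaryid)
  r[, `:=`(.ord = seq_len(.N), .fda_num = fda_dt_key(fda_dt),
           .pid_num = pid$num, .pid_chr = pid$chr)]
  # round 1: per caseid, max fda_dt then max primaryid
  data.table::setorder(r, caseid, .fda_num, .pid_num, .pid_chr)
  r1 <- r[, .SD[.N], by = caseid]
  # round 2: residual duplicate primaryids -> keep last in (fda_dt, input order)
  data.table::setorder(r1, primaryid, .fda_num, .ord)
  r2 <- r1[, .SD[.N], by = primaryid]
  keep <- r2$primaryid
  data.table::setorder(r2, .ord)
  reports <- r2[, c(".ord", ".fda_num", ".pid_num", ".pid_chr") := NULL]
  data.table::setcolorder(reports, names(db$reports))
  new_report_db(reports,
                db$drugs[primaryid %in% keep],
                db$reactions[primaryid %in% keep],
                db$outcomes[primaryid %in% keep])
}

#' Filter a database to primary-suspect reports for a target drug
#'
#' Retains exactly the reports carrying at least one drug entry with role
#' `PS` whose normalized name is in the synonym list.
#'
#' @param db a `report_db`.
#' @param drug_names character synonym list for the target drug
#'   (e.g. the generic and trade names); matched after normalization.
#' @return filtered `report_db`; the retained report count and their
#'   report-PT pair count are reported via `message()`.
#' @export
filter_primary_suspect <- function(db, drug_names) {
  stopifnot(inherits(db, "report_db"))
  if (length(drug_names) == 0L) stop_invalid("`drug_names` must be non-empty")
  syn <- normalize_name(drug_names)
  keep <- unique(db$drugs[role == "PS" & name %in% syn, primaryid])
  out <- new_report_db(db$reports[primaryid %in% keep],
                       db$drugs[primaryid %in% keep],
                       db$reactions[primaryid %in% keep],
                       db$outcomes[primaryid %in% keep])
  message("primary-suspect filter: ", n_reports(out), " reports, ",
          n_event_pairs(out), " report-PT pairs retained")
  out
}

#' Read a PT-to-SOC mapping table
#'
#' @param path TSV file with columns `pt` and `soc` (one primary SOC per
#'   PT).
#' @return named character vector mapping normalized PT to SOC.
#' @export
read_meddra_map <- function(path) {
  m <- data.table::fread(path, sep = "\t", colClasses = "character")
  names(m) <- tolower(names(m))
  stopifnot(all(c("pt", "soc") %in% names(m)))
  meddra_map(m$pt, m$soc)
}

#' Build a PT-to-SOC map from vectors
#'
#' @param pt character vector of preferred terms.
#' @param soc character vector of their primary system organ classes.
#' @return named character vector (normalized PT -> SOC).
#' @export
meddra_map <- function(pt, soc) {
  pt <- normalize_name(pt)
  dup <- tapply(soc, pt, function(s) length(unique(s)) > 1L)
  if (any(dup))
    stop_invalid("PT(s) mapped to more than one SOC: ",
                 paste(names(dup)[dup], collapse = ", "))
  m <- setNames(as.character(soc), pt)
  m[!duplicated(names(m))]
}

#' Annotate reactions with their system organ class
#'
#' Each distinct PT of each report gains exactly one SOC label, so the
#' SOC-level event count of a report is the number of its distinct PTs
#' mapping to that SOC.
#'
#' @param db a `report_db`.
#' @param map named character vector from [meddra_map()] /
#'   [read_meddra_map()].
#' @param unmapped `"error"` (default) to fail listing unmapped terms, or
#'   `"bucket"` to assign them to `"UNMAPPED"` with a warning.
#' @return `report_db` whose `reactions` table carries a `soc` column.
#' @export
map_pt_to_soc <- function(db, map, unmapped = c("error", "bucket")) {
  stopifnot(inherits(db, "report_db"))
  unmapped <- match.arg(unmapped)
  re <- data.table::copy(db$reactions)
  if (nrow(re) == 0L) {
    re[, soc := character()]
    db$reactions <- re
    return(db)
  }
  soc <- unname(map[re$pt])
  if (anyNA(soc)) {
    terms <- unique(re$pt[is.na(soc)])
    if (unmapped == "error")
      stop_invalid("unmapped PT(s): ", paste(terms, collapse = ", "))
    warning(length(terms), " PT(s) not in the map; bucketed as UNMAPPED",
            call. = FALSE)
    soc[is.na(soc)] <- "UNMAPPED"
  }
  re[, soc := soc]
  db$reactions <- re
  db
}
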