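# Semi-quantitative clinical-priority scoring of signal-positive adverse
# events: clinical relevance (DME/IME designation), reporting rate,
# signal stability across the four algorithms, and case fatality rate.
# Scores 0-2 per criterion, totals 0-8, banded low (0-2) / moderate (3-5)
# / high (6-8).

#' Load IME/DME designation lists
#'
#' @param ime_path,dme_path TSV/plain-text files with one PT per line (a
#'   header line `pt` is allowed). The published EMA lists can be supplied
#'   here; a small synthetic toy list ships with the package for tests.
#' @return list of class `designation_lists` with normalized term sets.
#' @export
read_designation_lists <- function(ime_path, dme_path) {
  read_terms <- function(p) {
    x <- readLines(p, warn = FALSE)
    x <- trimws(x)
    x <- x[x != "" & tolower(x) != "pt"]
    unique(normalize_name(x))
  }
  designation_lists(read_terms(ime_path), read_terms(dme_path))
}

#' Build designation lists from character vectors
#'
#' A term on both lists is treated as a DME (the rarer, stronger
#' designation). Lookup is case-insensitive on normalized PTs.
#'
#' @param ime_terms,dme_terms character vectors of PT names.
#' @return list of class `designation_lists`.
#' @export
designation_lists <- function(ime_terms = character(),
                              dme_terms = character()) {
  structure(list(ime_terms = unique(normalize_name(ime_terms)),
                 dme_terms = unique(normalize_name(dme_terms))),
            class = "designation_lists")
}

#' Clinical relevance of a term
#' @param pt preferred term (any case).
#' @param lists a [designation_lists()] object.
#' @return `"DME"`, `"IME"` or `"none"`.
#' @export
clinical_relevance <- function(pt, lists) {
  ptn <- normalize_name(pt)
  data.table::fifelse(ptn %in% lists$dme_terms, "DME",
                      data.table::fifelse(ptn %in% lists$ime_terms,
                                          "IME", "none"))
}

#' Reporting rate (cases to non-cases) and its category
#'
#' `rate = 100 n / (total_events - n)` in percent, the ratio of the term's
#' events to all other events of the drug; categorized as very common
#' (>= 10%), common (1-10%), uncommon (<= 1%).
#'
#' @param n event count for the term.
#' @param total_events the drug's total adverse-event (report-PT pair)
#'   count; must exceed `n`.
#' @return list `rate` (percent, full precision), `display` (2 decimals),
#'   `category`.
#' @export
reporting_rate <- function(n, total_events) {
  if (any(n < 0) || any(n > total_events))
    stop_invalid("`n` must lie in [0, total_events]")
  if (any(total_events == n))
    stop_invalid("reporting rate undefined when the term is the only event")
  rate <- 100 * n / (total_events - n)
  category <- data.table::fifelse(rate >= 10, "very_common",
                                  data.table::fifelse(rate > 1, "common",
                                                      "uncommon"))
  list(rate = rate, display = round(rate, 2), category = category)
}

#' Case fatality rate of a term
#'
#' `100 deaths / n` percent: the share of the term's reports carrying a
#' death outcome.
#'
#' @param deaths number of the term's reports with outcome `DE`.
#' @param n the term's report count; must be positive.
#' @return list `cfr` (percent), `display` (2 decimals).
#' @export
case_fatality_rate <- function(deaths, n) {
  if (any(n <= 0)) stop_invalid("case fatality undefined for n = 0")
  if (any(deaths < 0) || any(deaths > n))
    stop_invalid("`deaths` must lie in [0, n]")
  cfr <- 100 * deaths / n
  list(cfr = cfr, display = round(cfr, 2))
}

#' Default rubric point map
#'
#' Each criterion scores 0-2: relevance DME 2 / IME 1 / none 0; rate
#' very common 2 / common 1 / uncommon 0; stability 4 positive algorithms
#' 2 / 2-3 positive 1 / 0-1 positive 0; fatality above 50% 2 / 10-50% 1
#' / below 10% 0 (the top fatality score is reserved for rates over
#' 50%).
#'
#' @return nested named list of integer points.
#' @export
priority_rubric <- function() {
  list(relevance = c(DME = 2L, IME = 1L, none = 0L),
       rate = c(very_common = 2L, common = 1L, uncommon = 0L),
       stability = function(n_pos) ifelse(n_pos >= 4L, 2L,
                                          ifelse(n_pos >= 2L, 1L, 0L)),
       fatality = function(cfr) ifelse(cfr > 50, 2L,
                                       ifelse(cfr >= 10, 1L, 0L)))
}

#' Score one term on the clinical-priority rubric
#'
#' @param relevance `"DME"`, `"IME"` or `"none"`.
#' @param rate_category `"very_common"`, `"common"` or `"uncommon"`.
#' @param n_pos_algorithms number of positive disproportionality
#'   algorithms, 0-4.
#' @param cfr case fatality rate in percent.
#' @param rubric point map, see [priority_rubric()]; fully overridable.
#' @return list `components` (named integer vector of the four criterion
#'   scores), `total` (0-8), `band` (`"low"`, `"moderate"`, `"high"`).
#' @export
priority_score <- function(relevance, rate_category, n_pos_algorithms, cfr,
                           rubric = priority_rubric()) {
  args <- list(relevance = relevance, rate_category = rate_category,
               n_pos_algorithms = n_pos_algorithms, cfr = cfr)
  for (nm in names(args))
    if (is.null(args[[nm]]) || length(args[[nm]]) != 1L || is.na(args[[nm]]))
      stop_invalid("missing rubric input: ", nm)
  comp <- c(relevance = unname(rubric$relevance[[relevance]]),
            rate = unname(rubric$rate[[rate_category]]),
            stability = as.integer(rubric$stability(n_pos_algorithms)),
            fatality = as.integer(rubric$fatality(cfr)))
  total <- sum(comp)
  list(components = comp, total = total, band = priority_band(total))
}

#' Map a total score to its priority band
#'
#' The fixed partition: 0-2 low, 3-5 moderate, 6-8 high.
#'
#' @param total integer score in `[0, 8]`.
#' @return `"low"`, `"moderate"` or `"high"`.
#' @export
priority_band <- function(total) {
  if (any(total < 0 | total > 8)) stop_invalid("total score must be in [0, 8]")
  data.table::fifelse(total <= 2, "low",
                      data.table::fifelse(total <= 5, "moderate", "high"))
}

#' Clinical-priority assessment of all signal-positive terms
#'
#' Every PT positive in at least one disproportionality algorithm receives
#' an assessment; terms positive in none are skipped.
#'
#' @param signals PT-level table from [signal_table()].
#' @param db the primary-suspect filtered `report_db` for the target drug
#'   (used for death outcomes per term).
#' @param lists a [designation_lists()] object.
#' @param rubric point map, see [priority_rubric()].
#' @return data.table, one row per assessed term: `pt`, `n`,
#'   `reporting_rate`, `rate_category`, `cfr`, `n_pos`, `relevance`, the
#'   four component scores, `total`, `band`.
#' @export
prioritize_signals <- function(signals, db, lists, rubric = priority_rubric()) {
  stopifnot(inherits(db, "report_db"))
  sel <- signals[signals$n_pos >= 1L]
  total_events <- n_event_pairs(db)
  if (nrow(sel) == 0L)
    return(data.table::data.table(pt = character(), n = integer()))
  deaths_by_pt <- db$reactions[
    primaryid %in% db$outcomes[outcome == "DE", primaryid],
    .(deaths = .N), by = "pt"]
  out <- lapply(seq_len(nrow(sel)), function(i) {
    pt_i <- sel$term[i]
    n_i <- sel$n[i]
    de <- deaths_by_pt[pt == pt_i, deaths]
    de <- if (length(de)) de else 0L
    rr <- reporting_rate(n_i, total_events)
    cf <- case_fatality_rate(de, n_i)
    rel <- clinical_relevance(pt_i, lists)
    sc <- priority_score(rel, rr$category, sel$n_pos[i], cf$cfr, rubric)
    data.table::data.table(
      pt = pt_i, n = n_i, reporting_rate = rr$display,
      rate_category = rr$category, cfr = cf$display, deaths = de,
      n_pos = sel$n_pos[i], relevance = rel,
      score_relevance = sc$components[["relevance"]],
      score_rate = sc$components[["rate"]],
      score_stability = sc$components[["stability"]],
      score_fatality = sc$components[["fatality"]],
      total = sc$total, band = sc$band)
  })
  data.table::rbindlist(out)[order(-total, -n)]
}
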