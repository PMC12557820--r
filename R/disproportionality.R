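# Disproportionality statistics on 2x2 contingency tables built from
# report-PT pairs: reporting odds ratio, proportional reporting ratio with
# chi-square, the BCPNN information component, and the multi-item
# gamma-Poisson shrinker (empirical-Bayes geometric mean).

#' Build a 2x2 contingency table for one term
#'
#' Counting unit: the (report, distinct PT) pair. `a` is the number of
#' target-drug reports mentioning the term, `b` the remaining target-drug
#' report-PT pairs, and `c`, `d` the analogous counts over all non-target
#' reports, so `a + b` equals the target drug's total adverse-event count.
#' The comparator is the full deduplicated database minus the target's
#' primary-suspect reports.
#'
#' @param db a deduplicated, SOC-annotated `report_db`.
#' @param term PT or SOC label (case-normalized for PT matching).
#' @param target character synonym list identifying the target drug.
#' @param level `"PT"` or `"SOC"`.
#' @return object of class `contingency_table`: list with integer fields
#'   `a`, `b`, `c`, `d`, `n` and the `term`/`level` labels.
#' @export
build_contingency <- function(db, term, target, level = c("PT", "SOC")) {
  stopifnot(inherits(db, "report_db"))
  level <- match.arg(level)
  syn <- normalize_name(target)
  target_ids <- unique(db$drugs[role == "PS" & name %in% syn, primaryid])
  re <- db$reactions
  if (level == "PT") {
    term_n <- normalize_name(term)
    hit <- re$pt == term_n
  } else {
    if (!"soc" %in% names(re))
      stop_invalid("SOC-level tables require a SOC-annotated database; ",
                   "run map_pt_to_soc() first")
    hit <- re$soc == term
  }
  if (!any(hit))
    warning("term '", term, "' absent from the reaction vocabulary; ",
            "zero-count table", call. = FALSE)
  is_t <- re$primaryid %in% target_ids
  # per report a term counts once even when several of its PTs share a SOC
  a <- length(unique(re$primaryid[hit & is_t]))
  c_ <- length(unique(re$primaryid[hit & !is_t]))
  b <- sum(is_t) - sum(hit & is_t) + (sum(hit & is_t) - a)
  d <- sum(!is_t) - sum(hit & !is_t) + (sum(hit & !is_t) - c_)
  # for SOC level, pairs carrying the SOC beyond the first per report stay
  # in b/d (they are "other events" only once the report is counted in a)
  ct <- contingency_table(a, b, c_, d, term = term, level = level)
  if (ct$c == 0L && ct$a > 0L) attr(ct, "degenerate") <- TRUE
  ct
}

#' Construct a contingency table from counts
#'
#' @param a,b,c,d non-negative integer cells (target/event, target/other,
#'   comparator/event, comparator/other).
#' @param term,level optional labels.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, term = NA_character_,
                              level = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop_invalid("cells must be non-negative integers")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), n = as.integer(a + b + c + d),
                 term = term, level = level),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>", if (!is.na(x$term)) paste0(x$term, " "),
      sprintf("a=%d b=%d c=%d d=%d N=%d\n", x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Reporting odds ratio with 95% Wald interval
#'
#' `ROR = ad / bc`; interval `exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#' With any zero cell the statistic is undefined and `NA` is returned with
#' a reason (no continuity correction by default); setting
#' `haldane = TRUE` adds 0.5 to every cell instead.
#'
#' @param t a `contingency_table`.
#' @param haldane apply the Haldane-Anscombe 0.5 correction to zero-cell
#'   tables.
#' @return list `ror`, `lo`, `hi`, `reason` (NA unless undefined).
#' @export
ror_stats <- function(t, haldane = FALSE) {
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0L)) {
    if (!haldane)
      return(list(ror = NA_real_, lo = NA_real_, hi = NA_real_,
                  reason = "zero cell"))
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, lo = exp(log(ror) - 1.96 * se),
       hi = exp(log(ror) + 1.96 * se), reason = NA_character_)
}

#' Proportional reporting ratio and chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-square statistic is
#' `N(|ad - bc| - yates * N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]` with the Yates
#' continuity term floored at zero. A zero numerator (`a = 0`) is a valid
#' PRR of 0; the statistic is undefined only when the comparator never
#' reports the event (`c = 0`) or a margin is empty.
#'
#' @param t a `contingency_table`.
#' @param yates apply Yates' continuity correction (default TRUE).
#' @return list `prr`, `chi2`, `reason`.
#' @export
prr_stats <- function(t, yates = TRUE) {
  a <- t$a; b <- t$b; c <- t$c; d <- t$d; n <- t$n
  if (a + b == 0L || c + d == 0L || c == 0L)
    return(list(prr = NA_real_, chi2 = NA_real_, reason = "empty margin"))
  prr <- (a / (a + b)) / (c / (c + d))
  margins <- as.numeric(a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- if (margins == 0) NA_real_ else {
    dev <- abs(as.numeric(a) * d - as.numeric(b) * c)
    if (yates) dev <- max(0, dev - n / 2)
    n * dev^2 / margins
  }
  list(prr = prr, chi2 = chi2, reason = NA_character_)
}

#' Prior constants for the BCPNN information component
#'
#' The standard published priors: `alpha1 = beta1 = gamma11 = 1` for the
#' cell and margins, `alpha = beta = 2` for the totals.
#'
#' @param alpha1,beta1,gamma11,alpha,beta strictly positive reals.
#' @return list of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, gamma11 = 1,
                         alpha = 2, beta = 2) {
  p <- list(alpha1 = alpha1, beta1 = beta1, gamma11 = gamma11,
            alpha = alpha, beta = beta)
  if (any(unlist(p) <= 0)) stop_invalid("BCPNN priors must be positive")
  structure(p, class = "bcpnn_priors")
}

#' BCPNN information component and its lower bound
#'
#' Closed-form posterior expectation and variance of the information
#' component; the reported bound is `IC025 = E(IC) - 2 SD(IC)`. Defined
#' for every valid table, including `a = 0` (shrinkage keeps it finite).
#'
#' @param t a `contingency_table`.
#' @param priors a [bcpnn_priors()] object.
#' @return list `ic`, `ic025`.
#' @export
bcpnn_stats <- function(t, priors = bcpnn_priors()) {
  a <- t$a; n <- t$n
  if (n <= 0L) stop_invalid("N must be positive")
  a1 <- priors$alpha1; b1 <- priors$beta1; g11 <- priors$gamma11
  al <- priors$alpha; be <- priors$beta
  rowm <- t$a + t$b; colm <- t$a + t$c
  gamma <- g11 * (n + al) * (n + be) / ((rowm + a1) * (colm + b1))
  ic <- log2((a + g11) * (n + al) * (n + be) /
               ((n + gamma) * (rowm + a1) * (colm + b1)))
  v <- (1 / log(2)^2) * (
    (n - a + gamma - g11) / ((a + g11) * (1 + n + gamma)) +
    (n - rowm + al - a1) / ((rowm + a1) * (1 + n + al)) +
    (n - colm + be - b1) / ((colm + b1) * (1 + n + be)))
  list(ic = ic, ic025 = ic - 2 * sqrt(v))
}

# --- MGPS: two-component gamma mixture prior on the relative reporting
# ratio, marginal negative-binomial likelihood, empirical-Bayes fit.

# log marginal NB(a; alpha, beta, E) = log [ C(alpha+a-1, a) (b/(b+E))^a ... ]
lnb <- function(a, alpha, beta, E) {
  dnbinom(a, size = alpha, prob = beta / (beta + E), log = TRUE)
}

mgps_loglik <- function(par_log, a, E) {
  a1 <- exp(par_log[1]); b1 <- exp(par_log[2])
  a2 <- exp(par_log[3]); b2 <- exp(par_log[4])
  w <- plogis(par_log[5])
  l1 <- log(w) + lnb(a, a1, b1, E)
  l2 <- log1p(-w) + lnb(a, a2, b2, E)
  m <- pmax(l1, l2)
  sum(m + log(exp(l1 - m) + exp(l2 - m)))
}

#' Hyperparameters of the gamma-mixture shrinkage prior
#'
#' @param a1,b1 shape/rate of the first gamma component.
#' @param a2,b2 shape/rate of the second.
#' @param w mixture weight of the first component, in (0, 1).
#' @return list of class `mgps_hyper`.
#' @export
mgps_hyper <- function(a1, b1, a2, b2, w) {
  if (any(c(a1, b1, a2, b2) <= 0)) stop_invalid("shapes and rates must be > 0")
  if (w <= 0 || w >= 1) stop_invalid("`w` must lie strictly in (0, 1)")
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, w = w),
            class = "mgps_hyper")
}

#' @export
print.mgps_hyper <- function(x, ...) {
  cat(sprintf(
    "<mgps_hyper> w=%.3f  comp1 Gamma(%.3f, %.3f)  comp2 Gamma(%.3f, %.3f)\n",
    x$w, x$a1, x$b1, x$a2, x$b2))
  if (!is.null(attr(x, "loglik")))
    cat(sprintf("  marginal log-likelihood %.2f (%s)\n", attr(x, "loglik"),
                if (isTRUE(attr(x, "converged"))) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit the gamma-mixture hyperparameters over all drug-event cells
#'
#' Maximizes the marginal likelihood (a two-component negative-binomial
#' mixture over the observed cell counts, given baseline expected counts
#' `E = (a+b)(a+c)/N`) by bounded quasi-Newton on log-transformed
#' parameters from the documented start point `(0.2, 0.1, 2, 4, 1/3)`.
#'
#' @param a integer vector of observed cell counts (one per drug-event
#'   combination).
#' @param E positive baseline expected counts, same length.
#' @param start numeric start `c(a1, b1, a2, b2, w)`.
#' @param maxit iteration cap (default 500).
#' @return `mgps_hyper` with attributes `loglik` and `converged`.
#' @export
mgps_fit <- function(a, E, start = c(0.2, 0.1, 2, 4, 1 / 3), maxit = 500L) {
  if (length(a) < 2L) stop_invalid("at least 2 cells are required")
  if (length(a) != length(E) || any(E <= 0))
    stop_invalid("`E` must be positive and match `a` in length")
  par0 <- c(log(start[1:4]), qlogis_safe(start[5]))
  fit <- optim(par0, function(p) -mgps_loglik(p, a, E),
               method = "L-BFGS-B",
               lower = rep(log(1e-6), 5), upper = rep(log(1e6), 5),
               control = list(maxit = maxit, factr = 1e4))
  if (fit$convergence != 0L) {
    # line-search failures on flat likelihoods: polish with Nelder-Mead
    fit2 <- optim(fit$par, function(p) -mgps_loglik(p, a, E),
                  method = "Nelder-Mead",
                  control = list(maxit = 5 * maxit, reltol = 1e-12))
    if (fit2$value <= fit$value) fit <- fit2
  }
  h <- mgps_hyper(exp(fit$par[1]), exp(fit$par[2]),
                  exp(fit$par[3]), exp(fit$par[4]), plogis(fit$par[5]))
  attr(h, "loglik") <- -fit$value
  attr(h, "converged") <- fit$convergence == 0L
  if (fit$convergence != 0L) {
    cond <- structure(class = c("mgps_nonconvergence", "error", "condition"),
                      list(message = paste0("MGPS fit did not converge: ",
                                            fit$message),
                           call = sys.call(-1), best = h))
    stop(cond)
  }
  h
}

qlogis_safe <- function(p) log(p / (1 - p))

# Posterior probability that a cell belongs to the first mixture component.
mgps_posterior_q <- function(a, E, h) {
  l1 <- log(h$w) + lnb(a, h$a1, h$b1, E)
  l2 <- log1p(-h$w) + lnb(a, h$a2, h$b2, E)
  1 / (1 + exp(l2 - l1))
}

#' Empirical-Bayes geometric mean and its 5th percentile for one cell
#'
#' Posterior of the relative reporting ratio is the gamma mixture
#' `Q Gamma(a1 + a, b1 + E) + (1 - Q) Gamma(a2 + a, b2 + E)` with `Q` the
#' posterior component probability. `EBGM` is the geometric mean
#' `exp(Q(psi(a1+a) - ln(b1+E)) + (1-Q)(psi(a2+a) - ln(b2+E)))`; `EBGM05`
#' is the posterior 0.05 quantile found by bisection on the mixture CDF to
#' absolute tolerance 1e-8.
#'
#' @param t a `contingency_table` (or a list with fields `a`..`d`).
#' @param h fitted [mgps_hyper()] parameters.
#' @return list `ebgm`, `ebgm05`, `E`, `reason`.
#' @export
mgps_cell <- function(t, h) {
  a <- t$a
  E <- as.numeric(t$a + t$b) * (t$a + t$c) / t$n
  if (!is.finite(E) || E <= 0)
    return(list(ebgm = NA_real_, ebgm05 = NA_real_, E = E,
                reason = "zero expected count"))
  q <- mgps_posterior_q(a, E, h)
  s1 <- h$a1 + a; r1 <- h$b1 + E
  s2 <- h$a2 + a; r2 <- h$b2 + E
  ebgm <- exp(q * (digamma(s1) - log(r1)) + (1 - q) * (digamma(s2) - log(r2)))
  cdf <- function(x) q * pgamma(x, s1, rate = r1) + (1 - q) * pgamma(x, s2, rate = r2)
  lo <- 0
  hi <- max(qgamma(0.05, s1, rate = r1), qgamma(0.05, s2, rate = r2)) + 1
  while (cdf(hi) < 0.05) hi <- hi * 2
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < 0.05) lo <- mid else hi <- mid
  }
  list(ebgm = ebgm, ebgm05 = (lo + hi) / 2, E = E, reason = NA_character_)
}

#' Default signal-positivity thresholds
#'
#' The conventional four criteria: ROR positive when `a >= 3` and the CI
#' lower bound exceeds 1; PRR positive when `a >= 3`, `PRR >= 2` and
#' `chi2 >= 4`; BCPNN positive when `IC025 > 0`; MGPS positive when
#' `EBGM05 > 2`.
#'
#' @return named list of thresholds, each overridable.
#' @export
signal_thresholds <- function() {
  list(min_count = 3L, ror_lo = 1, prr = 2, chi2 = 4, ic025 = 0, ebgm05 = 2)
}

#' Evaluate the four positivity criteria for one term
#'
#' Absent (NA) statistics count as negative. The overall flag is the
#' conjunction of all four; the count of positive algorithms (0-4) feeds
#' the signal-stability criterion of the clinical-priority rubric.
#'
#' @param s list or one-row data.frame with fields `n` (the `a` count),
#'   `ror_lo`, `prr`, `chi2`, `ic025`, `ebgm05`.
#' @param thresholds see [signal_thresholds()].
#' @return list of logical flags `ror_pos`, `prr_pos`, `bcpnn_pos`,
#'   `mgps_pos`, `overall`, integer `n_pos`, and `small_count_caution`
#'   (`n < 10`).
#' @export
evaluate_criteria <- function(s, thresholds = signal_thresholds()) {
  th <- utils::modifyList(signal_thresholds(), as.list(thresholds))
  pos <- function(x) !is.na(x) & x
  ror_pos <- pos(s$n >= th$min_count & s$ror_lo > th$ror_lo)
  prr_pos <- pos(s$n >= th$min_count & s$prr >= th$prr & s$chi2 >= th$chi2)
  bcpnn_pos <- pos(s$ic025 > th$ic025)
  mgps_pos <- pos(s$ebgm05 > th$ebgm05)
  n_pos <- ror_pos + prr_pos + bcpnn_pos + mgps_pos
  list(ror_pos = ror_pos, prr_pos = prr_pos, bcpnn_pos = bcpnn_pos,
       mgps_pos = mgps_pos, overall = n_pos == 4L, n_pos = as.integer(n_pos),
       small_count_caution = s$n < 10L)
}

#' Disproportionality signal table over all terms
#'
#' Builds the 2x2 table for every PT (or SOC) observed in the database,
#' computes the four statistics, and flags positivity. The MGPS prior is
#' fitted once over all drug-event cells of the full database.
#'
#' @param db deduplicated, SOC-annotated `report_db` (the full database,
#'   target and comparator reports together).
#' @param target synonym list identifying the target drug.
#' @param level `"PT"` or `"SOC"`.
#' @param thresholds positivity thresholds, see [signal_thresholds()].
#' @param yates Yates-correct the PRR chi-square (default TRUE).
#' @param mgps_h optional pre-fitted `mgps_hyper` to reuse.
#' @return data.table with one row per term: counts, the four statistics
#'   with their bounds, per-algorithm flags, `n_pos`, `overall`, and
#'   `caution` (`n < 10`).
#' @export
signal_table <- function(db, target, level = c("PT", "SOC"),
                         thresholds = signal_thresholds(), yates = TRUE,
                         mgps_h = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(db, "report_db"))
  syn <- normalize_name(target)
  target_ids <- unique(db$drugs[role == "PS" & name %in% syn, primaryid])
  re <- db$reactions
  key <- if (level == "PT") re$pt else re$soc
  if (is.null(key))
    stop_invalid("SOC-level analysis requires map_pt_to_soc() first")
  is_t <- re$primaryid %in% target_ids
  # distinct (report, term) pairs at the requested level
  pairs <- unique(data.table::data.table(primaryid = re$primaryid, term = key,
                                         is_target = is_t))
  tot_t <- sum(is_t)
  tot_c <- sum(!is_t)
  agg <- pairs[, .(a = sum(is_target), c_ = sum(!is_target)), by = "term"]
  # at SOC level, a report's PT pairs beyond the first of a SOC stay in b/d
  agg[, `:=`(b = tot_t - a, d = tot_c - c_)]
  if (is.null(mgps_h)) mgps_h <- mgps_fit_db(db)
  out <- agg[order(-a)]
  stats <- lapply(seq_len(nrow(out)), function(i) {
    ct <- contingency_table(out$a[i], out$b[i], out$c_[i], out$d[i],
                            term = out$term[i], level = level)
    r <- ror_stats(ct)
    p <- prr_stats(ct, yates = yates)
    bc <- bcpnn_stats(ct)
    mg <- mgps_cell(ct, mgps_h)
    data.table::data.table(ror = r$ror, ror_lo = r$lo, ror_hi = r$hi,
                           prr = p$prr, chi2 = p$chi2, ic = bc$ic,
                           ic025 = bc$ic025, ebgm = mg$ebgm,
                           ebgm05 = mg$ebgm05)
  })
  out <- cbind(out, data.table::rbindlist(stats))
  data.table::setnames(out, c("a", "c_"), c("n", "n_comparator"))
  fl <- evaluate_criteria(
    list(n = out$n, ror_lo = out$ror_lo, prr = out$prr, chi2 = out$chi2,
         ic025 = out$ic025, ebgm05 = out$ebgm05), thresholds)
  out[, `:=`(ror_pos = fl$ror_pos, prr_pos = fl$prr_pos,
             bcpnn_pos = fl$bcpnn_pos, mgps_pos = fl$mgps_pos,
             n_pos = fl$n_pos, overall = fl$overall,
             caution = fl$small_count_caution)]
  attr(out, "mgps_hyper") <- mgps_h
  attr(out, "level") <- level
  out[]
}

#' Fit the MGPS prior over every (PS drug, PT) cell of a database
#'
#' @param db a `report_db`.
#' @param ... passed to [mgps_fit()].
#' @return fitted `mgps_hyper`.
#' @export
mgps_fit_db <- function(db, ...) {
  ps <- db$drugs[role == "PS", .(primaryid, name)]
  cells <- unique(ps[db$reactions, on = "primaryid", nomatch = NULL,
                     .(primaryid, name, pt)])
  counts <- cells[, .(a = .N), by = .(name, pt)]
  n_tot <- nrow(cells)
  drug_m <- cells[, .(nd = .N), by = "name"]
  pt_m <- cells[, .(np = .N), by = "pt"]
  counts <- drug_m[counts, on = "name"]
  counts <- pt_m[counts, on = "pt"]
  E <- as.numeric(counts$nd) * counts$np / n_tot
  mgps_fit(counts$a, E, ...)
}
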