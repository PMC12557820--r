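---
title: "Methods: disproportionality signal detection and clinical prioritization for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection and clinical prioritization for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous-reporting systems such as FAERS collect voluntary reports of
suspected adverse drug events. They have no denominators — we observe only
reports, never the population at risk — so drug–event association is
assessed by *disproportionality*: is an event reported with the drug of
interest more often than its share among all other drugs' reports would
predict? `srsignal` implements that analysis end to end for one target
drug: ingestion and deduplication of the quarterly extract tables,
construction of 2×2 contingency tables per MedDRA preferred term (PT) and
system organ class (SOC), four disproportionality statistics with
positivity criteria, a semi-quantitative clinical-priority rubric,
time-to-onset description, and a case/non-case logistic model of risk
factors for a chosen outcome SOC.

## Counting unit and data model

Every analysis counts **(report, distinct PT) pairs**: one report can
contribute several adverse events, but the same PT at most once. This is
the convention that reconciles a report count with a larger event count
(e.g. 3,150 reports carrying 7,187 events) and it is applied identically
on both sides of every contingency table.

The parsed database (`report_db`) is relational: a reports table (one row
per DEMO row), drug entries with roles PS/SS/C/I and therapy start dates,
a distinct-PT reaction table, and outcome codes. Unknown fields stay
explicitly unknown; nothing is imputed.

### Deduplication

Two rounds, applied before any analysis:

1. within each `caseid`, keep the report with the latest `fda_dt`;
   ties go to the larger `primaryid` (compared numerically when both ids
   parse as numbers — FAERS ids are numeric strings of varying length, so
   lexicographic order would misrank them);
2. residual duplicate `primaryid`s are removed keeping the last record in
   (`fda_dt`, input order).

An unparseable or partial `fda_dt` sorts earliest, so a dated report
always survives over an undated rival. The operation is idempotent, and
the synthetic generator emits a ground-truth survivor list so the rule is
tested against an oracle it did not compute.

### Partial dates

`YYYY` and `YYYYMM` values are retained for description but treated as
unknown wherever day-level arithmetic is required (time-to-onset). This
avoids fabricating precision; the generator can degrade a configurable
fraction of dates to exercise the path.

## The four disproportionality statistics

With cells $a$ (target drug, event), $b$ (target drug, other events),
$c$, $d$ (comparator likewise) and $N = a+b+c+d$:

* **ROR** $= ad/bc$ with Wald interval
  $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. Undefined on
  zero cells; by default no Haldane–Anscombe 0.5 correction is applied
  (a flag exists), because silently manufacturing intervals for
  never-co-reported pairs is worse than reporting the statistic absent.
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$ with the 2×2 chi-square
  $N(|ad-bc| - \tfrac{N}{2})^2 / [(a+b)(c+d)(a+c)(b+d)]$, Yates-corrected
  by default (configurable); the continuity term is floored at zero.
* **BCPNN information component**: the closed-form posterior expectation
  of $\log_2$ observed-over-expected under the standard priors
  ($\alpha_1=\beta_1=\gamma_{11}=1$, $\alpha=\beta=2$), with
  $\mathrm{IC025} = E(\mathrm{IC}) - 2\,\mathrm{SD}(\mathrm{IC})$. It is
  finite even at $a = 0$ and converges to the raw
  $\log_2\frac{aN}{(a+b)(a+c)}$ as counts grow — both properties are
  asserted in the tests.
* **MGPS / EBGM**: an empirical-Bayes model with a two-component gamma
  prior on the relative reporting ratio $\lambda$, where the observed
  count of each drug–event cell is Poisson with mean $\lambda E$ and
  $E = (a+b)(a+c)/N$ is the independence expectation. The
  hyperparameters $(a_1, b_1, a_2, b_2, w)$ maximize the marginal
  likelihood, a mixture of negative binomials, over *all* drug–event
  cells of the database. Per cell, the posterior is a gamma mixture;
  `EBGM` is its geometric mean
  $\exp\!\big(Q[\psi(a_1{+}a) - \ln(b_1{+}E)] + (1{-}Q)[\cdot]\big)$ and
  `EBGM05` its 0.05 quantile.

### Positivity criteria

A term is a confirmed signal only when **all four** algorithms are
positive simultaneously; the count of positive algorithms (0–4) feeds the
priority rubric's stability criterion. Defaults (each configurable):
ROR positive iff $a \ge 3$ and the CI lower bound exceeds 1; PRR positive
iff $a \ge 3$, PRR $\ge 2$, $\chi^2 \ge 4$; BCPNN positive iff
IC025 $> 0$; MGPS positive iff EBGM05 $> 2$. These are the conventional
published criteria for the four algorithms, and they exactly explain the
composition of the reference analysis's signal tables. Terms with
$a < 10$ carry a small-count caution flag. The comparator is the full
deduplicated database minus the target drug's primary-suspect reports;
whether a reference set should also exclude the target's non-PS mentions
is genuinely open, and the full-database comparator is the common
default.

### Numerical choices

* MGPS optimization is on log-transformed shapes/rates and logit weight,
  bounded quasi-Newton (L-BFGS-B) from the start point
  $(0.2, 0.1, 2, 4, 1/3)$, iteration cap 500. When the line search aborts
  on a flat likelihood (small stratified databases), a Nelder-Mead polish
  runs from the best point before non-convergence is declared; a
  non-convergent fit errors carrying the best-so-far parameters.
* EBGM05 is found by bisection on the mixture CDF to absolute tolerance
  1e-8; tests compare it against an independent numeric-integration
  oracle at 1e-6.
* Every closed-form statistic is checked against a naive transcription on
  1,000 random tables at 1e-10, with all products in double precision
  (the cross-products overflow 32-bit integers routinely).

## Clinical-priority rubric

Adverse events positive in at least one algorithm are scored 0–2 on four
criteria and banded by total: 0–2 low, 3–5 moderate, 6–8 high.

| criterion | 0 | 1 | 2 |
|---|---|---|---|
| clinical relevance | unlisted | IME | DME |
| reporting rate (cases : non-cases, $100\,n/(T-n)$) | ≤ 1% | 1–10% | ≥ 10% |
| signal stability (positive algorithms) | 0–1 | 2–3 | 4 |
| case fatality rate | < 10% | 10–50% | > 50% |

The top fatality score is deliberately reserved for rates above 50%:
death outcomes in spontaneous reports conflate drug effect with
underlying disease, so the rubric is conservative. A term on both the
IME and DME designation lists scores as DME (the rarer, stronger
designation). The exact per-criterion point values of the published
rubric are not reprinted in its source, so the 0/1/2 map above — which
satisfies all stated constraints (four criteria, 0–8 range, top fatality
score only above 50%) — ships as the default and is fully overridable;
consequently the package's tests cover the band partition and component
computations, not any particular study's total-score column. The
designation lists themselves are user-supplied files (the EMA publishes
them under its own terms); the bundled `*_toy.tsv` lists are synthetic
stand-ins covering the generator vocabulary only.

## Time-to-onset

Onset is the difference in whole days between the event date and the
**earliest full-precision therapy start** of the target drug on the
report (earliest exposure is the conservative anchor when several
therapy rows exist). Reports with missing or partial dates, or an event
preceding therapy start, are excluded with a recorded reason — never
imputed. Day 0 (same-day onset) falls in the first descriptive bin,
whose printed endpoints 0–30, 31–60, ..., 181–360, >360 are all
inclusive.

Kaplan-Meier cumulative incidence uses the product-limit estimator;
since spontaneous reports carry no follow-up, the replication path
treats every included record as an event (the estimator accepts
censoring flags for generality, and without censoring it equals
$1 - \mathrm{ECDF}$, asserted at 1e-12). Group comparisons use the
standard log-rank chi-square. Median and IQR are linear-interpolation
quantiles of the raw days.

## Case/non-case risk model

Reports whose distinct PTs include at least one term of the outcome SOC
(hepatobiliary disorders by default) are cases; all other reports of the
target drug are non-cases. Age is banded <45 / 45–65 / 65–75 / >75 and
reports with unknown age or sex are dropped (complete-case analysis —
the reference margins only total the known-covariate reports). Exposure
to a drug class is a match of any drug entry against the class synonym
list in any role except the target's own PS entry; the inclusive
any-role default is configurable to non-suspect roles only, since
"concomitant medication" has no role rule in the source conventions.

Univariate odds ratios come from the closed-form cross-product with Wald
intervals; the multivariable model is maximum-likelihood logistic
regression (IRLS; convergence at score tolerance 1e-8 / relative
log-likelihood change 1e-10, cap 50 iterations) with references age <45,
female, unexposed. Separation (a coefficient diverging beyond ±15) and
rank deficiency are errors naming the term. Because no individual-level
joint covariate data accompany published marginal tables, multivariable
correctness is established by parameter recovery on synthetic cohorts,
not against printed multivariable ORs.

## The synthetic generator

`simulate_reports()` emulates one quarter of a deduplicatable six-table
extract. Its defaults are the study conditions of the analysis it
supports: 3,150 reports; 2.3 distinct events per report; 42.1% unknown
age and 35.8% unknown sex; onset dates on 17.8% of reports; outcome
frequencies (hospitalization 23.3%, death 7.5%, ...) from the
descriptive distribution; a Weibull(shape 0.8, scale 76) onset delay
whose median sits near 48 days (a single Weibull cannot match both the
reported median and the long upper quartile exactly; the compromise
favors the median); concomitant-exposure prevalences RTX 12%, CTX 4%,
PPI 7%, statins 4% from the case/non-case margins.

Event sampling is a slot model: each report draws
$K \sim \mathrm{ZTPoisson}$ event slots from the catalog's normalized
probability shares and keeps the distinct PTs. Two consequences are
deliberate:

* the ZTP rate is solved numerically so the *expected number of distinct
  PTs* equals `events_per_report_mean` exactly, keeping the marginal
  calibration testable at 3 standard errors;
* a planted (drug, PT, OR) association boosts the PT's **slot share**
  through the odds inversion `plant_association()`, with the remaining
  shares rescaled. Because the downstream contingency tables count
  event-versus-other-events pairs, odds on the slot-share scale are
  exactly what the reporting odds ratio measures, so the planted target
  is recovered without systematic bias (planting on the per-report
  presence scale instead would attenuate the pair-counted ROR by about
  4% at the default event load). Residual attenuation from within-report
  deduplication is below 1%, well inside sampling error at the tested
  sizes.

The distribution of events per report is not observable from published
descriptive tables; the zero-truncated Poisson is a modelling choice and
is configurable. Duplicate injection adds later-or-equal-dated versions
with larger primaryids and returns the survivor ground truth *from the
generator*, keeping deduplication tests independent of the code under
test.

What the generator does **not** emulate: real MedDRA vocabulary breadth
(a toy catalog of ~30 PTs in 11 SOCs suffices), pharmacological
plausibility of co-medication patterns, reporting-volume trends over
quarters, correlated missingness, or free-text drug-name noise beyond
case/whitespace. Passing tests therefore demonstrate algorithmic
correctness and calibration under controlled conditions, not robustness
to every artifact of real spontaneous data.

## Problem sizes used by the test suite

The property suites run at the sizes the methods need, chosen once:
1,000 random tables for the closed-form oracles; 10,000 cells for MGPS
hyperparameter recovery (within 10%, mixture weight within ±0.05);
20 seeds × 50,000 reports for planted-ROR recovery (the target inside
its own 95% CI in ≥ 90% of seeds — note a nominal-coverage estimator
fails this binomial bar about 7% of the time by chance alone);
50 seeds × 50,000 rows for logistic coefficient recovery (mean bias
< 0.02); 1,000 null replicates for the log-rank type-I error
(rejection rate asserted in [0.03, 0.07] at α = 0.05).

## Known limitations

* Stratified/covariate-adjusted MGPS (stratification by age, sex,
  period) is out of scope; the subgroup analysis simply reruns the
  unadjusted statistics within strata.
* No multiple-comparison control across terms is applied, matching the
  practice the pipeline reproduces.
* The reporting-rate denominator (cases to non-cases) is a convention of
  the priority rubric, not an incidence estimate; spontaneous data
  support neither incidence nor causal claims.
* Report-level outcomes are single-valued in the generator (real reports
  may carry several outcome codes; the parser accepts them).
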