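# Shared fixtures: a tiny hand-built quarter, and naive independent
# transcriptions of the closed-form statistics used as oracles.

# Three reports, two drugs, four PTs; every join hand-checkable.
write_toy_quarter <- function(dir = tempfile("quarter_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(file, lines) writeLines(lines, file.path(dir, file))
  w("DEMO.txt", c(
    "primaryid$caseid$fda_dt$event_dt$age$sex$wt$reporter$occr_country",
    "1011$101$20230105$20230131$63$F$70$MD$US",
    "1021$102$20230210$$45$M$$CN$JP",
    "1031$103$20230312$$$$$$US"))
  w("DRUG.txt", c(
    "primaryid$caseid$drug_seq$role_cod$drugname",
    "1011$101$1$PS$Avacopan",
    "1021$102$1$PS$OTHERDRUG",
    "1021$102$2$C$avacopan ",
    "1031$103$1$PS$OTHERDRUG"))
  w("REAC.txt", c(
    "primaryid$caseid$pt",
    "1011$101$Nausea",
    "1011$101$Jaundice",
    "1021$102$Nausea",
    "1031$103$Cholestasis"))
  w("OUTC.txt", c(
    "primaryid$caseid$outc_cod",
    "1011$101$DE"))
  w("THER.txt", c(
    "primaryid$caseid$dsg_drug_seq$start_dt",
    "1011$101$1$20230101"))
  dir
}

toy_soc_map <- function() {
  meddra_map(c("Nausea", "Jaundice", "Cholestasis"),
             c("Gastrointestinal disorders", "Hepatobiliary disorders",
               "Hepatobiliary disorders"))
}

# --- naive oracle transcriptions, independent of the package internals ---

naive_ror <- function(a, b, c, d) {
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror = ror, lo = exp(log(ror) - 1.96 * se), hi = exp(log(ror) + 1.96 * se))
}

naive_prr <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))

naive_chi2 <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (yates) dev <- max(0, dev - n / 2)
  n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

naive_ic <- function(a, b, c, d, a1 = 1, b1 = 1, g11 = 1, al = 2, be = 2) {
  n <- a + b + c + d
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  ic <- log2((a + g11) * (n + al) * (n + be) /
               ((n + gam) * (a + b + a1) * (a + c + b1)))
  v <- (1 / log(2)^2) * (
    (n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
    (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
    (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be)))
  c(ic = ic, ic025 = ic - 2 * sqrt(v))
}

# Standard log-rank by direct tabulation over shared event times.
naive_logrank2 <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    at1 <- sum(time >= t & group == g[1])
    at2 <- sum(time >= t & group == g[2])
    d1 <- sum(time == t & event == 1 & group == g[1])
    d2 <- sum(time == t & event == 1 & group == g[2])
    n <- at1 + at2; d <- d1 + d2
    if (n == 0 || d == 0) next
    o1 <- o1 + d1
    e1 <- e1 + d * at1 / n
    if (n > 1) v <- v + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

random_tables <- function(n, seed) {
  set.seed(seed)
  data.frame(a = sample(1:200, n, TRUE), b = sample(1:2000, n, TRUE),
             c = sample(1:2000, n, TRUE), d = sample(1:50000, n, TRUE))
}
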