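# Independent oracles and shared fixtures for the test suite.

# Brute-force upper-tail hypergeometric probability by direct summation of
# binomial-coefficient pmf terms (log-space coefficients so corpus-scale N
# does not overflow). Deliberately independent of stats::phyper.
brute_hyper_tail <- function(N, n, m, k) {
  hi <- min(n, m)
  if (k > hi) stop("k exceeds min(n, m)")
  if (k == 0) return(1)
  i <- k:hi
  sum(exp(lchoose(n, i) + lchoose(N - n, m - i) - lchoose(N, m)))
}

# Brute-force ROC area: concordant case/control pairs (+1/2 per tie) over
# all pairs, oriented to be >= 0.5.
brute_auc <- function(cases, controls) {
  u <- 0
  for (x in cases) for (y in controls) {
    u <- u + (x > y) + 0.5 * (x == y)
  }
  a <- u / (length(cases) * length(controls))
  max(a, 1 - a)
}

table1_studies <- function() {
  read_studies_tsv(fixture_path("studies"))
}

table4_degrees <- function() {
  c(RAC1 = 10L, NRAS = 8L, TRAF6 = 7L, ERBB4 = 5L, NOTCH2 = 5L, PTGS2 = 5L,
    ELAVL1 = 4L, PARK2 = 4L, SMAD4 = 4L, YES1 = 4L, RACGAP1 = 3L, HEYL = 1L,
    IL17A = 1L, IQGAP1 = 1L, IRAK1 = 1L, NOVA1 = 1L, OTUD7B = 1L,
    PTPRE = 1L, ROBO1 = 1L, SORT1 = 1L)
}

# Published tail probabilities for the hub connectivity test, one per
# distinct degree observed among the 20 hub genes.
table4_pvalues <- function() {
  c(`10` = 0.007305, `8` = 0.044385, `7` = 0.091440, `5` = 0.276934,
    `4` = 0.412161, `3` = 0.558826, `1` = 0.812719)
}

random_effects_panel <- function(k, seed, mu = -0.5, tau2 = 0.09) {
  set.seed(seed)
  v <- stats::runif(k, 0.02, 0.3)
  data.frame(study_id = sprintf("s%02d", seq_len(k)),
             g = stats::rnorm(k, mu, sqrt(tau2 + v)),
             variance = v, se = sqrt(v))
}
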