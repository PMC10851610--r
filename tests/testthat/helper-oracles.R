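# Independent oracles, deliberately written from first principles so they
# share no code with the implementation they check.

# percentile rank by explicit counting: midrank over ties, round half-up
brute_rank <- function(value, reference) {
  n_lt <- sum(reference < value)
  n_eq <- sum(reference == value)
  r <- floor(100 * (n_lt + 0.5 * n_eq) / length(reference) + 0.5)
  min(max(r, 0), 100)
}

# two-sided Fisher p by full hypergeometric enumeration over the table
# support, minimum-likelihood rule
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-group log-rank chi-square from the observed-minus-expected table
logrank_oracle <- function(time, event, group) {
  group <- as.character(group)
  g1 <- unique(group)[1]
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at1 <- sum(time >= t & group == g1)
    at2 <- sum(time >= t & group != g1)
    d1 <- sum(time == t & event == 1 & group == g1)
    d2 <- sum(time == t & event == 1 & group != g1)
    d <- d1 + d2
    n <- at1 + at2
    if (n < 2 || d == 0) next
    O <- O + d1
    E <- E + d * at1 / n
    V <- V + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# product-limit estimator by direct recursion
km_oracle <- function(time, event) {
  times <- sort(unique(time))
  s <- 1
  surv <- numeric(0)
  for (t in times) {
    at_risk <- sum(time >= t)
    deaths <- sum(time == t & event == 1)
    s <- s * (1 - deaths / at_risk)
    surv <- c(surv, s)
  }
  data.frame(time = times, surv = surv)
}

# small, fast generator configuration for contract tests
small_config <- function(seed = 1, ...) {
  generator_config(n_reference = 150L, n_discovery = 400L,
                   n_retrospective = 60L,
                   arm_split = c(combination = 35L, monotherapy = 25L),
                   seed = seed, ...)
}

# hand-built rank matrix covering the default panel
toy_ranks <- function(values, samples = 1) {
  genes <- default_ctab_panel()$genes
  matrix(rep(values, length.out = samples * length(genes)),
         nrow = samples, byrow = TRUE,
         dimnames = list(sprintf("S%d", seq_len(samples)), genes))
}
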