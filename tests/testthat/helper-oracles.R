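# Brute-force oracles, independent of the distribution functions used in R/.

# Hypergeometric pmf at k case alleles from first principles.
oracle_table_prob <- function(k, case_an, ctrl_an, k_total) {
  choose(case_an, k) * choose(ctrl_an, k_total - k) / choose(case_an + ctrl_an, k_total)
}

# One-tailed (case-enrichment) Fisher p by enumerating every table with the
# observed margins.
oracle_fet_one_sided <- function(case_ac, case_an, ctrl_ac, ctrl_an) {
  k_total <- case_ac + ctrl_ac
  ks <- max(0, k_total - ctrl_an):min(case_an, k_total)
  probs <- oracle_table_prob(ks, case_an, ctrl_an, k_total)
  sum(probs[ks >= case_ac])
}

# Two-sided Fisher p by the point-probability rule over the same support.
oracle_fet_two_sided <- function(a, b, c, d) {
  case_an <- a + b; ctrl_an <- c + d; k_total <- a + c
  ks <- max(0, k_total - ctrl_an):min(case_an, k_total)
  probs <- oracle_table_prob(ks, case_an, ctrl_an, k_total)
  p_obs <- oracle_table_prob(a, case_an, ctrl_an, k_total)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Poisson upper tail including the observed value, by direct pmf summation
# (log-space terms summed upward until negligible).
oracle_poisson_upper <- function(obs, lambda, kmax = 2000L) {
  if (obs == 0) return(1)
  ks <- obs:(obs + kmax)
  sum(exp(ks * log(lambda) - lambda - lgamma(ks + 1)))
}

# Hand step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(1, q)
  out
}

# Chi-square(4) survival closed form: exp(-x/2) * (1 + x/2).
oracle_chisq4_upper <- function(x) exp(-x / 2) * (1 + x / 2)

# Small cohort configuration for fast tests.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_trios = 300L, n_singletons = 150L, n_controls = 5000L,
                   n_genes = 40L, seed = 11L)
  do.call(cohort_config, utils::modifyList(defaults, args))
}
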