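#' Poisson burden of de novo mutations against mutability expectation
#'
#' Tests whether the observed DNM count exceeds the mutability-based
#' expectation `E = n_trios * mu`. The p-value is the upper tail including
#' the observed value, `P(Poisson(E) >= observed)`; `p_mid` is the
#' mid-p variant `P(X > obs) + P(X = obs)/2`, used downstream for the
#' z-score transform because the conservative tail is strongly discrete at
#' small expectations.
#'
#' @param observed observed DNM count.
#' @param n_trios number of sequenced trios.
#' @param mu per-birth de novo probability (per gene or summed over a set).
#' @param unit,class optional labels carried into the result row.
#' @return one-row data.frame: `unit`, `class`, `observed`, `expected`,
#'   `enrichment`, `p`, `p_mid`, `attributable_fraction`.
#' @examples
#' poisson_burden(5, 1000, 1e-3)  # E = 1, p ~ 3.66e-3
#' @export
poisson_burden <- function(observed, n_trios, mu, unit = NA_character_,
                           class = NA_character_) {
  observed <- check_count(observed, "observed")
  n_trios <- check_count(n_trios, "n_trios", min = 1L)
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0)
    stop_input("mu must be a single positive rate")
  E <- n_trios * mu
  p <- ppois(observed - 1L, E, lower.tail = FALSE)
  p_mid <- ppois(observed, E, lower.tail = FALSE) + dpois(observed, E) / 2
  data.frame(
    unit = unit, class = class, observed = observed, expected = E,
    enrichment = observed / E, p = p, p_mid = p_mid,
    attributable_fraction = max(0, observed - E) / n_trios,
    stringsAsFactors = FALSE
  )
}

#' Gene-set de novo burden
#'
#' Sums observed and expected DNM counts over a gene set for one functional
#' class, then applies the [poisson_burden()] arithmetic to the totals.
#'
#' @param counts class-counts table from [aggregate_counts()] or
#'   [simulate_class_counts()].
#' @param mutability mutability table covering the set.
#' @param genes character vector of gene names (non-empty).
#' @param class one of `"synonymous"`, `"T-mis"`, `"D-mis"`, `"LOF"`, or
#'   `"damaging"` (D-mis + LOF pooled).
#' @param n_trios number of trios.
#' @return one-row burden data.frame (see [poisson_burden()]).
#' @export
geneset_burden <- function(counts, mutability, genes, class, n_trios) {
  if (length(genes) == 0L) stop_input("empty gene set")
  missing <- setdiff(genes, mutability$gene)
  if (length(missing))
    stop_input("genes absent from mutability table: ", paste(missing, collapse = ", "))
  if (class == "damaging") {
    sel <- counts$gene %in% genes & counts$class %in% DAMAGING_CLASSES
    mu <- sum(damaging_mu(mutability)[genes])
  } else {
    sel <- counts$gene %in% genes & counts$class == class
    mu <- sum(mutability[[mu_column(class)]][match(genes, mutability$gene)])
  }
  poisson_burden(sum(counts$n_dnm[sel]), n_trios, mu,
                 unit = paste0("set[", length(genes), "]"), class = class)
}

#' Attributable fraction from excess de novo mutations
#'
#' Excess of observed over expected DNM carriers as a fraction of probands,
#' floored at zero.
#'
#' @param observed,expected observed count and mutability expectation.
#' @param n_probands cohort size the fraction is expressed over.
#' @export
attributable_fraction_dnm <- function(observed, expected, n_probands) {
  n_probands <- check_count(n_probands, "n_probands", min = 1L)
  max(0, observed - expected) / n_probands
}

#' Genomic inflation scaled to 1,000 samples
#'
#' Converts one-sided p-values to 1-df chi-square quantiles, takes the ratio
#' of their median to the null median (0.4549364), and rescales the
#' inflation to a cohort of 1,000 samples:
#' `lambda_1000 = 1 + (lambda - 1) * 1000 / n_samples`.
#'
#' @param pvals p-values in (0, 1].
#' @param n_samples cohort size behind the tests.
#' @return list with `lambda` and `lambda_1000`.
#' @export
lambda_1000 <- function(pvals, n_samples) {
  if (length(pvals) == 0L) stop_input("empty p-value list")
  if (any(pvals <= 0 | pvals > 1)) stop_input("p-values must be in (0, 1]")
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  lam <- median(qchisq(1 - pvals, df = 1)) / qchisq(0.5, df = 1)
  list(lambda = lam, lambda_1000 = 1 + (lam - 1) * (1000 / n_samples))
}

#' Observed/expected quantiles for a QQ plot
#'
#' @param pvals p-values.
#' @param n_samples cohort size (for the lambda annotation).
#' @return data.frame with ascending `observed` p-values and uniform
#'   `expected` quantiles `i / (n + 1)`; `lambda_1000` kept as an attribute.
#' @export
qq_summary <- function(pvals, n_samples) {
  l <- lambda_1000(pvals, n_samples)
  n <- length(pvals)
  out <- data.frame(observed = sort(pvals), expected = seq_len(n) / (n + 1))
  attr(out, "lambda_1000") <- l$lambda_1000
  out
}

#' Expected number of genes with recurrent de novo mutations
#'
#' Closed-form expectation of the number of genes carrying at least
#' `min_hits` damaging DNMs under the mutability null:
#' `sum_g P(Poisson(n_trios * mu_g,damaging) >= min_hits)`, with an optional
#' simulation cross-check.
#'
#' @param mutability mutability table.
#' @param n_trios number of trios.
#' @param min_hits minimum DNM count per gene (>= 1).
#' @param n_sim if > 0, also return the Monte-Carlo mean and SD over
#'   `n_sim` simulated cohorts.
#' @param seed seed for the simulation cross-check.
#' @return list with `expected` and, when simulated, `sim_mean`, `sim_sd`.
#' @export
expected_multihit_genes <- function(mutability, n_trios, min_hits = 2L,
                                    n_sim = 0L, seed = 1L) {
  min_hits <- check_count(min_hits, "min_hits", min = 1L)
  lam <- n_trios * damaging_mu(mutability)
  out <- list(expected = sum(ppois(min_hits - 1L, lam, lower.tail = FALSE)))
  if (n_sim > 0L) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    hits <- replicate(n_sim, sum(rpois(length(lam), lam) >= min_hits))
    out$sim_mean <- mean(hits)
    out$sim_sd <- sd(hits)
  }
  out
}

#' Monte-Carlo maximum-likelihood estimate of the number of risk genes
#'
#' For each candidate risk-gene count R in `r_grid` and enrichment e in
#' `enrichment_grid`, simulates `n_sim` cohorts (R risk genes drawn with
#' probability proportional to damaging mutability, or uniformly; damaging
#' DNM counts Poisson with the enrichment applied at risk genes) and
#' evaluates the empirical likelihood of the observed summary statistic --
#' the pair (number of genes with >= 1 damaging DNM, number with >= 2) --
#' from a jointly binned frequency table with add-one smoothing (bin width
#' 2; the smoothing denominator uses the bins occupied anywhere on the
#' grid). The profile log-likelihood over e is maximised in R; the 95\% CI
#' is the span of grid points within 1.92 log-likelihood units of the
#' maximum.
#'
#' @param observed_per_gene integer vector of damaging DNM counts per gene.
#' @param mutability mutability table (same genes).
#' @param n_trios number of trios.
#' @param enrichment_grid candidate fold-enrichments at risk genes.
#' @param r_grid candidate risk-gene counts.
#' @param n_sim simulations per grid point (>= 100).
#' @param seed RNG seed.
#' @param weighted_sampling draw risk genes proportionally to damaging
#'   mutability (default) or uniformly.
#' @return list: `r_hat`, `ci_low`, `ci_high`, `loglik_curve` (data.frame of
#'   R, profile log-likelihood, best enrichment), `degenerate` flag.
#' @export
risk_gene_mle <- function(observed_per_gene, mutability, n_trios,
                          enrichment_grid = c(5, 10, 20),
                          r_grid = seq(0L, nrow(mutability), by = 10L),
                          n_sim = 200L, seed = 1L, weighted_sampling = TRUE) {
  if (length(enrichment_grid) == 0L || length(r_grid) == 0L)
    stop_input("enrichment_grid and r_grid must be non-empty")
  n_sim <- check_count(n_sim, "n_sim", min = 100L)
  n_genes <- nrow(mutability)
  if (length(observed_per_gene) != n_genes)
    stop_input("observed_per_gene must have one count per mutability gene")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  mu <- unname(damaging_mu(mutability))
  w <- if (weighted_sampling) mu / sum(mu) else rep(1 / n_genes, n_genes)
  obs <- c(sum(observed_per_gene >= 1L), sum(observed_per_gene >= 2L))
  bw <- 2L
  bin_of <- function(s1, s2) paste(s1 %/% bw, s2 %/% bw)
  obs_bin <- bin_of(obs[1], obs[2])

  grid <- expand.grid(R = r_grid, e = enrichment_grid, KEEP.OUT.ATTRS = FALSE)
  sims <- lapply(seq_len(nrow(grid)), function(i) {
    R <- grid$R[i]; e <- grid$e[i]
    vapply(seq_len(n_sim), function(s) {
      lam <- n_trios * mu
      if (R > 0L) {
        risk <- sample.int(n_genes, min(R, n_genes), prob = w)
        lam[risk] <- lam[risk] * e
      }
      x <- rpois(n_genes, lam)
      c(sum(x >= 1L), sum(x >= 2L))
    }, numeric(2))
  })
  all_bins <- unique(c(obs_bin, unlist(lapply(sims, function(s) bin_of(s[1, ], s[2, ])))))
  B <- length(all_bins)
  ll <- vapply(sims, function(s) {
    hits <- sum(bin_of(s[1, ], s[2, ]) == obs_bin)
    log((hits + 1) / (n_sim + B))
  }, numeric(1))
  grid$ll <- ll
  prof <- vapply(r_grid, function(R) max(grid$ll[grid$R == R]), numeric(1))
  best_e <- vapply(r_grid, function(R) {
    rows <- grid[grid$R == R, ]
    rows$e[which.max(rows$ll)]
  }, numeric(1))
  r_hat <- r_grid[which.max(prof)]
  keep <- prof >= max(prof) - 1.92
  degenerate <- length(r_grid) == 1L
  if (degenerate) warning("degenerate r_grid: CI equals the single grid point")
  list(
    r_hat = r_hat,
    ci_low = min(r_grid[keep]),
    ci_high = max(r_grid[keep]),
    loglik_curve = data.frame(R = r_grid, loglik = prof, enrichment = best_e),
    degenerate = degenerate
  )
}
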