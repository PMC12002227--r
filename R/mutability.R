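#' Sample a synthetic per-gene mutability table
#'
#' Draws a gene panel with per-gene, per-class de novo mutation probabilities
#' ("mutabilities"). The mutability \eqn{\mu_{gc}} is the probability of one
#' de novo variant of class \eqn{c} arising in gene \eqn{g} per live birth, so
#' the expected DNM count in a cohort is `n_trios * mu` (no extra factor of 2).
#'
#' Per-gene total mutability is drawn log-normally around `target_total_mu`
#' (default 2.4e-4 per birth, emulating the large, constraint-selected genes
#' of a disease panel rather than the genome-wide average gene) and split
#' across the four functional classes by a Dirichlet draw whose mean split is
#' 32\% synonymous, 42\% tolerated missense, 16\% damaging missense, 10\% LOF,
#' so that synonymous+missense mass exceeds LOF mass on average.
#'
#' @param n_genes number of panel genes (>= 1).
#' @param seed integer seed; the table is deterministic given the seed.
#' @param target_total_mu mean per-gene total mutability (per birth).
#' @return A data.frame with one row per gene: `gene`, `chrom`, `start`,
#'   `end` (0-based half-open panel interval), `pli`, and per-class columns
#'   `mu_syn`, `mu_tmis`, `mu_dmis`, `mu_lof`. The configured target is kept
#'   in `attr(, "target_total_mu")`.
#' @examples
#' mut <- sample_mutabilities(10, seed = 1)
#' stopifnot(all(mut$mu_lof > 0))
#' @export
sample_mutabilities <- function(n_genes, seed = 1L, target_total_mu = 2.4e-4) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  sdlog <- 0.8
  total <- rlnorm(n_genes, meanlog = log(target_total_mu) - sdlog^2 / 2, sdlog = sdlog)
  # Dirichlet split via normalized gammas; concentration keeps class ordering realistic.
  conc <- c(syn = 16, tmis = 21, dmis = 8, lof = 5)
  g <- vapply(conc, function(a) rgamma(n_genes, shape = a), numeric(n_genes))
  if (n_genes == 1L) g <- matrix(g, nrow = 1L, dimnames = list(NULL, names(conc)))
  share <- g / rowSums(g)

  gene_len <- pmax(900L, round(rlnorm(n_genes, log(2500), 0.6) / 3) * 3L)
  start <- cumsum(c(0L, head(gene_len, -1L) + 5000L))
  tab <- data.frame(
    gene = sprintf("G%04d", seq_len(n_genes)),
    chrom = paste0("chr", (seq_len(n_genes) - 1L) %% 22L + 1L),
    start = start,
    end = start + gene_len,
    pli = stats::rbeta(n_genes, 0.4, 0.4),
    mu_syn = total * share[, "syn"],
    mu_tmis = total * share[, "tmis"],
    mu_dmis = total * share[, "dmis"],
    mu_lof = total * share[, "lof"],
    stringsAsFactors = FALSE
  )
  attr(tab, "target_total_mu") <- target_total_mu
  tab
}

# Map functional-class labels to mutability columns.
mu_column <- function(class) {
  m <- c("synonymous" = "mu_syn", "T-mis" = "mu_tmis", "D-mis" = "mu_dmis", "LOF" = "mu_lof")
  out <- m[class]
  if (anyNA(out)) stop_input("unknown functional class: ", paste(class[is.na(out)], collapse = ", "))
  unname(out)
}

#' Per-gene damaging mutability (D-mis + LOF)
#' @param mutability a table from [sample_mutabilities()] (or same columns).
#' @return numeric vector named by gene.
#' @export
damaging_mu <- function(mutability) {
  setNames(mutability$mu_dmis + mutability$mu_lof, mutability$gene)
}
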