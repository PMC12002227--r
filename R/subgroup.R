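#' Two-sided Fisher exact test on a clinical 2x2 table
#'
#' Two-sided exact p by the point-probability rule (sum over tables with
#' fixed margins whose probability does not exceed the observed table's),
#' plus the row-wise proportions.
#'
#' @param a,b,c,d cell counts: `a/(a+b)` versus `c/(c+d)`.
#' @return list with `p`, `prop1 = a/(a+b)`, `prop2 = c/(c+d)`.
#' @examples
#' feature_2x2(2, 5, 15, 3)  # p ~ 1.7e-2
#' @export
feature_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop_input("cell counts must be non-negative")
  if (sum(cells) == 0) stop_input("all-zero table")
  m <- matrix(cells, 2, 2, byrow = TRUE)
  list(p = fisher.test(m, alternative = "two.sided")$p.value,
       prop1 = if (a + b > 0) a / (a + b) else NaN,
       prop2 = if (c + d > 0) c / (c + d) else NaN)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum p-value: exact when both groups have at most 10
#' observations and there are no ties, otherwise the normal approximation
#' with tie correction (no continuity correction).
#'
#' @param x,y numeric vectors (both non-empty).
#' @export
rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop_input("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 10L && length(y) <= 10L && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = FALSE)$p.value
  )
}

#' Monte-Carlo test of non-random phenotype distribution across genes
#'
#' Statistic: Pearson chi-square of the gene-category x phenotype-category
#' contingency table. The phenotype labels are permuted across probands
#' `n_perm` times; `p = (1 + #\{permuted >= observed\}) / (1 + n_perm)`.
#'
#' @param gene_of_variant per-proband gene (or gene-category) labels.
#' @param phenotype per-proband phenotype labels.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `p`, `statistic`, `n_perm`.
#' @export
phenotype_permutation_test <- function(gene_of_variant, phenotype,
                                       n_perm = 10000L, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  if (length(gene_of_variant) != length(phenotype))
    stop_input("label vectors must have equal length")
  if (length(unique(gene_of_variant)) < 2L || length(unique(phenotype)) < 2L)
    stop_input("need at least two categories on each axis")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  pearson <- function(g, p) {
    tab <- table(g, p)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - expd)^2 / expd)
  }
  obs <- pearson(gene_of_variant, phenotype)
  exceed <- sum(vapply(seq_len(n_perm), function(i) {
    pearson(gene_of_variant, sample(phenotype)) >= obs
  }, logical(1)))
  list(p = (1 + exceed) / (1 + n_perm), statistic = obs, n_perm = n_perm)
}

#' Gene x phenotype subgroup meta-analysis
#'
#' For each gene and each phenotype category (the eight cardiac subtypes
#' plus the four EC/NDD categories isolated, EC-only, NDD-only, EC+NDD),
#' computes the damaging DNM burden and the case-control burden within the
#' subgroup, then applies the JL-FDR machinery jointly over all gene x
#' phenotype cells so that the FDR accounts for the full grid.
#'
#' @param cohort a `simulated_cohort` (or list with `variants`, `pedigree`,
#'   `phenotypes`, `controls`, `mutability`, `config`).
#' @param genes gene set to test (e.g. the significant genes).
#' @param fdr_level FDR level.
#' @param thresholds rarity thresholds applied before counting, see
#'   [filter_thresholds()].
#' @return list: `cells` (ranked gene x phenotype meta table), `fit`.
#' @export
subgroup_meta <- function(cohort, genes, fdr_level = 0.05,
                          thresholds = filter_thresholds()) {
  ph <- cohort$phenotypes
  ecndd <- ifelse(ph$ec & ph$ndd, "EC+NDD",
           ifelse(ph$ec, "EC", ifelse(ph$ndd, "NDD", "isolated")))
  categories <- c(lapply(setNames(nm = CARDIAC_SUBTYPES), function(s) ph$proband_id[ph$cardiac_subtype == s]),
                  lapply(setNames(nm = c("isolated", "EC", "NDD", "EC+NDD")),
                         function(s) ph$proband_id[ecndd == s]))

  vr <- filter_very_rare(cohort$variants, thresholds)
  trio_pb <- cohort$pedigree$sample_id[cohort$pedigree$phenotype == 2L &
                                       cohort$pedigree$father_id != "0"]
  mu_d <- damaging_mu(cohort$mutability)
  ctrl <- cohort$controls
  ctrl_d <- rowsum(ctrl$ctrl_ac[ctrl$class %in% DAMAGING_CLASSES],
                   ctrl$gene[ctrl$class %in% DAMAGING_CLASSES])
  ctrl_an <- ctrl$ctrl_an[match(rownames(ctrl_d), ctrl$gene)]

  rows <- list()
  for (cat in names(categories)) {
    pb <- categories[[cat]]
    if (length(pb) == 0L) { warning("subgroup ", cat, " has zero probands; skipped"); next }
    n_trio_sub <- sum(trio_pb %in% pb)
    sub <- vr[vr$sample_id %in% pb & vr$gene %in% genes, , drop = FALSE]
    cls <- classify_variants(sub$consequence, sub$metasvm)
    dmg <- sub[cls %in% DAMAGING_CLASSES, , drop = FALSE]
    for (g in genes) {
      gd <- dmg[dmg$gene == g, , drop = FALSE]
      n_dnm <- sum(gd$origin == "de_novo")
      ac <- sum(gd$origin %in% c("transmitted", "unphased"))
      pb_res <- poisson_burden(n_dnm, max(1L, n_trio_sub), mu_d[[g]], unit = g, class = "damaging")
      cc_res <- fet_burden(ac, 2L * length(pb),
                           ctrl_d[g, 1], ctrl_an[match(g, rownames(ctrl_d))],
                           unit = g, class = "damaging")
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, phenotype = cat, n_probands = length(pb),
        n_dnm = n_dnm, case_ac = ac,
        p_dnm = pb_res$p, p_cc = cc_res$p,
        z_dnm = p_to_z(pmax(pb_res$p_mid, 1e-300)),
        z_cc = p_to_z(pmax(cc_res$p_mid, 1e-300)),
        p_fisher = fishers_method(pmax(pb_res$p, 1e-300), pmax(cc_res$p, 1e-300)),
        stringsAsFactors = FALSE
      )
    }
  }
  cells <- do.call(rbind, rows)
  z <- cbind(cells$z_dnm, cells$z_cc)
  fit <- fit_mixture_em(z)
  ranked <- jl_fdr(z, fit, genes = paste(cells$gene, cells$phenotype, sep = "|"),
                   fdr_level = fdr_level)
  m <- match(ranked$gene, paste(cells$gene, cells$phenotype, sep = "|"))
  out <- cells[m, , drop = FALSE]
  out$local_fdr <- ranked$local_fdr
  out$jl_fdr <- ranked$jl_fdr
  out$significant <- ranked$significant
  rownames(out) <- NULL
  list(cells = out, fit = fit)
}

#' Cysteine-altering predicate
#'
#' TRUE when a missense change introduces or removes exactly one cysteine
#' (xor of reference and alternate residues being C), leaving an odd
#' cysteine count in a disulfide-bonded domain.
#'
#' @param aa_ref,aa_alt single-letter amino acids.
#' @export
cysteine_altering <- function(aa_ref, aa_alt) {
  xor(aa_ref == "C", aa_alt == "C")
}

#' Protein-region variant-class enrichment
#'
#' Counts predicate-positive case and control alleles inside each protein
#' region (1-based inclusive residue coordinates) and tests case enrichment
#' with a one-tailed Fisher exact test against the chromosome denominators;
#' the fold is the allele-frequency ratio. A final row pools the region
#' union. Records lacking a protein position are skipped and counted in
#' `attr(, "n_skipped")`.
#'
#' @param case_variants data.frame with `gene`, `protein_pos`, `aa_ref`,
#'   `aa_alt` for missense records.
#' @param ctrl_variants same schema for control carriers (one row per
#'   allele).
#' @param regions data.frame: `gene`, `name`, `start`, `end`.
#' @param case_an,ctrl_an chromosome denominators.
#' @param predicate function of (aa_ref, aa_alt) returning logical; default
#'   [cysteine_altering()].
#' @return data.frame per region (plus `"union"`): counts, `fold`, `p`.
#' @export
region_class_enrichment <- function(case_variants, ctrl_variants, regions,
                                    case_an, ctrl_an,
                                    predicate = cysteine_altering) {
  if (any(regions$start > regions$end)) stop_input("region start > end")
  prep <- function(v) {
    miss <- is.na(v$protein_pos)
    if (any(miss)) warning(sum(miss), " record(s) without protein_pos skipped")
    v <- v[!miss, , drop = FALSE]
    v$positive <- predicate(v$aa_ref, v$aa_alt)
    v
  }
  ca <- prep(case_variants)
  co <- prep(ctrl_variants)
  one_region <- function(gene, start, end, name) {
    in_ca <- ca$gene == gene & ca$protein_pos >= start & ca$protein_pos <= end & ca$positive
    in_co <- co$gene == gene & co$protein_pos >= start & co$protein_pos <= end & co$positive
    f <- fet_burden(sum(in_ca), case_an, sum(in_co), ctrl_an)
    data.frame(region = name, case_pos = sum(in_ca), ctrl_pos = sum(in_co),
               fold = f$enrichment, p = f$p, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
    one_region(regions$gene[i], regions$start[i], regions$end[i], regions$name[i])))
  in_any_ca <- rep(FALSE, nrow(ca)); in_any_co <- rep(FALSE, nrow(co))
  for (i in seq_len(nrow(regions))) {
    in_any_ca <- in_any_ca | (ca$gene == regions$gene[i] &
                              ca$protein_pos >= regions$start[i] & ca$protein_pos <= regions$end[i])
    in_any_co <- in_any_co | (co$gene == regions$gene[i] &
                              co$protein_pos >= regions$start[i] & co$protein_pos <= regions$end[i])
  }
  fu <- fet_burden(sum(in_any_ca & ca$positive), case_an,
                   sum(in_any_co & co$positive), ctrl_an)
  out <- rbind(per, data.frame(region = "union",
                               case_pos = sum(in_any_ca & ca$positive),
                               ctrl_pos = sum(in_any_co & co$positive),
                               fold = fu$enrichment, p = fu$p,
                               stringsAsFactors = FALSE))
  attr(out, "n_skipped") <- sum(is.na(case_variants$protein_pos)) +
    sum(is.na(ctrl_variants$protein_pos))
  out
}
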