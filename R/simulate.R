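#' Configure a synthetic trio cohort
#'
#' Bundles and validates the generator parameters. Defaults are the study
#' conditions the pipeline is designed around: 3,887 trios and 7,668 singleton
#' probands over a 248-gene panel, 60 risk genes, de novo enrichment of 6.1x
#' (damaging missense) and 14.3x (LOF) at risk genes, 78\% transmission of
#' damaging parental alleles at risk genes, and a gnomAD-scale control cohort.
#'
#' @param n_trios,n_singletons,n_controls cohort sizes (controls are diploid
#'   individuals).
#' @param n_genes panel size.
#' @param risk_gene_fraction fraction of panel genes that are true risk genes.
#' @param dnm_enrichment fold-enrichment (>= 1) of de novo rates at risk
#'   genes, applied to damaging classes only; a scalar or a named vector with
#'   entries `"D-mis"` and `"LOF"`.
#' @param transmission_prob probability in [0.5, 1) that a damaging parental
#'   allele at a risk gene is transmitted to the proband.
#' @param carrier_freq per-gene probability that one parent carries a very
#'   rare allele of any class (split across classes by mutability share).
#' @param coverage_fraction_range range (lo, hi) in (0,1] for the per-gene
#'   callable fraction, drawn independently for cases and controls.
#' @param phenotype_concordance probability that a damaging risk-gene carrier
#'   receives the gene's linked cardiac subtype.
#' @param common_site_prob probability a parental/unphased site is a decoy
#'   "not actually rare" site (population MAF above the rarity threshold, so
#'   it is removed by [filter_very_rare()]).
#' @param site_reuse_prob probability a site recurs within the cohort
#'   (modelling recurrent variants); 0 keeps every simulated site unique.
#' @param seed integer seed; one stream drives the whole cohort.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_trios = 3887L, n_singletons = 7668L,
                          n_controls = 133743L, n_genes = 248L,
                          risk_gene_fraction = 60 / 248,
                          dnm_enrichment = c("D-mis" = 6.1, "LOF" = 14.3),
                          transmission_prob = 0.78,
                          carrier_freq = 2e-3,
                          coverage_fraction_range = c(0.9, 1),
                          phenotype_concordance = 0.8,
                          common_site_prob = 0.05,
                          site_reuse_prob = 0,
                          seed = 1L) {
  cfg <- list(
    n_trios = check_count(n_trios, "n_trios"),
    n_singletons = check_count(n_singletons, "n_singletons"),
    n_controls = check_count(n_controls, "n_controls"),
    n_genes = check_count(n_genes, "n_genes", min = 1L),
    risk_gene_fraction = check_prob(risk_gene_fraction, "risk_gene_fraction"),
    dnm_enrichment = dnm_enrichment,
    transmission_prob = check_prob(transmission_prob, "transmission_prob", lo = 0.5),
    carrier_freq = check_prob(carrier_freq, "carrier_freq"),
    coverage_fraction_range = coverage_fraction_range,
    phenotype_concordance = check_prob(phenotype_concordance, "phenotype_concordance"),
    common_site_prob = check_prob(common_site_prob, "common_site_prob"),
    site_reuse_prob = check_prob(site_reuse_prob, "site_reuse_prob"),
    seed = check_count(seed, "seed")
  )
  if (any(dnm_enrichment < 1)) stop_input("dnm_enrichment must be >= 1")
  if (!is.null(names(dnm_enrichment)) &&
      !all(names(dnm_enrichment) %in% DAMAGING_CLASSES))
    stop_input("named dnm_enrichment entries must be among: ",
               paste(DAMAGING_CLASSES, collapse = ", "))
  r <- coverage_fraction_range
  if (length(r) != 2L || any(r <= 0) || any(r > 1) || r[1] > r[2])
    stop_input("coverage_fraction_range must be (lo, hi) within (0, 1]")
  if (transmission_prob >= 1) stop_input("transmission_prob must be < 1")
  class(cfg) <- "cohort_config"
  cfg
}

# Per-class enrichment vector for a risk gene.
enrichment_by_class <- function(dnm_enrichment) {
  e <- setNames(rep(1, length(VARIANT_CLASSES)), VARIANT_CLASSES)
  if (is.null(names(dnm_enrichment))) {
    e[DAMAGING_CLASSES] <- dnm_enrichment[1]
  } else {
    e[names(dnm_enrichment)] <- dnm_enrichment
  }
  e
}

# Ground truth shared by both generator paths. Assumes RNG already seeded.
draw_truth <- function(config, mutability) {
  n <- config$n_genes
  n_risk <- round(config$risk_gene_fraction * n)
  is_risk <- rep(FALSE, n)
  if (n_risk > 0) is_risk[sample.int(n, n_risk)] <- TRUE
  e <- enrichment_by_class(config$dnm_enrichment)
  data.frame(
    gene = mutability$gene,
    is_risk = is_risk,
    enrichment_dmis = ifelse(is_risk, e[["D-mis"]], 1),
    enrichment_lof = ifelse(is_risk, e[["LOF"]], 1),
    transmission_prob = ifelse(is_risk, config$transmission_prob, 0.5),
    linked_subtype = sample(CARDIAC_SUBTYPES[1:7], n, replace = TRUE),
    syndromic = is_risk & runif(n) < 0.5,
    stringsAsFactors = FALSE
  )
}

draw_coverage <- function(config, genes) {
  r <- config$coverage_fraction_range
  data.frame(
    gene = genes,
    callable_fraction_cases = runif(length(genes), r[1], r[2]),
    callable_fraction_controls = runif(length(genes), r[1], r[2]),
    stringsAsFactors = FALSE
  )
}

# Long gene x class scaffold with per-cell rates. Used by both generators.
rate_table <- function(config, mutability, truth, coverage) {
  n <- config$n_genes
  long <- expand.grid(gene_i = seq_len(n), class = VARIANT_CLASSES,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  mu <- as.matrix(mutability[, c("mu_syn", "mu_tmis", "mu_dmis", "mu_lof")])
  colnames(mu) <- VARIANT_CLASSES
  long$gene <- mutability$gene[long$gene_i]
  long$mu <- mu[cbind(long$gene_i, match(long$class, VARIANT_CLASSES))]
  long$share <- long$mu / rowSums(mu)[long$gene_i]
  enr <- cbind(1, 1, truth$enrichment_dmis, truth$enrichment_lof)
  colnames(enr) <- VARIANT_CLASSES
  long$e <- enr[cbind(long$gene_i, match(long$class, VARIANT_CLASSES))]
  long$tau <- ifelse(long$class %in% DAMAGING_CLASSES,
                     truth$transmission_prob[long$gene_i], 0.5)
  long$cf_case <- coverage$callable_fraction_cases[long$gene_i]
  long$cf_ctrl <- coverage$callable_fraction_controls[long$gene_i]
  long
}

#' Simulate per-gene, per-class counts directly
#'
#' Fast count-level counterpart of [simulate_cohort()]: draws the same
#' distributions at the gene x class aggregate level without materialising
#' individual variant records. DNM counts are Poisson with mean
#' `n_trios * mu_gc * e_gc`; parental informative alleles are binomial with
#' per-parent rate `carrier_freq * share_c`, transmitted with probability
#' `transmission_prob` at risk genes (damaging classes) and 1/2 otherwise;
#' control allele counts are binomial at the matched population frequency
#' over coverage-adjusted chromosome counts.
#'
#' @param config a [cohort_config()].
#' @param mutability a mutability table covering `n_genes` (default: sampled
#'   from the config seed).
#' @return list with `counts` (gene x class: `n_dnm`, `case_ac`, `case_an`,
#'   `T`, `U`, `n_unphased`), `controls`, `coverage`, `truth`, `mutability`.
#' @export
simulate_class_counts <- function(config, mutability = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(mutability)) mutability <- sample_mutabilities(config$n_genes, seed = config$seed)
  if (nrow(mutability) != config$n_genes)
    stop_input("mutability has ", nrow(mutability), " genes; config expects ", config$n_genes)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  truth <- draw_truth(config, mutability)
  coverage <- draw_coverage(config, mutability$gene)
  rt <- rate_table(config, mutability, truth, coverage)
  keep_rare <- 1 - config$common_site_prob

  n_cells <- nrow(rt)
  n_dnm <- rpois(n_cells, config$n_trios * rt$mu * rt$e)
  H <- rbinom(n_cells, 2L * config$n_trios,
              pmin(1, config$carrier_freq * rt$share * rt$cf_case * keep_rare))
  T_ <- rbinom(n_cells, H, rt$tau)
  U_ <- H - T_
  n_unph <- rbinom(n_cells, config$n_singletons,
                   pmin(1, 2 * config$carrier_freq * rt$share * rt$tau * rt$cf_case * keep_rare))
  case_an <- pmax(1L, round(2 * (config$n_trios + config$n_singletons) * rt$cf_case))
  ctrl_an <- pmax(1L, round(2 * config$n_controls * rt$cf_ctrl))
  ctrl_ac <- rbinom(n_cells, ctrl_an,
                    pmin(1, config$carrier_freq * rt$share * keep_rare / 2))

  counts <- data.frame(gene = rt$gene, class = rt$class, n_dnm = n_dnm,
                       case_ac = T_ + n_unph, case_an = case_an,
                       T = T_, U = U_, n_unphased = n_unph,
                       stringsAsFactors = FALSE)
  controls <- data.frame(gene = rt$gene, class = rt$class,
                         ctrl_ac = ctrl_ac, ctrl_an = ctrl_an,
                         stringsAsFactors = FALSE)
  list(counts = counts, controls = controls, coverage = coverage,
       truth = truth, mutability = mutability)
}

#' Simulate a trio/singleton cohort with known ground truth
#'
#' Generates individual variant records, a 6-column pedigree, per-proband
#' phenotypes, matched control allele counts, and the ground-truth table of
#' risk genes and effect parameters. All randomness derives from a single
#' stream keyed by `config$seed`, so identical configs give byte-identical
#' cohorts.
#'
#' Statistical structure: DNM counts per gene x class are Poisson with mean
#' `n_trios * mu_gc * e_gc` (enrichment only at risk genes, damaging
#' classes); each parental heterozygous very-rare allele is transmitted with
#' probability 1/2 (non-risk) or `transmission_prob` (risk gene, damaging
#' class); singleton probands carry unphased alleles at the induced
#' frequency; control allele counts are drawn at the matching population
#' frequency over coverage-adjusted chromosome counts. Each simulated site is
#' unique unless `site_reuse_prob > 0`; a `common_site_prob` fraction of
#' inherited sites carry a population MAF above the rarity threshold and are
#' there to be removed by [filter_very_rare()].
#'
#' @inheritParams simulate_class_counts
#' @return A `simulated_cohort` list: `variants`, `pedigree`, `phenotypes`,
#'   `truth`, `controls`, `coverage`, `mutability`, `config`.
#' @export
simulate_cohort <- function(config, mutability = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(mutability)) mutability <- sample_mutabilities(config$n_genes, seed = config$seed)
  if (nrow(mutability) != config$n_genes)
    stop_input("mutability has ", nrow(mutability), " genes; config expects ", config$n_genes)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  truth <- draw_truth(config, mutability)
  coverage <- draw_coverage(config, mutability$gene)
  rt <- rate_table(config, mutability, truth, coverage)

  n_trios <- config$n_trios
  n_single <- config$n_singletons
  n_probands <- n_trios + n_single
  trio_fid <- sprintf("T%05d", seq_len(n_trios))
  single_fid <- sprintf("S%05d", seq_len(n_single))
  trio_pb <- sprintf("%s-01", trio_fid)
  single_pb <- sprintf("%s-01", single_fid)

  pedigree <- rbind(
    data.frame(family_id = trio_fid, sample_id = trio_pb,
               father_id = sprintf("%s-02", trio_fid), mother_id = sprintf("%s-03", trio_fid),
               sex = sample(1:2, n_trios, TRUE),
               phenotype = rep(2L, n_trios), stringsAsFactors = FALSE),
    data.frame(family_id = rep(trio_fid, 2L),
               sample_id = c(sprintf("%s-02", trio_fid), sprintf("%s-03", trio_fid)),
               father_id = rep("0", 2L * n_trios), mother_id = rep("0", 2L * n_trios),
               sex = rep(1:2, each = n_trios),
               phenotype = rep(1L, 2L * n_trios), stringsAsFactors = FALSE),
    data.frame(family_id = single_fid, sample_id = single_pb,
               father_id = rep("0", n_single), mother_id = rep("0", n_single),
               sex = sample(1:2, n_single, TRUE),
               phenotype = rep(2L, n_single), stringsAsFactors = FALSE)
  )

  n_cells <- nrow(rt)
  keep_rare <- 1 - config$common_site_prob

  # --- de novo records (trio probands only; not coverage-thinned) ---
  n_dnm <- rpois(n_cells, n_trios * rt$mu * rt$e)
  dnm_cell <- rep(seq_len(n_cells), n_dnm)
  dnm <- data.frame(
    cell = dnm_cell,
    origin = rep("de_novo", length(dnm_cell)),
    fam = sample(seq_len(max(n_trios, 1L)), length(dnm_cell), TRUE),
    stringsAsFactors = FALSE
  )
  dnm$sample_id <- trio_pb[dnm$fam]
  dnm$family_id <- trio_fid[dnm$fam]
  dnm$common <- rep(FALSE, nrow(dnm))

  # --- parental carrier alleles in trios ---
  H <- rbinom(n_cells, 2L * n_trios,
              pmin(1, config$carrier_freq * rt$share * rt$cf_case))
  par_cell <- rep(seq_len(n_cells), H)
  transmitted <- runif(length(par_cell)) < rt$tau[par_cell]
  par_fam <- sample(seq_len(max(n_trios, 1L)), length(par_cell), TRUE)
  par_is_father <- runif(length(par_cell)) < 0.5
  par <- data.frame(
    cell = par_cell,
    origin = ifelse(transmitted, "transmitted", "untransmitted_parental"),
    fam = par_fam, stringsAsFactors = FALSE
  )
  par$sample_id <- ifelse(transmitted, trio_pb[par_fam],
                          sprintf("%s%s", trio_fid[par_fam],
                                  ifelse(par_is_father, "-02", "-03")))
  par$family_id <- trio_fid[par_fam]
  par$common <- runif(length(par_cell)) < config$common_site_prob

  # --- unphased alleles in singleton probands ---
  n_unph <- rbinom(n_cells, n_single,
                   pmin(1, 2 * config$carrier_freq * rt$share * rt$tau * rt$cf_case))
  unph_cell <- rep(seq_len(n_cells), n_unph)
  unph_fam <- sample(seq_len(max(n_single, 1L)), length(unph_cell), TRUE)
  unph <- data.frame(
    cell = unph_cell, origin = rep("unphased", length(unph_cell)),
    fam = unph_fam, stringsAsFactors = FALSE
  )
  unph$sample_id <- single_pb[unph_fam]
  unph$family_id <- single_fid[unph_fam]
  unph$common <- runif(length(unph_cell)) < config$common_site_prob

  rec <- rbind(dnm[, c("cell", "origin", "sample_id", "family_id", "common")],
               par[, c("cell", "origin", "sample_id", "family_id", "common")],
               unph[, c("cell", "origin", "sample_id", "family_id", "common")])
  nrec <- nrow(rec)

  gene_i <- rt$gene_i[rec$cell]
  gene_start <- mutability$start[gene_i]
  gene_len <- mutability$end[gene_i] - gene_start
  rec$gene <- rt$gene[rec$cell]
  rec$chrom <- mutability$chrom[gene_i]
  offset <- floor(runif(nrec) * gene_len)
  rec$pos <- pos0_to_1(gene_start + offset)
  # optional site recurrence: reuse the first site drawn in the same gene
  if (config$site_reuse_prob > 0 && nrec > 1L) {
    reuse <- runif(nrec) < config$site_reuse_prob
    first_in_gene <- match(rec$gene, rec$gene)
    reuse[first_in_gene == seq_len(nrec)] <- FALSE
    rec$pos[reuse] <- rec$pos[first_in_gene[reuse]]
  }
  bases <- c("A", "C", "G", "T")
  rec$ref <- bases[sample.int(4L, nrec, TRUE)]
  alt_shift <- sample.int(3L, nrec, TRUE)
  rec$alt <- bases[(match(rec$ref, bases) - 1L + alt_shift) %% 4L + 1L]

  cls <- rt$class[rec$cell]
  rec$consequence <- ifelse(cls == "synonymous", "synonymous",
                     ifelse(cls %in% c("T-mis", "D-mis"), "missense",
                            sample(c("stopgain", "frameshift", "canonical-splice"), nrec, TRUE)))
  rec$metasvm <- ifelse(cls == "D-mis", "D", ifelse(cls == "T-mis", "T", NA_character_))

  rec$maf_bravo <- ifelse(rec$common, runif(nrec, 2e-5, 1e-3), 0)
  rec$maf_esp <- ifelse(rec$common, rec$maf_bravo * runif(nrec, 0.5, 1.5), 0)
  rec$maf_gnomad <- ifelse(rec$common, rec$maf_bravo * runif(nrec, 0.5, 1.5), 0)

  site_key <- paste(rec$gene, rec$pos, rec$ref, rec$alt, sep = ":")
  rec$cohort_ac <- as.integer(ave(rep(1L, nrec), site_key, FUN = sum))
  rec$cohort_an <- 2L * n_probands

  is_mis <- rec$consequence == "missense"
  rec$protein_pos <- ifelse(is_mis, pmax(1L, ceiling((offset + 1L) / 3)), NA_integer_)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rec$aa_ref <- ifelse(is_mis, aa[sample.int(20L, nrec, TRUE)], NA_character_)
  aa_alt <- aa[sample.int(20L, nrec, TRUE)]
  same <- !is.na(rec$aa_ref) & aa_alt == rec$aa_ref
  aa_alt[same] <- aa[(match(rec$aa_ref[same], aa) %% 20L) + 1L]
  rec$aa_alt <- ifelse(is_mis, aa_alt, NA_character_)

  variants <- rec[, c("chrom", "pos", "ref", "alt", "gene", "consequence", "metasvm",
                      "maf_bravo", "maf_esp", "maf_gnomad", "cohort_ac", "cohort_an",
                      "origin", "sample_id", "family_id", "protein_pos", "aa_ref", "aa_alt")]
  rownames(variants) <- NULL

  # --- phenotypes: risk carriers pull their gene's linked subtype ---
  risk_damaging <- rec$gene %in% truth$gene[truth$is_risk] &
    cls %in% DAMAGING_CLASSES & rec$origin != "untransmitted_parental" & !rec$common
  carrier_gene <- tapply(rec$gene[risk_damaging], rec$sample_id[risk_damaging],
                         function(g) g[1])
  all_pb <- c(trio_pb, single_pb)
  baseline_w <- c(CTD = 0.20, TOF = 0.10, LVO = 0.20, HLHS = 0.10,
                  ASD = 0.15, AVC = 0.08, LAT = 0.07, other = 0.10)
  subtype <- sample(names(baseline_w), n_probands, TRUE, prob = baseline_w)
  names(subtype) <- all_pb
  hit <- intersect(names(carrier_gene), all_pb)
  if (length(hit)) {
    linked <- truth$linked_subtype[match(carrier_gene[hit], truth$gene)]
    use_linked <- runif(length(hit)) < config$phenotype_concordance
    subtype[hit[use_linked]] <- linked[use_linked]
  }
  p_ec <- rep(0.30, n_probands)
  p_ndd <- rep(0.20, n_probands)
  names(p_ec) <- names(p_ndd) <- all_pb
  syn_carrier <- hit[truth$syndromic[match(carrier_gene[hit], truth$gene)]]
  p_ec[syn_carrier] <- 0.6
  p_ndd[syn_carrier] <- 0.6
  phenotypes <- data.frame(
    proband_id = all_pb,
    cardiac_subtype = unname(subtype),
    ec = runif(n_probands) < p_ec,
    ndd = runif(n_probands) < p_ndd,
    stringsAsFactors = FALSE
  )

  # --- control allele counts at the matched non-risk frequency ---
  ctrl_an <- pmax(1L, round(2 * config$n_controls * rt$cf_ctrl))
  ctrl_ac <- rbinom(n_cells, ctrl_an,
                    pmin(1, config$carrier_freq * rt$share * keep_rare / 2))
  controls <- data.frame(gene = rt$gene, class = rt$class,
                         ctrl_ac = ctrl_ac, ctrl_an = ctrl_an,
                         stringsAsFactors = FALSE)

  out <- list(variants = variants, pedigree = pedigree, phenotypes = phenotypes,
              truth = truth, controls = controls, coverage = coverage,
              mutability = mutability, config = config)
  class(out) <- "simulated_cohort"
  out
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated cohort:", x$config$n_trios, "trios,", x$config$n_singletons,
      "singletons,", x$config$n_genes, "genes (",
      sum(x$truth$is_risk), "risk ),", nrow(x$variants), "variant records\n")
  invisible(x)
}
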