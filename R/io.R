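VARIANT_COLUMNS <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "metasvm",
                     "maf_bravo", "maf_esp", "maf_gnomad", "cohort_ac", "cohort_an",
                     "origin", "sample_id", "family_id", "protein_pos", "aa_ref", "aa_alt")

#' Read an annotated variant table
#'
#' Reads the pipeline's tab-separated variant schema (or a VCF whose INFO
#' field carries the annotation keys), enforcing one alternate allele per
#' row and `cohort_ac <= cohort_an` per record. Errors name the offending
#' column or line.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"vcf"`; `"auto"` picks by extension.
#' @return data.frame of variant records.
#' @export
read_variants <- function(path, dialect = c("auto", "tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("no such file: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  v <- if (dialect == "vcf") read_variants_vcf(path) else {
    d <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(metasvm = "character", aa_ref = "character",
                                   aa_alt = "character"))
    missing <- setdiff(VARIANT_COLUMNS, names(d))
    if (length(missing)) stop_input("missing column(s): ", paste(missing, collapse = ", "))
    d <- d[, VARIANT_COLUMNS]
    # all-NA columns come back logical from read.delim; pin the schema types
    for (col in c("pos", "cohort_ac", "cohort_an", "protein_pos"))
      d[[col]] <- as.integer(d[[col]])
    for (col in c("maf_bravo", "maf_esp", "maf_gnomad"))
      d[[col]] <- as.numeric(d[[col]])
    d
  }
  multi <- grepl(",", v$alt, fixed = TRUE)
  if (any(multi))
    stop_input("multi-allelic row(s) must be pre-split (first at line ", which(multi)[1], ")")
  bad <- v$cohort_ac > v$cohort_an
  if (any(bad))
    stop_input("cohort_ac > cohort_an at line ", which(bad)[1])
  if (any(v$pos < 1)) stop_input("pos must be >= 1")
  v
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_get <- function(key) vcfR::extract.info(vcf, element = key)
  num <- function(x) suppressWarnings(as.numeric(x))
  int <- function(x) suppressWarnings(as.integer(x))
  chr_or_na <- function(x) ifelse(x == "." | x == "", NA_character_, x)
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    gene = info_get("GENE"), consequence = info_get("CSQ"),
    metasvm = chr_or_na(info_get("METASVM")),
    maf_bravo = num(info_get("MAF_BRAVO")), maf_esp = num(info_get("MAF_ESP")),
    maf_gnomad = num(info_get("MAF_GNOMAD")),
    cohort_ac = int(info_get("COHORT_AC")), cohort_an = int(info_get("COHORT_AN")),
    origin = info_get("ORIGIN"), sample_id = info_get("SAMPLE_ID"),
    family_id = info_get("FAMILY_ID"),
    protein_pos = int(info_get("PROTEIN_POS")),
    aa_ref = chr_or_na(info_get("AA_REF")), aa_alt = chr_or_na(info_get("AA_ALT")),
    stringsAsFactors = FALSE
  )
}

#' Read a 6-column PED file and classify families
#'
#' Families whose proband has both parents present are trios; probands with
#' one listed parent (duos) are treated as singletons with a warning; a
#' non-zero parent identifier with no corresponding row is a structural
#' error.
#'
#' @param path PED file path (no header: family, individual, father, mother,
#'   sex, phenotype).
#' @return list: `ped` (the table), `trios` (family/proband/father/mother),
#'   `singletons` (proband ids), `n_trios`, `n_singletons`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  ped <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(ped) != 6L) stop_input("PED file must have exactly 6 columns")
  names(ped) <- c("family_id", "sample_id", "father_id", "mother_id", "sex", "phenotype")
  probands <- ped[ped$phenotype == "2", , drop = FALSE]
  has_f <- probands$father_id != "0"
  has_m <- probands$mother_id != "0"
  ref_missing <- (has_f & !(probands$father_id %in% ped$sample_id)) |
    (has_m & !(probands$mother_id %in% ped$sample_id))
  if (any(ref_missing))
    stop_input("proband ", probands$sample_id[ref_missing][1],
               " references a parent absent from the file")
  is_trio <- has_f & has_m
  is_duo <- xor(has_f, has_m)
  if (any(is_duo))
    warning(sum(is_duo), " duo proband(s) treated as singletons (unphased variants only)")
  list(
    ped = ped,
    trios = data.frame(family_id = probands$family_id[is_trio],
                       proband = probands$sample_id[is_trio],
                       father = probands$father_id[is_trio],
                       mother = probands$mother_id[is_trio],
                       stringsAsFactors = FALSE),
    singletons = probands$sample_id[!is_trio],
    n_trios = sum(is_trio),
    n_singletons = sum(!is_trio)
  )
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits `variants.tsv`, `cohort.ped` (6-column, headerless), `phenotypes.tsv`,
#' `truth.tsv`, `controls.tsv`, `mutability.tsv`, `coverage.tsv`; all
#' re-readable by the package's readers.
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  write.table(cohort$pedigree, file.path(dir, "cohort.ped"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  write_tsv(cohort$controls, file.path(dir, "controls.tsv"))
  write_tsv(cohort$mutability, file.path(dir, "mutability.tsv"))
  write_tsv(cohort$coverage, file.path(dir, "coverage.tsv"))
  invisible(dir)
}

#' Load a run configuration from YAML
#'
#' The YAML maps input paths (`variants`, `pedigree`, `phenotypes`,
#' `controls`, `mutability`, `coverage`) and optional thresholds
#' (`max_pop_maf`, `max_cohort_maf`, `fdr_level`, `genomewide_alpha`,
#' `seed`). All referenced files must exist.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(max_pop_maf = 1e-5, max_cohort_maf = 1.3e-4,
                   fdr_level = 0.05, genomewide_alpha = 2.6e-6, seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("variants", "pedigree", "phenotypes", "controls", "mutability")) {
    if (is.null(cfg[[k]])) stop_input("config is missing required path: ", k)
    if (!file.exists(cfg[[k]])) stop_input("config path does not exist: ", cfg[[k]])
  }
  class(cfg) <- "run_config"
  cfg
}

load_cohort_dir <- function(cfg) {
  ped <- read_pedigree(cfg$pedigree)
  list(
    variants = read_variants(cfg$variants),
    pedigree = ped$ped,
    n_trios = ped$n_trios,
    n_singletons = ped$n_singletons,
    phenotypes = read.delim(cfg$phenotypes, stringsAsFactors = FALSE),
    controls = read.delim(cfg$controls, stringsAsFactors = FALSE),
    mutability = read.delim(cfg$mutability, stringsAsFactors = FALSE),
    coverage = if (!is.null(cfg$coverage)) read.delim(cfg$coverage, stringsAsFactors = FALSE)
  )
}

#' Run the full discovery pipeline
#'
#' Executes filter, aggregation, per-gene damaging DNM burden, case-control
#' burden, Fisher/JL-FDR meta-analysis, TDT, and (when at least two genes
#' reach significance) the phenotype-subgroup meta-analysis; writes every
#' stage's table as TSV plus a JSON summary. Outputs carry no timestamps,
#' so identical inputs and seeds give byte-identical files (the `run.log`
#' is the only timestamped artifact).
#'
#' @param x a `simulated_cohort`, a `run_config`, or a YAML config path.
#' @param out_dir output directory.
#' @param fdr_level FDR significance level (default 0.05).
#' @param thresholds rarity thresholds, see [filter_thresholds()].
#' @return invisibly, a list with all stage tables and the summary.
#' @export
run_pipeline <- function(x, out_dir, fdr_level = 0.05,
                         thresholds = filter_thresholds()) {
  if (is.character(x)) x <- read_run_config(x)
  if (inherits(x, "run_config")) {
    thresholds <- filter_thresholds(x$max_pop_maf, x$max_cohort_maf)
    fdr_level <- x$fdr_level
    x <- load_cohort_dir(x)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...,
                                "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  stage <- function(name, expr) {
    log_line("stage ", name, " start")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ped <- x$pedigree
  if (is.null(x$n_trios)) {
    pb <- ped[ped$phenotype == 2L, , drop = FALSE]
    x$n_trios <- sum(pb$father_id != "0" & pb$mother_id != "0")
    x$n_singletons <- nrow(pb) - x$n_trios
  }
  n_trios <- x$n_trios
  n_probands <- n_trios + x$n_singletons
  mut <- x$mutability
  log_line("thresholds: max_pop_maf=", thresholds$max_pop_maf,
           " max_cohort_maf=", thresholds$max_cohort_maf, " fdr_level=", fdr_level)

  filtered <- stage("filter", filter_very_rare(x$variants, thresholds))
  counts <- stage("aggregate",
                  aggregate_counts(filtered, mut, phenotypes = x$phenotypes))

  cf_case <- if (!is.null(x$coverage))
    x$coverage$callable_fraction_cases[match(mut$gene, x$coverage$gene)]
  else rep(1, nrow(mut))

  mu_d <- damaging_mu(mut)
  dnm_by_gene <- rowsum(counts$n_dnm[counts$class %in% DAMAGING_CLASSES],
                        counts$gene[counts$class %in% DAMAGING_CLASSES])
  dnm_tab <- stage("burden-dnm", do.call(rbind, lapply(mut$gene, function(g)
    poisson_burden(dnm_by_gene[g, 1], n_trios, mu_d[[g]],
                   unit = g, class = "damaging"))))

  ctrl <- x$controls
  cc_tab <- stage("burden-cc", {
    ac_by_gene <- rowsum(counts$case_ac[counts$class %in% DAMAGING_CLASSES],
                         counts$gene[counts$class %in% DAMAGING_CLASSES])
    ctrl_ac <- rowsum(ctrl$ctrl_ac[ctrl$class %in% DAMAGING_CLASSES],
                      ctrl$gene[ctrl$class %in% DAMAGING_CLASSES])
    ctrl_an <- ctrl$ctrl_an[match(mut$gene, ctrl$gene)]
    do.call(rbind, lapply(seq_along(mut$gene), function(i) {
      g <- mut$gene[i]
      fet_burden(ac_by_gene[g, 1],
                 coverage_adjust(2L * n_probands, cf_case[i]),
                 ctrl_ac[g, 1], ctrl_an[i], unit = g, class = "damaging")
    }))
  })

  meta <- stage("meta", meta_analysis(dnm_tab, cc_tab, fdr_level = fdr_level))
  sig_genes <- meta$meta$gene[meta$meta$significant]

  tdt_tab <- stage("tdt", {
    per_gene <- do.call(rbind, lapply(mut$gene, function(g) {
      sel <- counts$gene == g & counts$class %in% DAMAGING_CLASSES
      T_ <- sum(counts$T[sel]); U_ <- sum(counts$U[sel])
      if (T_ + U_ == 0L) {
        data.frame(unit = g, class = "damaging", T = 0L, U = 0L, chi2 = 0,
                   p = 1, transmitted_fraction = NA_real_, grr = NA_real_,
                   attributable_fraction = 0, stringsAsFactors = FALSE)
      } else tdt_test(T_, U_, unit = g, class = "damaging")
    }))
    per_gene
  })
  safe_geneset_tdt <- function(genes) {
    sel <- counts$gene %in% genes & counts$class %in% DAMAGING_CLASSES
    if (sum(counts$T[sel]) + sum(counts$U[sel]) == 0L) return(NULL)
    geneset_tdt(counts, genes, "damaging", n_trios)
  }
  tdt_panel <- safe_geneset_tdt(mut$gene)
  tdt_sig <- if (length(sig_genes)) safe_geneset_tdt(sig_genes) else NULL

  syn_p <- vapply(mut$gene, function(g)
    poisson_burden(counts$n_dnm[counts$gene == g & counts$class == "synonymous"][1],
                   n_trios, mut$mu_syn[match(g, mut$gene)])$p, numeric(1))
  qq <- qq_summary(syn_p, n_samples = n_probands)

  assoc <- NULL
  if (length(sig_genes) >= 2L && !is.null(x$phenotypes) && !is.null(x$variants)) {
    cohort_like <- list(variants = x$variants, pedigree = ped,
                        phenotypes = x$phenotypes, controls = ctrl,
                        mutability = mut, config = x$config)
    assoc <- stage("assoc", subgroup_meta(cohort_like, sig_genes, fdr_level = fdr_level))
  }

  af_dnm <- if (length(sig_genes)) {
    b <- geneset_burden(counts, mut, sig_genes, "damaging", n_trios)
    attributable_fraction_dnm(b$observed, b$expected, n_probands)
  } else 0
  af_tdt <- if (!is.null(tdt_sig)) tdt_sig$attributable_fraction * n_trios / n_probands else 0
  af_combined <- 1 - (1 - af_dnm) * (1 - af_tdt)

  summary <- list(
    n_trios = n_trios, n_singletons = x$n_singletons,
    n_genes = nrow(mut), fdr_level = fdr_level,
    n_significant = length(sig_genes), significant_genes = sig_genes,
    pi0 = meta$fit$pi0,
    predicted_risk_genes = predicted_risk_genes(meta$fit, nrow(mut)),
    lambda_1000_synonymous = attr(qq, "lambda_1000"),
    attributable_fraction_dnm = af_dnm,
    attributable_fraction_transmitted = af_tdt,
    attributable_fraction_combined = af_combined
  )

  write_tsv(filtered, file.path(out_dir, "filtered_variants.tsv"))
  write_tsv(counts, file.path(out_dir, "class_counts.tsv"))
  write_tsv(dnm_tab, file.path(out_dir, "burden_dnm.tsv"))
  write_tsv(cc_tab, file.path(out_dir, "burden_cc.tsv"))
  write_tsv(meta$meta, file.path(out_dir, "meta.tsv"))
  write_tsv(tdt_tab, file.path(out_dir, "tdt.tsv"))
  write_tsv(qq, file.path(out_dir, "qq_synonymous.tsv"))
  if (!is.null(assoc)) write_tsv(assoc$cells, file.path(out_dir, "subgroup_assoc.tsv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done")

  invisible(list(filtered = filtered, counts = counts, dnm = dnm_tab, cc = cc_tab,
                 meta = meta, tdt = tdt_tab, tdt_panel = tdt_panel,
                 assoc = assoc, qq = qq, summary = summary))
}
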