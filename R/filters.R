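#' Classify variants into functional classes
#'
#' Maps annotated consequence + metapredictor call to the analysis classes:
#' LOF (stopgain, frameshift, canonical-splice), D-mis (missense predicted
#' damaging), T-mis (missense predicted tolerated or unscored), synonymous,
#' and other (inframe indels and everything else declared).
#'
#' @param consequence character vector from \{synonymous, missense, stopgain,
#'   frameshift, canonical-splice, inframe-indel, other\}.
#' @param metasvm character vector of metapredictor calls ("D", "T", or NA);
#'   only consulted for missense.
#' @return character vector over \{LOF, D-mis, T-mis, synonymous, other\}.
#' @examples
#' classify_variants(c("stopgain", "missense"), c(NA, "D"))
#' @export
classify_variants <- function(consequence, metasvm = rep(NA_character_, length(consequence))) {
  known <- c("synonymous", "missense", "stopgain", "frameshift",
             "canonical-splice", "inframe-indel", "other")
  bad <- setdiff(unique(consequence), known)
  if (length(bad))
    stop_input("unknown consequence value(s): ", paste(bad, collapse = ", "))
  out <- rep("other", length(consequence))
  out[consequence == "synonymous"] <- "synonymous"
  out[consequence %in% c("stopgain", "frameshift", "canonical-splice")] <- "LOF"
  mis <- consequence == "missense"
  out[mis] <- ifelse(!is.na(metasvm[mis]) & metasvm[mis] == "D", "D-mis", "T-mis")
  out
}

#' Rarity thresholds for very rare variants
#'
#' @param max_pop_maf maximum population MAF in each reference database
#'   (default 1e-5).
#' @param max_cohort_maf maximum within-cohort MAF (default 1.3e-4).
#' @export
filter_thresholds <- function(max_pop_maf = 1e-5, max_cohort_maf = 1.3e-4) {
  list(max_pop_maf = check_prob(max_pop_maf, "max_pop_maf", lo = 1e-300, hi = 1 - 1e-12),
       max_cohort_maf = check_prob(max_cohort_maf, "max_cohort_maf", lo = 1e-300, hi = 1 - 1e-12))
}

#' Keep only very rare variants
#'
#' Retains records whose population MAF is at or below `max_pop_maf` in both
#' the BRAVO and ESP columns and whose within-cohort MAF
#' (`cohort_ac / cohort_an`) is at or below `max_cohort_maf`. Missing
#' population frequencies are treated as 0 (absent from the database).
#' Input order is preserved; filtering is idempotent.
#'
#' @param records variant data.frame (see [read_variants()] for the schema).
#' @param thresholds a [filter_thresholds()] list.
#' @return The retained rows of `records`.
#' @export
filter_very_rare <- function(records, thresholds = filter_thresholds()) {
  if (nrow(records) == 0L) return(records)
  if (any(records$cohort_an == 0))
    stop_input("cohort_an is 0 for ", sum(records$cohort_an == 0), " record(s)")
  bravo <- ifelse(is.na(records$maf_bravo), 0, records$maf_bravo)
  esp <- ifelse(is.na(records$maf_esp), 0, records$maf_esp)
  keep <- bravo <= thresholds$max_pop_maf &
    esp <= thresholds$max_pop_maf &
    records$cohort_ac / records$cohort_an <= thresholds$max_cohort_maf
  records[keep, , drop = FALSE]
}

#' Harmonize case and control capture territory
#'
#' Intersects the case and control capture intervals (0-based half-open, BED
#' convention), drops variant records falling outside the shared territory,
#' and computes per-gene callable fractions over the shared intervals
#' relative to each platform's own footprint.
#'
#' @param case_intervals,control_intervals data.frames with columns `chrom`,
#'   `start`, `end`, `gene`.
#' @param records variant data.frame with 1-based `pos`.
#' @return list with `coverage` (per gene: `callable_fraction_cases`,
#'   `callable_fraction_controls`) carrying the shared intervals in
#'   `attr(, "shared_intervals")`, and `records` (retained rows).
#' @export
harmonize_territory <- function(case_intervals, control_intervals, records) {
  for (iv in list(case_intervals, control_intervals)) {
    if (any(iv$end <= iv$start))
      stop_input("malformed interval (end <= start) in interval set")
  }
  key <- function(iv) paste(iv$chrom, iv$gene)
  shared <- NULL
  genes <- union(key(case_intervals), key(control_intervals))
  cov <- lapply(genes, function(k) {
    ca <- case_intervals[key(case_intervals) == k, , drop = FALSE]
    co <- control_intervals[key(control_intervals) == k, , drop = FALSE]
    if (nrow(ca) == 0L || nrow(co) == 0L) {
      inter <- IRanges::IRanges()
    } else {
      inter <- IRanges::intersect(
        IRanges::IRanges(start = ca$start + 1L, end = ca$end),
        IRanges::IRanges(start = co$start + 1L, end = co$end)
      )
    }
    gene <- sub("^\\S+ ", "", k)
    chrom <- sub(" .*$", "", k)
    shared_df <- if (length(inter) == 0L) {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 gene = character(), stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = chrom, start = IRanges::start(inter) - 1L,
                 end = IRanges::end(inter), gene = gene, stringsAsFactors = FALSE)
    }
    w_shared <- sum(IRanges::width(inter))
    w_case <- sum(pmax(0L, ca$end - ca$start))
    w_ctrl <- sum(pmax(0L, co$end - co$start))
    list(cov = data.frame(
      gene = gene,
      callable_fraction_cases = if (w_case > 0) w_shared / w_case else 0,
      callable_fraction_controls = if (w_ctrl > 0) w_shared / w_ctrl else 0,
      stringsAsFactors = FALSE
    ), shared = shared_df)
  })
  coverage <- do.call(rbind, lapply(cov, `[[`, "cov"))
  shared <- do.call(rbind, lapply(cov, `[[`, "shared"))
  rownames(coverage) <- rownames(shared) <- NULL
  attr(coverage, "shared_intervals") <- shared

  if (nrow(records) > 0L) {
    inside <- vapply(seq_len(nrow(records)), function(i) {
      s <- shared[shared$chrom == records$chrom[i] & shared$gene == records$gene[i], , drop = FALSE]
      any(records$pos[i] > s$start & records$pos[i] <= s$end)
    }, logical(1))
    records <- records[inside, , drop = FALSE]
  }
  list(coverage = coverage, records = records)
}

#' Aggregate filtered records into per-gene, per-class counts
#'
#' Collapses duplicate observations of the same variant in the same
#' individual to one allele, then tallies per gene x functional class (and
#' optionally x cardiac subtype): de novo count, case TUV allele count
#' (transmitted + unphased alleles carried by probands), transmitted (T) and
#' untransmitted (U) parental alleles, and the unphased count. Records whose
#' gene is absent from the panel are skipped with a warning and reported in
#' `attr(, "rejects")`.
#'
#' @param records filtered, classified variant data.frame.
#' @param panel a table with a `gene` column (e.g. a mutability table).
#' @param phenotypes optional phenotype table (`proband_id`,
#'   `cardiac_subtype`, `ec`, `ndd`); when supplied, `case_an` is set to
#'   2 x number of probands and `by_phenotype = TRUE` splits counts by
#'   subtype.
#' @param by_phenotype also stratify counts by cardiac subtype.
#' @return data.frame of class counts; every panel gene x class appears even
#'   when all its counts are zero (unstratified mode).
#' @export
aggregate_counts <- function(records, panel, phenotypes = NULL, by_phenotype = FALSE) {
  if (by_phenotype && is.null(phenotypes))
    stop_input("by_phenotype = TRUE requires a phenotype table")
  in_panel <- records$gene %in% panel$gene
  rejects <- records[!in_panel, , drop = FALSE]
  if (nrow(rejects) > 0L) {
    rejects$reason <- "gene_not_in_panel"
    warning(nrow(rejects), " record(s) in genes outside the panel were skipped")
  }
  records <- records[in_panel, , drop = FALSE]

  # one allele per variant per individual
  dk <- paste(records$gene, records$chrom, records$pos, records$ref,
              records$alt, records$sample_id, sep = ":")
  records <- records[!duplicated(dk), , drop = FALSE]

  cls <- classify_variants(records$consequence, records$metasvm)
  keys <- data.frame(gene = records$gene, class = cls, stringsAsFactors = FALSE)
  if (by_phenotype) {
    sub <- phenotypes$cardiac_subtype[match(records$sample_id, phenotypes$proband_id)]
    # untransmitted parental alleles count toward the proband of their family
    fam_pb <- paste0(records$family_id, "-01")
    sub[is.na(sub)] <- phenotypes$cardiac_subtype[match(
      fam_pb[is.na(sub)], phenotypes$proband_id)]
    keys$subtype <- sub
  }

  if (nrow(keys) == 0L) {
    out <- data.frame(gene = character(), class = character(),
                      stringsAsFactors = FALSE)
    if (by_phenotype) out$subtype <- character()
    out$n_dnm <- out$case_ac <- out$T <- out$U <- out$n_unphased <- integer()
  } else {
    grp <- do.call(paste, c(keys, sep = "\r"))
    flags <- cbind(
      n_dnm = as.integer(records$origin == "de_novo"),
      case_ac = as.integer(records$origin %in% c("transmitted", "unphased")),
      T = as.integer(records$origin == "transmitted"),
      U = as.integer(records$origin == "untransmitted_parental"),
      n_unphased = as.integer(records$origin == "unphased")
    )
    sums <- rowsum(flags, grp)
    parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
    out <- data.frame(gene = parts[, 1], class = parts[, 2], stringsAsFactors = FALSE)
    if (by_phenotype) out$subtype <- parts[, 3]
    out <- cbind(out, as.data.frame(sums, row.names = FALSE))
  }

  if (!by_phenotype) {
    scaffold <- expand.grid(gene = panel$gene, class = VARIANT_CLASSES,
                            stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    m <- match(paste(scaffold$gene, scaffold$class), paste(out$gene, out$class))
    for (col in c("n_dnm", "case_ac", "T", "U", "n_unphased")) {
      scaffold[[col]] <- ifelse(is.na(m), 0L, out[[col]][m])
    }
    # "other"-class rows are not part of the scaffold but are kept for inspection
    extra <- out[!(out$class %in% VARIANT_CLASSES), , drop = FALSE]
    out <- rbind(scaffold, extra)
  }
  out$case_an <- if (!is.null(phenotypes)) 2L * nrow(phenotypes) else NA_integer_
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}
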