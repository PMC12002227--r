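make_record <- function(n = 1L, ...) {
  base <- data.frame(
    chrom = "chr1", pos = seq_len(n) * 10L, ref = "A", alt = "T",
    gene = "G0001", consequence = "missense", metasvm = "D",
    maf_bravo = 0, maf_esp = 0, maf_gnomad = 0,
    cohort_ac = 1L, cohort_an = 23110L, origin = "unphased",
    sample_id = paste0("S", seq_len(n)), family_id = paste0("F", seq_len(n)),
    protein_pos = NA_integer_, aa_ref = NA_character_, aa_alt = NA_character_,
    stringsAsFactors = FALSE
  )
  mod <- list(...)
  for (k in names(mod)) base[[k]] <- mod[[k]]
  base
}

test_that("functional classing follows the consequence/metapredictor rules", {
  cases <- list(
    list("synonymous", NA, "synonymous"),
    list("missense", "D", "D-mis"),
    list("missense", "T", "T-mis"),
    list("missense", NA, "T-mis"),
    list("stopgain", NA, "LOF"),
    list("frameshift", NA, "LOF"),
    list("canonical-splice", NA, "LOF"),
    list("inframe-indel", NA, "other"),
    list("other", NA, "other")
  )
  for (cs in cases) {
    expect_identical(classify_variants(cs[[1]], cs[[2]]), cs[[3]],
                     label = paste(cs[[1]], cs[[2]]))
  }
  expect_error(classify_variants("nonsense_mediated_decay"),
               "nonsense_mediated_decay", class = "trioburden_input_error")
})

test_that("rarity filtering applies both population and cohort thresholds", {
  th <- filter_thresholds()
  expect_equal(nrow(filter_very_rare(make_record(maf_bravo = 2e-5), th)), 0L)
  expect_equal(nrow(filter_very_rare(make_record(maf_esp = 2e-5), th)), 0L)
  # AC 1 / AN 23110 = 4.3e-5 <= 1.3e-4 -> kept
  expect_equal(nrow(filter_very_rare(make_record(), th)), 1L)
  expect_equal(nrow(filter_very_rare(make_record(cohort_ac = 4L), th)), 0L)
  # missing population frequency treated as absent
  expect_equal(nrow(filter_very_rare(make_record(maf_bravo = NA_real_), th)), 1L)
  expect_equal(nrow(filter_very_rare(make_record()[0, ], th)), 0L)
  expect_error(filter_very_rare(make_record(cohort_an = 0L), th),
               class = "trioburden_input_error")
})

test_that("filtering is idempotent and preserves order", {
  set.seed(1)
  r <- make_record(50L,
                   maf_bravo = sample(c(0, 2e-5), 50, TRUE),
                   cohort_ac = sample(1:5, 50, TRUE))
  once <- filter_very_rare(r)
  expect_identical(filter_very_rare(once), once)
  expect_true(!is.unsorted(match(once$sample_id, r$sample_id)))
})

test_that("territory harmonization keeps only the shared intervals", {
  iv <- function(start, end, gene = "G0001")
    data.frame(chrom = "chr1", start = start, end = end, gene = gene,
               stringsAsFactors = FALSE)
  r <- make_record(3L, pos = c(141L, 160L, 220L))

  # identical sets: everything retained
  h <- harmonize_territory(iv(100, 250), iv(100, 250), r)
  expect_equal(nrow(h$records), 3L)
  expect_equal(h$coverage$callable_fraction_cases, 1)

  # [100,200) intersect [150,250) = [150,200): 0-based 140 (1-based 141) is out
  h2 <- harmonize_territory(iv(100, 200), iv(150, 250), r)
  s <- attr(h2$coverage, "shared_intervals")
  expect_equal(c(s$start, s$end), c(150L, 200L))
  # brute-force membership scan over every base
  shared_bases <- 150:199
  keep_bf <- (r$pos - 1L) %in% shared_bases
  expect_equal(h2$records$pos, r$pos[keep_bf])
  expect_equal(h2$records$pos, 160L)

  # a case exon absent from the control set loses its records
  h3 <- harmonize_territory(iv(100, 250), iv(300, 400), r)
  expect_equal(nrow(h3$records), 0L)

  expect_error(harmonize_territory(iv(200, 100), iv(100, 200), r),
               class = "trioburden_input_error")
})

test_that("aggregation tallies counts per gene and class with dedup", {
  panel <- data.frame(gene = c("G0001", "G0002"), stringsAsFactors = FALSE)
  ph <- data.frame(proband_id = c("P1", "P2"), cardiac_subtype = c("TOF", "ASD"),
                   ec = FALSE, ndd = FALSE, stringsAsFactors = FALSE)

  one <- make_record(consequence = "stopgain", metasvm = NA_character_,
                     origin = "de_novo", sample_id = "P1")
  a <- aggregate_counts(one, panel, phenotypes = ph)
  expect_equal(a$n_dnm[a$gene == "G0001" & a$class == "LOF"], 1L)
  expect_equal(unique(a$case_an), 4L)

  dup <- rbind(one, one)
  a2 <- aggregate_counts(dup, panel, phenotypes = ph)
  expect_equal(sum(a2$n_dnm), 1L)

  # mixed records vs an independent tally
  mixed <- rbind(
    make_record(consequence = "stopgain", origin = "de_novo", sample_id = "P1"),
    make_record(pos = 20L, consequence = "missense", metasvm = "D",
                origin = "transmitted", sample_id = "P1"),
    make_record(pos = 30L, consequence = "missense", metasvm = "T",
                origin = "untransmitted_parental", sample_id = "F1-02"),
    make_record(pos = 40L, gene = "G0002", consequence = "synonymous",
                origin = "unphased", sample_id = "P2"),
    make_record(pos = 50L, gene = "G0002", consequence = "frameshift",
                origin = "unphased", sample_id = "P2"),
    make_record(pos = 60L, gene = "G0002", consequence = "frameshift",
                origin = "transmitted", sample_id = "P1")
  )
  a3 <- aggregate_counts(mixed, panel, phenotypes = ph)
  pick <- function(g, cl, col) a3[[col]][a3$gene == g & a3$class == cl]
  expect_equal(pick("G0001", "LOF", "n_dnm"), 1L)
  expect_equal(pick("G0001", "D-mis", "T"), 1L)
  expect_equal(pick("G0001", "T-mis", "U"), 1L)
  expect_equal(pick("G0002", "synonymous", "n_unphased"), 1L)
  expect_equal(pick("G0002", "LOF", "case_ac"), 2L)
  expect_equal(sum(a3$n_dnm) + sum(a3$case_ac) + sum(a3$U), 6L)

  # unknown gene goes to the rejects table with a warning
  stray <- make_record(gene = "NOT_IN_PANEL")
  expect_warning(a4 <- aggregate_counts(rbind(one, stray), panel, phenotypes = ph),
                 "outside the panel")
  expect_equal(nrow(attr(a4, "rejects")), 1L)
  expect_equal(sum(a4$n_dnm), 1L)
})
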