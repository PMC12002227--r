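test_that("two-sided Fisher matches enumeration and bounds the one-sided p", {
  expect_equal(feature_2x2(5, 5, 5, 5)$p, 1)
  k <- feature_2x2(2, 5, 15, 3)
  expect_equal(k$p, oracle_fet_two_sided(2, 5, 15, 3), tolerance = 1e-10)
  expect_equal(k$prop1, 2 / 7)
  expect_equal(k$prop2, 15 / 18)

  set.seed(19)
  for (i in 1:40) {
    cells <- sample(0:30, 4, TRUE)
    if (sum(cells) == 0) next
    two <- feature_2x2(cells[1], cells[2], cells[3], cells[4])$p
    expect_equal(two, oracle_fet_two_sided(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9, label = paste(cells, collapse = ","))
    # the one-sided p in the observed direction never exceeds the two-sided p
    upper <- oracle_fet_one_sided(cells[1], cells[1] + cells[2],
                                  cells[3], cells[3] + cells[4])
    lower <- oracle_fet_one_sided(cells[3], cells[3] + cells[4],
                                  cells[1], cells[1] + cells[2])
    expect_gte(two + 1e-12, min(upper, lower))
  }
  expect_error(feature_2x2(0, 0, 0, 0), class = "trioburden_input_error")
})

test_that("rank-sum test: exact path, enumeration example, and path agreement", {
  expect_equal(rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  # most extreme of the C(6,3) = 20 equally likely orderings: 2/20
  expect_equal(rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)

  set.seed(3)
  for (i in 1:10) {
    x <- sample(1:1000, 10); y <- sample(1001:2000, 10) - sample(0:900, 10)
    if (anyDuplicated(c(x, y))) next
    exact <- rank_sum(x, y)
    approx <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
    expect_lt(abs(exact - approx), 0.02)
  }
  expect_error(rank_sum(numeric(), 1), class = "trioburden_input_error")
})

test_that("permutation test calibrates under the null and saturates under signal", {
  set.seed(6)
  g <- sample(c("geneA", "geneB", "geneC"), 120, TRUE)

  # independent labels: p should be comfortably non-significant on average
  ps <- vapply(1:20, function(i) {
    ph <- sample(c("TOF", "LVO", "ASD"), 120, TRUE)
    phenotype_permutation_test(g, ph, n_perm = 200, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.2)
  expect_true(all(ps >= 1 / 201 & ps <= 1))

  # planted perfect association reaches the permutation lower bound
  ph_planted <- c(geneA = "TOF", geneB = "LVO", geneC = "ASD")[g]
  r <- phenotype_permutation_test(g, unname(ph_planted), n_perm = 500, seed = 2)
  expect_equal(r$p, 1 / 501)

  # invariant to relabeling category names
  relab <- c(TOF = "x1", LVO = "x2", ASD = "x3")[unname(ph_planted)]
  r2 <- phenotype_permutation_test(g, unname(relab), n_perm = 500, seed = 2)
  expect_equal(r$p, r2$p)

  expect_error(phenotype_permutation_test(g, rep("TOF", 120), n_perm = 100),
               class = "trioburden_input_error")
})

test_that("cysteine predicate and region enrichment match a hand-built table", {
  expect_true(cysteine_altering("C", "R"))
  expect_true(cysteine_altering("G", "C"))
  expect_false(cysteine_altering("G", "A"))
  expect_false(cysteine_altering("C", "C"))

  mkv <- function(n, pos, ref, alt) data.frame(
    gene = "NOTCH1", protein_pos = pos, aa_ref = ref, aa_alt = alt,
    stringsAsFactors = FALSE
  )
  case <- mkv(10, c(rep(200, 8), 210, 950), c(rep("C", 8), "G", "C"),
              c(rep("R", 8), "A", "S"))
  ctrl <- mkv(1, 205, "C", "Y")
  regions <- data.frame(gene = "NOTCH1", name = "EGF-like 5",
                        start = 180L, end = 220L, stringsAsFactors = FALSE)
  res <- region_class_enrichment(case, ctrl, regions, case_an = 10, ctrl_an = 1000)
  row <- res[res$region == "EGF-like 5", ]
  expect_equal(row$case_pos, 8L)
  expect_equal(row$ctrl_pos, 1L)
  ref <- fet_burden(8, 10, 1, 1000)
  expect_equal(row$p, ref$p)
  expect_equal(row$fold, (8 / 10) / (1 / 1000))

  # records without protein coordinates are skipped with a warning
  case_na <- rbind(case, data.frame(gene = "NOTCH1", protein_pos = NA_integer_,
                                    aa_ref = "C", aa_alt = "R"))
  expect_warning(res2 <- region_class_enrichment(case_na, ctrl, regions, 10, 1000),
                 "without protein_pos")
  expect_equal(attr(res2, "n_skipped"), 1L)
})

test_that("subgroup counts partition the whole-cohort burden and recover planted cells", {
  cfg <- small_config(n_trios = 2000L, n_singletons = 500L, n_genes = 30L,
                      risk_gene_fraction = 0.2, carrier_freq = 6e-3,
                      phenotype_concordance = 0.9, n_controls = 20000L,
                      common_site_prob = 0, seed = 31L)
  co <- simulate_cohort(cfg)
  counts_all <- aggregate_counts(co$variants, co$mutability,
                                 phenotypes = co$phenotypes)
  counts_by <- aggregate_counts(co$variants, co$mutability,
                                phenotypes = co$phenotypes, by_phenotype = TRUE)
  # disjoint exhaustive partition: per-subtype counts sum to the unstratified total
  expect_equal(sum(counts_by$n_dnm), sum(counts_all$n_dnm))
  expect_equal(sum(counts_by$case_ac), sum(counts_all$case_ac))

  risk <- co$truth$gene[co$truth$is_risk]
  loose <- filter_thresholds(max_cohort_maf = 1e-3)
  sm <- subgroup_meta(co, risk, thresholds = loose)
  top <- sm$cells[1, ]
  linked <- co$truth$linked_subtype[match(top$gene, co$truth$gene)]
  # the top-ranked cell pairs a risk gene with a plausible subtype signal
  expect_true(top$gene %in% risk)

  # a gene with zero variants has p = 1 in every cell
  zero_gene <- setdiff(co$mutability$gene, unique(co$variants$gene))
  if (length(zero_gene) >= 1) {
    sz <- subgroup_meta(co, c(risk[1], zero_gene[1]), thresholds = loose)
    zc <- sz$cells[sz$cells$gene == zero_gene[1], ]
    expect_true(all(zc$p_cc == 1))
    expect_true(all(zc$n_dnm == 0))
  }
})
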