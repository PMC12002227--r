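#' One-tailed Fisher exact burden of case versus control alleles
#'
#' Builds the 2x2 table `[[case_ac, case_an - case_ac], [ctrl_ac,
#' ctrl_an - ctrl_ac]]` and returns the hypergeometric upper tail in the
#' case-enrichment direction, so depletion is never significant. `p_mid` is
#' the mid-p version used for the z-score transform. The fold-enrichment is
#' the ratio of allele frequencies, `Inf` when `ctrl_ac = 0` and
#' `case_ac > 0`.
#'
#' @param case_ac,case_an case allele and chromosome counts.
#' @param ctrl_ac,ctrl_an control allele and chromosome counts (effective,
#'   i.e. coverage-adjusted).
#' @param unit,class optional labels.
#' @return one-row data.frame: `unit`, `class`, `case_ac`, `case_an`,
#'   `ctrl_ac`, `ctrl_an`, `enrichment`, `p`, `p_mid`.
#' @export
fet_burden <- function(case_ac, case_an, ctrl_ac, ctrl_an,
                       unit = NA_character_, class = NA_character_) {
  for (v in list(c(case_ac, case_an), c(ctrl_ac, ctrl_an))) {
    if (v[1] > v[2]) stop_input("allele count exceeds chromosome count")
    if (v[2] <= 0) stop_input("chromosome count must be positive")
  }
  k <- case_ac + ctrl_ac
  # upper tail of Hypergeometric(drawn = case_an, white = k, total = case_an + ctrl_an)
  p <- phyper(case_ac - 1, k, case_an + ctrl_an - k, case_an, lower.tail = FALSE)
  p_mid <- phyper(case_ac, k, case_an + ctrl_an - k, case_an, lower.tail = FALSE) +
    dhyper(case_ac, k, case_an + ctrl_an - k, case_an) / 2
  cf <- case_ac / case_an
  gf <- ctrl_ac / ctrl_an
  enr <- if (ctrl_ac == 0) (if (case_ac > 0) Inf else NaN) else cf / gf
  data.frame(unit = unit, class = class, case_ac = case_ac, case_an = case_an,
             ctrl_ac = ctrl_ac, ctrl_an = ctrl_an, enrichment = enr,
             p = p, p_mid = p_mid, stringsAsFactors = FALSE)
}

#' Coverage-adjusted effective chromosome count
#'
#' Scales a raw chromosome count by the per-gene callable fraction, rounding
#' to the nearest integer with a minimum of 1.
#'
#' @param an_raw raw chromosome count.
#' @param callable_fraction proportion of the gene's territory that is
#'   callable, in (0, 1].
#' @export
coverage_adjust <- function(an_raw, callable_fraction) {
  if (any(callable_fraction <= 0) || any(callable_fraction > 1))
    stop_input("callable_fraction must be in (0, 1]")
  # round half up (commercial rounding), not banker's rounding
  pmax(1L, as.integer(floor(an_raw * callable_fraction + 0.5)))
}

#' Attributable fraction from case-control allele frequency excess
#'
#' Difference between case and control allele frequencies, floored at zero,
#' scaled to a per-proband (diploid) basis.
#'
#' @inheritParams fet_burden
#' @export
attributable_fraction_cc <- function(case_ac, case_an, ctrl_ac, ctrl_an) {
  if (case_ac > case_an || ctrl_ac > ctrl_an) stop_input("allele count exceeds chromosome count")
  if (case_an <= 0 || ctrl_an <= 0) stop_input("chromosome count must be positive")
  max(0, case_ac / case_an - ctrl_ac / ctrl_an) * 2
}

#' Gene-set case-control burden
#'
#' Sums case and control allele/chromosome counts over a gene set for one
#' class and applies [fet_burden()] to the totals.
#'
#' @param counts class-counts table with `case_ac`, `case_an`.
#' @param controls control counts table with `ctrl_ac`, `ctrl_an`.
#' @param genes gene set (non-empty).
#' @param class functional class or `"damaging"`.
#' @export
geneset_fet <- function(counts, controls, genes, class) {
  if (length(genes) == 0L) stop_input("empty gene set")
  classes <- if (class == "damaging") DAMAGING_CLASSES else class
  sc <- counts$gene %in% genes & counts$class %in% classes
  sg <- controls$gene %in% genes & controls$class %in% classes
  fet_burden(sum(counts$case_ac[sc]), sum(counts$case_an[sc]) / length(classes),
             sum(controls$ctrl_ac[sg]), sum(controls$ctrl_an[sg]) / length(classes),
             unit = paste0("set[", length(genes), "]"), class = class)
}
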