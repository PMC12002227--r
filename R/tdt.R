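#' Transmission disequilibrium test
#'
#' Chi-square TDT on transmitted (T) versus untransmitted (U) parental
#' alleles: statistic `(T - U)^2 / (T + U)` with no continuity correction,
#' p-value from the upper tail of the 1-df chi-square distribution. The
#' genotypic risk ratio is estimated as `T / U` (`Inf` when `U = 0`).
#'
#' @param T,U transmitted and untransmitted informative allele counts.
#' @param unit,class optional labels.
#' @return one-row data.frame: `unit`, `class`, `T`, `U`, `chi2`, `p`,
#'   `transmitted_fraction`, `grr`, `attributable_fraction` (NA here; filled
#'   by [geneset_tdt()], which knows the trio count).
#' @examples
#' tdt_test(118, 34)  # 78\% transmitted, p = 9.5e-12
#' @export
tdt_test <- function(T, U, unit = NA_character_, class = NA_character_) {
  T <- check_count(T, "T"); U <- check_count(U, "U")
  if (T + U == 0L) stop_input("T + U must be >= 1")
  chi2 <- (T - U)^2 / (T + U)
  data.frame(
    unit = unit, class = class, T = T, U = U, chi2 = chi2,
    p = pchisq(chi2, df = 1, lower.tail = FALSE),
    transmitted_fraction = T / (T + U),
    grr = if (U == 0L) Inf else T / U,
    attributable_fraction = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Gene-set transmission disequilibrium test
#'
#' Sums T and U over a gene set for one functional class (or pooled damaging
#' classes), applies [tdt_test()], and adds the transmission-based
#' attributable fraction `max(0, T - (T + U)/2) / n_trios`: the excess of
#' transmitted alleles over the Mendelian expectation, per trio.
#'
#' @param counts class-counts table with `T` and `U` columns.
#' @param genes gene set (non-empty).
#' @param class functional class or `"damaging"`.
#' @param n_trios number of trios.
#' @export
geneset_tdt <- function(counts, genes, class, n_trios) {
  if (length(genes) == 0L) stop_input("empty gene set")
  n_trios <- check_count(n_trios, "n_trios", min = 1L)
  classes <- if (class == "damaging") DAMAGING_CLASSES else class
  sel <- counts$gene %in% genes & counts$class %in% classes
  out <- tdt_test(sum(counts$T[sel]), sum(counts$U[sel]),
                  unit = paste0("set[", length(genes), "]"), class = class)
  out$attributable_fraction <- max(0, out$T - (out$T + out$U) / 2) / n_trios
  out
}
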