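---
title: "Statistical methods for rare-variant gene discovery in trio cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for rare-variant gene discovery in trio cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioburden)
```

## The problem

Dominant disease genes for congenital heart disease (CHD) and similar
disorders leave two complementary genetic footprints in a sequenced cohort of
probands: an excess of *de novo* mutations (DNMs) over the per-gene
mutational expectation, and an excess of very rare inherited ("transmitted or
unphased", TUV) damaging alleles relative to population controls. Neither
stream alone is powerful at realistic per-gene counts (often 0-5 events), so
the two are combined per gene and the multiple-testing burden across a
targeted panel is handled with an empirical-Bayes false discovery rate
computed jointly on both evidence axes.

`trioburden` implements that full pipeline — filtering, counting, the two
burden tests, the joint-local FDR (JL-FDR) meta-analysis, transmission
disequilibrium testing (TDT), attributable fractions, risk-gene-count
estimation, and phenotype-subgroup association — plus a cohort simulator
with known ground truth so that every stage can be validated end to end
without access to controlled individual-level data.

## Models and statistics

### De novo burden against mutability

Each gene \(g\) and functional class \(c \in\) {synonymous, T-mis, D-mis,
LOF} has a *mutability* \(\mu_{gc}\): the probability of one de novo variant
of that class per live birth. In \(n\) trios the null DNM count is
Poisson with mean \(E = n\,\mu_{gc}\) (no extra factor of 2; \(\mu\) is
defined per birth, not per haploid genome). The burden test reports the
upper tail including the observed value, \(P(X \ge O)\), the fold-enrichment
\(O/E\), and the attributable fraction \(\max(0, O-E)/n\): the excess of
mutation carriers per proband. Gene-set burdens sum \(O\) and \(E\) over the
set — both are additive — and apply the same arithmetic.

QQ calibration uses the genomic inflation factor
\(\lambda = \mathrm{median}\,\chi^2_{1}(1-p)/0.4549364\), rescaled to a
1,000-sample cohort as \(\lambda_{1000} = 1 + (\lambda - 1)\,(1000/n)\). The
rescaling formula is pinned here because the burden is a one-event-per-trio
statistic whose inflation scales with cohort size.

### Case-control TUV burden

Very rare alleles (population MAF \(\le 10^{-5}\) in two reference
databases, within-cohort MAF \(\le 1.3\times10^{-4}\)) carried by probands
are compared with control allele counts by a one-tailed Fisher exact test on
\[\begin{pmatrix} \mathrm{case\ AC} & \mathrm{case\ AN} - \mathrm{case\ AC}\\
\mathrm{ctrl\ AC} & \mathrm{ctrl\ AN} - \mathrm{ctrl\ AC}\end{pmatrix},\]
with the tail fixed in the case-enrichment direction (depletion is never
significant). Chromosome denominators are *effective* counts: the raw AN
scaled by the per-gene callable fraction over the capture territory shared
by the case and control platforms (`harmonize_territory()`,
`coverage_adjust()`; rounding is half-up with a floor of 1). The
within-cohort MAF rule is read as *retaining* variants at or below the
threshold: the stated purpose of the filter is restricting to very rare
variants, so the filter direction follows the purpose.

### Meta-analysis and JL-FDR

Per gene, the two one-sided p-values are combined by Fisher's method
(\(X = -2(\ln p_1 + \ln p_2)\) against \(\chi^2_4\); inputs floored at
1e-300). For FDR control across the panel the two evidence streams are kept
as a *pair* of z-scores \(z = (\Phi^{-1}(1-p_{\mathrm{dnm}}),
\Phi^{-1}(1-p_{\mathrm{cc}}))\), clipped to \(\pm 8\), and modelled as a
two-component bivariate normal mixture:

* a **null** component fixed at the standard bivariate normal with zero
  correlation — both inputs are one-sided p-values, uniform under the null
  by construction, and the two tests use disjoint data (de novo counts vs
  inherited/control alleles);
* an **alternative** component with weight \(1-\pi_0\), a mean constrained
  non-negative componentwise, and a free covariance, estimated by EM.

The per-gene local FDR is the posterior null probability
\(\pi_0\phi_0(z)/[\pi_0\phi_0(z) + (1-\pi_0)\phi_1(z)]\); genes are ranked
by it and the reported JL-FDR is the running mean of local FDRs down the
ranking (step-up averaging), so the flagged set at level 0.05 has estimated
FDR at most 0.05. `predicted_risk_genes()` reports
\(\mathrm{round}((1-\pi_0)\,n_{\mathrm{genes}})\), the expected number of
panel genes that belong to the alternative component.

Two numerical choices matter here:

* **mid-p for the z transform.** At per-gene expected counts of ~0.2 the
  conservative tail \(P(X\ge O)\) is extremely discrete: most genes have
  \(p = 1\), which maps to \(z = -8\) and would shred the fixed N(0,1) null.
  The z-scores therefore use the Lancaster mid-p,
  \(P(X > O) + \tfrac12 P(X = O)\), whose null distribution is far closer to
  uniform. The conservative \(P(X \ge O)\) remains the p-value reported for
  every gene and gene set.
* **collapse guard.** With pure-null data the alternative component is not
  identified (it can sit exactly on the null), and the EM weight drifts
  arbitrarily. After fitting, the mixture is compared with the pure-null
  model by likelihood ratio; unless it wins by a BIC margin
  (\(2\Delta\ell > 6\log n\), six free parameters), the fit is collapsed to
  \(\pi_0 = 1\) and nothing can be declared significant. This keeps the
  realized false-discovery proportion of a fully null panel near zero while
  leaving any real signal (whose \(2\Delta\ell\) is in the hundreds)
  untouched.

The EM itself is deterministic: \(\pi_0\) starts at 0.9, the alternative
mean at the average of pairs with both coordinates above 1 (fallback
\((2,2)\)), covariance at identity; iteration stops when the log-likelihood
gain falls below `tol` (1e-8). Because the non-negativity projection of the
mean can in principle break the EM ascent property, any update that would
decrease the log-likelihood is replaced by the weight-only update (an exact
partial M-step), which keeps the trace non-decreasing.

### Transmission disequilibrium

For each parental heterozygous very-rare damaging allele, transmission to
the proband is a fair coin under the null. With \(T\) transmitted and \(U\)
untransmitted alleles the statistic is \((T-U)^2/(T+U)\) against
\(\chi^2_1\), **without** continuity correction — this choice reproduces the
standard worked examples exactly (e.g. \(T=118, U=34\) gives
\(p = 9.5\times10^{-12}\)). The genotypic risk ratio is estimated as
\(T/U\), and the transmission attributable fraction is
\(\max(0, T - (T+U)/2)/n_{\mathrm{trios}}\): the excess over Mendelian
expectation per trio. Homozygous parents would contribute two informative
transmissions; at the frequencies involved they effectively never occur.

### Risk-gene-count MLE

How many panel genes carry de novo risk? For each candidate count \(R\) on
a grid, cohorts are simulated (risk genes drawn proportionally to damaging
mutability, a grid of enrichments applied, Poisson counts drawn) and the
empirical likelihood of the observed summary statistic — the pair (number
of genes with \(\ge 1\) damaging DNM, number with \(\ge 2\)) — is read from
a jointly binned frequency table (bin width 2) with add-one smoothing; the
smoothing denominator uses the set of bins occupied anywhere on the grid so
likelihoods are comparable across grid points. The profile over the
enrichment grid is maximized in \(R\); the 95% CI spans all grid points
within 1.92 log-likelihood units of the maximum. The multi-hit counts are
chosen as the summary because they are the observable that drives
recurrent-gene discovery; the closed-form check
`expected_multihit_genes()` computes \(\sum_g P(\mathrm{Pois}(n\mu_g) \ge
k)\) and is verified against simulation.

### Subgroup association and protein-region enrichment

Phenotype-level signal is assessed on a grid of gene × category cells: the
eight cardiac subtypes (CTD, TOF, LVO, HLHS, ASD, AVC, LAT, other) plus the
four EC/NDD categories (isolated, EC only, NDD only, EC+NDD). Within each
cell the damaging DNM and case-control burdens are recomputed on the
subgroup's probands and the same JL-FDR machinery is applied jointly over
all cells, so the multiplicity of 12 categories × genes is accounted for.
Clinical 2×2 comparisons use the two-sided Fisher exact test
(point-probability rule), continuous comparisons the Wilcoxon rank-sum test
(exact below n=10 per arm without ties, tie-corrected normal approximation
otherwise), and cohort-level non-randomness a Monte-Carlo permutation of
phenotype labels against the Pearson chi-square statistic (the statistic is
a pinned choice; the add-one `(1 + \#\{exceed\})/(1 + n_{perm})` estimator
keeps p strictly positive).

Protein-region enrichment (the ΔCys analysis) counts missense alleles
matching a named residue predicate — default *cysteine-altering*:
exactly one of the reference/alternate residues is C, leaving an odd
cysteine count in a disulfide-bonded domain — inside 1-based inclusive
residue windows, and applies the one-tailed Fisher machinery per region and
for the region union.

## The cohort simulator

`simulate_cohort()` generates the full object graph (variant records,
6-column pedigree, phenotypes, control counts, ground truth) from one seed;
`simulate_class_counts()` draws the same distributions directly at the
gene × class level for fast calibration studies. The defaults are the study
conditions the package is designed around:

| parameter | default | rationale |
|---|---|---|
| `n_trios` / `n_singletons` | 3,887 / 7,668 | cohort scale of a modern multi-center CHD study |
| `n_genes` | 248 | targeted panel size |
| `risk_gene_fraction` | 60/248 | significant-gene yield at that scale |
| `dnm_enrichment` | D-mis 6.1×, LOF 14.3× | panel-level damaging DNM enrichment |
| `transmission_prob` | 0.78 | LOF over-transmission at risk genes |
| `carrier_freq` | 2e-3 per parent per gene | anchored to ~250 informative damaging parental alleles across 60 genes × 7,774 parents |
| mean total mutability | 2.4e-4 per gene per birth | panel genes are large, constraint-selected genes, ~3× the genome-average gene; gives ~200 expected damaging panel DNMs at 3,887 trios |
| `coverage_fraction_range` | (0.9, 1) | >95% of targeted bases callable |
| `phenotype_concordance` | 0.8 | gene-linked cardiac subtype for risk carriers |
| `common_site_prob` | 0.05 | decoy non-rare sites that the rarity filter must remove |

Simulated very rare sites are unique (each allele its own site), so
post-filter MAF stays below 1e-5 by construction; recurrence can be turned
on with `site_reuse_prob`. Controls are drawn at the matched population
frequency of non-risk carrier alleles over coverage-adjusted chromosome
counts, which makes the case-control test exactly calibrated under the
null.

What the generator deliberately does **not** emulate: sequencing error and
read-level artifacts, population structure and relatedness, mutational
hotspots within genes, winner's-curse ascertainment of the panel, and
phenotype misclassification. Passing recovery tests therefore demonstrate
the *statistical machinery* is correct under the declared generative model,
not that real-data results are reproduced.

One scale interaction deserves note: the within-cohort MAF threshold
(1.3e-4) is calibrated for an ~11,500-proband cohort, where a singleton
allele has MAF ~4.3e-5. In small simulated cohorts a singleton allele
exceeds the threshold, so tests on reduced cohorts either relax
`max_cohort_maf` or aggregate unfiltered records; the full-scale default
passes unchanged.

## Validation summary

The test-suite and `scripts/acceptance.R` validate, among other things:

* worked transmission and clinical 2×2 statistics recomputed from published
  count tables at printed precision;
* exact equivalence of the Fisher (both tails), Poisson-tail and BH
  machinery with brute-force enumeration oracles;
* type-I calibration of all three per-gene tests and a realized
  false-discovery proportion ≤ 0.08 at nominal 0.05 under 200 fully null
  cohort replicates (248 genes, 3,887 trios, 25,000 control chromosomes);
* recovery of planted enrichment (10×), transmission (0.75), mixture weight
  (±0.1), and risk-gene count (95% CI coverage ≥ 90%) on simulated cohorts;
* byte-identical pipeline outputs for identical config and seed.

The calibration and recovery problem sizes above were chosen to finish in a
few minutes on one CPU while leaving Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

* The JL-FDR rejection region is defined through the local-FDR ranking and
  its running mean; other joint-region constructions exist and can differ
  in which borderline genes they flag.
* The risk-gene-count likelihood is an empirical Monte-Carlo construction;
  only parameter recovery on synthetic data is claimed, not reproduction of
  any published point estimate.
* Inframe indels are classed `other` and never counted as damaging.
* Duos (one parent sequenced) are treated as singletons: their variants
  enter as unphased, never as informative transmissions.
* The effective-chromosome coverage adjustment is per gene, not per base.
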