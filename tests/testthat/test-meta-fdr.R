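test_that("Fisher's method matches the chi-square(4) closed form", {
  expect_equal(fishers_method(1, 1), 1)
  x <- -2 * (log(0.5) + log(0.5))
  expect_equal(fishers_method(0.5, 0.5), oracle_chisq4_upper(x), tolerance = 1e-10)
  expect_equal(fishers_method(0.5, 0.5), 0.5965736, tolerance = 1e-6)

  set.seed(2)
  p1 <- runif(30); p2 <- runif(30)
  expect_equal(fishers_method(p1, p2),
               oracle_chisq4_upper(-2 * (log(p1) + log(p2))),
               tolerance = 1e-10)

  # one very strong p-value vs two moderate ones: identical statistic here
  expect_equal(fishers_method(1e-6, 1), fishers_method(1e-3, 1e-3),
               tolerance = 1e-12)
  expect_lt(fishers_method(1e-8, 1), fishers_method(1e-3, 1e-3))
  expect_error(fishers_method(0, 0.5), class = "trioburden_input_error")
})

test_that("p-to-z transform inverts the normal tail and caps extremes", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.025), 1.959964, tolerance = 1e-6)
  expect_equal(p_to_z(1e-300), 8)
  expect_equal(p_to_z(1), -8)
  expect_error(p_to_z(0), class = "trioburden_input_error")
})

test_that("BH q-values match the hand step-up computation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  }
})

test_that("EM fit recovers mixture parameters and keeps a monotone trace", {
  # 80% null + 20% alternative at mean (3,3)
  set.seed(5)
  n <- 1000L
  lab <- runif(n) < 0.2
  z <- cbind(rnorm(n), rnorm(n))
  z[lab, ] <- z[lab, ] + 3
  fit <- fit_mixture_em(z)
  expect_true(fit$converged)
  expect_lt(abs(fit$pi0 - 0.8), 0.1)
  expect_lt(max(abs(fit$mu1 - c(3, 3))), 0.5)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))

  # pure-null z: pi0 pushed high in nearly all replicates (n = 248)
  set.seed(9)
  hits <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    z0 <- cbind(rnorm(248), rnorm(248))
    f0 <- fit_mixture_em(z0)
    expect_true(all(diff(f0$loglik_trace) > -1e-6))
    if (f0$pi0 >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 95L)

  expect_error(fit_mixture_em(cbind(rnorm(5), rnorm(5))),
               class = "trioburden_input_error")
})

test_that("local and running FDR behave as density ratios and running means", {
  fit <- structure(list(pi0 = 0.95, mu1 = c(3, 3), sigma1 = diag(2),
                        loglik_trace = 0, converged = TRUE, n_iter = 0L),
                   class = "mixture_fit")
  z <- rbind(c(0, 0), c(8, 8), c(1, 1), c(4, 4))
  res <- jl_fdr(z, fit, genes = c("null", "extreme", "mid", "strong"))
  expect_gt(res$local_fdr[res$gene == "null"], 0.9)
  expect_lt(res$local_fdr[res$gene == "extreme"], 1e-6)
  expect_true(all(res$local_fdr >= 0 & res$local_fdr <= 1))
  expect_true(!is.unsorted(res$jl_fdr))
  # running FDR never exceeds the worst local fdr in the rejection set
  expect_true(all(res$jl_fdr <= cummax(res$local_fdr) + 1e-12))
})

test_that("predicted risk-gene count is the alternative mass times panel size", {
  fake <- function(pi0) structure(list(pi0 = pi0), class = "mixture_fit")
  expect_equal(predicted_risk_genes(fake(1), 248), 0L)
  expect_equal(predicted_risk_genes(fake(0.552), 248), 111L)
  expect_equal(predicted_risk_genes(fake(0.5), 100), 50L)
})

test_that("meta-analysis flags planted risk genes on simulated evidence", {
  cfg <- small_config(n_trios = 3887L, n_singletons = 3000L, n_genes = 100L,
                      risk_gene_fraction = 0.15, carrier_freq = 6e-3,
                      n_controls = 30000L, seed = 23L)
  cc <- simulate_class_counts(cfg)
  mu_d <- damaging_mu(cc$mutability)
  dnm_by_gene <- rowsum(cc$counts$n_dnm[cc$counts$class %in% c("D-mis", "LOF")],
                        cc$counts$gene[cc$counts$class %in% c("D-mis", "LOF")])
  dnm <- do.call(rbind, lapply(cc$mutability$gene, function(g)
    poisson_burden(dnm_by_gene[g, 1], cfg$n_trios, mu_d[[g]], unit = g)))
  ac <- rowsum(cc$counts$case_ac[cc$counts$class %in% c("D-mis", "LOF")],
               cc$counts$gene[cc$counts$class %in% c("D-mis", "LOF")])
  an <- cc$counts$case_an[match(cc$mutability$gene, cc$counts$gene)]
  ctrl_ac <- rowsum(cc$controls$ctrl_ac[cc$controls$class %in% c("D-mis", "LOF")],
                    cc$controls$gene[cc$controls$class %in% c("D-mis", "LOF")])
  ctrl_an <- cc$controls$ctrl_an[match(cc$mutability$gene, cc$controls$gene)]
  ccb <- do.call(rbind, lapply(seq_along(cc$mutability$gene), function(i)
    fet_burden(ac[i, 1], an[i], ctrl_ac[i, 1], ctrl_an[i],
               unit = cc$mutability$gene[i])))
  m <- meta_analysis(dnm, ccb)
  sig <- m$meta$gene[m$meta$significant]
  risk <- cc$truth$gene[cc$truth$is_risk]
  expect_gt(length(intersect(sig, risk)), 0L)
  # discoveries are dominated by true risk genes
  if (length(sig) > 0) expect_gte(mean(sig %in% risk), 0.75)
})
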