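#' Fisher's method for two p-values
#'
#' Combines two independent one-sided p-values via
#' `X = -2 (ln p1 + ln p2)`, referred to the upper tail of a chi-square
#' distribution with 4 degrees of freedom. Callers must pre-floor zero
#' p-values (the pipeline uses 1e-300).
#'
#' @param p1,p2 p-values in (0, 1]; vectorised.
#' @export
fishers_method <- function(p1, p2) {
  if (any(p1 <= 0) || any(p2 <= 0)) stop_input("p-values must be > 0 (pre-floor at 1e-300)")
  if (any(p1 > 1) || any(p2 > 1)) stop_input("p-values must be <= 1")
  pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}

#' One-sided p-value to z-score
#'
#' `z = qnorm(1 - p)`, clipped to `[-cap, cap]` for numerical safety so that
#' extreme genes stay extreme but finite.
#'
#' @param p one-sided p-values in (0, 1].
#' @param cap clipping bound (default 8).
#' @export
p_to_z <- function(p, cap = 8) {
  if (any(p <= 0)) stop_input("p-values must be > 0")
  if (any(p > 1)) stop_input("p-values must be <= 1")
  pmin(cap, pmax(-cap, qnorm(1 - p)))
}

#' Fit a two-component bivariate normal mixture by EM
#'
#' Models per-gene evidence pairs `z = (z_dnm, z_cc)` as a mixture of a
#' fully fixed null component (standard bivariate normal, zero correlation
#' -- both inputs are one-sided p-values, uniform under the null) and an
#' alternative component whose mean (constrained non-negative
#' componentwise), covariance, and weight `1 - pi0` are estimated.
#'
#' Initialisation is deterministic: `pi0 = 0.9`, `mu1` = mean of pairs with
#' both coordinates > 1 (fallback (2, 2) when that set is empty), `sigma1` =
#' identity. Iteration stops when the log-likelihood gain drops below `tol`
#' or at `max_iter` (then `converged = FALSE`).
#'
#' @param z two-column matrix or data.frame of z-score pairs (>= 10 rows).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @param seed accepted for interface symmetry; the fit is deterministic.
#' @return list of class `mixture_fit`: `pi0`, `mu1`, `sigma1`,
#'   `loglik_trace`, `converged`, `n_iter`.
#' @export
fit_mixture_em <- function(z, tol = 1e-8, max_iter = 1000L, seed = 1L) {
  z <- as.matrix(z)
  if (nrow(z) < 10L) stop_input("need at least 10 z-score pairs")
  if (ncol(z) != 2L) stop_input("z must have two columns")

  pi0 <- 0.9
  both_high <- z[, 1] > 1 & z[, 2] > 1
  mu1 <- if (any(both_high)) pmax(0, colMeans(z[both_high, , drop = FALSE])) else c(2, 2)
  sigma1 <- diag(2)
  log_phi0 <- dmvnorm2_log(z, c(0, 0), diag(2))

  loglik <- function(pi0, mu1, sigma1) {
    l1 <- dmvnorm2_log(z, mu1, sigma1)
    sum(log(pi0 * exp(log_phi0) + (1 - pi0) * exp(l1)))
  }
  trace <- loglik(pi0, mu1, sigma1)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step
    d0 <- pi0 * exp(log_phi0)
    d1 <- (1 - pi0) * exp(dmvnorm2_log(z, mu1, sigma1))
    g1 <- d1 / (d0 + d1)
    # M-step
    w <- sum(g1)
    pi0_new <- min(1 - 1e-6, max(1e-6, 1 - w / nrow(z)))
    mu1_new <- mu1
    sigma1_new <- sigma1
    if (w > 0) {
      mu1_new <- pmax(0, colSums(z * g1) / w)
      d <- sweep(z, 2, mu1_new)
      sigma1_new <- crossprod(d * g1, d) / w + diag(1e-6, 2)
    }
    ll <- loglik(pi0_new, mu1_new, sigma1_new)
    prev <- trace[length(trace)]
    if (ll < prev) {
      # the non-negativity projection of mu1 can break the ascent property;
      # fall back to the weight-only update, which is an exact partial M-step
      pi0 <- min(1 - 1e-6, max(1e-6, 1 - w / nrow(z)))
      ll <- loglik(pi0, mu1, sigma1)
    } else {
      pi0 <- pi0_new; mu1 <- mu1_new; sigma1 <- sigma1_new
    }
    trace <- c(trace, ll)
    if (abs(ll - prev) < tol) { converged <- TRUE; break }
  }
  # Guard against the non-identified boundary: when the fitted mixture does
  # not beat the pure-null model by a BIC-worthy margin (6 free parameters:
  # weight, 2 mean, 3 covariance), the weight estimate is arbitrary and is
  # collapsed to the null.
  lrt <- 2 * (trace[length(trace)] - sum(log_phi0))
  collapsed <- lrt < 6 * log(nrow(z))
  if (collapsed) pi0 <- 1
  structure(list(pi0 = pi0, mu1 = mu1, sigma1 = sigma1,
                 loglik_trace = trace, converged = converged, n_iter = iter,
                 lrt_2dll = lrt, collapsed = collapsed),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Two-component bivariate normal mixture: pi0 = %.3f, mu1 = (%.2f, %.2f), %s after %d iterations\n",
              x$pi0, x$mu1[1], x$mu1[2],
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Joint-local false discovery rate
#'
#' Computes the per-gene local FDR under a fitted mixture,
#' `lfdr(g) = pi0 phi0(z_g) / [pi0 phi0(z_g) + (1 - pi0) phi1(z_g)]`,
#' ranks genes by ascending local FDR, and reports the running FDR
#' `jl_fdr(g)` as the mean local FDR over the top-ranked set ending at `g`
#' (step-up averaging). Genes with `jl_fdr <= fdr_level` are flagged
#' significant.
#'
#' @param z two-column matrix/data.frame of z pairs, optionally with
#'   rownames or a `gene` attribute supplying gene names.
#' @param fit a [fit_mixture_em()] result.
#' @param genes optional gene names.
#' @param fdr_level significance level (default 0.05).
#' @return data.frame in ranked order: `gene`, `z_dnm`, `z_cc`,
#'   `local_fdr`, `jl_fdr`, `significant`.
#' @export
jl_fdr <- function(z, fit, genes = NULL, fdr_level = 0.05) {
  z <- as.matrix(z)
  if (is.null(genes)) genes <- if (!is.null(rownames(z))) rownames(z) else as.character(seq_len(nrow(z)))
  d0 <- fit$pi0 * exp(dmvnorm2_log(z, c(0, 0), diag(2)))
  d1 <- (1 - fit$pi0) * exp(dmvnorm2_log(z, fit$mu1, fit$sigma1))
  lfdr <- d0 / (d0 + d1)
  ord <- order(lfdr)
  out <- data.frame(gene = genes[ord], z_dnm = z[ord, 1], z_cc = z[ord, 2],
                    local_fdr = lfdr[ord], stringsAsFactors = FALSE)
  out$jl_fdr <- cumsum(out$local_fdr) / seq_len(nrow(out))
  out$significant <- out$jl_fdr <= fdr_level
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up q-values with monotonicity enforcement (wraps
#' `p.adjust(method = "BH")`).
#'
#' @param pvals p-values in (0, 1].
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1)) stop_input("p-values must be in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Predicted number of risk genes from the mixture weight
#'
#' `round((1 - pi0) * n_genes)`: the expected count of panel genes belonging
#' to the alternative component.
#'
#' @param fit a [fit_mixture_em()] result.
#' @param n_genes panel size.
#' @export
predicted_risk_genes <- function(fit, n_genes) {
  as.integer(round((1 - fit$pi0) * n_genes))
}

#' Per-gene meta-analysis of DNM and case-control evidence
#'
#' Takes per-gene one-sided DNM and case-control burden tables (matched by
#' gene), combines their conservative p-values by Fisher's method (floored
#' at 1e-300), transforms the mid-p values to z-scores, fits the JL-FDR
#' mixture, and returns the ranked meta table.
#'
#' @param dnm data.frame with `unit` (gene) and `p`, `p_mid` columns.
#' @param cc data.frame with the same columns for the case-control test.
#' @param fdr_level FDR significance level.
#' @param z_cap z-score clipping bound.
#' @return list: `meta` (ranked data.frame with `p_fisher`, `local_fdr`,
#'   `jl_fdr`, `significant`), `fit` (the mixture fit), `z` (z matrix).
#' @export
meta_analysis <- function(dnm, cc, fdr_level = 0.05, z_cap = 8) {
  m <- match(dnm$unit, cc$unit)
  if (anyNA(m)) stop_input("case-control table is missing genes present in the DNM table")
  cc <- cc[m, , drop = FALSE]
  floor_p <- function(p) pmax(p, 1e-300)
  p_fisher <- fishers_method(floor_p(dnm$p), floor_p(cc$p))
  z <- cbind(z_dnm = p_to_z(floor_p(dnm$p_mid), cap = z_cap),
             z_cc = p_to_z(floor_p(cc$p_mid), cap = z_cap))
  fit <- fit_mixture_em(z)
  res <- jl_fdr(z, fit, genes = dnm$unit, fdr_level = fdr_level)
  res$p_fisher <- p_fisher[match(res$gene, dnm$unit)]
  list(meta = res, fit = fit, z = z)
}
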