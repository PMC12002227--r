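# Internal helpers: argument checks and coordinate conversions.

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("trioburden_input_error", "error")))
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    stop_input(name, " must be a single integer >= ", min, " (got ", deparse(x), ")")
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi)
    stop_input(name, " must be a probability in [", lo, ", ", hi, "]")
  as.numeric(x)
}

# 1-based variant position -> membership test against 0-based half-open intervals.
# All BED-style interval handling is funnelled through these two.
pos1_to_0 <- function(pos) pos - 1L
pos0_to_1 <- function(pos) pos + 1L

# Bivariate normal log-density; mean length-2, sigma 2x2.
dmvnorm2_log <- function(z, mean, sigma) {
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  if (det_s <= 0) stop("covariance not positive definite")
  inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[2, 1], sigma[1, 1]), 2) / det_s
  d1 <- z[, 1] - mean[1]
  d2 <- z[, 2] - mean[2]
  quad <- inv[1, 1] * d1^2 + 2 * inv[1, 2] * d1 * d2 + inv[2, 2] * d2^2
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * quad
}
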