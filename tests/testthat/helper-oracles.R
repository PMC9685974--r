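# Independent oracles for the exact-inference engine, built on stats::dhyper
# and direct enumeration only -- they never touch the package's own
# noncentral hypergeometric code paths.

# two-sided minimum-likelihood p by central hypergeometric enumeration
brute_fisher_p <- function(a, b, c, d) {
  s <- a + c
  ks <- max(0, s - (c + d)):min(a + b, s)
  probs <- dhyper(ks, m = a + b, n = c + d, k = s)
  sum(probs[probs <= probs[ks == a] * (1 + 1e-7)])
}

# conditional-MLE oracle: dense grid search over log psi
grid_cmle <- function(a, b, c, d, lo = -10, hi = 10, n_grid = 8001) {
  s <- a + c
  ks <- max(0, s - (c + d)):min(a + b, s)
  logw <- lchoose(a + b, ks) + lchoose(c + d, s - ks)
  ts <- seq(lo, hi, length.out = n_grid)
  ll <- vapply(ts, function(t) {
    lw <- logw + ks * t
    lw[ks == a] - (max(lw) + log(sum(exp(lw - max(lw)))))
  }, numeric(1))
  exp(ts[which.max(ll)])
}

# tail probabilities for CI grid inversion
tail_ge <- function(a, b, c, d, psi) {
  s <- a + c
  ks <- max(0, s - (c + d)):min(a + b, s)
  lw <- lchoose(a + b, ks) + lchoose(c + d, s - ks) + ks * log(psi)
  w <- exp(lw - max(lw))
  sum(w[ks >= a]) / sum(w)
}
tail_le <- function(a, b, c, d, psi) {
  s <- a + c
  ks <- max(0, s - (c + d)):min(a + b, s)
  lw <- lchoose(a + b, ks) + lchoose(c + d, s - ks) + ks * log(psi)
  w <- exp(lw - max(lw))
  sum(w[ks <= a]) / sum(w)
}

# Benjamini-Hochberg by the direct step-up rejection rule
brute_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- suppressWarnings(max(which(p[o] <= seq_len(m) / m * alpha)))
  rejected <- logical(m)
  if (is.finite(k) && k >= 1) rejected[o[seq_len(k)]] <- TRUE
  rejected
}

# random valid 2x2 table with margins bounded by mx
random_table <- function(mx = 25) {
  m1 <- sample(1:mx, 1); m2 <- sample(1:mx, 1)
  a <- sample(0:m1, 1); c <- sample(0:m2, 1)
  c(a = a, b = m1 - a, c = c, d = m2 - c)
}

# minimal annotated variant table for cascade tests
toy_records <- function(n, ...) {
  variant_records(data.frame(
    chrom = "t", pos = seq_len(n), ref = "A", alt = "C",
    gene = sprintf("GENE%03d", seq_len(n)),
    consequence = "nonsynonymous_snv", cadd = 30,
    maf_reference = 0.001, qc_pass = TRUE, stringsAsFactors = FALSE, ...))
}
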