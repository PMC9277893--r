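# shared fixtures and independent oracles

# bimodal log-normal PI intensity sample with known truth
make_bimodal <- function(n_live, n_dead, fl = fluor_model(), seed = 1) {
  withr::with_seed(seed, {
    c(10^rnorm(n_live, fl$live_mu, fl$live_sigma),
      10^rnorm(n_dead, fl$dead_mu, fl$dead_sigma))
  })
}

# naive O(bins^2)-style Otsu oracle: scan every split of the pooled
# histogram and recompute class weights/means from scratch
otsu_naive <- function(intensities, bins = 512L) {
  x <- log10(intensities)
  br <- seq(min(x), max(x), length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  mids <- (br[-(bins + 1L)] + br[-1L]) / 2
  best <- -Inf; best_t <- NA_integer_
  for (t in seq_len(bins - 1L)) {
    n0 <- sum(cnt[1:t]); n1 <- sum(cnt[(t + 1L):bins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(cnt[1:t] * mids[1:t]) / n0
    mu1 <- sum(cnt[(t + 1L):bins] * mids[(t + 1L):bins]) / n1
    w0 <- n0 / (n0 + n1); w1 <- n1 / (n0 + n1)
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_t <- t }
  }
  10^br[best_t + 1L]
}

# dense trapezoid over the piecewise-linear interpolant (grid includes the
# knots, so it integrates the interpolant essentially exactly)
auc_dense_oracle <- function(day, survival, n_grid = 1e4) {
  f <- approxfun(day, survival)
  g <- sort(unique(c(seq(min(day), max(day), length.out = n_grid), day)))
  y <- f(g)
  sum(diff(g) * (head(y, -1) + tail(y, -1)) / 2)
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
phyper_enum_oracle <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# strain -> archetype map with n strains per class
make_mutant_map <- function(n_per_class,
                            classes = c("average", "short_lived", "long_lived")) {
  map <- rep(classes, each = n_per_class)
  names(map) <- sprintf("mut%03d", seq_along(map))
  map
}

# gene-set fixture: background g1..gN, one term = first K genes,
# hits = k genes from the term + (n - k) from outside it
enrich_fixture <- function(N, K, n, k, term = "T1") {
  genes <- sprintf("g%05d", seq_len(N))
  list(
    background = genes,
    collection = gene_set_collection(setNames(list(genes[seq_len(K)]), term)),
    hits = c(genes[seq_len(k)], genes[(K + 1):(K + n - k)])
  )
}
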