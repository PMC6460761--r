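# Independent oracle implementations used to cross-check the package.
# Deliberately written as plain loops over explicit frequency tables, not
# by calling any package internals.

# Nei-Chesser corrected heterozygosities and Hedrick standardization,
# from a list population -> vector of haplotype labels.
oracleGst <- function(hap_by_pop) {
  k <- length(hap_by_pop)
  alleles <- unique(unlist(hap_by_pop))
  n_j <- sapply(hap_by_pop, length)
  n_tilde <- k / sum(1 / n_j)
  freq <- matrix(0, k, length(alleles))
  for (j in seq_len(k)) {
    for (i in seq_along(alleles)) {
      freq[j, i] <- sum(hap_by_pop[[j]] == alleles[i]) / n_j[j]
    }
  }
  sum_p2 <- numeric(k)
  for (j in seq_len(k)) sum_p2[j] <- sum(freq[j, ]^2)
  hs <- (n_tilde / (n_tilde - 1)) * (1 - mean(sum_p2))
  pbar <- numeric(length(alleles))
  for (i in seq_along(alleles)) pbar[i] <- mean(freq[, i])
  ht <- 1 - sum(pbar^2) + hs / (n_tilde * k)
  ht <- max(ht, hs)
  gst <- if (ht > 0) (ht - hs) / ht else NA_real_
  gp <- if (is.na(gst)) NA_real_ else if (gst == 0) 0 else
    min(max(gst * (k - 1 + hs) / ((k - 1) * (1 - hs)), 0), 1)
  list(hs = hs, ht = ht, gst = gst, gprime = gp)
}

# textbook Gelman-Rubin PSRF, explicit sums
oraclePsrf <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  means <- sapply(chains, function(x) sum(x) / n)
  W <- 0
  for (x in chains) W <- W + sum((x - sum(x) / n)^2) / (n - 1)
  W <- W / m
  grand <- sum(means) / m
  B <- n * sum((means - grand)^2) / (m - 1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# ESS with explicit autocovariance sums and the same paired
# initial-positive-sequence truncation rule
oracleEss <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  c0 <- sum((x - mu)^2) / n
  rho <- function(t) sum((x[1:(n - t)] - mu) * (x[(t + 1):n] - mu)) / n / c0
  s <- 0
  t <- 1
  while (t + 1 <= min(n - 1, 1000)) {
    pair <- rho(t) + rho(t + 1)
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2
  }
  n / (1 + 2 * s)
}

# haplotype labels of an alignment, for feeding oracleGst
hapLabels <- function(aln, popmap) {
  seqs <- as.character(aln@sequences)
  split(seqs, as.character(popmap[sampleIds(aln)]))
}

# Exact posterior tail probability P(sigma_b2 > cut) for the two-island
# intercept-only model by 1-D quadrature: island effects and the grand
# mean are marginalized analytically (flat mean prior), the residual
# variance is held at its known value, and the half-Cauchy prior enters
# directly. Independent of the Gibbs sampler.
oracleSigmaB2Tail <- function(y, pop, s2w, hc_scale, cut) {
  yb <- tapply(y, pop, mean)
  nj <- tapply(y, pop, length)
  stopifnot(length(yb) == 2)
  loglik <- function(sb2)
    dnorm(yb[1] - yb[2], 0, sqrt(sum(sb2 + s2w / nj)), log = TRUE)
  sb_grid <- exp(seq(log(1e-5), log(1e5), length.out = 8000))
  lp <- sapply(sb_grid, function(s) loglik(s^2)) +
    dcauchy(sb_grid, 0, hc_scale, log = TRUE)
  w <- exp(lp - max(lp)) * sb_grid            # log-grid Jacobian
  sum(w[sb_grid^2 > cut]) / sum(w)
}
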