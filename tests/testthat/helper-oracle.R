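# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths: plain loops, no vectorized sharing with the implementation.

# density of a 5-component normal mixture, one point at a time
oracle_mixture_density <- function(y, mu, sigma2, pi) {
  vapply(y, function(yi) {
    tot <- 0
    for (j in 1:5) tot <- tot + pi[j] * stats::dnorm(yi, mu[j], sqrt(sigma2))
    tot
  }, numeric(1))
}

# posterior matrix by direct evaluation of the Bayes formula
oracle_posteriors <- function(y, mu, sigma2, pi) {
  out <- matrix(NA_real_, length(y), 5)
  for (i in seq_along(y)) {
    if (is.na(y[i])) next
    f <- numeric(5)
    for (j in 1:5) f[j] <- pi[j] * stats::dnorm(y[i], mu[j], sqrt(sigma2))
    out[i, ] <- f / sum(f)
  }
  out
}

# textbook single-population 5-component Gaussian mixture EM with shared
# variance; mirrors the convergence protocol (E-step, likelihood check,
# M-step) but shares no code with the package engine
oracle_gmm_em <- function(y, mu, sigma2, pi, tol = 1e-9, max_iter = 1000,
                          floor = 1e-6) {
  y <- y[!is.na(y)]
  n <- length(y)
  ll_prev <- -Inf
  iter <- 0
  repeat {
    f <- matrix(0, n, 5)
    for (j in 1:5) f[, j] <- pi[j] * stats::dnorm(y, mu[j], sqrt(sigma2))
    ll <- sum(log(rowSums(f)))
    if (iter > 0 && abs(ll - ll_prev) < tol) break
    if (iter >= max_iter) break
    ll_prev <- ll
    iter <- iter + 1
    p <- f / rowSums(f)
    w <- colSums(p)
    for (j in 1:5) if (w[j] > 1e-12) mu[j] <- sum(p[, j] * y) / w[j]
    s2 <- 0
    for (j in 1:5) s2 <- s2 + sum(p[, j] * (y - mu[j])^2)
    sigma2 <- max(s2 / n, floor)
    pi <- w / n
  }
  list(mu = mu, sigma2 = sigma2, pi = pi, loglik = ll, n_iter = iter)
}

# Expected F1 segregation by exhaustive enumeration of gamete pairs:
# every unordered pair of 2 chromosomes from each parent, counted equally.
oracle_f1_counts <- function(d1, d2) {
  gam <- function(d) {
    alleles <- c(rep(1, d), rep(0, 4 - d))
    out <- integer(0)
    for (a in 1:3) for (b in (a + 1):4) {
      out <- c(out, alleles[a] + alleles[b])
    }
    out
  }
  g1 <- gam(d1)
  g2 <- gam(d2)
  counts <- integer(5)
  for (x in g1) for (y in g2) counts[x + y + 1] <- counts[x + y + 1] + 1L
  counts
}
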