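# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package (normal equations instead of QR,
# a plain Newton loop instead of glm.fit) so agreement is a real check.

oracle_ols <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(sigma2 * diag(solve(crossprod(X))))
  list(coefficients = drop(beta), se = se)
}

oracle_irls <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    step <- solve(crossprod(X, w * X), crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(crossprod(X, plogis(drop(X %*% beta)) *
                                    plogis(-drop(X %*% beta)) * X))))
  list(coefficients = beta, se = se)
}

# classical NOIA dominance coding over the ordered classes 11, 12, 21, 22,
# valid when the two heterozygote classes have equal frequency
oracle_noia_dom <- function(q) {
  p11 <- q[1]; h <- q[2] + q[3]; p22 <- q[4]
  D <- p11 + p22 - (p11 - p22)^2
  unname(c(-2 * h * p22 / D, 4 * p11 * p22 / D, 4 * p11 * p22 / D,
           -2 * p11 * h / D))
}

# brute-force variance of a genotype-indexed value under a distribution q
oracle_var <- function(vals, q) sum(q * vals^2) - sum(q * vals)^2

# functional-POE effects from genotypic values, straight from the verbal
# contrast definitions (independent of any design matrix)
oracle_func_effects <- function(G) {
  c(intercept = unname(G[1]),
    add = unname((G[4] - G[1]) / 2),
    poe = unname(G[2] - G[3]),
    dom = unname((G[2] + G[3]) / 2 - (G[1] + G[4]) / 2))
}

# all four ordered genotype classes, one row each
all_genotypes <- function() list(n_m = c(0L, 0L, 1L, 1L),
                                 n_f = c(0L, 1L, 0L, 1L))

# dataset with exact genotype counts (deterministic composition)
counts_dataset <- function(n11, n12, n21, n22, phenotype = NULL,
                           trait_kind = "auto") {
  idx <- rep(1:4, c(n11, n12, n21, n22))
  g <- all_genotypes()
  if (is.null(phenotype)) phenotype <- seq_along(idx)
  poe_data(phenotype, g$n_m[idx], g$n_f[idx], trait_kind = trait_kind)
}

# plain named q-vector from a genotype_freqs object (attributes stripped)
qvec <- function(freqs) {
  q <- unclass(freqs)
  attributes(q) <- list(names = names(q))
  q
}
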