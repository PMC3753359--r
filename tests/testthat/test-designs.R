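test_that("functional POE design encodes the verbal contrasts", {
  X <- poe_design(all_genotypes(), "func_poe")
  expect_equal(X[1, ], c(intercept = 1, add = 0, poe = 0, dom = 0))
  expect_equal(X[2, ], c(intercept = 1, add = 1, poe = 0.5, dom = 1))
  expect_equal(X[3, ], c(intercept = 1, add = 1, poe = -0.5, dom = 1))
  expect_equal(X[4, ], c(intercept = 1, add = 2, poe = 0, dom = 0))
  # the design must reproduce arbitrary genotypic values from the contrast
  # definitions (R = G11, a = (G22-G11)/2, i = G12-G21, d = het vs hom mean)
  set.seed(1)
  for (rep in 1:20) {
    G <- rnorm(4, sd = 5)
    eff <- oracle_func_effects(G)
    expect_equal(drop(X %*% eff), G, tolerance = 1e-12)
  }
  # Table-style generative check
  expect_equal(unname(genotypic_values("func_poe", c(90, 3, -3, 1.2))),
               c(90, 92.7, 95.7, 96))
  expect_equal(unname(genotypic_values("func_poe", c(0, 1, 0, 0))),
               c(0, 1, 1, 2))
})

test_that("functional usual design ignores parental origin", {
  X <- poe_design(all_genotypes(), "func_usual")
  expect_equal(X[4, ], c(intercept = 1, add = 2, dom = 0))
  # invert the 3-class system: G = (0, 1.5, 2) -> (R, a, d) = (0, 1, 0.5)
  eff <- solve(X[c(1, 2, 4), ], c(0, 1.5, 2))
  expect_equal(unname(eff), c(0, 1, 0.5))
  expect_equal(unname(genotypic_values("func_usual", c(5, 0, 0))),
               rep(5, 4))
})

test_that("statistical POE design: centered columns and NOIA dominance", {
  q5 <- ordered_genotype_probs(0.5)
  X <- poe_design(all_genotypes(), "stat_poe", q5)
  expect_equal(unname(X[, "add"]), c(-1, 0, 0, 1))
  expect_equal(unname(X[, "poe"]), c(0, 1, -1, 0))
  expect_equal(unname(X[, "dom"]), c(-0.5, 0.5, 0.5, -0.5))

  q28 <- ordered_genotype_probs(0.28)
  X28 <- poe_design(all_genotypes(), "stat_poe", q28)
  expect_equal(unname(X28[, "add"]), c(-0.56, 0.44, 0.44, 1.44))
  # dominance column agrees with the classical closed form at q12 = q21
  for (p in c(0.03, 0.28, 0.48, 0.5)) {
    q <- ordered_genotype_probs(p)
    Xp <- poe_design(all_genotypes(), "stat_poe", q)
    expect_equal(unname(Xp[, "dom"]), oracle_noia_dom(qvec(q)),
                 tolerance = 1e-12)
    Xu <- poe_design(all_genotypes(), "stat_usual", q)
    expect_equal(unname(Xu[, "dom"]), oracle_noia_dom(qvec(q)),
                 tolerance = 1e-12)
  }
  # frequency-weighted column means vanish (centering)
  qv <- unclass(q28)
  expect_lt(max(abs(colSums(qv * X28[, -1]))), 1e-14)
})

test_that("degenerate frequencies drop the dominance column with a report", {
  q <- genotype_freqs(0.6, 0, 0, 0.4)  # no heterozygotes in the population
  X <- poe_design(all_genotypes(), "stat_poe", q)
  expect_false("dom" %in% colnames(X))
  expect_identical(attr(X, "dropped"), "dom")
})

test_that("reconstruction: effects -> G -> effects is the identity", {
  freqs <- list(NULL, ordered_genotype_probs(0.28), NULL,
                ordered_genotype_probs(0.28))
  names(freqs) <- c("func_poe", "stat_poe", "func_usual", "stat_usual")
  set.seed(2)
  for (model in names(freqs)) {
    Xu <- poe_design(all_genotypes(), model, freqs[[model]])
    k <- ncol(Xu)
    rows <- if (k == 4) 1:4 else c(1, 2, 4)
    expect_equal(qr(Xu[rows, ])$rank, k)
    for (rep in 1:10) {
      eff <- rnorm(k)
      G <- drop(Xu %*% eff)
      back <- solve(Xu[rows, ], G[rows])
      expect_equal(unname(back), eff, tolerance = 1e-10)
    }
  }
})

test_that("effect transformations preserve genotypic values and round-trip", {
  f <- ordered_genotype_probs(0.28)
  eff <- c(90, 3, -3, 1.2)
  st <- transform_effects(eff, "func_poe", "stat_poe", f)
  expect_equal(unname(genotypic_values("stat_poe", st, f)),
               unname(genotypic_values("func_poe", eff)), tolerance = 1e-10)
  back <- transform_effects(st, "stat_poe", "func_poe", f)
  expect_equal(unname(back), eff, tolerance = 1e-10)
  # POE proportionality alpha2 = i/2 whenever q12 = q21
  expect_equal(unname(st["poe"]), -1.5)
  # usual <-> usual: dominance unchanged, additive shifted by a d-term
  us <- transform_effects(c(0, 1, 0.5), "func_usual", "stat_usual", f)
  expect_equal(unname(us["dom"]), 0.5)
  expect_false(isTRUE(all.equal(unname(us["add"]), 1)))
  us0 <- transform_effects(c(0, 1, 0), "func_usual", "stat_usual", f)
  expect_equal(unname(us0["add"]), 1)  # no dominance, no shift
  expect_error(transform_effects(eff, "func_poe", "stat_usual", f),
               "same genotypic-value space")
})

test_that("statistical POE Gram matrix is diagonal under HWE, not otherwise", {
  for (p in c(0.03, 0.28, 0.48, 0.5)) {
    g <- orthogonality_gram("stat_poe", ordered_genotype_probs(p))
    expect_lt(g$max_offdiag, 1e-12)
  }
  # q12 != q21: the add x poe entry equals Var(n_f) - Var(n_m)
  q <- genotype_freqs(0.4, 0.3, 0.2, 0.1)
  g <- orthogonality_gram("stat_poe", q)
  pf <- p_paternal(q); pm <- p_maternal(q)
  expect_equal(g$gram["add", "poe"], pf * (1 - pf) - pm * (1 - pm),
               tolerance = 1e-12)
  # the functional design is not orthogonal even under HWE
  gf <- orthogonality_gram("func_poe", ordered_genotype_probs(0.28))
  expect_gt(abs(gf$gram["add", "dom"]), 1e-3)
})

test_that("maternal/paternal allelic split round-trips", {
  expect_equal(maternal_paternal_effects(a = 3, i = -3),
               c(a_m = 4.5, a_f = 1.5))
  expect_equal(allelic_to_poe_effects(a_m = 2, a_f = 2), c(a = 2, i = 0))
  set.seed(3)
  for (rep in 1:20) {
    ai <- rnorm(2)
    mp <- maternal_paternal_effects(ai[1], ai[2])
    expect_equal(unname(allelic_to_poe_effects(mp["a_m"], mp["a_f"])), ai)
  }
})
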