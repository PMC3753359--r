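test_that("presets reproduce the study configurations", {
  s1 <- scenario_preset("quant-strong")
  expect_equal(unname(s1$effects), c(90, 3, -3, 1.2))
  expect_equal(s1$residual_variance, 144)
  expect_equal(s1$n_individuals, 2000)
  expect_equal(s1$maf, 0.28)
  expect_equal(unname(scenario_preset("quant-moderate")$effects["poe"]), -2)
  expect_equal(unname(scenario_preset("quant-weak")$effects["poe"]), -1)
  cc <- scenario_preset("cc-weak", maf = 0.48)
  expect_equal(unname(cc$effects[c("add", "poe", "dom")]), c(2, -0.6, 0.5))
  expect_equal(cc$n_cases, 1000)
  expect_equal(cc$maf, 0.48)
  expect_identical(scenario_preset("quant-1")$effects,
                   scenario_preset("quant-strong")$effects)
  expect_error(scenario_preset("nope"), "unknown preset")
  expect_error(poe_scenario("binary", c(0, 1, 0, 0), 0.3, n_cases = 0,
                            n_controls = 10), "n_cases")
})

test_that("quantitative generator: genotypic values plus Gaussian noise", {
  sc0 <- poe_scenario("quantitative", c(90, 3, -3, 1.2), 0.28,
                      residual_variance = 0, n_individuals = 500)
  set.seed(20)
  d <- simulate_quantitative(sc0)
  G <- genotypic_values("func_poe", sc0$effects)
  expect_equal(d$phenotype, unname(G[genotype_code(d$n_m, d$n_f)]))

  set.seed(21)
  sc <- poe_scenario("quantitative", c(90, 3, -3, 1.2), 0.28,
                     residual_variance = 144, n_individuals = 1e5)
  d <- simulate_quantitative(sc)
  q <- qvec(ordered_genotype_probs(0.28))
  # brute force over the four genotypes:
  # 0.5184*90 + 0.2016*92.7 + 0.2016*95.7 + 0.0784*96
  mu <- sum(q * G)
  expect_equal(mu, 92.16384)
  se_mean <- sqrt((144 + oracle_var(G, q)) / 1e5)
  expect_lt(abs(mean(d$phenotype) - mu), 4 * se_mean)
  # genotype class proportions match HWE within binomial error
  props <- as.vector(table(factor(genotype_code(d$n_m, d$n_f),
                                  c("11", "12", "21", "22")))) / 1e5
  expect_true(all(abs(props - q) < 4 * sqrt(q * (1 - q) / 1e5)))
  # empirical phenotype variance ties to the variance decomposition
  st <- transform_effects(sc$effects, "func_poe", "stat_poe",
                          ordered_genotype_probs(0.28))
  vt <- variance_components(st, ordered_genotype_probs(0.28))$V_total
  expect_lt(abs(var(d$phenotype) - (144 + vt)), 4 * (144 + vt) *
              sqrt(2 / 1e5))
})

test_that("penetrance table follows the logistic/Bayes construction", {
  # constant penetrance cancels in the conditioning
  pt0 <- penetrance_table(c(0.7, 0, 0, 0), 0.28)
  q <- qvec(ordered_genotype_probs(0.28))
  expect_equal(unname(pt0$case_dist), unname(q), tolerance = 1e-12)
  expect_equal(unname(pt0$control_dist), unname(q), tolerance = 1e-12)

  # additive log(2) at maf 1/2: direct arithmetic over four genotypes
  pt <- penetrance_table(c(0, log(2), 0, 0), 0.5)
  expect_equal(unname(pt$penetrance), c(0.5, 2/3, 2/3, 0.8),
               tolerance = 1e-12)
  cw <- 0.25 * c(0.5, 2/3, 2/3, 0.8)
  expect_equal(unname(pt$case_dist), cw / sum(cw), tolerance = 1e-12)
  kw <- 0.25 * (1 - c(0.5, 2/3, 2/3, 0.8))
  expect_equal(unname(pt$control_dist), kw / sum(kw), tolerance = 1e-12)

  # saturated positive baseline: cases mirror the population and the
  # control distribution stays finite through the negated-logit complement
  pt_hi <- penetrance_table(c(100, 2, -2, 0.5), 0.28)
  expect_equal(unname(pt_hi$case_dist), unname(q), tolerance = 1e-10)
  expect_true(all(is.finite(pt_hi$control_dist) & pt_hi$control_dist > 0))
  # and the mirrored rare-disease baseline enriches cases by exp(G - G11)
  pt_lo <- penetrance_table(c(-100, 2, -2, 0.5), 0.28)
  G <- genotypic_values("func_poe", c(0, 2, -2, 0.5))
  expw <- q * exp(G)
  expect_equal(unname(pt_lo$case_dist), unname(expw / sum(expw)),
               tolerance = 1e-10)
  expect_equal(unname(pt_lo$control_dist), unname(q), tolerance = 1e-10)

  # distributions stay proper across extreme baselines
  for (R in c(-100, 0, 100)) {
    pt <- penetrance_table(c(R, 2, -2, 0.5), 0.28)
    expect_equal(sum(pt$case_dist), 1, tolerance = 1e-12)
    expect_equal(sum(pt$control_dist), 1, tolerance = 1e-12)
    expect_true(all(pt$case_dist >= 0 & pt$control_dist >= 0))
  }
})

test_that("case-control generator draws from the conditional distributions", {
  sc0 <- poe_scenario("binary", c(-100, 0, 0, 0), 0.28,
                      n_cases = 2000, n_controls = 2000)
  set.seed(22)
  d <- simulate_case_control(sc0)
  q <- qvec(ordered_genotype_probs(0.28))
  props <- as.vector(table(factor(genotype_code(d$n_m, d$n_f),
                                  c("11", "12", "21", "22")))) / 4000
  expect_true(all(abs(props - q) < 4 * sqrt(q * (1 - q) / 4000)))

  # control genotype log-ratios recover -(G_g - G_g') for a rare disease
  set.seed(23)
  sc <- poe_scenario("binary", c(100, 2, -2, 0.5), 0.28,
                     n_cases = 1e5, n_controls = 1e5)
  d <- simulate_case_control(sc)
  ctrl <- d[d$phenotype == 0, ]
  counts <- table(factor(genotype_code(ctrl$n_m, ctrl$n_f),
                         c("11", "12", "21", "22")))
  G <- genotypic_values("func_poe", sc$effects)
  lr <- log(counts[["12"]] / counts[["11"]]) - log(q[2] / q[1])
  expect_lt(abs(lr - (-(G[2] - G[1]))), 0.1)

  expect_error(poe_scenario("binary", c(0, 1, 1, 0), 0.3,
                            n_cases = 10, n_controls = 0), "n_controls")
})

test_that("simulation is reproducible from the seed", {
  sc <- scenario_preset("quant-strong")
  set.seed(99); d1 <- simulate_quantitative(sc)
  set.seed(99); d2 <- simulate_quantitative(sc)
  expect_identical(d1, d2)
  sb <- scenario_preset("cc-strong")
  set.seed(99); b1 <- simulate_case_control(sb)
  set.seed(99); b2 <- simulate_case_control(sb)
  expect_identical(b1, b2)
})
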