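#' Simulation scenario for a one-locus study
#'
#' A scenario bundles the generative configuration: the functional POE
#' effects \eqn{(R, a, i, d)} (the genotypic values are
#' \eqn{G = X_{func} (R, a, i, d)'}), the minor allele frequency (genotypes
#' are drawn from the HWE ordered-genotype distribution), and either the
#' residual variance and sample size (quantitative trait) or the case and
#' control counts (binary trait, penetrance-based sampling; see
#' [penetrance_table()]).
#'
#' @param trait_kind `"quantitative"` or `"binary"`.
#' @param effects functional effect vector `c(R, a, i, d)`; for a binary
#'   trait these are log-odds (logit) effects.
#' @param maf minor allele frequency, in (0, 1).
#' @param residual_variance residual variance \eqn{\sigma^2} (quantitative;
#'   0 is allowed, giving noise-free phenotypes).
#' @param n_individuals individuals per replicate (quantitative).
#' @param n_cases,n_controls counts per replicate (binary).
#' @return a list of class `"poe_scenario"`.
#' @seealso [scenario_preset()] for the study presets.
#' @export
poe_scenario <- function(trait_kind = c("quantitative", "binary"), effects,
                         maf, residual_variance = NULL, n_individuals = NULL,
                         n_cases = NULL, n_controls = NULL) {
  trait_kind <- match.arg(trait_kind)
  if (length(effects) != 4L || !is.numeric(effects) || anyNA(effects))
    stop("'effects' must be numeric c(R, a, i, d)")
  if (!is.numeric(maf) || length(maf) != 1 || maf <= 0 || maf >= 1)
    stop("'maf' must lie strictly between 0 and 1")
  effects <- stats::setNames(as.numeric(effects),
                             c("intercept", "add", "poe", "dom"))
  if (trait_kind == "quantitative") {
    if (is.null(residual_variance) || residual_variance < 0)
      stop("quantitative scenarios need residual_variance >= 0")
    if (is.null(n_individuals) || n_individuals < 1)
      stop("quantitative scenarios need n_individuals >= 1")
  } else {
    if (is.null(n_cases) || n_cases < 1 || is.null(n_controls) ||
        n_controls < 1)
      stop("binary scenarios need n_cases >= 1 and n_controls >= 1")
  }
  structure(list(trait_kind = trait_kind, effects = effects, maf = maf,
                 residual_variance = residual_variance,
                 n_individuals = n_individuals, n_cases = n_cases,
                 n_controls = n_controls),
            class = "poe_scenario")
}

#' @export
print.poe_scenario <- function(x, ...) {
  cat(sprintf("poe_scenario (%s trait), MAF = %g\n", x$trait_kind, x$maf))
  cat("effects (R, a, i, d):", paste(x$effects, collapse = ", "), "\n")
  if (x$trait_kind == "quantitative")
    cat(sprintf("sigma^2 = %g, n = %d\n", x$residual_variance,
                x$n_individuals))
  else
    cat(sprintf("%d cases + %d controls\n", x$n_cases, x$n_controls))
  invisible(x)
}

#' Named study scenarios
#'
#' Preset generative configurations used throughout the package's power and
#' type-I-error studies:
#'
#' * `"quant-strong"` / `"quant-moderate"` / `"quant-weak"` (aliases
#'   `"quant-1/2/3"`): quantitative trait, effects
#'   (90.0, 3.0, i, 1.2) with POE i = -3, -2, -1, residual variance 144.0,
#'   2000 individuals per replicate.
#' * `"cc-strong"` / `"cc-weak"` (aliases `"cc-1/2"`): case-control trait,
#'   logit effects (-100.0, 2.0, i, 0.5) with POE i = -2, -0.6,
#'   1000 cases + 1000 controls. The baseline log-odds is large and
#'   negative -- a rare disease -- so case genotypes are enriched
#'   proportionally to exp(G) while controls mirror the population; results
#'   are invariant to the baseline's magnitude once it is extreme (see the
#'   methods vignette).
#' * `"quant-null"` / `"cc-null"`: all genetic effects zero (additive, POE
#'   and dominance), for type-I-error studies.
#'
#' @param name preset name.
#' @param maf minor allele frequency; the study default is 0.28, with 0.03
#'   and 0.48 as the standard variants.
#' @return a [poe_scenario()].
#' @examples
#' scenario_preset("quant-strong")
#' scenario_preset("cc-weak", maf = 0.48)
#' @export
scenario_preset <- function(name, maf = 0.28) {
  key <- c("quant-1" = "quant-strong", "quant-2" = "quant-moderate",
           "quant-3" = "quant-weak", "cc-1" = "cc-strong", "cc-2" = "cc-weak")
  if (name %in% names(key)) name <- key[[name]]
  switch(name,
    "quant-strong" = poe_scenario("quantitative", c(90, 3, -3, 1.2), maf,
                                  residual_variance = 144,
                                  n_individuals = 2000),
    "quant-moderate" = poe_scenario("quantitative", c(90, 3, -2, 1.2), maf,
                                    residual_variance = 144,
                                    n_individuals = 2000),
    "quant-weak" = poe_scenario("quantitative", c(90, 3, -1, 1.2), maf,
                                residual_variance = 144,
                                n_individuals = 2000),
    "quant-null" = poe_scenario("quantitative", c(90, 0, 0, 0), maf,
                                residual_variance = 144,
                                n_individuals = 2000),
    "cc-strong" = poe_scenario("binary", c(-100, 2, -2, 0.5), maf,
                               n_cases = 1000, n_controls = 1000),
    "cc-weak" = poe_scenario("binary", c(-100, 2, -0.6, 0.5), maf,
                             n_cases = 1000, n_controls = 1000),
    "cc-null" = poe_scenario("binary", c(-100, 0, 0, 0), maf,
                             n_cases = 1000, n_controls = 1000),
    stop("unknown preset: ", name)
  )
}

# draw n ordered genotypes (class indices 1..4) from a distribution
.draw_genotypes <- function(n, prob) {
  sample.int(4L, n, replace = TRUE, prob = prob)
}

#' Simulate a quantitative-trait dataset
#'
#' Each individual's ordered genotype is drawn i.i.d. from the HWE
#' distribution at the scenario's minor allele frequency; the phenotype is
#' the functional-POE genotypic value plus Normal(0, \eqn{\sigma^2}) noise.
#' Randomness comes from the current RNG stream: call `set.seed()` first for
#' reproducibility.
#'
#' @param scenario a quantitative [poe_scenario()].
#' @return a [poe_data()] dataset.
#' @examples
#' set.seed(1)
#' simulate_quantitative(scenario_preset("quant-strong"))
#' @export
simulate_quantitative <- function(scenario) {
  stopifnot(inherits(scenario, "poe_scenario"))
  if (scenario$trait_kind != "quantitative")
    stop("scenario is not quantitative")
  q <- ordered_genotype_probs(scenario$maf)
  G <- genotypic_values("func_poe", scenario$effects)
  idx <- .draw_genotypes(scenario$n_individuals, unclass(q))
  y <- G[idx]
  if (scenario$residual_variance > 0)
    y <- y + stats::rnorm(length(idx), 0, sqrt(scenario$residual_variance))
  poe_data(y, .GT_NM[idx], .GT_NF[idx], trait_kind = "quantitative")
}

#' Penetrance table and case/control genotype distributions
#'
#' The penetrance of ordered genotype g is the logistic of its genotypic
#' value, \eqn{f_g = logistic(G_g)} with
#' \eqn{G = X_{func}(R, a, i, d)'} on the log-odds scale. By Bayes' theorem
#' the genotype distribution among cases is \eqn{q_g f_g / \sum q f} and
#' among controls \eqn{q_g (1 - f_g) / \sum q (1 - f)}. The complement
#' \eqn{1 - f_g} is computed as \eqn{logistic(-G_g)}: at extreme baselines
#' the naive difference underflows to exactly zero and would leave the
#' control distribution 0/0, whereas the negated-logit form keeps the
#' *relative* control frequencies (proportional to \eqn{q_g e^{-G_g}})
#' well-defined for any finite effects.
#'
#' @param effects functional log-odds effects `c(R, a, i, d)`.
#' @param maf minor allele frequency in (0, 1).
#' @return list of class `"poe_penetrance"` with `penetrance`, `case_dist`,
#'   `control_dist` (each a named length-4 vector over 11, 12, 21, 22).
#' @examples
#' penetrance_table(c(0, log(2), 0, 0), maf = 0.5)
#' @export
penetrance_table <- function(effects, maf) {
  if (maf <= 0 || maf >= 1) stop("'maf' must lie strictly between 0 and 1")
  q <- .q4(ordered_genotype_probs(maf))
  G <- genotypic_values("func_poe", effects)
  f <- stats::plogis(G)
  fc <- stats::plogis(-G)  # 1 - f, underflow-safe
  case_w <- q * f
  ctrl_w <- q * fc
  if (sum(case_w) <= 0 || sum(ctrl_w) <= 0)
    stop("degenerate penetrances: one sampling stratum has zero mass")
  structure(list(penetrance = stats::setNames(f, .GT_CODES),
                 case_dist = stats::setNames(case_w / sum(case_w), .GT_CODES),
                 control_dist = stats::setNames(ctrl_w / sum(ctrl_w),
                                                .GT_CODES)),
            class = "poe_penetrance")
}

#' @export
print.poe_penetrance <- function(x, ...) {
  tab <- rbind(penetrance = x$penetrance, cases = x$case_dist,
               controls = x$control_dist)
  print(signif(tab, 6))
  invisible(x)
}

#' Simulate a case-control dataset
#'
#' Draws `n_cases` ordered genotypes from the case genotype distribution and
#' `n_controls` from the control distribution of [penetrance_table()];
#' disease status is 1 for cases and 0 for controls. Randomness comes from
#' the current RNG stream.
#'
#' @param scenario a binary [poe_scenario()].
#' @return a [poe_data()] dataset with a binary trait.
#' @examples
#' set.seed(1)
#' simulate_case_control(scenario_preset("cc-strong"))
#' @export
simulate_case_control <- function(scenario) {
  stopifnot(inherits(scenario, "poe_scenario"))
  if (scenario$trait_kind != "binary") stop("scenario is not binary")
  pt <- penetrance_table(scenario$effects, scenario$maf)
  idx <- c(.draw_genotypes(scenario$n_cases, pt$case_dist),
           .draw_genotypes(scenario$n_controls, pt$control_dist))
  y <- rep(c(1, 0), c(scenario$n_cases, scenario$n_controls))
  poe_data(y, .GT_NM[idx], .GT_NF[idx], trait_kind = "binary")
}

#' Simulate a dataset from any scenario
#' @param scenario a [poe_scenario()].
#' @return a [poe_data()] dataset.
#' @export
simulate_scenario <- function(scenario) {
  if (scenario$trait_kind == "quantitative") simulate_quantitative(scenario)
  else simulate_case_control(scenario)
}
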