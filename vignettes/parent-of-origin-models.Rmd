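---
title: "Modelling parent-of-origin effects with orthogonal one-locus designs"
author: "noiapoe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling parent-of-origin effects with orthogonal one-locus designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noiapoe)
```

## The problem

A locus shows a parent-of-origin effect (POE) when the same allele affects
the phenotype differently depending on whether it was transmitted by the
mother or the father; genomic imprinting is the best-known cause. Standard
association models collapse the two heterozygotes into one class and cannot
see this. Working with *ordered* genotypes -- 11, 12, 21, 22, first digit
maternal, allele 2 the minor/variant allele -- restores the information,
at the price of one extra parameter and, if the coding is chosen carelessly,
correlated effect estimates.

This package implements four codings of the genotype-phenotype map
$y = G + \varepsilon$ (or $\mathrm{logit}\,P(D=1) = G$ for disease traits),
where $G_{jk}$ is the genotypic value of ordered genotype $jk$.

## The four models

Writing $N_m, N_f \in \{0, 1\}$ for the maternal and paternal variant-allele
counts, $N = N_m + N_f$, and $H = 1\{N = 1\}$:

* **Func-POE** (functional, with POE): columns
  $(1,\; N,\; (N_f - N_m)/2,\; H)$ with coefficients $(R, a, i, d)$. These
  are direct allele-substitution contrasts: $R = G_{11}$,
  $a = (G_{22} - G_{11})/2$, $i = G_{12} - G_{21}$ (paternal-origin minus
  maternal-origin variant), $d = (G_{12} + G_{21})/2 - (G_{11} + G_{22})/2$.
* **Func-Usual**: the same without the POE column.
* **Stat-POE** (statistical/NOIA, with POE): the additive and POE columns
  are centred at their population means,
  $N - E[N]$ and $(N_f - N_m) - E[N_f - N_m]$, and the dominance column is
  the heterozygote indicator orthogonalized against the other three columns
  under the genotype-frequency weighting, then scaled so that its
  coefficient equals the functional $d$.
* **Stat-Usual**: the same without the POE column.

Under Hardy-Weinberg equilibrium (HWE) -- or more generally whenever the two
heterozygote classes are equally frequent, or the allele frequency is 1/2 --
the frequency-weighted cross-products of the Stat-POE columns all vanish
(`orthogonality_gram()`), so the estimates are uncorrelated: adding or
removing the POE term leaves the additive test unchanged. The genetic
variance then decomposes exactly (`variance_components()`):

$$V_G = V_{A1} + V_{A2} + V_D
      = \alpha_1^2\,\mathrm{Var}(N) + \alpha_2^2\,\mathrm{Var}(N_f - N_m)
        + \delta^2\,\mathrm{Var}(w_{dom}).$$

When $q_{12} \neq q_{21}$ the additive and POE columns acquire the
covariance $p_f(1-p_f) - p_m(1-p_m)$ and the decomposition no longer sums to
$V_G$; the Gram matrix makes the failure visible and quantifiable.

```{r}
f <- ordered_genotype_probs(0.28)
orthogonality_gram("stat_poe", f)
variance_components(transform_effects(c(90, 3, -3, 1.2),
                                      "func_poe", "stat_poe", f), f)
```

### Parameterization choices

Four choices were genuinely open and are fixed as follows:

* **Column scalings.** The functional POE column is $(N_f - N_m)/2$ so the
  coefficient equals $i$ exactly; the statistical POE column is the centred
  $(N_f - N_m)$, so under equal heterozygote frequencies
  $\alpha_2 = i/2$. Wald statistics and power are invariant to column
  scale, so only scale-free quantities are compared against external
  benchmarks. The statistical additive column is centred but not
  variance-standardized: centring is what drives the orthogonality
  argument, and standardization would only rescale coefficients.
* **Dominance column by projection, not by formula.** The statistical
  dominance column is computed as the frequency-weighted least-squares
  residual of $H$ on the other columns (a joint projection -- the columns
  need not be mutually orthogonal). At $q_{12} = q_{21}$ this reproduces
  the classical NOIA closed form
  $(-2 h q_{22}/D,\; 4 q_{11} q_{22}/D,\; -2 q_{11} h/D)$ with
  $h = q_{12} + q_{21}$, $D = q_{11} + q_{22} - (q_{11} - q_{22})^2$
  (a regression test enforces this), and it remains well-defined for
  arbitrary frequencies. A useful consequence of the joint projection is
  that the dominance coefficient equals the functional $d$ for *any*
  frequency vector. If the population has no heterozygotes (or nothing but
  heterozygotes) the column is undefined and is dropped with a report.
* **Transformations as basis changes.** `transform_effects()` inverts the
  target design numerically instead of using transcribed closed-form
  matrices; preservation of genotypic values and exact round-trips are the
  correctness criteria.
* **Design frequencies.** Inside simulation studies the designs use the
  exact generating population frequencies, matching the framework's
  population-parameter definitions; for user data the default is empirical
  sample proportions, with an HWE-constrained alternative
  (`estimate_frequencies()`).

## Inference

`fit_poe()` fits by ordinary least squares (quantitative traits) or
logistic regression via iteratively reweighted least squares (binary), and
reports per-coefficient Wald tests $z = \hat\beta/\widehat{SE}$ with
two-sided normal p-values; $z^2$ against $\chi^2_1$ is identical and both
are reported. Numerical policy:

* Normal rather than $t$ reference for the linear model: at the design
  sample size of 2000 the difference is below $10^{-3}$ in the p-value.
* IRLS runs to a deviance tolerance of $10^{-12}$ with a 100-iteration cap;
  a coefficient beyond 30 on the logit scale is treated as separation and
  flagged `converged = FALSE`.
* Columns that are constant in the sample or linearly dependent on earlier
  columns are dropped via pivoted QR and reported as `aliased`, with `NA`
  tests. This matters at low minor-allele frequency: with MAF 0.03 and
  2000 individuals the 22-homozygote class is empty in a sizeable fraction
  of replicates, making the functional additive and dominance columns
  collinear.

## What the simulators emulate

`simulate_quantitative()` draws ordered genotypes i.i.d. from the HWE
distribution at the scenario's MAF (the population is assumed in HWE, so
the two heterozygote classes are equally likely) and adds Gaussian noise to
the Func-POE genotypic value. `simulate_case_control()` computes
per-genotype penetrances $f_g = \mathrm{logistic}(G_g)$ and draws case
genotypes from $q_g f_g/\sum q f$ and controls from
$q_g(1-f_g)/\sum q(1-f)$ (Bayes), with $1-f_g$ evaluated as
$\mathrm{logistic}(-G_g)$ so that extreme baselines do not underflow the
control weights to 0/0.

The preset scenarios (`scenario_preset()`) fix the study conditions:
quantitative effects $(90.0, 3.0, i, 1.2)$ with POE $i \in \{-3, -2, -1\}$,
residual variance 144.0, 2000 individuals per replicate; case-control logit
effects $(-100.0, 2.0, i, 0.5)$ with $i \in \{-2, -0.6\}$, 1000 cases +
1000 controls; MAF 0.28 by default with 0.03 and 0.48 variants;
1000 replicates for power and type-I-error studies.

**Why the case-control baseline is large and negative.** The Bayes sampling
construction is invariant to the magnitude of the baseline log-odds once it
is extreme -- only the genetic contrasts and the orientation survive. The
orientation matters, though: with a large *positive* baseline, penetrance
saturates at 1 for every genotype, the population is essentially all
diseased, and controls collapse onto the common-homozygote class (at MAF
0.28 the expected number of 22-homozygote controls per 1000 is about 2.5,
and the additive contrast becomes untestable in the ~8% of replicates with
none). A large *negative* baseline is the standard rare-disease situation:
controls mirror the population and cases are enriched for risk genotypes in
proportion to $e^{G}$. Only the rare-disease orientation is consistent with
retrospective case-control sampling -- the case fraction in the sample
(one half) then exceeds the population prevalence -- and it is the one under
which generative parameters are recovered cleanly (intercept aside, which
outcome-dependent sampling shifts by design). The presets therefore use
$-100.0$; `penetrance_table()` itself is generic and accepts any baseline.

What the generators deliberately do **not** model: departure from HWE,
linkage disequilibrium with neighbouring loci, covariates, family
structure, uncertainty in parental origin (phasing is taken as known), and
missing genotypes. Passing simulation benchmarks therefore says nothing
about robustness to phasing error or population stratification in real
data.

## Monte-Carlo engine

`run_power_study()` simulates replicates, fits one or more models to the
*same* replicate (so between-model comparisons are paired), and reports
per-coefficient rejection rates at each threshold, mean estimates and
empirical SEs. A master seed spawns one sub-seed per replicate, so any
replicate is reproducible in isolation and runs with the same seed are
bit-identical. Non-converged replicates are excluded from every
coefficient's denominator (and counted); a coefficient aliased in a
replicate is excluded from that coefficient's denominator only. A study
with more than 5% unusable replicates is flagged. `run_type1_study()`
zeroes the additive, POE *and* dominance effects -- the dominance effect
too, so that its own false-positive rate is meaningful -- and defaults to
the nominal level 0.05.

Problem sizes used in the shipped tests and the acceptance script: power
and type-I studies run the full 1000 replicates at the preset sample sizes;
cross-model invariance properties use 100-200 replicates; parameter
recovery uses a single replicate of $10^5$ individuals (or
$10^5 + 10^5$ cases/controls).

## Known limitations

* Orthogonality of the statistical coding for binary traits holds under
  the null but not under strong alternatives (the information weights
  re-weight the genotype classes), so case-control power comparisons
  between nested statistical models are approximate.
* The functional additive contrast is fragile when a homozygote class is
  nearly absent (rare variants in modest samples); the statistical coding
  degrades more gracefully. Both are reported honestly via aliasing flags
  rather than patched.
* Single locus only: no multi-locus (epistasis) or gene-environment
  extensions, no family-based designs, no inference of parental origin.
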