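#' noiapoe: orthogonal one-locus association models with parent-of-origin effects
#'
#' A gene is imprinted when the phenotypic effect of an allele depends on
#' whether it was transmitted by the mother or the father (a parent-of-origin
#' effect, POE). This package models a single diallelic locus through its four
#' *ordered* genotypes -- 11, 12, 21, 22, first digit maternal, allele "2" the
#' minor/variant allele -- and provides four genotype-phenotype regression
#' codings: the functional and statistical (NOIA) models, each with and
#' without a POE term. The statistical codings use population genotype
#' frequencies to make the effect estimates uncorrelated under
#' Hardy-Weinberg equilibrium, which yields an orthogonal decomposition of the
#' genetic variance and leaves the main-effect test unchanged when the POE
#' term is added. Simulators for quantitative traits and case-control
#' (penetrance-based) sampling, plus a Monte-Carlo power/type-I-error engine,
#' reproduce the framework's operating characteristics.
#'
#' @section Main entry points:
#' * [poe_data()], [read_poe_tsv()] -- datasets of ordered genotypes.
#' * [poe_design()], [transform_effects()], [variance_components()] -- models.
#' * [fit_poe()] -- Wald-test inference (linear or logistic).
#' * [poe_scenario()], [simulate_quantitative()], [simulate_case_control()].
#' * [run_power_study()], [run_type1_study()], [tabulate_power()].
#'
#' @docType package
#' @name noiapoe-package
#' @aliases noiapoe
#' @importFrom stats pnorm rnorm var glm.control ks.test
#' @importFrom utils read.delim write.table
"_PACKAGE"

# ordered genotype classes, in fixed order 11, 12, 21, 22
.GT_CODES <- c("11", "12", "21", "22")
.GT_NM <- c(0L, 0L, 1L, 1L)  # maternal variant-allele count
.GT_NF <- c(0L, 1L, 0L, 1L)  # paternal variant-allele count

#' Ordered genotype codes from parental allele counts
#'
#' The code is a two-digit label; the first digit is the maternal allele, the
#' second the paternal allele, with "2" the variant (minor) allele. So `12`
#' means the variant allele came from the father only.
#'
#' @param n_m integer vector of maternal variant-allele counts (0 or 1).
#' @param n_f integer vector of paternal variant-allele counts (0 or 1).
#' @return character vector of codes in `c("11", "12", "21", "22")`.
#' @examples
#' genotype_code(c(0, 0, 1, 1), c(0, 1, 0, 1))
#' @export
genotype_code <- function(n_m, n_f) {
  stopifnot(length(n_m) == length(n_f))
  if (!all(n_m %in% 0:1) || !all(n_f %in% 0:1))
    stop("parental allele counts must be 0 or 1")
  paste0(n_m + 1L, n_f + 1L)
}

#' Parse ordered genotype codes
#'
#' @param code character (or numeric) vector of codes among 11, 12, 21, 22.
#' @return a list with integer vectors `n_m` and `n_f`.
#' @examples
#' parse_genotype_code(c("11", "12", "21", "22"))
#' @export
parse_genotype_code <- function(code) {
  code <- as.character(code)
  idx <- match(code, .GT_CODES)
  if (anyNA(idx))
    stop("malformed genotype code: ",
         paste(unique(code[is.na(idx)]), collapse = ", "),
         " (expected 11, 12, 21 or 22)")
  list(n_m = .GT_NM[idx], n_f = .GT_NF[idx])
}

#' Ordered genotype frequencies
#'
#' Container for the probabilities of the four ordered genotypes 11, 12, 21,
#' 22. The marginal variant-allele frequencies of the maternally and
#' paternally transmitted alleles are `p_m = q21 + q22` and
#' `p_f = q12 + q22`; under Hardy-Weinberg equilibrium both equal the
#' population allele frequency and `q12 = q21`.
#'
#' @param q11,q12,q21,q22 nonnegative probabilities summing to 1.
#' @return an object of class `"genotype_freqs"`: a named numeric vector with
#'   attributes `p_m` and `p_f`.
#' @seealso [ordered_genotype_probs()] for the HWE constructor,
#'   [estimate_frequencies()] for estimation from data.
#' @examples
#' genotype_freqs(0.4, 0.3, 0.2, 0.1)
#' @export
genotype_freqs <- function(q11, q12, q21, q22) {
  q <- c(q11 = q11, q12 = q12, q21 = q21, q22 = q22)
  if (anyNA(q) || any(q < 0)) stop("genotype frequencies must be nonnegative")
  if (abs(sum(q) - 1) > 1e-8)
    stop("genotype frequencies must sum to 1 (got ", format(sum(q)), ")")
  structure(q, p_m = unname(q[3] + q[4]), p_f = unname(q[2] + q[4]),
            class = "genotype_freqs")
}

# plain named probability vector, attributes stripped
.q4 <- function(freqs) {
  q <- unclass(freqs)
  attributes(q) <- list(names = names(q))
  q
}

#' @export
print.genotype_freqs <- function(x, ...) {
  cat("ordered genotype frequencies (11, 12, 21, 22):\n")
  print(round(unclass(x), 6))
  cat(sprintf("maternal variant frequency p_m = %.6g, paternal p_f = %.6g\n",
              attr(x, "p_m"), attr(x, "p_f")))
  invisible(x)
}

#' Maternal and paternal variant-allele frequencies
#'
#' @param freqs a [genotype_freqs()] object.
#' @return a single numeric value.
#' @export
p_maternal <- function(freqs) attr(freqs, "p_m")

#' @rdname p_maternal
#' @export
p_paternal <- function(freqs) attr(freqs, "p_f")

#' Hardy-Weinberg ordered genotype distribution
#'
#' Under HWE with variant-allele frequency `p`, maternal and paternal
#' transmissions are independent Bernoulli(`p`) draws, so the ordered
#' genotypes 11, 12, 21, 22 have probabilities
#' \eqn{(1-p)^2, p(1-p), p(1-p), p^2}; the two heterozygote classes are
#' equally frequent.
#'
#' @param p variant (minor) allele frequency in \[0, 1\].
#' @return a [genotype_freqs()] object.
#' @examples
#' ordered_genotype_probs(0.28)
#' @export
ordered_genotype_probs <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("allele frequency 'p' must be a single number in [0, 1]")
  genotype_freqs((1 - p)^2, p * (1 - p), p * (1 - p), p^2)
}

#' Estimate ordered genotype frequencies from a dataset
#'
#' `empirical` returns the four sample proportions; `hwe_constrained`
#' estimates the allele frequency \eqn{\hat p = (n12 + n21 + 2 n22)/(2n)} and
#' returns the HWE distribution at \eqn{\hat p}.
#'
#' @param data a [poe_data()] dataset (or any data.frame with `n_m`, `n_f`).
#' @param mode `"empirical"` or `"hwe_constrained"`.
#' @return a [genotype_freqs()] object.
#' @examples
#' d <- poe_data(phenotype = c(1, 2, 3, 4),
#'               n_m = c(0, 0, 1, 0), n_f = c(0, 1, 0, 0))
#' estimate_frequencies(d, "empirical")
#' estimate_frequencies(d, "hwe_constrained")
#' @export
estimate_frequencies <- function(data, mode = c("empirical", "hwe_constrained")) {
  mode <- match.arg(mode)
  if (NROW(data) < 1L) stop("dataset is empty")
  code <- genotype_code(data$n_m, data$n_f)
  counts <- tabulate(match(code, .GT_CODES), nbins = 4L)
  n <- sum(counts)
  if (mode == "empirical") {
    pr <- counts / n
    genotype_freqs(pr[1], pr[2], pr[3], pr[4])
  } else {
    p_hat <- (counts[2] + counts[3] + 2 * counts[4]) / (2 * n)
    ordered_genotype_probs(p_hat)
  }
}
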