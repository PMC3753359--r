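#' @keywords internal
.MODELS <- c("func_poe", "stat_poe", "func_usual", "stat_usual")

.needs_freqs <- function(model) model %in% c("stat_poe", "stat_usual")

.check_model <- function(model) {
  model <- match.arg(model, .MODELS)
  model
}

.check_freqs <- function(freqs) {
  if (!inherits(freqs, "genotype_freqs"))
    stop("'freqs' must be a genotype_freqs object")
  freqs
}

# Frequency-weighted Gram-Schmidt of the heterozygote indicator against the
# earlier columns, scaled so that the regression coefficient on the resulting
# column equals the functional dominance deviation
# d = (G12 + G21)/2 - (G11 + G22)/2. At q12 = q21 this reproduces the
# classical NOIA dominance coding. Returns NULL when the column degenerates
# (no heterozygotes, or nothing but heterozygotes, in the population).
.dominance_column <- function(X, q) {
  het <- c(0, 1, 1, 0)
  # joint q-weighted projection of the heterozygote indicator onto the span
  # of the earlier columns (the columns need not be mutually orthogonal)
  gram <- crossprod(X, q * X)
  proj <- tryCatch(X %*% solve(gram, crossprod(X, q * het)),
                   error = function(e) NULL)
  if (is.null(proj)) return(NULL)
  u <- het - drop(proj)
  ss <- sum(q * u * u)
  if (ss < 1e-12) return(NULL)
  f <- c(-0.5, 0.5, 0.5, -0.5)
  k <- which.max(abs(u))
  s <- q[k] * u[k] / (f[k] * ss)
  u * s
}

# 4 x k design over the ordered genotype classes 11, 12, 21, 22
.unique_design <- function(model, freqs = NULL) {
  N <- .GT_NM + .GT_NF
  het <- as.numeric(N == 1L)
  poe_raw <- .GT_NF - .GT_NM
  dropped <- character(0)
  if (model == "func_poe") {
    X <- cbind(intercept = 1, add = N, poe = poe_raw / 2, dom = het)
  } else if (model == "func_usual") {
    X <- cbind(intercept = 1, add = N, dom = het)
  } else {
    q <- unclass(.check_freqs(freqs))
    p_m <- q[3] + q[4]
    p_f <- q[2] + q[4]
    if (model == "stat_poe") {
      X <- cbind(intercept = 1,
                 add = N - (p_m + p_f),
                 poe = poe_raw - (p_f - p_m))
    } else {
      X <- cbind(intercept = 1, add = N - (p_m + p_f))
    }
    dom <- .dominance_column(X, q)
    if (is.null(dom)) {
      dropped <- "dom"
    } else {
      X <- cbind(X, dom = dom)
    }
  }
  rownames(X) <- .GT_CODES
  attr(X, "dropped") <- dropped
  X
}

#' Design matrix of a genotype-phenotype model
#'
#' Builds the regression design for one of the four one-locus models over
#' ordered genotypes (first digit maternal, allele 2 the variant):
#'
#' * `func_poe` -- functional model with a POE term: columns
#'   `intercept`, `add` = \eqn{N_m + N_f}, `poe` = \eqn{(N_f - N_m)/2},
#'   `dom` = heterozygote indicator. The coefficients are the reference
#'   genotypic value \eqn{R = G_{11}}, the main additive effect
#'   \eqn{a = (G_{22} - G_{11})/2}, the parent-of-origin effect
#'   \eqn{i = G_{12} - G_{21}} (paternal-origin minus maternal-origin
#'   variant), and the dominance deviation
#'   \eqn{d = (G_{12} + G_{21})/2 - (G_{11} + G_{22})/2}.
#' * `func_usual` -- the same without the POE column.
#' * `stat_poe` -- the statistical (NOIA) model: additive and POE columns are
#'   centered at their population means, and the dominance column is the
#'   heterozygote indicator orthogonalized against the others under the
#'   genotype-frequency weighting, scaled so its coefficient equals the
#'   functional `d`. Under HWE (or whenever `q12 = q21` or `p = 1/2`) all
#'   columns are mutually uncorrelated in the population.
#' * `stat_usual` -- the statistical model without the POE column.
#'
#' For degenerate frequencies (no heterozygotes, or only heterozygotes, in
#' the population) the statistical dominance column is undefined; it is
#' dropped and recorded in the `"dropped"` attribute.
#'
#' @param genotypes a [poe_data()] dataset, or a data.frame/list with
#'   elements `n_m` and `n_f`.
#' @param model one of `"func_poe"`, `"stat_poe"`, `"func_usual"`,
#'   `"stat_usual"`.
#' @param freqs a [genotype_freqs()] object; required for the statistical
#'   models.
#' @return an `n x k` numeric matrix with labelled columns and attribute
#'   `"dropped"` naming any dropped column.
#' @examples
#' g <- list(n_m = c(0, 0, 1, 1), n_f = c(0, 1, 0, 1))
#' poe_design(g, "func_poe")
#' poe_design(g, "stat_poe", ordered_genotype_probs(0.5))
#' @export
poe_design <- function(genotypes, model = .MODELS, freqs = NULL) {
  model <- .check_model(model)
  if (.needs_freqs(model) && is.null(freqs))
    stop("statistical models require 'freqs'")
  U <- .unique_design(model, freqs)
  idx <- match(genotype_code(genotypes$n_m, genotypes$n_f), .GT_CODES)
  X <- U[idx, , drop = FALSE]
  rownames(X) <- NULL
  attr(X, "dropped") <- attr(U, "dropped")
  X
}

#' Genotypic values implied by a model's effects
#'
#' Multiplies the model's design over the four ordered genotype classes by
#' the effect vector, giving the genotypic values
#' \eqn{(G_{11}, G_{12}, G_{21}, G_{22})}. For the models without a POE term
#' the two heterozygote values coincide.
#'
#' @param model model name as in [poe_design()].
#' @param effects numeric effect vector matching the model's columns
#'   (`intercept`, `add`, `poe`, `dom` for the POE models; no `poe`
#'   otherwise).
#' @param freqs [genotype_freqs()], required for statistical models.
#' @return named numeric vector of length 4 (`"11"`, `"12"`, `"21"`, `"22"`).
#' @examples
#' genotypic_values("func_poe", c(90, 3, -3, 1.2))
#' @export
genotypic_values <- function(model = .MODELS, effects, freqs = NULL) {
  model <- .check_model(model)
  U <- .unique_design(model, freqs)
  if (length(effects) != ncol(U))
    stop("expected ", ncol(U), " effects for model ", model,
         ", got ", length(effects))
  drop(U %*% as.numeric(effects))
}

#' Transform effects between model parameterizations
#'
#' Re-expresses an effect vector of one model in the basis of another model
#' spanning the same genotypic-value space: functional <-> statistical with
#' POE (four ordered genotype classes), or functional <-> statistical without
#' POE (three genotype classes). The transformation is computed numerically
#' as a change of design basis, so genotypic values are preserved exactly and
#' the round trip is the identity. Under `q12 = q21` the POE components of
#' the two POE models are proportional: `alpha2 = i/2` with this package's
#' column scalings.
#'
#' @param effects effect vector in the `from` parameterization.
#' @param from,to model names as in [poe_design()].
#' @param freqs [genotype_freqs()], required when either model is
#'   statistical.
#' @return named numeric effect vector in the `to` parameterization.
#' @examples
#' f <- ordered_genotype_probs(0.28)
#' transform_effects(c(90, 3, -3, 1.2), "func_poe", "stat_poe", f)
#' @export
transform_effects <- function(effects, from = .MODELS, to = .MODELS,
                              freqs = NULL) {
  from <- .check_model(from)
  to <- .check_model(to)
  poe_models <- c("func_poe", "stat_poe")
  if (xor(from %in% poe_models, to %in% poe_models))
    stop("models must span the same genotypic-value space ",
         "(usual <-> usual, poe <-> poe)")
  Uf <- .unique_design(from, freqs)
  Ut <- .unique_design(to, freqs)
  if (length(attr(Ut, "dropped")))
    stop("target design is degenerate (", attr(Ut, "dropped"), " undefined)")
  if (length(effects) != ncol(Uf))
    stop("expected ", ncol(Uf), " effects for model ", from)
  G <- Uf %*% as.numeric(effects)
  if (ncol(Ut) == 4L) {
    beta <- solve(Ut, G)
  } else {
    # three genotype classes: rows 11, heterozygote, 22
    beta <- solve(Ut[c(1, 2, 4), ], G[c(1, 2, 4)])
  }
  stats::setNames(drop(beta), colnames(Ut))
}

#' Frequency-weighted Gram matrix of a model design
#'
#' Computes \eqn{Gram[c, c'] = \sum_g q_g X[g, c] X[g, c']} over the ordered
#' genotype classes. For the statistical POE model the off-diagonal entries
#' vanish under HWE (or `q12 = q21`, or `p = 1/2`): the effect estimates are
#' then uncorrelated, so adding or removing one term leaves the others'
#' tests unchanged. The functional designs are not orthogonal in this sense.
#'
#' @inheritParams poe_design
#' @return a list of class `"poe_gram"` with elements `gram` (the matrix) and
#'   `max_offdiag` (largest absolute off-diagonal entry).
#' @examples
#' orthogonality_gram("stat_poe", ordered_genotype_probs(0.28))$max_offdiag
#' @export
orthogonality_gram <- function(model = .MODELS, freqs) {
  model <- .check_model(model)
  freqs <- .check_freqs(freqs)
  X <- .unique_design(model, freqs)
  gram <- t(X) %*% (unclass(freqs) * X)
  off <- gram
  diag(off) <- 0
  structure(list(gram = gram, max_offdiag = max(abs(off)), model = model),
            class = "poe_gram")
}

#' @export
print.poe_gram <- function(x, ...) {
  cat("frequency-weighted Gram matrix (", x$model, "):\n", sep = "")
  print(signif(x$gram, 6))
  cat("max |off-diagonal| =", format(x$max_offdiag), "\n")
  invisible(x)
}

#' Split the additive effect into maternal and paternal allelic effects
#'
#' An equivalent re-parameterization of the POE models replaces the main
#' additive effect `a` and the POE `i` by separate maternal and paternal
#' allelic effects: `a_m = a - i/2`, `a_f = a + i/2`, with inverse
#' `a = (a_m + a_f)/2`, `i = a_f - a_m`.
#'
#' @param a main allelic additive effect.
#' @param i parent-of-origin effect (paternal-origin minus maternal-origin).
#' @return named numeric vector `c(a_m, a_f)`.
#' @examples
#' maternal_paternal_effects(a = 3, i = -3)
#' allelic_to_poe_effects(a_m = 4.5, a_f = 1.5)
#' @export
maternal_paternal_effects <- function(a, i) {
  c(a_m = a - i / 2, a_f = a + i / 2)
}

#' @rdname maternal_paternal_effects
#' @param a_m,a_f maternal and paternal allelic additive effects.
#' @export
allelic_to_poe_effects <- function(a_m, a_f) {
  c(a = (a_m + a_f) / 2, i = a_f - a_m)
}

#' Orthogonal decomposition of the one-locus genetic variance
#'
#' Under the statistical POE parameterization, the genetic variance of the
#' genotypic values G under the genotype distribution decomposes as
#' \deqn{V_{A1} = \alpha_1^2 Var(N_m + N_f), \quad
#'       V_{A2} = \alpha_2^2 Var(N_f - N_m), \quad
#'       V_D = \delta^2 Var(w_{dom}),}
#' two additive components (main effect and POE) and a dominance component.
#' Under HWE, `q12 = q21`, or `p = 1/2` these are mutually uncorrelated and
#' sum to the total genetic variance `V_total = Var(G)`.
#'
#' @param stat_effects statistical effect vector
#'   `(mu, alpha1, alpha2, delta)`.
#' @param freqs a [genotype_freqs()] object.
#' @return list of class `"poe_varcomp"` with `V_A1`, `V_A2`, `V_D`,
#'   `V_total`.
#' @examples
#' variance_components(c(90, 3, 0, 0), ordered_genotype_probs(0.28))
#' @export
variance_components <- function(stat_effects, freqs) {
  freqs <- .check_freqs(freqs)
  q <- unclass(freqs)
  X <- .unique_design("stat_poe", freqs)
  if (length(attr(X, "dropped"))) {
    X <- cbind(X, dom = 0)
    stat_effects <- c(stat_effects[1:3], 0)
  }
  if (length(stat_effects) != 4L)
    stop("expected 4 statistical effects (mu, alpha1, alpha2, delta)")
  wvar <- function(x) sum(q * x^2) - sum(q * x)^2
  G <- drop(X %*% as.numeric(stat_effects))
  structure(list(
    V_A1 = stat_effects[2]^2 * wvar(X[, "add"]),
    V_A2 = stat_effects[3]^2 * wvar(X[, "poe"]),
    V_D = stat_effects[4]^2 * wvar(X[, "dom"]),
    V_total = wvar(G)
  ), class = "poe_varcomp")
}

#' @export
print.poe_varcomp <- function(x, ...) {
  v <- unlist(x)
  cat("genetic variance components:\n")
  print(round(v, 6))
  cat("V_A1 + V_A2 + V_D - V_total =",
      format(v[1] + v[2] + v[3] - v[4]), "\n")
  invisible(x)
}
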