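#' Wald test of a single coefficient
#'
#' @param estimate coefficient estimate.
#' @param se its standard error; must be positive.
#' @return list with `z = estimate/se`, `chisq = z^2`, and the two-sided
#'   p-value from the standard normal (equivalently `chisq` against
#'   chi-square with 1 df).
#' @examples
#' wald_test(1.96, 1)
#' @export
wald_test <- function(estimate, se) {
  if (!is.finite(se) || se <= 0) stop("standard error must be positive")
  z <- estimate / se
  list(z = z, chisq = z^2, p = 2 * stats::pnorm(-abs(z)))
}

# drop near-constant columns, then aliased columns, via pivoted QR;
# returns kept column indices (intercept always kept)
.usable_columns <- function(X) {
  keep <- sort(unique(c(1L, which(apply(X, 2, stats::var) > 1e-12))))
  qr_x <- qr(X[, keep, drop = FALSE])
  if (qr_x$rank < length(keep))
    keep <- keep[sort(qr_x$pivot[seq_len(qr_x$rank)])]
  keep
}

#' Fit a one-locus association model
#'
#' Builds the requested model design for the dataset and fits it by ordinary
#' least squares (quantitative trait) or logistic regression via iteratively
#' reweighted least squares (binary trait). Each coefficient is reported with
#' its standard error and a two-sided Wald test. For OLS the covariance is
#' \eqn{\hat\sigma^2 (X'X)^{-1}} with \eqn{\hat\sigma^2 = RSS/(n-k)} and
#' p-values use the standard normal (at the sample sizes this framework
#' targets the difference from the t reference is negligible). For logistic
#' fits the covariance is the inverse observed information.
#'
#' Columns that are constant in the sample, or linearly dependent on earlier
#' columns (e.g. when a genotype class is absent), are dropped: their
#' entries are reported as `NA` and listed in `$aliased`. Logistic fits are
#' flagged `converged = FALSE` when IRLS fails to converge within `maxit`
#' iterations or a coefficient diverges beyond 30 on the logit scale
#' (a symptom of separation).
#'
#' @param data a [poe_data()] dataset.
#' @param model model name as in [poe_design()].
#' @param freqs genotype frequencies used to build statistical designs.
#'   `NULL` (default) estimates them from the data via `freq_mode`.
#' @param freq_mode how to estimate frequencies when `freqs` is `NULL`:
#'   `"empirical"` sample proportions or `"hwe_constrained"`.
#' @param maxit IRLS iteration cap for logistic fits.
#' @return an object of class `"poe_fit"`: a list with `coefficients`,
#'   `se`, `z`, `chisq`, `p`, `converged`, `n_used`, `aliased`, `model`,
#'   `trait_kind`, `fitted`, `residuals`.
#' @examples
#' set.seed(1)
#' sc <- scenario_preset("quant-strong")
#' d <- simulate_quantitative(sc)
#' fit_poe(d, "stat_poe", freqs = ordered_genotype_probs(sc$maf))
#' @export
fit_poe <- function(data, model = .MODELS, freqs = NULL,
                    freq_mode = c("empirical", "hwe_constrained"),
                    maxit = 100L) {
  model <- .check_model(model)
  stopifnot(inherits(data, "poe_data"))
  freq_mode <- match.arg(freq_mode)
  if (.needs_freqs(model) && is.null(freqs))
    freqs <- estimate_frequencies(data, freq_mode)
  X <- poe_design(data, model, freqs)
  y <- data$phenotype
  labels <- colnames(X)
  keep <- .usable_columns(X)
  Xk <- X[, keep, drop = FALSE]
  kind <- trait_kind(data)

  if (kind == "quantitative") {
    fit <- stats::lm.fit(Xk, y)
    k <- ncol(Xk)
    n <- length(y)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - k)
    xtx_inv <- chol2inv(qr.R(fit$qr))[order(fit$qr$pivot),
                                      order(fit$qr$pivot), drop = FALSE]
    se_k <- sqrt(sigma2 * diag(xtx_inv))
    beta_k <- fit$coefficients
    converged <- TRUE
    fitted <- drop(Xk %*% beta_k)
  } else {
    if (length(unique(y)) < 2L)
      stop("binary trait must contain both cases and controls")
    fit <- suppressWarnings(
      stats::glm.fit(Xk, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12,
                                                  maxit = maxit)))
    beta_k <- fit$coefficients
    info <- crossprod(Xk, fit$weights * Xk)
    cov_k <- tryCatch(solve(info), error = function(e) NULL)
    converged <- fit$converged && all(is.finite(beta_k)) &&
      all(abs(beta_k) < 30) && !is.null(cov_k)
    se_k <- if (is.null(cov_k)) rep(NA_real_, ncol(Xk)) else sqrt(diag(cov_k))
    fitted <- fit$fitted.values
  }

  full <- function(v) {
    out <- stats::setNames(rep(NA_real_, length(labels)), labels)
    out[keep] <- v
    out
  }
  beta <- full(beta_k)
  se <- full(se_k)
  z <- beta / se
  structure(list(
    coefficients = beta, se = se, z = z, chisq = z^2,
    p = 2 * stats::pnorm(-abs(z)),
    converged = converged, n_used = length(y),
    aliased = labels[setdiff(seq_along(labels), keep)],
    model = model, trait_kind = kind,
    fitted = fitted, residuals = y - fitted
  ), class = "poe_fit")
}

#' @export
print.poe_fit <- function(x, ...) {
  cat(sprintf("%s %s fit, n = %d%s\n", x$model, x$trait_kind, x$n_used,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- cbind(estimate = x$coefficients, se = x$se, z = x$z,
               `z^2` = x$chisq, p = x$p)
  print(signif(tab, 5))
  if (length(x$aliased))
    cat("aliased (dropped) columns:", paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.poe_fit <- function(object, ...) object$coefficients
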