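#' Monte-Carlo power study for one model and scenario
#'
#' For each replicate the scenario is simulated, the requested model design
#' is built (by default with the exact population genotype frequencies -- the
#' generating HWE values -- matching the framework's population-parameter
#' formulation; `design_freqs = "empirical"` switches to per-replicate sample
#' frequencies for sensitivity analysis), the model is fitted, and the
#' per-coefficient Wald p-values are recorded. The rejection rate of each
#' coefficient at each significance threshold estimates power (or type-I
#' error, under a null scenario).
#'
#' Replicates whose fit does not converge are excluded from the denominator
#' of every coefficient and counted in `n_excluded`; a coefficient aliased in
#' a particular replicate (e.g. a genotype class absent at low MAF) is
#' excluded from that coefficient's denominator only. The study is flagged
#' when more than 5\% of replicates are unusable.
#'
#' @param scenario a [poe_scenario()].
#' @param model model name as in [poe_design()], or a character vector of
#'   several models fitted to the *same* simulated replicates.
#' @param alphas significance thresholds for the Wald p-values.
#' @param n_replicates number of Monte-Carlo replicates.
#' @param seed master seed; spawns one sub-seed per replicate so any
#'   replicate can be reproduced in isolation. `NULL` uses the current RNG
#'   stream.
#' @param design_freqs `"population"` or `"empirical"`.
#' @return an object of class `"poe_power_study"`: a list with `rates`
#'   (model x coefficient x alpha array), `estimates` and `se` (mean
#'   estimate and empirical SE per model/coefficient), `n_used`,
#'   `n_excluded`, `flagged`, plus the study configuration.
#' @examples
#' run_power_study(scenario_preset("quant-strong"), "stat_poe",
#'                 alphas = 0.001, n_replicates = 50, seed = 1)
#' @export
run_power_study <- function(scenario, model = "stat_poe", alphas = 0.001,
                            n_replicates = 1000L, seed = NULL,
                            design_freqs = c("population", "empirical")) {
  stopifnot(inherits(scenario, "poe_scenario"))
  design_freqs <- match.arg(design_freqs)
  models <- vapply(model, .check_model, "")
  if (any(alphas < 0 | alphas > 1)) stop("alphas must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  pop_freqs <- ordered_genotype_probs(scenario$maf)

  coefs <- c("intercept", "add", "poe", "dom")
  pvals <- array(NA_real_,
                 c(length(models), length(coefs), n_replicates),
                 dimnames = list(models, coefs, NULL))
  ests <- array(NA_real_,
                c(length(models), length(coefs), n_replicates),
                dimnames = list(models, coefs, NULL))
  conv <- matrix(TRUE, length(models), n_replicates)

  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    dat <- simulate_scenario(scenario)
    freqs <- if (design_freqs == "population") pop_freqs else
      estimate_frequencies(dat, "empirical")
    for (m in seq_along(models)) {
      fit <- fit_poe(dat, models[m], freqs = freqs)
      conv[m, r] <- fit$converged
      if (fit$converged) {
        idx <- match(names(fit$p), coefs)
        pvals[m, idx, r] <- fit$p
        ests[m, idx, r] <- fit$coefficients
      }
    }
  }

  rates <- array(NA_real_, c(length(models), length(coefs), length(alphas)),
                 dimnames = list(models, coefs, paste0("alpha=", alphas)))
  n_used <- matrix(0L, length(models), length(coefs),
                   dimnames = list(models, coefs))
  for (m in seq_along(models)) {
    for (cc in seq_along(coefs)) {
      p <- pvals[m, cc, ]
      ok <- !is.na(p)
      n_used[m, cc] <- sum(ok)
      if (any(ok))
        rates[m, cc, ] <- vapply(alphas,
                                 function(a) mean(p[ok] < a), 0)
    }
  }
  n_excluded <- rowSums(!conv)
  structure(list(
    rates = rates,
    estimates = apply(ests, c(1, 2), mean, na.rm = TRUE),
    se = apply(ests, c(1, 2), stats::sd, na.rm = TRUE),
    n_replicates = n_replicates, n_used = n_used,
    n_excluded = stats::setNames(n_excluded, models),
    flagged = any(n_excluded > 0.05 * n_replicates),
    scenario = scenario, models = models, alphas = alphas,
    design_freqs = design_freqs, seed = seed,
    pvalues = pvals
  ), class = "poe_power_study")
}

#' @export
print.poe_power_study <- function(x, ...) {
  cat(sprintf("power study: %s trait, MAF %g, %d replicates%s\n",
              x$scenario$trait_kind, x$scenario$maf, x$n_replicates,
              if (x$flagged) "  [FLAGGED: >5% replicates excluded]" else ""))
  for (a in seq_along(x$alphas)) {
    cat("rejection rates at alpha =", x$alphas[a], ":\n")
    print(round(x$rates[, , a, drop = TRUE], 4))
  }
  invisible(x)
}

#' Monte-Carlo type-I-error study
#'
#' Runs [run_power_study()] on a null version of the scenario: the additive,
#' POE and dominance effects are all set to zero (the intercept and, for a
#' quantitative trait, the residual variance are kept), so rejection rates
#' estimate type-I error. Dominance is zeroed together with the main effects
#' so that its own false-positive rate is interpretable.
#'
#' @inheritParams run_power_study
#' @param alphas nominal levels; default 0.05.
#' @return a `"poe_power_study"` object.
#' @examples
#' run_type1_study(scenario_preset("quant-strong"), "stat_poe",
#'                 n_replicates = 50, seed = 1)
#' @export
run_type1_study <- function(scenario, model = "stat_poe", alphas = 0.05,
                            n_replicates = 1000L, seed = NULL,
                            design_freqs = c("population", "empirical")) {
  null_sc <- scenario
  null_sc$effects[c("add", "poe", "dom")] <- 0
  run_power_study(null_sc, model = model, alphas = alphas,
                  n_replicates = n_replicates, seed = seed,
                  design_freqs = design_freqs)
}

#' Tabulate power-study results
#'
#' Collects one or more study results into a tidy data frame (`layout =
#' "long"`: one row per model, coefficient and alpha) or a wide
#' power-table layout (`layout = "wide"`: coefficients as row groups, one
#' column per study, at a single alpha). Mixing trait kinds in a wide table
#' is an error.
#'
#' @param results a `"poe_power_study"` or list of them, optionally named.
#' @param layout `"long"` or `"wide"`.
#' @param alpha threshold used for the wide layout (must be one of the
#'   studies' alphas).
#' @return a data.frame.
#' @export
tabulate_power <- function(results, layout = c("long", "wide"),
                           alpha = NULL) {
  layout <- match.arg(layout)
  if (inherits(results, "poe_power_study")) results <- list(results)
  if (length(results) == 0L) stop("no study results to tabulate")
  if (!all(vapply(results, inherits, TRUE, "poe_power_study")))
    stop("all elements must be poe_power_study objects")
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("study", seq_along(results))
  long <- do.call(rbind, lapply(names(results), function(nm) {
    x <- results[[nm]]
    grid <- expand.grid(model = x$models,
                        coefficient = dimnames(x$rates)[[2]],
                        alpha = x$alphas, stringsAsFactors = FALSE)
    grid$study <- nm
    grid$trait_kind <- x$scenario$trait_kind
    grid$maf <- x$scenario$maf
    grid$power <- mapply(function(m, cc, a) {
      x$rates[m, cc, paste0("alpha=", a)]
    }, grid$model, grid$coefficient, grid$alpha)
    grid$n_used <- mapply(function(m, cc) x$n_used[m, cc],
                          grid$model, grid$coefficient)
    grid$mc_se <- sqrt(grid$power * (1 - grid$power) /
                         pmax(grid$n_used, 1))
    grid[!is.na(grid$power),
         c("study", "trait_kind", "maf", "model", "coefficient", "alpha",
           "power", "mc_se", "n_used")]
  }))
  rownames(long) <- NULL
  if (layout == "long") return(long)
  if (length(unique(long$trait_kind)) > 1L)
    stop("cannot mix trait kinds in one wide table")
  if (is.null(alpha)) alpha <- min(long$alpha)
  sub <- long[long$alpha == alpha & long$coefficient != "intercept", ]
  if (nrow(sub) == 0L) stop("no results at alpha = ", alpha)
  out <- stats::reshape(
    sub[, c("coefficient", "model", "study", "power")],
    idvar = c("coefficient", "model"), timevar = "study",
    direction = "wide")
  names(out) <- sub("^power\\.", "", names(out))
  rownames(out) <- NULL
  out
}

#' Write study results to TSV and/or JSON
#'
#' @param results as in [tabulate_power()].
#' @param tsv,json output paths (`NULL` to skip either).
#' @return the long-format data.frame, invisibly.
#' @export
write_power_results <- function(results, tsv = NULL, json = NULL) {
  long <- tabulate_power(results, "long")
  if (!is.null(tsv))
    utils::write.table(long, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("JSON output requires the 'jsonlite' package")
    jsonlite::write_json(long, json, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(long)
}
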