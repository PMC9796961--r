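#' Percentile bounds of a bootstrap sample
#'
#' Empirical percentiles with linear interpolation between order statistics
#' (the default `quantile` type 7 convention: the p-th percentile of a
#' sorted sample `x_(1) <= ... <= x_(B)` sits at position
#' `1 + p (B - 1)`, interpolating linearly between neighbours).
#'
#' @param x numeric vector of bootstrap re-estimates.
#' @param level confidence level (default 0.95 gives the 2.5th and 97.5th
#'   percentiles).
#' @return numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(x, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  a <- (1 - level) / 2
  unname(quantile(x, probs = c(a, 1 - a), type = 7, names = FALSE))
}

#' Parametric bootstrap confidence intervals for model parameters
#'
#' Simulates `n_reps` replicate folded joint SFS of the observed size from
#' the fitted model at its maximum-composite-likelihood estimates, re-fits
#' the model to each, and returns per-parameter percentile intervals of the
#' re-estimates. The point estimate is reported as fitted and is not forced
#' inside the interval. Replicates whose refit fails are recorded and
#' excluded; more than 20% failures is an error.
#'
#' @param fit a `fit_result` for the model whose uncertainty is wanted.
#' @param n_snps number of SNPs per bootstrap replicate (default: the
#'   observed SNP mass, rounded).
#' @param n_reps number of parametric bootstrap replicates (default 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param refit_settings `fit_settings` used for the bootstrap refits; by
#'   default a reduced schedule (fewer replicates and simulations than the
#'   original fit), flagged in the output as `reduced_refit`.
#' @return an object of class `bootstrap_result`: a `ci` data.frame
#'   (`parameter`, `point`, `lower`, `upper`), the matrix of bootstrap
#'   re-estimates, `n_reps`, `level`, `n_failed` and the refit settings.
#' @export
parametric_bootstrap <- function(fit, n_snps = NULL, n_reps = 100,
                                 level = 0.95, seed = 1,
                                 refit_settings = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (is.null(n_snps)) n_snps <- round(fit$n_snps)
  if (!is.finite(n_snps) || n_snps < 1) stop("n_snps must be >= 1")
  reduced <- is.null(refit_settings)
  if (reduced) {
    refit_settings <- fit_settings(
      n_sims = max(1000, fit$settings$n_sims %/% 5),
      n_sims_final = max(1000, fit$settings$n_sims %/% 5),
      cycles = fit$settings$cycles,
      iters_per_cycle = fit$settings$iters_per_cycle,
      stop_tol = fit$settings$stop_tol,
      n_replicates = max(2L, fit$settings$n_replicates %/% 5),
      prescan = fit$settings$prescan,
      bounds = fit$settings$bounds
    )
  }
  model <- model_from_params(fit$spec, fit$estimates, fit$anchor, fit$mu)
  draws <- vector("list", n_reps)
  n_failed <- 0L
  sizes <- fit$sample_sizes
  samples <- sample_config(sizes[1], sizes[2], sizes[3])
  for (rep in seq_len(n_reps)) {
    boot_sfs <- simulate_sfs(model, samples, n_snps,
                             seed = .derive_seed(seed, 5000 + rep))
    est <- tryCatch({
      refit <- fit_model(boot_sfs, fit$spec, fit$anchor,
                         settings = refit_settings,
                         seed = .derive_seed(seed, rep), mu = fit$mu)
      refit$estimates
    }, error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L else draws[[rep]] <- est
  }
  if (n_failed > 0.2 * n_reps) {
    stop(sprintf("%d of %d bootstrap refits failed", n_failed, n_reps))
  }
  mat <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  ci <- data.frame(
    parameter = colnames(mat),
    point = unname(fit$estimates[colnames(mat)]),
    lower = apply(mat, 2, function(x) percentile_ci(x, level)[1]),
    upper = apply(mat, 2, function(x) percentile_ci(x, level)[2]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(ci = ci, draws = mat, n_reps = n_reps, level = level,
                 n_failed = n_failed, reduced_refit = reduced,
                 refit_settings = refit_settings),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> %d replicates (%d failed), %.0f%% percentile CIs%s\n",
    x$n_reps, x$n_failed, 100 * x$level,
    if (x$reduced_refit) " [reduced refit settings]" else ""))
  print(x$ci, digits = 4)
  invisible(x)
}

#' Write bootstrap confidence intervals as a TSV table
#'
#' One row per parameter: point estimate, lower and upper percentile bound.
#'
#' @param boot a `bootstrap_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_table <- function(boot, path) {
  stopifnot(inherits(boot, "bootstrap_result"))
  write.table(boot$ci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
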