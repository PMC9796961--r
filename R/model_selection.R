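#' Akaike's information criterion
#'
#' `AIC = 2k - 2 lnL`, with `lnL` the maximum composite log-likelihood in
#' natural log and `k` the number of free parameters.
#'
#' @param lnL maximum (composite) log-likelihood.
#' @param k number of free parameters (>= 0).
#' @return the AIC value.
#' @export
#' @examples
#' aic(-3147.64, 8)  # 6311.28
aic <- function(lnL, k) {
  if (any(k < 0)) stop("k must be >= 0")
  2 * k - 2 * lnL
}

#' Compare fitted demographic models by AIC
#'
#' Computes, for each candidate, `AIC = 2k - 2 lnL`, the rescaled
#' `delta_AIC = AIC - min(AIC)` and the Akaike weight
#' `w = exp(-delta/2) / sum_j exp(-delta_j/2)`; weights are computed from
#' full-precision deltas, not from rounded printed values. Rows are sorted
#' by AIC ascending, so the best-supported model (delta = 0) comes first.
#'
#' @param results either a list of `fit_result` objects, or a data.frame
#'   with columns `model` (label), `lnL` and `k`.
#' @return a `data.frame` with columns `model`, `lnL`, `k`, `AIC`,
#'   `delta_AIC`, `weight`, sorted by AIC.
#' @export
compare_models <- function(results) {
  if (is.data.frame(results)) {
    if (!all(c("model", "lnL", "k") %in% names(results))) {
      stop("data.frame input needs columns model, lnL, k")
    }
    tab <- results[, c("model", "lnL", "k")]
  } else if (is.list(results) && length(results) > 0 &&
             all(vapply(results, inherits, logical(1), "fit_result"))) {
    tab <- data.frame(
      model = vapply(results, function(r) format(r$spec), character(1)),
      lnL = vapply(results, `[[`, numeric(1), "lnL"),
      k = vapply(results, `[[`, numeric(1), "k"),
      stringsAsFactors = FALSE
    )
  } else {
    stop("results must be fit_result objects or a data.frame(model, lnL, k)")
  }
  if (nrow(tab) == 0) stop("at least one model is required")
  tab$AIC <- aic(tab$lnL, tab$k)
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  rel <- exp(-tab$delta_AIC / 2)
  tab$weight <- rel / sum(rel)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
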