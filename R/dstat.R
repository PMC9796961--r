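#' ABBA/BABA site-pattern weights from derived-allele frequencies
#'
#' Frequency-weighted four-taxon pattern weights: with derived-allele
#' frequencies `p1, p2, p3, p4` in the P1, P2, P3 and outgroup groups,
#' `abba = (1 - p1) p2 p3 (1 - p4)` and `baba = p1 (1 - p2) p3 (1 - p4)`.
#' With a fixed ancestral outgroup (`p4 = 0`) these reduce to the
#' biallelic-count form. Vectorized over sites.
#'
#' @param p1,p2,p3,p4 derived-allele frequencies in `[0, 1]` (`p4` is the
#'   outgroup frequency).
#' @return a list with numeric components `abba` and `baba`.
#' @export
#' @examples
#' site_pattern_weights(0, 1, 1, 0)  # pure ABBA site
site_pattern_weights <- function(p1, p2, p3, p4) {
  for (p in list(p1, p2, p3, p4)) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) {
      stop("frequencies must lie in [0, 1]")
    }
  }
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

#' Assign deme labels to the four D-statistic roles
#'
#' @param p1,p2,p3,outgroup deme/taxon labels present in the dataset. The
#'   four groups must be disjoint and non-empty; `D > 0` indicates excess
#'   allele sharing between P2 and P3, `D < 0` between P1 and P3.
#' @return an object of class `quartet_assignment`.
#' @export
quartet_assignment <- function(p1, p2, p3, outgroup) {
  q <- list(p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup)
  labs <- unlist(q)
  if (anyDuplicated(labs)) stop("quartet roles must use disjoint labels")
  structure(q, class = "quartet_assignment")
}

#' Four-taxon ABBA/BABA D-statistic with locus-bootstrap standard error
#'
#' Per-site derived-allele frequencies are computed from all non-missing
#' alleles in each group; sites are polarized by the outgroup (the derived
#' allele is the allele at lower frequency among outgroup calls, ties kept
#' as coded), and loci missing in any group are excluded. The statistic is
#' `D = (sum abba - sum baba) / (sum abba + sum baba)` over the retained
#' loci; its standard deviation comes from resampling loci with replacement
#' `n_boot` times, `Z = D / SD`, and the p-value is two-sided normal.
#'
#' @param dataset a `snp_dataset`.
#' @param quartet a `quartet_assignment`.
#' @param n_boot bootstrap replicates for the SD (default 1000).
#' @param seed integer seed for the bootstrap resampling.
#' @return an object of class `dstat_result` with fields `D`, `SD`, `Z`,
#'   `p_value`, `abba`, `baba`, `n_loci`, `n_boot`.
#' @export
d_statistic <- function(dataset, quartet, n_boot = 1000, seed = 1) {
  stopifnot(inherits(dataset, "snp_dataset"),
            inherits(quartet, "quartet_assignment"))
  groups <- lapply(quartet, function(lab) {
    which(dataset$samples$deme %in% lab)
  })
  empty <- vapply(groups, length, integer(1)) == 0
  if (any(empty)) {
    stop("no individuals for quartet role(s): ",
         paste(names(groups)[empty], collapse = ", "))
  }
  freq <- function(cols) {
    g <- dataset$geno[, cols, drop = FALSE]
    nobs <- 2 * rowSums(!is.na(g))
    ifelse(nobs > 0, rowSums(g, na.rm = TRUE) / nobs, NA_real_)
  }
  p <- lapply(groups, freq)
  keep <- !Reduce(`|`, lapply(p, is.na))
  if (!any(keep)) stop("no loci with data in all four groups")
  p <- lapply(p, `[`, keep)
  # polarize on the outgroup: derived = minority allele among outgroup calls
  flip <- p$outgroup > 0.5
  p <- lapply(p, function(x) ifelse(flip, 1 - x, x))
  w <- site_pattern_weights(p$p1, p$p2, p$p3, p$outgroup)
  informative <- (w$abba + w$baba) > 0
  if (sum(w$abba) + sum(w$baba) <= 0) {
    stop("no informative loci (all ABBA and BABA weights are zero)")
  }
  abba <- sum(w$abba)
  baba <- sum(w$baba)
  D <- (abba - baba) / (abba + baba)
  n_loci <- length(p$p1)
  boot <- .with_seed(.derive_seed(seed, 77), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_loci, n_loci, replace = TRUE)
      a <- sum(w$abba[idx]); bb <- sum(w$baba[idx])
      if (a + bb > 0) (a - bb) / (a + bb) else NA_real_
    }, numeric(1))
  })
  SD <- stats::sd(boot, na.rm = TRUE)
  Z <- if (is.finite(SD) && SD > 0) D / SD else NA_real_
  structure(list(D = D, SD = SD, Z = Z,
                 p_value = if (is.na(Z)) NA_real_ else 2 * pnorm(-abs(Z)),
                 abba = abba, baba = baba, n_loci = n_loci,
                 n_informative = sum(informative), n_boot = n_boot,
                 quartet = quartet),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf(
    "<dstat_result> D = %.4f +/- %.4f SD; Z = %.2f; p = %.3g\n",
    x$D, x$SD, x$Z, x$p_value))
  cat(sprintf("  ABBA = %.2f, BABA = %.2f over %d loci (%d informative)\n",
              x$abba, x$baba, x$n_loci, x$n_informative))
  invisible(x)
}

#' Run D-statistic tests for a batch of quartets
#'
#' @param dataset a `snp_dataset`.
#' @param quartets a list of `quartet_assignment` objects, or a data.frame
#'   with columns `p1`, `p2`, `p3`, `outgroup`.
#' @param n_boot,seed passed to [d_statistic()].
#' @param z_threshold significance convention reported alongside the raw
#'   p-value (default `|Z| > 3`).
#' @return a data.frame with one row per quartet: `p1`, `p2`, `p3`,
#'   `outgroup`, `D`, `SD`, `Z`, `p_value`, `significant`, `abba`, `baba`,
#'   `n_loci`.
#' @export
d_statistic_batch <- function(dataset, quartets, n_boot = 1000, seed = 1,
                              z_threshold = 3) {
  if (is.data.frame(quartets)) {
    quartets <- lapply(seq_len(nrow(quartets)), function(i) {
      quartet_assignment(quartets$p1[i], quartets$p2[i], quartets$p3[i],
                         quartets$outgroup[i])
    })
  }
  rows <- lapply(seq_along(quartets), function(i) {
    q <- quartets[[i]]
    r <- d_statistic(dataset, q, n_boot = n_boot,
                     seed = .derive_seed(seed, i))
    data.frame(p1 = q$p1, p2 = q$p2, p3 = q$p3, outgroup = q$outgroup,
               D = r$D, SD = r$SD, Z = r$Z, p_value = r$p_value,
               significant = is.finite(r$Z) && abs(r$Z) > z_threshold,
               abba = r$abba, baba = r$baba, n_loci = r$n_loci,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
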