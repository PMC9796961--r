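#' The speciation-by-fusion study model
#'
#' The best-supported scenario (fusion topology with contemporary gene flow)
#' at its published point estimates: parental-clade divergence
#' `T_div1 = 2,052,400` generations, hybrid founding at
#' `T_hyb = 1,365,495` generations with admixture proportion
#' `gamma_hyb = 0.24` from the `bin` side, contemporary sizes
#' `N_sau = 2,834,490` and `N_alg = 680,545`, ancestral sizes
#' `N_anc = 40,956`, `N_anc_sau = 933,380`, `N_anc_bin = 9,721`, and
#' contemporary per-generation migration rates
#' `m_sau_alg = 7.19e-8`, `m_bin_alg = 2.74e-8`, `m_bin_sau = 5.74e-8`;
#' `mu = 2.8e-9` per site per generation and a 1-year generation time.
#' The `bin` deme's size is anchored from nucleotide diversity
#' (`N_e = pi / (4 mu)`); the published analysis does not print the anchor,
#' so the default corresponds to `pi = 0.0112` at this `mu`.
#'
#' @param anchor fixed diploid size of the `bin` deme (default 1e6).
#' @param mu mutation rate per site per generation.
#' @return a `demographic_model`.
#' @export
study_model <- function(anchor = 1e6, mu = 2.8e-9) {
  demographic_model(
    model_spec("fusion", "contemporary"),
    N_bin = anchor, N_sau = 2834490, N_alg = 680545,
    N_anc = 40956, N_anc_sau = 933380, N_anc_bin = 9721,
    T_div1 = 2052400, T_hyb = 1365495, gamma_hyb = 0.24,
    m_sau_alg = 7.19e-8, m_bin_alg = 2.74e-8, m_bin_sau = 5.74e-8,
    mu = mu, generation_time_years = 1
  )
}

#' Mask genotype calls at random
#'
#' Masks each genotype call independently with probability `rate`,
#' emulating the high missingness of reduced-representation SNP matrices.
#' Deterministic given `seed`.
#'
#' @param dataset a `snp_dataset`.
#' @param rate missingness rate in `[0, 1)`.
#' @param seed integer seed.
#' @return a `snp_dataset` with calls replaced by `NA`.
#' @export
apply_missingness <- function(dataset, rate, seed = 1) {
  stopifnot(inherits(dataset, "snp_dataset"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(dataset)
  geno <- dataset$geno
  mask <- .with_seed(.derive_seed(seed, 11), {
    matrix(runif(length(geno)) < rate, nrow(geno), ncol(geno))
  })
  geno[mask] <- NA_integer_
  snp_dataset(geno, dataset$samples, dataset$loci)
}

# per-locus retained polymorphic mass under hypergeometric projection:
# 0 if any deme's non-missing haploid count is below the projection size,
# else 1 minus the projected probability of being monomorphic
.retained_mass <- function(geno, cols, projection) {
  n_loci <- nrow(geno)
  p_all0 <- rep(1, n_loci)
  p_all1 <- rep(1, n_loci)
  covered <- rep(TRUE, n_loci)
  for (k in seq_along(cols)) {
    g <- geno[, cols[[k]], drop = FALSE]
    d <- rowSums(g, na.rm = TRUE)
    nobs <- 2 * rowSums(!is.na(g))
    m <- projection[k]
    ok <- nobs >= m
    covered <- covered & ok
    q0 <- q1 <- rep(1, n_loci)
    q0[ok] <- dhyper(0, d[ok], nobs[ok] - d[ok], m)
    q1[ok] <- dhyper(m, d[ok], nobs[ok] - d[ok], m)
    p_all0 <- p_all0 * q0
    p_all1 <- p_all1 * q1
  }
  ifelse(covered, pmax(0, 1 - p_all0 - p_all1), 0)
}

#' Generate a study-like SNP dataset with known ground truth
#'
#' Simulates unlinked SNPs under the speciation-by-fusion study model
#' ([study_model()]) for three demes plus an outgroup (a fourth deme
#' splitting from the root at `2 * T_div1` with size `N_anc`, used only to
#' polarize D-statistic sites), applies independent genotype missingness,
#' and sizes the dataset so that the default 50%-of-individuals projection
#' retains approximately `ceiling(scale * 1998)` variable SNPs. Loci are
#' simulated in fixed-size chunks and kept in order until the target
#' retained mass is reached, so regeneration from the returned truth record
#' is bit-identical.
#'
#' @param scale fraction of the full study size (0 < scale <= 1).
#' @param seed integer seed.
#' @param missing_rate genotype missingness rate (default 0.6).
#' @param n_diploid named diploid sample sizes for `bin`, `sau`, `alg`.
#' @param n_out_diploid diploid outgroup sample size.
#' @param anchor,mu passed to [study_model()].
#' @return a list with components `dataset` (a `snp_dataset`) and `truth`
#'   (a `truth_record`: the generating model, sample configuration, locus
#'   count, missingness rate, scale, seed and target).
#' @export
generate_study_like <- function(scale = 1.0, seed = 1, missing_rate = 0.6,
                                n_diploid = c(bin = 18, sau = 14, alg = 6),
                                n_out_diploid = 4, anchor = 1e6,
                                mu = 2.8e-9) {
  if (scale <= 0 || scale > 1) stop("scale must lie in (0, 1]")
  target <- ceiling(scale * 1998)
  model <- study_model(anchor = anchor, mu = mu)
  samples <- sample_config(2 * n_diploid[["bin"]], 2 * n_diploid[["sau"]],
                           2 * n_diploid[["alg"]], 2 * n_out_diploid)
  projection <- 2L * pmax(1L, as.integer(n_diploid) %/% 2L)
  chunk_size <- 2000L
  chunks <- list()
  cum_mass <- 0
  chunk_i <- 0L
  n_keep <- 0L
  while (cum_mass < target) {
    chunk_i <- chunk_i + 1L
    if (chunk_i > 200L) stop("failed to reach target SNP count")
    ds <- simulate_snp_dataset(model, samples, chunk_size,
                               seed = .derive_seed(seed, 100 + chunk_i))
    ds <- apply_missingness(ds, missing_rate,
                            seed = .derive_seed(seed, 300 + chunk_i))
    cols <- lapply(c("bin", "sau", "alg"), function(d) {
      which(ds$samples$deme == d)
    })
    mass <- .retained_mass(ds$geno, cols, projection)
    cum <- cum_mass + cumsum(mass)
    if (cum[chunk_size] >= target) {
      n_keep <- which(cum >= target)[1]
      chunks[[chunk_i]] <- list(ds = ds, keep = n_keep)
      cum_mass <- cum[n_keep]
    } else {
      chunks[[chunk_i]] <- list(ds = ds, keep = chunk_size)
      cum_mass <- cum[chunk_size]
    }
  }
  geno <- do.call(rbind, lapply(chunks, function(ch) {
    ch$ds$geno[seq_len(ch$keep), , drop = FALSE]
  }))
  n_loci <- nrow(geno)
  loci <- paste0("locus_", seq_len(n_loci))
  dataset <- snp_dataset(geno, chunks[[1]]$ds$samples, loci)
  truth <- structure(list(
    model = model, samples = samples,
    n_diploid = n_diploid, n_out_diploid = n_out_diploid,
    n_loci = n_loci, missing_rate = missing_rate, scale = scale,
    seed = seed, target_snps = target, retained_mass = cum_mass,
    projection = projection, anchor = anchor, mu = mu
  ), class = "truth_record")
  list(dataset = dataset, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf(
    "<truth_record> %s at study point estimates; %d loci, %.0f%% missing,\n",
    format(x$model$spec), x$n_loci, 100 * x$missing_rate))
  cat(sprintf("  scale %.2f targeting %d retained SNPs (got %.1f), seed %d\n",
              x$scale, x$target_snps, x$retained_mass, x$seed))
  invisible(x)
}

#' Serialize a truth record to JSON
#'
#' @param truth a `truth_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_record <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  doc <- list(
    topology = truth$model$spec$topology,
    gene_flow = truth$model$spec$gene_flow,
    params = as.list(truth$model$params),
    mu = truth$mu, anchor = truth$anchor,
    n_diploid = as.list(truth$n_diploid),
    n_out_diploid = truth$n_out_diploid,
    n_loci = truth$n_loci, missing_rate = truth$missing_rate,
    scale = truth$scale, seed = truth$seed,
    target_snps = truth$target_snps, retained_mass = truth$retained_mass,
    projection = truth$projection
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
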