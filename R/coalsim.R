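# Deme indexing used throughout the simulator: 1 = bin, 2 = sau, 3 = alg,
# 4 = out (outgroup, only when sampled).
.DEMES <- c("bin", "sau", "alg")

#' Haploid sample configuration
#'
#' @param n_bin,n_sau,n_alg haploid sample sizes for the three demes.
#' @param n_out haploid outgroup sample size (used only for D-statistic
#'   datasets; the outgroup never enters the joint SFS).
#' @return an object of class `sample_config` (named integer vector).
#' @export
sample_config <- function(n_bin, n_sau, n_alg, n_out = 0) {
  n <- c(bin = as.integer(n_bin), sau = as.integer(n_sau),
         alg = as.integer(n_alg), out = as.integer(n_out))
  if (any(is.na(n)) || any(n < 0)) stop("sample sizes must be >= 0")
  if (sum(n) < 2) stop("total sample size must be >= 2")
  structure(n, class = "sample_config")
}

# Deterministic small-integer seed streams derived from one user seed.
# Exact in double arithmetic (result < 2^41) and scrambled again by the
# engine's splitmix64 initializer.
.derive_seed <- function(seed, k) {
  ((seed %% 1048576) * 2097152 + (k %% 2097152)) + 1
}

# Run `expr` under a local R RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Compile a demographic_model into the epoch/event arrays consumed by the
# C++ engine. Epochs are the intervals between consecutive events; a pulse
# and a merge emitted at the same instant are processed in listed order
# (pulse first), with a zero-length epoch between them.
.compile_demography <- function(model, include_outgroup = FALSE,
                                N_out = NULL, T_out = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  p <- as.list(model$params)
  spec <- model$spec
  K <- if (include_outgroup) 4L else 3L
  if (include_outgroup) {
    if (is.null(N_out)) N_out <- p$N_anc
    if (is.null(T_out)) T_out <- 2 * p$T_div1
    if (T_out <= p$T_div1) stop("outgroup split must predate T_div1")
  }

  ev <- list()  # each: list(time, type (0 pulse / 1 merge), src, dst, prob)
  sizes <- list()
  migs <- list()
  contemp_mig <- function() {
    M <- matrix(0, K, K)
    if (spec$gene_flow %in% c("contemporary", "full")) {
      M[1, 2] <- M[2, 1] <- p$m_bin_sau
      M[1, 3] <- M[3, 1] <- p$m_bin_alg
      M[2, 3] <- M[3, 2] <- p$m_sau_alg
    }
    M
  }
  anc_mig <- function() {
    M <- matrix(0, K, K)
    if (spec$gene_flow %in% c("ancestral", "full")) {
      M[1, 2] <- M[2, 1] <- p$m_anc
    }
    M
  }
  sz <- function(bin = 0, sau = 0, alg = 0) {
    out <- c(bin, sau, alg)
    if (include_outgroup) out <- c(out, N_out)
    out
  }
  push_epoch <- function(s, m) {
    sizes[[length(sizes) + 1]] <<- s
    migs[[length(migs) + 1]] <<- m
  }
  push_event <- function(time, type, src, dst, prob = 1) {
    ev[[length(ev) + 1]] <<- list(time = time, type = type, src = src,
                                  dst = dst, prob = prob)
  }

  if (spec$topology == "fusion") {
    push_epoch(sz(p$N_bin, p$N_sau, p$N_alg), contemp_mig())
    push_event(p$T_hyb, 0L, 3L, 1L, p$gamma_hyb)   # pulse alg -> bin
    push_epoch(sz(p$N_bin, p$N_sau, p$N_alg), contemp_mig())  # zero-length
    push_event(p$T_hyb, 1L, 3L, 2L)                # remaining alg -> sau
    push_epoch(sz(p$N_anc_bin, p$N_anc_sau, 0), anc_mig())
    push_event(p$T_div1, 1L, 1L, 2L)
    push_epoch(sz(0, p$N_anc, 0), matrix(0, K, K))
  } else {
    if (spec$topology == "introgression") {
      push_epoch(sz(p$N_bin, p$N_sau, p$N_alg), contemp_mig())
      push_event(p$T_int, 0L, 3L, 1L, p$gamma_int)  # pulse alg -> bin
    }
    push_epoch(sz(p$N_bin, p$N_sau, p$N_alg), contemp_mig())
    push_event(p$T_div2, 1L, 3L, 2L)               # alg -> sau
    push_epoch(sz(p$N_bin, p$N_anc_sau, 0), anc_mig())
    push_event(p$T_div1, 1L, 1L, 2L)
    push_epoch(sz(0, p$N_anc, 0), matrix(0, K, K))
  }
  if (include_outgroup) {
    push_event(T_out, 1L, 4L, 2L)
    last <- sizes[[length(sizes)]]
    last[4] <- 0
    push_epoch(last, matrix(0, K, K))
  }

  times <- vapply(ev, `[[`, numeric(1), "time")
  if (is.unsorted(times)) stop("internal error: events out of order")
  list(
    n_demes = K,
    ev_time = times,
    ev_type = vapply(ev, `[[`, integer(1), "type"),
    ev_src = vapply(ev, function(e) as.integer(e$src - 1L), integer(1)),
    ev_dst = vapply(ev, function(e) as.integer(e$dst - 1L), integer(1)),
    ev_prob = vapply(ev, `[[`, numeric(1), "prob"),
    sizes = unlist(sizes),
    mig = unlist(migs)
  )
}

.samples_vec <- function(samples, K) {
  stopifnot(inherits(samples, "sample_config"))
  as.integer(samples[seq_len(K)])
}

#' Simulate one genealogy under a demographic model
#'
#' Backward-time structured coalescent: continuous migration within each
#' epoch at the model's rates, instantaneous admixture pulses (each `alg`
#' lineage jumps to `bin` with probability gamma at the pulse time,
#' otherwise to `sau` under fusion / stays in `alg` under introgression),
#' deme mergers at the divergence times, and full coalescence in the root
#' deme.
#'
#' @param model a `demographic_model`.
#' @param samples a `sample_config` (haploid sizes). If `n_out > 0` an
#'   outgroup deme is attached, splitting from the root deme at
#'   `2 * T_div1` with size `N_anc`.
#' @param seed integer seed (all simulator randomness is explicit).
#' @return a `genealogy`: node times (generations), parent pointers
#'   (`NA` at the root), and deme labels of the leaves. Leaves are nodes
#'   `1..n`, ordered by deme (`bin`, `sau`, `alg`, `out`).
#' @export
simulate_genealogy <- function(model, samples, seed) {
  out <- samples[["out"]] > 0
  dem <- .compile_demography(model, include_outgroup = out)
  K <- if (out) 4L else 3L
  g <- cpp_simulate_genealogy(dem, .samples_vec(samples, K),
                              .derive_seed(seed, 0))
  labels <- c(.DEMES, "out")[g$leaf_deme]
  structure(list(parent = g$parent, time = g$time, leaf_deme = labels,
                 n_leaves = length(labels)),
            class = "genealogy")
}

#' Simulate a dataset of unlinked biallelic SNPs
#'
#' One independent genealogy per locus; a single variant per locus is placed
#' uniformly on the total branch length (infinite sites), so every locus is
#' polymorphic in the full haploid sample. Because short loci carry a SNP
#' with probability proportional to their total branch length, genealogies
#' are drawn length-biased (rejection sampling), making the configuration
#' probabilities exactly proportional to expected subtending branch lengths
#' — the same quantity the composite likelihood uses. Consecutive haploid
#' lineages within a deme are paired into diploid individuals.
#'
#' @inheritParams simulate_genealogy
#' @param n_loci number of SNP loci.
#' @return a `snp_dataset` with diploid genotypes coded 0/1/2.
#' @export
simulate_snp_dataset <- function(model, samples, n_loci, seed) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  out <- samples[["out"]] > 0
  K <- if (out) 4L else 3L
  n <- .samples_vec(samples, K)
  if (any(n %% 2L != 0L)) {
    stop("haploid sample sizes must be even to form diploid genotypes")
  }
  dem <- .compile_demography(model, include_outgroup = out)
  hap <- cpp_simulate_snps(dem, n, as.integer(n_loci), .derive_seed(seed, 1))
  geno <- hap[, seq(1, ncol(hap), by = 2), drop = FALSE] +
    hap[, seq(2, ncol(hap), by = 2), drop = FALSE]
  demes <- rep(c(.DEMES, "out")[seq_len(K)], times = n %/% 2L)
  ids <- paste0(demes, "_", unlist(lapply(n %/% 2L, seq_len)))
  colnames(geno) <- ids
  snp_dataset(geno,
              samples = data.frame(id = ids, deme = demes,
                                   outgroup = demes == "out",
                                   stringsAsFactors = FALSE),
              loci = paste0("locus_", seq_len(n_loci)))
}

#' Monte-Carlo expected folded joint SFS under a model
#'
#' Simulates `n_sims` genealogies and accumulates, for every joint
#' allele-count configuration, the expected branch length subtending that
#' configuration; under infinite sites with one variant per locus placed
#' uniformly on the tree, entry probabilities conditional on polymorphism
#' are proportional to these branch lengths. The spectrum is folded on the
#' global minor allele, monomorphic entries are excluded, and entries with
#' zero simulated mass are floored at `1 / (10 * n_sims)` before
#' renormalization (so observed data never meet a zero probability).
#'
#' @inheritParams simulate_genealogy
#' @param n_sims number of simulated genealogies (>= 1000).
#' @return a `joint_sfs` whose mass is a probability distribution
#'   (`sum = 1`) over folded polymorphic entries.
#' @export
expected_sfs <- function(model, samples, n_sims, seed) {
  if (n_sims < 1000) stop("n_sims must be >= 1000")
  if (samples[["out"]] > 0) {
    stop("the joint SFS is defined over the three focal demes; set n_out = 0")
  }
  dem <- .compile_demography(model, include_outgroup = FALSE)
  n <- .samples_vec(samples, 3L)
  raw <- cpp_expected_branch_sfs(dem, n, as.integer(n_sims),
                                 .derive_seed(seed, 2))
  nz <- n[n > 0]
  arr <- array(raw, dim = nz + 1L)
  arr <- .fold_mass(arr)
  arr <- .zero_monomorphic(arr)
  tot <- sum(arr)
  if (tot <= 0) stop("no polymorphic branch mass simulated")
  arr <- arr / tot
  sup <- .folded_support(dim(arr))
  floor_p <- 1 / (10 * n_sims)
  zero <- sup & arr == 0
  if (any(zero)) {
    arr[zero] <- floor_p
    arr <- arr / sum(arr)
  }
  new_joint_sfs(arr, n = nz, folded = TRUE, polymorphic_only = TRUE,
                probability = TRUE)
}

#' Simulate a folded joint SFS of a given number of SNPs
#'
#' Convenience wrapper: simulates `n_snps` unlinked polymorphic SNPs at the
#' configured haploid sample sizes and tabulates their folded joint spectrum
#' directly (no projection, no missing data).
#'
#' @inheritParams simulate_genealogy
#' @param n_snps number of polymorphic SNPs.
#' @return a `joint_sfs` of counts (total mass `n_snps`).
#' @export
simulate_sfs <- function(model, samples, n_snps, seed) {
  if (samples[["out"]] > 0) stop("set n_out = 0 for SFS simulation")
  dem <- .compile_demography(model, include_outgroup = FALSE)
  n <- .samples_vec(samples, 3L)
  hap <- cpp_simulate_snps(dem, n, as.integer(n_snps), .derive_seed(seed, 1))
  deme_of <- rep(seq_len(3L), times = n)
  counts <- vapply(which(n > 0), function(d) {
    rowSums(hap[, deme_of == d, drop = FALSE])
  }, numeric(n_snps))
  nz <- n[n > 0]
  mult <- cumprod(c(1, nz[-length(nz)] + 1))
  idx <- as.vector(counts %*% mult) + 1
  arr <- array(tabulate(idx, nbins = prod(nz + 1L)), dim = nz + 1L)
  arr <- .zero_monomorphic(.fold_mass(arr))
  new_joint_sfs(arr, n = nz, folded = TRUE, polymorphic_only = TRUE)
}

#' Distribution of pairwise times to common ancestry
#'
#' Simulates replicate genealogies and returns the time to the most recent
#' common ancestor of the full sample; used for calibration checks against
#' closed forms and independent simulators.
#'
#' @inheritParams simulate_genealogy
#' @param n_sims number of replicate genealogies.
#' @return numeric vector of TMRCAs in generations.
#' @export
simulate_tmrca <- function(model, samples, n_sims, seed) {
  out <- samples[["out"]] > 0
  K <- if (out) 4L else 3L
  dem <- .compile_demography(model, include_outgroup = out)
  cpp_sim_tmrca(dem, .samples_vec(samples, K), as.integer(n_sims),
                .derive_seed(seed, 3))
}
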