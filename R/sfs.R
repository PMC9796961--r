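#' SNP dataset of unlinked biallelic loci
#'
#' Container for diploid genotypes at unlinked biallelic SNPs (one SNP per
#' locus), coded as 0/1/2 copies of the alternate allele with `NA` for
#' missing calls, together with an individual-to-deme assignment and an
#' outgroup flag.
#'
#' @param geno integer matrix, loci x individuals, values 0/1/2/`NA`.
#' @param samples data.frame with columns `id`, `deme` and logical
#'   `outgroup`; one row per genotype column, in column order.
#' @param loci character vector of locus identifiers (default generated).
#' @return an object of class `snp_dataset`.
#' @export
snp_dataset <- function(geno, samples, loci = NULL) {
  geno <- as.matrix(geno)
  if (!all(geno %in% c(0L, 1L, 2L, NA))) {
    stop("genotypes must be 0, 1, 2 or NA")
  }
  storage.mode(geno) <- "integer"
  if (!is.data.frame(samples) ||
      !all(c("id", "deme") %in% names(samples))) {
    stop("samples must be a data.frame with columns id and deme")
  }
  if (is.null(samples$outgroup)) samples$outgroup <- FALSE
  if (nrow(samples) != ncol(geno)) {
    stop("samples rows must match genotype columns")
  }
  if (anyDuplicated(samples$id)) stop("individual IDs must be unique")
  if (any(!nzchar(samples$deme)) || anyNA(samples$deme)) {
    stop("every individual needs a non-empty deme label")
  }
  if (is.null(loci)) loci <- paste0("locus_", seq_len(nrow(geno)))
  if (length(loci) != nrow(geno)) stop("loci length must match rows")
  colnames(geno) <- samples$id
  rownames(geno) <- loci
  structure(list(geno = geno, samples = samples, loci = loci),
            class = "snp_dataset")
}

#' @export
print.snp_dataset <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf("<snp_dataset> %d loci x %d individuals (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * miss))
  print(table(x$samples$deme))
  invisible(x)
}

new_joint_sfs <- function(mass, n, folded, polymorphic_only,
                          probability = FALSE) {
  mass <- as.array(mass)
  if (!identical(dim(mass), as.integer(n + 1L))) {
    stop("mass dimensions must be n + 1")
  }
  if (any(mass < 0)) stop("SFS entries must be non-negative")
  structure(list(mass = mass, n = as.integer(n), folded = folded,
                 polymorphic_only = polymorphic_only,
                 probability = probability, n_snps = sum(mass)),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf(
    "<joint_sfs> haploid sizes (%s), %s, %s; total mass %.4g%s\n",
    paste(x$n, collapse = ", "),
    if (x$folded) "folded" else "unfolded",
    if (x$polymorphic_only) "polymorphic-only" else "all entries",
    x$n_snps,
    if (x$probability) " (probability scale)" else " SNPs"))
  invisible(x)
}

# total derived count per cell, as an array matching arr
.tot_index <- function(dims) {
  arr <- array(0, dim = dims)
  Reduce(`+`, lapply(seq_along(dims), function(k) slice.index(arr, k) - 1))
}

# fold an unfolded mass array on the global minor allele; cells at exactly
# half total frequency receive the average of the complementary pair
.fold_mass <- function(arr) {
  dims <- dim(arr)
  if (is.null(dims)) dims <- length(arr)
  n <- dims - 1L
  N <- sum(n)
  rev_arr <- do.call(`[`, c(list(arr),
                            lapply(dims, function(d) d:1),
                            list(drop = FALSE)))
  tot <- .tot_index(dims)
  out <- arr + rev_arr
  out[2 * tot > N] <- 0
  half <- 2 * tot == N
  out[half] <- out[half] / 2
  out
}

.zero_monomorphic <- function(arr) {
  dims <- dim(arr)
  tot <- .tot_index(dims)
  arr[tot == 0 | tot == sum(dims - 1L)] <- 0
  arr
}

# cells a folded polymorphic spectrum can occupy
.folded_support <- function(dims) {
  tot <- .tot_index(dims)
  N <- sum(dims - 1L)
  tot >= 1 & 2 * tot <= N
}

#' Fold a joint SFS on the global minor allele
#'
#' Entries `(i, j, k)` and `(n1 - i, n2 - j, n3 - k)` are combined onto the
#' side whose summed count is below half the total sample size; pairs at
#' exactly half frequency are averaged between the two cells, so total mass
#' is preserved. Idempotent.
#'
#' @param sfs a `joint_sfs` (folded or unfolded).
#' @return a folded `joint_sfs`.
#' @export
fold_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "joint_sfs"))
  mass <- .fold_mass(sfs$mass)
  if (sfs$polymorphic_only) mass <- .zero_monomorphic(mass)
  new_joint_sfs(mass, sfs$n, folded = TRUE,
                polymorphic_only = sfs$polymorphic_only,
                probability = sfs$probability)
}

#' Hypergeometric projection of an allele count
#'
#' Distributes the mass of `derived` copies observed among `n_from`
#' non-missing haploid copies over counts `0..n_to` in a downsampled set of
#' `n_to` copies, by the expectation over all subsamples without
#' replacement: entry `j` equals
#' `choose(derived, j) * choose(n_from - derived, n_to - j) / choose(n_from, n_to)`.
#'
#' @param derived derived (alternate) allele count, `0 <= derived <= n_from`.
#' @param n_from observed non-missing haploid size.
#' @param n_to target haploid size, `1 <= n_to <= n_from`.
#' @return numeric vector of length `n_to + 1` summing to 1.
#' @export
#' @examples
#' project_counts(2, 4, 2)  # 1/6, 4/6, 1/6
project_counts <- function(derived, n_from, n_to) {
  if (n_to < 1 || n_to > n_from) stop("need 1 <= n_to <= n_from")
  if (derived < 0 || derived > n_from) stop("need 0 <= derived <= n_from")
  dhyper(0:n_to, derived, n_from - derived, n_to)
}

#' Folded joint SFS from SNP genotypes with projection
#'
#' For each locus and deme, the observed non-missing allele counts are
#' projected down to the target haploid size by the expected hypergeometric
#' mass (deterministic, variance-free); loci whose non-missing haploid count
#' falls below the projection size in any deme are dropped. The spectrum is
#' then folded on the global minor allele and monomorphic entries are zeroed
#' (mass that projection sends to monomorphic cells is discarded, matching
#' an analysis conditioned on polymorphism). The retained number of variable
#' SNPs is the total remaining mass.
#'
#' @param dataset a `snp_dataset`; outgroup individuals are ignored.
#' @param projection named or positional haploid sizes for demes
#'   (`bin`, `sau`, `alg`). Default: 50% of the individuals per deme
#'   (rounded down, at least one diploid), i.e. `2 * max(1, floor(n/2))`
#'   haploids.
#' @param demes the three deme labels, in axis order.
#' @return a folded, polymorphic-only `joint_sfs`.
#' @export
joint_sfs <- function(dataset, projection = NULL,
                      demes = c("bin", "sau", "alg")) {
  stopifnot(inherits(dataset, "snp_dataset"))
  if (nrow(dataset$geno) == 0) stop("empty dataset")
  if (length(demes) != 3) stop("exactly three demes required")
  cols <- lapply(demes, function(d) {
    which(dataset$samples$deme == d & !dataset$samples$outgroup)
  })
  n_ind <- vapply(cols, length, integer(1))
  if (any(n_ind == 0)) {
    stop("no individuals for deme(s): ",
         paste(demes[n_ind == 0], collapse = ", "))
  }
  if (is.null(projection)) {
    projection <- 2L * pmax(1L, n_ind %/% 2L)
  }
  projection <- as.integer(projection)
  if (any(projection < 1)) stop("projection sizes must be >= 1")
  if (any(projection > 2L * n_ind)) {
    stop("projection sizes cannot exceed observed haploid sizes")
  }
  n_loci <- nrow(dataset$geno)
  d_mat <- matrix(0L, n_loci, 3)
  nobs_mat <- matrix(0L, n_loci, 3)
  for (k in 1:3) {
    g <- dataset$geno[, cols[[k]], drop = FALSE]
    d_mat[, k] <- as.integer(rowSums(g, na.rm = TRUE))
    nobs_mat[, k] <- as.integer(2L * rowSums(!is.na(g)))
  }
  raw <- cpp_project_joint_sfs(d_mat, nobs_mat, projection)
  arr <- array(raw, dim = projection + 1L)
  arr <- .zero_monomorphic(.fold_mass(arr))
  new_joint_sfs(arr, n = projection, folded = TRUE, polymorphic_only = TRUE)
}

#' Read and write dadi-style joint SFS text files
#'
#' Line 1: the per-axis lengths (`n + 1`) followed by `folded` or
#' `unfolded`. Line 2: the entries flattened in row-major (C) order, last
#' axis fastest. Line 3: a 0/1 mask row (1 = masked entry), same order.
#' Masked entries are zeroed on read. The writer prints 17 significant
#' digits, so write/read round-trips are bit-exact.
#'
#' @param sfs a `joint_sfs`.
#' @param path file path.
#' @return `read_sfs` returns a `joint_sfs`; `write_sfs` returns `path`
#'   invisibly.
#' @export
write_sfs <- function(sfs, path) {
  stopifnot(inherits(sfs, "joint_sfs"))
  dims <- dim(sfs$mass)
  flat <- function(a) as.vector(aperm(a, rev(seq_along(dims))))
  mask <- array(0L, dim = dims)
  tot <- .tot_index(dims)
  N <- sum(dims - 1L)
  if (sfs$polymorphic_only) mask[tot == 0 | tot == N] <- 1L
  if (sfs$folded) mask[2 * tot > N] <- 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(dims, if (sfs$folded) "folded" else "unfolded"),
                   collapse = " "), con)
  writeLines(paste(sprintf("%.17g", flat(sfs$mass)), collapse = " "), con)
  writeLines(paste(flat(mask), collapse = " "), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("SFS file needs a header and an entry row")
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  fold_tok <- tolower(head_tok[length(head_tok)])
  if (fold_tok %in% c("folded", "unfolded")) {
    dims <- suppressWarnings(as.integer(head_tok[-length(head_tok)]))
    folded <- fold_tok == "folded"
  } else {
    dims <- suppressWarnings(as.integer(head_tok))
    folded <- FALSE
  }
  if (anyNA(dims) || any(dims < 2)) stop("malformed SFS header: ", lines[1])
  vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]]))
  if (length(vals) != prod(dims) || anyNA(vals)) {
    stop(sprintf("SFS entry row has %d values; header implies %d",
                 length(vals), prod(dims)))
  }
  unflat <- function(v) aperm(array(v, dim = rev(dims)),
                              rev(seq_along(dims)))
  arr <- unflat(vals)
  poly <- FALSE
  if (length(lines) >= 3) {
    mk <- suppressWarnings(as.integer(strsplit(trimws(lines[3]),
                                               "\\s+")[[1]]))
    if (length(mk) != prod(dims) || anyNA(mk)) {
      stop("SFS mask row does not match header dimensions")
    }
    mask <- unflat(mk)
    arr[mask == 1L] <- 0
    tot <- .tot_index(dims)
    poly <- mask[tot == 0][1] == 1L
  }
  new_joint_sfs(arr, n = dims - 1L, folded = folded,
                polymorphic_only = poly)
}
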