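#' Read an individual-to-deme grouping table
#'
#' Tab-separated with a header; columns `id`, `deme` and optionally a
#' logical/0-1 `outgroup` column. IDs must be unique and labels non-empty.
#'
#' @param path TSV path.
#' @return a data.frame with columns `id`, `deme`, `outgroup`.
#' @export
read_grouping <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("id", "deme") %in% names(tab))) {
    stop("grouping table needs columns 'id' and 'deme'")
  }
  if (anyDuplicated(tab$id)) stop("duplicate individual IDs in grouping")
  if (any(!nzchar(tab$deme)) || anyNA(tab$deme)) {
    stop("deme labels must be non-empty")
  }
  tab$outgroup <- if (is.null(tab$outgroup)) FALSE else as.logical(tab$outgroup)
  tab[, c("id", "deme", "outgroup")]
}

#' @rdname read_grouping
#' @param grouping a grouping data.frame.
#' @export
write_grouping <- function(grouping, path) {
  write.table(grouping, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.GT_CODES <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
               "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)

#' Read biallelic SNP genotypes from a VCF file
#'
#' Keeps biallelic SNP records only (single-base REF and ALT); multiallelic
#' and indel records are skipped with a message. Genotypes are recoded to
#' 0/1/2 copies of the ALT allele, with any genotype containing `.` treated
#' as missing. Every sample in the VCF must appear in the grouping table.
#'
#' @param path VCF path (plain text or gzipped).
#' @param grouping a grouping data.frame (see [read_grouping()]) or a path
#'   to one.
#' @return a `snp_dataset`.
#' @export
read_vcf <- function(path, grouping) {
  if (is.character(grouping)) grouping <- read_grouping(grouping)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) {
                  stop("malformed VCF '", path, "': ", conditionMessage(e))
                })
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(sprintf("skipped %d non-biallelic-SNP record(s)", n_skip))
  }
  if (!any(keep)) stop("no biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  ids <- colnames(gt)
  unknown <- setdiff(ids, grouping$id)
  if (length(unknown) > 0) {
    stop("sample IDs absent from grouping table: ",
         paste(unknown, collapse = ", "))
  }
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt))
  known <- gt %in% names(.GT_CODES)
  geno[known] <- .GT_CODES[gt[known]]
  loci <- fix[keep, "ID"]
  if (anyNA(loci) || any(loci == ".") || anyDuplicated(loci)) {
    loci <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])
  }
  samples <- grouping[match(ids, grouping$id), , drop = FALSE]
  rownames(samples) <- NULL
  snp_dataset(geno, samples, loci)
}

#' Write a SNP dataset as a plain-text VCF
#'
#' One record per locus (CHROM = locus ID, POS = 1, REF = A, ALT = T, which
#' is sufficient for unlinked loci with no genomic coordinates); genotypes
#' are written as `0/0`, `0/1`, `1/1` or `./.`. The output re-reads with
#' [read_vcf()] to an identical dataset.
#'
#' @param dataset a `snp_dataset`.
#' @param path output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dataset, path) {
  stopifnot(inherits(dataset, "snp_dataset"))
  gt_str <- c("0/0", "0/1", "1/1")
  geno <- dataset$geno
  body <- matrix("./.", nrow(geno), ncol(geno))
  ok <- !is.na(geno)
  body[ok] <- gt_str[geno[ok] + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=fusioncoal",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$samples$id), collapse = "\t"),
    paste(dataset$loci, 1L, dataset$loci, "A", "T", ".", ".", ".", "GT",
          apply(body, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
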