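#' Construct a cohort genotype matrix
#'
#' The central container of the pipeline: N samples genotyped at L loci.
#' Genotypes are unordered diploid allele pairs coded as allele indices
#' (0 = reference, i = i-th alternative allele of the locus); phase is never
#' used by the analysis and is discarded. Missing calls are `NA` in both
#' allele slots.
#'
#' @param samples Character vector of unique sample identifiers (N > 0).
#' @param loci Data frame with columns `chrom`, `pos` (1-based), `id`
#'   (variant identifier or `NA`), `ref`, and `alt` (comma-separated
#'   alternative alleles for multi-allelic records).
#' @param allele1,allele2 Integer L x N matrices of allele indices. Pairs are
#'   stored unordered; the constructor sorts each pair so that
#'   `allele1 <= allele2`.
#' @return An object of class `genotype_matrix`.
#' @seealso [read_cohort_vcf()], [write_cohort_vcf()]
#' @export
genotype_matrix <- function(samples, loci, allele1, allele2) {
  samples <- as.character(samples)
  if (length(samples) == 0L) stop_input("a cohort needs at least one sample")
  if (anyDuplicated(samples)) stop_input("duplicate sample identifiers")
  required <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(required %in% names(loci))) {
    stop_input("loci must have columns %s", paste(required, collapse = ", "))
  }
  loci <- as.data.frame(loci)[required]
  loci$pos <- as.integer(loci$pos)
  if (any(loci$pos < 1L)) stop_input("locus positions must be >= 1")
  if (!all(valid_allele(loci$ref))) stop_input("invalid reference allele")
  alts <- strsplit(loci$alt, ",", fixed = TRUE)
  if (any(lengths(alts) == 0L) || !all(valid_allele(unlist(alts)))) {
    stop_input("invalid alternative allele")
  }
  if (any(mapply(function(r, a) r %in% a, loci$ref, alts))) {
    stop_input("reference allele duplicated among alternatives")
  }
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  L <- nrow(loci); N <- length(samples)
  if (!identical(dim(allele1), c(L, N)) || !identical(dim(allele2), c(L, N))) {
    stop_input("allele matrices must be %d x %d", L, N)
  }
  n_all <- lengths(alts)
  bad <- allele1 < 0L | allele2 < 0L | allele1 > n_all | allele2 > n_all
  if (any(bad, na.rm = TRUE)) stop_input("allele index outside the locus alleles")
  if (any(is.na(allele1) != is.na(allele2))) {
    stop_input("half-missing genotype call")
  }
  # unordered pairs: store sorted
  swap <- which(allele1 > allele2)
  if (length(swap)) {
    tmp <- allele1[swap]; allele1[swap] <- allele2[swap]; allele2[swap] <- tmp
  }
  storage.mode(allele1) <- "integer"; storage.mode(allele2) <- "integer"
  dimnames(allele1) <- dimnames(allele2) <- NULL
  structure(list(samples = samples, loci = loci,
                 allele1 = allele1, allele2 = allele2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.1f%% missing calls)\n",
              n_samples(x), n_loci(x),
              100 * mean(is.na(x$allele1))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(n_loci(x), n_samples(x))

#' Cohort dimensions
#'
#' @param gm A [genotype_matrix()].
#' @return `n_samples()` returns N, `n_loci()` returns L.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_loci <- function(gm) nrow(gm$loci)

# Alleles of locus i as a character vector indexed 1 + allele code.
locus_alleles <- function(gm, i) {
  c(gm$loci$ref[i], strsplit(gm$loci$alt[i], ",", fixed = TRUE)[[1]])
}

# Index (0 = ref, 1.. = alts) of an allele string at locus i, or NA.
allele_index <- function(gm, i, allele) {
  m <- match(allele, locus_alleles(gm, i))
  if (is.na(m)) NA_integer_ else m - 1L
}

# Subset loci by integer index, keeping all samples.
subset_loci <- function(gm, idx) {
  structure(list(samples = gm$samples,
                 loci = gm$loci[idx, , drop = FALSE],
                 allele1 = gm$allele1[idx, , drop = FALSE],
                 allele2 = gm$allele2[idx, , drop = FALSE]),
            class = "genotype_matrix")
}

#' Write a cohort genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 file with a GT FORMAT field, one record per locus,
#' genotypes unphased (`/` separator) and missing calls as `./.`. The writer
#' is the exact inverse of [read_cohort_vcf()]: writing and re-reading
#' reproduces samples, loci and calls.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @param header_comments Optional character vector written as `##` meta lines
#'   (used by the simulator to record its seed).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(gm, path, header_comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (cm in header_comments) writeLines(paste0("##", cm), con)
  writeLines(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  if (n_loci(gm) > 0L) {
    gt <- matrix(paste(gm$allele1, gm$allele2, sep = "/"),
                 nrow = n_loci(gm))
    gt[is.na(gm$allele1)] <- "./."
    id <- ifelse(is.na(gm$loci$id) | gm$loci$id == "", ".", gm$loci$id)
    body <- cbind(gm$loci$chrom, gm$loci$pos, id, gm$loci$ref, gm$loci$alt,
                  ".", ".", ".", "GT", gt)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}
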