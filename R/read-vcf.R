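#' Read a multi-sample cohort VCF into a genotype matrix
#'
#' Parses GT fields of a VCF 4.2+ file. Multi-allelic records are preserved
#' with all their alternative alleles; positions stay 1-based; phase
#' separators (`|`) are accepted and ignored; `./.` becomes a missing call.
#' By default only single-nucleotide variants are admitted, matching the
#' scope of the downstream filters.
#'
#' @param path Path to a VCF file with at least one sample column.
#' @param snv_only Drop records whose ref or any alt is longer than one base
#'   (default `TRUE`).
#' @return A [genotype_matrix()] with one column per VCF sample, loci in file
#'   order.
#' @export
read_cohort_vcf <- function(path, snv_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) {
    stop_input("cohort VCF has zero sample columns: %s", path)
  }
  loci <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  loci$id[loci$id %in% "."] <- NA_character_
  samples <- colnames(gt_raw)[-1L]
  if (nrow(loci) == 0L) {
    z <- matrix(integer(), 0L, length(samples))
    return(genotype_matrix(samples, loci, z, z))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L)
  parts <- strsplit(as.vector(gt), "[/|]")
  bad <- !is.na(as.vector(gt)) & lengths(parts) != 2L
  if (any(bad)) {
    stop_input("non-diploid GT '%s' at record %d",
               as.vector(gt)[which(bad)[1L]],
               (which(bad)[1L] - 1L) %% nrow(gt) + 1L)
  }
  a1 <- matrix(NA_integer_, nrow(gt), ncol(gt))
  a2 <- a1
  ok <- !is.na(as.vector(gt))
  first <- vapply(parts[ok], `[`, "", 1L)
  second <- vapply(parts[ok], `[`, "", 2L)
  a1[ok] <- suppressWarnings(as.integer(first))   # "." -> NA
  a2[ok] <- suppressWarnings(as.integer(second))
  half <- is.na(a1) != is.na(a2)
  a1[half] <- NA_integer_; a2[half] <- NA_integer_
  if (snv_only) {
    keep <- nchar(loci$ref) == 1L &
      vapply(strsplit(loci$alt, ",", fixed = TRUE),
             function(a) all(nchar(a) == 1L), logical(1))
    loci <- loci[keep, , drop = FALSE]
    a1 <- a1[keep, , drop = FALSE]; a2 <- a2[keep, , drop = FALSE]
  }
  genotype_matrix(samples, loci, a1, a2)
}

#' Read population allele frequencies from a frequency VCF
#'
#' Supports three dialects of per-record frequency annotation:
#' \describe{
#'   \item{`"freq"`}{the NCBI `freq.vcf` dialect (default): an INFO field
#'     `FREQ=Study:f_ref,f_alt1,...` listing the reference-allele frequency
#'     followed by one frequency per alternative allele. Several
#'     `|`-separated studies may be present; the first (or the one named by
#'     `study`) is used. A `.` entry is a missing estimate; when only the
#'     reference frequency is present the alternative frequency is derived as
#'     `1 - f_ref` for biallelic records only.}
#'   \item{`"af"`}{an `AF=` INFO field holding one alternative-allele
#'     frequency per alt, comma-separated.}
#'   \item{`"ref"`}{an INFO field (`RAF=`) holding a single reference-allele
#'     frequency; alt frequency derived as its complement for biallelic
#'     records, multi-allelic records are unresolvable.}
#' }
#' Records whose frequency cannot be resolved are excluded from the result
#' and returned in the `"unresolved"` attribute.
#'
#' @param path Path to the frequency VCF.
#' @param dialect One of `"freq"`, `"af"`, `"ref"`.
#' @param study For the `"freq"` dialect, the study label to select; `NULL`
#'   takes the first study on each record.
#' @param ref_cohort_size Number of persons behind the frequency estimates
#'   (default 163190, the size of the European reference set used as the
#'   default test denominator downstream).
#' @return Data frame with columns `chrom`, `pos`, `id`, `allele`, `freq`,
#'   `ref_cohort_size`, one row per resolvable alternative allele, in file
#'   order.
#' @export
read_population_frequencies <- function(path,
                                        dialect = c("freq", "af", "ref"),
                                        study = NULL,
                                        ref_cohort_size = 163190) {
  dialect <- match.arg(dialect)
  if (!is_count(ref_cohort_size) || ref_cohort_size <= 0) {
    stop_input("ref_cohort_size must be a positive count")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) return(structure(empty_popfreq(), unresolved = NULL))
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  freqs <- mapply(parse_freq_info, fix[, "INFO"], n_alt,
                  MoreArgs = list(dialect = dialect, study = study),
                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  fv <- unlist(freqs) %||% numeric()
  if (any(!is.na(fv) & (fv < 0 | fv > 1))) {
    bad <- rep(seq_along(freqs), n_alt)[which(!is.na(fv) & (fv < 0 | fv > 1))[1L]]
    stop_input("frequency outside [0,1] at %s:%s",
               fix[bad, "CHROM"], fix[bad, "POS"])
  }
  id <- fix[, "ID"]
  id[id %in% "."] <- NA_character_
  rec <- rep(seq_len(nrow(fix)), n_alt)
  res <- data.frame(chrom = fix[rec, "CHROM"], pos = as.integer(fix[rec, "POS"]),
                    id = id[rec], allele = unlist(alts) %||% character(),
                    freq = fv, ref_cohort_size = ref_cohort_size,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  un <- res[is.na(res$freq), , drop = FALSE]
  res <- res[!is.na(res$freq), , drop = FALSE]
  rownames(res) <- rownames(un) <- NULL
  attr(res, "unresolved") <- if (nrow(un)) un else NULL
  res
}

empty_popfreq <- function() {
  data.frame(chrom = character(), pos = integer(), id = character(),
             allele = character(), freq = numeric(),
             ref_cohort_size = numeric(), stringsAsFactors = FALSE)
}

# One alt-allele frequency per alt, NA where unresolvable.
parse_freq_info <- function(info, n_alt, dialect, study) {
  get_field <- function(tag) {
    m <- regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]*"), info))
    if (!length(m)) return(NA_character_)
    sub(paste0("^;?", tag, "="), "", m)
  }
  if (dialect == "af") {
    raw <- get_field("AF")
    if (is.na(raw)) return(rep(NA_real_, n_alt))
    vals <- suppressWarnings(as.numeric(strsplit(raw, ",", fixed = TRUE)[[1]]))
    length(vals) <- n_alt
    return(vals)
  }
  if (dialect == "ref") {
    raw <- get_field("RAF")
    f_ref <- suppressWarnings(as.numeric(raw))
    if (is.na(f_ref) || n_alt != 1L) return(rep(NA_real_, n_alt))
    return(1 - f_ref)
  }
  # NCBI FREQ dialect: FREQ=Study1:f_ref,f_alt1,..|Study2:...
  raw <- get_field("FREQ")
  if (is.na(raw)) return(rep(NA_real_, n_alt))
  studies <- strsplit(raw, "|", fixed = TRUE)[[1]]
  labels <- sub(":.*$", "", studies)
  pick <- if (is.null(study)) 1L else match(study, labels)
  if (is.na(pick)) return(rep(NA_real_, n_alt))
  vals <- strsplit(sub("^[^:]*:", "", studies[pick]), ",", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(vals))   # "." -> NA
  length(vals) <- n_alt + 1L
  f_alt <- vals[-1L]
  # biallelic record with only the ref frequency stated: complement
  if (n_alt == 1L && is.na(f_alt[1L]) && !is.na(vals[1L])) f_alt <- 1 - vals[1L]
  f_alt
}

#' Write population frequencies as a FREQ-dialect VCF
#'
#' Inverse of [read_population_frequencies()] for the default dialect; used
#' by the synthetic-cohort simulator.
#'
#' @param pf Data frame as returned by [read_population_frequencies()].
#' @param path Output path.
#' @param ref Named character vector mapping `chrom:pos` to the reference
#'   allele (needed because frequency rows only carry alternative alleles).
#' @param study Study label written into the FREQ field.
#' @param header_comments Optional `##` meta lines.
#' @return `path`, invisibly.
#' @export
write_population_frequencies <- function(pf, path, ref, study = "Synthetic",
                                         header_comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (cm in header_comments) writeLines(paste0("##", cm), con)
  writeLines(paste0('##INFO=<ID=FREQ,Number=.,Type=String,Description=',
                    '"Study:ref and alt allele frequencies">'), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"), con)
  if (nrow(pf)) {
    key <- locus_key(pf$chrom, pf$pos)
    groups <- split(seq_len(nrow(pf)), factor(key, levels = unique(key)))
    if (any(!names(groups) %in% names(ref))) {
      stop_input("no reference allele supplied for %s",
                 setdiff(names(groups), names(ref))[1L])
    }
    lines <- vapply(names(groups), function(k) {
      i <- groups[[k]]
      info <- sprintf("FREQ=%s:%s", study,
                      paste(formatC(c(1 - sum(pf$freq[i]), pf$freq[i]),
                                    format = "fg", digits = 10), collapse = ","))
      paste(pf$chrom[i[1L]], pf$pos[i[1L]],
            ifelse(is.na(pf$id[i[1L]]), ".", pf$id[i[1L]]),
            ref[[k]], paste(pf$allele[i], collapse = ","), ".", ".", info,
            sep = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}
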