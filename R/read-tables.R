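#' Read per-allele damage annotations
#'
#' Reads a tab-delimited annotation table (SIFT-style) with columns `chrom`,
#' `pos`, `ref`, `alt`, `prediction`, and optionally `gene`. Predictions form
#' a closed, case-insensitive vocabulary: `TOLERATED` or `DELETERIOUS`; any
#' other label is rejected.
#'
#' @param path Path to the TSV file (header required; `#` lines ignored).
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `prediction`
#'   (normalized to upper case), `gene` (`NA` when absent).
#' @export
read_damage_annotations <- function(path) {
  d <- read_tsv(path)
  names(d) <- tolower(names(d))
  required <- c("chrom", "pos", "ref", "alt", "prediction")
  if (!all(required %in% names(d))) {
    stop_input("damage annotation needs columns %s",
               paste(required, collapse = ", "))
  }
  pred <- toupper(trimws(d$prediction))
  bad <- setdiff(unique(pred), c("TOLERATED", "DELETERIOUS"))
  if (length(bad)) {
    stop_input("unrecognized damage prediction label(s): %s",
               paste(bad, collapse = ", "))
  }
  data.frame(chrom = as.character(d$chrom), pos = as.integer(d$pos),
             ref = as.character(d$ref), alt = as.character(d$alt),
             prediction = pred,
             gene = if ("gene" %in% names(d)) as.character(d$gene) else NA_character_,
             stringsAsFactors = FALSE)
}

#' Read gene annotation from BED or GFF3
#'
#' Accepts BED (0-based half-open, native internal convention) or GFF3
#' (1-based closed, converted on read via [interval_to_zero_based()]). GFF3
#' `gene` features must carry an `ID` attribute. Overlapping genes are
#' retained as-is; no merging is done.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"`, `"gff3"`, or `NULL` to infer from the extension.
#' @return Data frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`.
#' @export
read_gene_annotation <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  format <- match.arg(format, c("bed", "gff3"))
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    types <- as.character(gr$type)
    if (any(types == "gene")) gr <- gr[types == "gene"]
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids)) {
      stop_input("GFF3 gene features must carry an ID attribute")
    }
    symbol <- gr$Name %||% ids
    symbol[is.na(symbol)] <- ids[is.na(symbol)]
  } else {
    ids <- gr$name %||% paste0("gene", seq_along(gr))
    symbol <- ids
  }
  # rtracklayer yields 1-based closed ranges for both formats
  iv <- interval_to_zero_based(GenomicRanges::start(gr), GenomicRanges::end(gr))
  out <- data.frame(gene_id = as.character(ids), symbol = as.character(symbol),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = iv$start, end = iv$end,
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "*"
  if (any(out$start >= out$end)) stop_input("gene interval with start >= end")
  rownames(out) <- NULL
  out
}

#' Write gene annotation as BED
#'
#' Internal gene intervals are already BED-convention (0-based half-open), so
#' the printed coordinates round-trip exactly through
#' [read_gene_annotation()].
#'
#' @param genes Data frame as returned by [read_gene_annotation()].
#' @param path Output path.
#' @param header_comments Optional comment lines (prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path, header_comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in header_comments) writeLines(paste0("#", cm), con)
  if (nrow(genes)) {
    writeLines(paste(genes$chrom,
                     format(genes$start, scientific = FALSE, trim = TRUE),
                     format(genes$end, scientific = FALSE, trim = TRUE),
                     genes$gene_id, 0L,
                     ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a GMT-style gene-set database
#'
#' Each tab-separated line is `category <tab> description <tab> gene1 ...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene identifiers; descriptions
#'   are kept in the `"description"` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop_input("GMT line with fewer than 3 fields")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop_input("duplicate category name in GMT")
  attr(sets, "description") <- setNames(vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' @rdname read_gene_sets
#' @param sets Named list of gene-identifier vectors.
#' @param descriptions Optional named descriptions; defaults to the set name.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% attr(sets, "description") %||%
    setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a quantitative phenotype table
#'
#' Accepts the long layout (`sample`, `measure`, `value`) and returns the
#' wide per-sample table used by the association stage.
#'
#' @param path Path to the TSV file.
#' @return Data frame with a `sample` column and one numeric column per
#'   measure; missing measurements are `NA`.
#' @export
read_phenotypes <- function(path) {
  d <- read_tsv(path)
  names(d) <- tolower(names(d))
  if (!all(c("sample", "measure", "value") %in% names(d))) {
    stop_input("phenotype table needs columns sample, measure, value")
  }
  samples <- unique(as.character(d$sample))
  measures <- unique(as.character(d$measure))
  if (length(measures) == 0L) stop_input("phenotype table has no measures")
  wide <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (m in measures) {
    sel <- d$measure == m
    wide[[m]] <- as.numeric(d$value[sel])[match(samples, d$sample[sel])]
  }
  wide
}

#' @rdname read_phenotypes
#' @param pheno Wide phenotype data frame (`sample` column plus measures).
#' @param header_comments Optional comment lines.
#' @export
write_phenotypes <- function(pheno, path, header_comments = character()) {
  measures <- setdiff(names(pheno), "sample")
  long <- data.frame(
    sample = rep(pheno$sample, times = length(measures)),
    measure = rep(measures, each = nrow(pheno)),
    value = unlist(pheno[measures], use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(long, path, comments = header_comments)
}
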