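# Internal helpers shared across modules.

# Canonical join key for a (locus, allele) pair. Allele joins are always done
# on chrom:pos:allele; dbSNP ids are carried for display only.
locus_allele_key <- function(chrom, pos, allele) {
  paste(chrom, pos, allele, sep = ":")
}

locus_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

valid_allele <- function(a) {
  nzchar(a) & grepl("^[ACGTN]+$", a)
}

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Deterministic TSV writer used for every pipeline output: commented header
# lines first, then a tab-separated table with column names, no quoting, and
# "NA" for missing values.
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}
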