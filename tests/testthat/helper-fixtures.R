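# Fixture builders used across test files. Everything is constructed in
# code; nothing is read from stored data.

# A small genotype matrix from a compact description: `calls` is a list (one
# element per locus) of character vectors like c("0/0", "0/1", "./.").
make_gm <- function(calls, chrom = "chr1", pos = NULL, ref = "A", alt = "G",
                    id = NA_character_, samples = NULL) {
  L <- length(calls)
  N <- length(calls[[1]])
  samples <- samples %||% sprintf("S%02d", seq_len(N))
  pos <- pos %||% seq(100L, by = 100L, length.out = L)
  split_call <- function(g) {
    if (g == "./.") c(NA_integer_, NA_integer_)
    else as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
  }
  a <- lapply(calls, function(row) vapply(row, split_call, integer(2)))
  a1 <- do.call(rbind, lapply(a, function(m) m[1, ]))
  a2 <- do.call(rbind, lapply(a, function(m) m[2, ]))
  loci <- data.frame(chrom = chrom, pos = pos, id = rep_len(id, L),
                     ref = rep_len(ref, L), alt = rep_len(alt, L),
                     stringsAsFactors = FALSE)
  genotype_matrix(samples, loci, a1, a2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

locus_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# Damage annotation rows for the alt allele of selected loci of a gm.
make_damage <- function(gm, loci_idx = seq_len(n_loci(gm)),
                        prediction = "DELETERIOUS") {
  data.frame(chrom = gm$loci$chrom[loci_idx], pos = gm$loci$pos[loci_idx],
             ref = gm$loci$ref[loci_idx],
             alt = vapply(strsplit(gm$loci$alt[loci_idx], ",", fixed = TRUE),
                          `[`, "", 1L),
             prediction = rep_len(prediction, length(loci_idx)),
             gene = NA_character_, stringsAsFactors = FALSE)
}

# Population-frequency rows for selected loci of a gm.
make_popfreq <- function(gm, loci_idx, freq, ref_cohort_size = 163190) {
  data.frame(chrom = gm$loci$chrom[loci_idx], pos = gm$loci$pos[loci_idx],
             id = gm$loci$id[loci_idx],
             allele = vapply(strsplit(gm$loci$alt[loci_idx], ",", fixed = TRUE),
                             `[`, "", 1L),
             freq = freq,
             ref_cohort_size = rep(ref_cohort_size, length(loci_idx)),
             stringsAsFactors = FALSE)
}

# Write a VCF from raw lines (for malformed/edge-case inputs).
write_vcf_lines <- function(records, samples = c("S1", "S2"),
                            path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               records), path)
  path
}

# Write a frequency VCF in the NCBI FREQ dialect from INFO strings.
write_freq_vcf <- function(rows, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=FREQ,Number=.,Type=String,Description="freqs">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"),
               rows), path)
  path
}
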