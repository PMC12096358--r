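#' Find polymorphic positions in a cohort
#'
#' A position is polymorphic when at least one non-missing call carries at
#' least one non-reference allele. Loci where every call is homozygous
#' reference, or all calls are missing, are excluded.
#'
#' @param gm A [genotype_matrix()].
#' @return Integer vector of locus indices (row positions in `gm$loci`), in
#'   file order.
#' @export
find_polymorphic_positions <- function(gm) {
  alt_seen <- rowSums(gm$allele1 > 0L | gm$allele2 > 0L, na.rm = TRUE) > 0L
  which(alt_seen)
}

#' Filter loci to homozygous damaging genotypes
#'
#' Implements the central selection rule of the prioritization cascade:
#' retain exactly the loci where at least `min_hom` samples are homozygous
#' for an allele labeled DELETERIOUS. Homozygosity means both allele copies
#' equal that specific allele; compound heterozygotes for two damaging
#' alternatives do not count. Missing calls are excluded from all tallies.
#' A locus with two distinct damaging alleles each homozygous in someone
#' yields one record per allele.
#'
#' @param gm A [genotype_matrix()].
#' @param annotations Damage annotation data frame from
#'   [read_damage_annotations()], joined by (chrom, pos, allele).
#' @param min_hom Minimum number of homozygous carriers required (default 1,
#'   the rule applied to the full cohort before frequency testing).
#' @return Data frame of filtered loci, one row per (locus, damaging allele):
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `damaging_allele`, `hom_count`,
#'   `het_count`, `called_samples`, `cohort_allele_count`
#'   (`= 2*hom_count + het_count`), and `is_known` (`NA` until
#'   [partition_known_novel()] fills it).
#' @export
damaging_homozygote_filter <- function(gm, annotations, min_hom = 1) {
  if (!is_count(min_hom) || min_hom < 1) stop_input("min_hom must be >= 1")
  del <- annotations[annotations$prediction == "DELETERIOUS", , drop = FALSE]
  out <- empty_filtered()
  if (nrow(del) == 0L || n_loci(gm) == 0L) return(out)
  lkey <- locus_key(gm$loci$chrom, gm$loci$pos)
  del$locus_i <- match(locus_key(del$chrom, del$pos), lkey)
  del <- del[!is.na(del$locus_i), , drop = FALSE]
  del <- del[!duplicated(locus_allele_key(del$chrom, del$pos, del$alt)), ,
             drop = FALSE]
  if (nrow(del) == 0L) return(out)
  ai <- vapply(seq_len(nrow(del)),
               function(j) allele_index(gm, del$locus_i[j], del$alt[j]),
               integer(1))
  del <- del[!is.na(ai), , drop = FALSE]   # annotation for an allele absent here
  ai <- ai[!is.na(ai)]
  if (nrow(del) == 0L) return(out)
  A1 <- gm$allele1[del$locus_i, , drop = FALSE]
  A2 <- gm$allele2[del$locus_i, , drop = FALSE]
  copies <- (A1 == ai) + (A2 == ai)        # ai recycles along rows
  hom <- as.integer(rowSums(copies == 2L, na.rm = TRUE))
  het <- as.integer(rowSums(copies == 1L, na.rm = TRUE))
  called <- as.integer(rowSums(!is.na(A1)))
  keep <- hom >= min_hom
  i <- del$locus_i[keep]
  res <- data.frame(chrom = gm$loci$chrom[i], pos = gm$loci$pos[i],
                    id = gm$loci$id[i], ref = gm$loci$ref[i],
                    alt = gm$loci$alt[i],
                    damaging_allele = del$alt[keep],
                    hom_count = hom[keep], het_count = het[keep],
                    called_samples = called[keep],
                    cohort_allele_count = 2L * hom[keep] + het[keep],
                    is_known = rep(NA, length(i)), stringsAsFactors = FALSE)
  if (nrow(res) == 0L) return(out)
  rownames(res) <- NULL
  res
}

empty_filtered <- function() {
  data.frame(chrom = character(), pos = integer(), id = character(),
             ref = character(), alt = character(),
             damaging_allele = character(), hom_count = integer(),
             het_count = integer(), called_samples = integer(),
             cohort_allele_count = integer(), is_known = logical(),
             stringsAsFactors = FALSE)
}

#' Partition filtered loci into known and novel
#'
#' A locus is known when the reference population carries a frequency record
#' for its damaging allele (dbSNP-style membership); otherwise it is novel.
#' The two parts are disjoint and jointly exhaust the input.
#'
#' @param filtered Data frame from [damaging_homozygote_filter()].
#' @param popfreq Population-frequency data frame from
#'   [read_population_frequencies()].
#' @return List with data frames `known` and `novel`, both with `is_known`
#'   set.
#' @export
partition_known_novel <- function(filtered, popfreq) {
  fkey <- locus_allele_key(filtered$chrom, filtered$pos,
                           filtered$damaging_allele)
  pkey <- locus_allele_key(popfreq$chrom, popfreq$pos, popfreq$allele)
  filtered$is_known <- fkey %in% pkey
  list(known = filtered[filtered$is_known, , drop = FALSE],
       novel = filtered[!filtered$is_known, , drop = FALSE])
}

#' Recurrence rule for novel loci
#'
#' Loci absent from the reference population cannot be frequency-tested;
#' they are retained only when homozygous-damaging in at least `k` cohort
#' members (default 8, the rule stated for a 48-person cohort). The
#' threshold is an absolute count, not a fraction.
#'
#' @param novel Data frame of novel filtered loci.
#' @param k Minimum homozygote count (default 8).
#' @return The retained subset, same columns.
#' @export
novel_recurrence_filter <- function(novel, k = 8) {
  if (!is_count(k) || k < 1) stop_input("k must be >= 1")
  novel[novel$hom_count >= k, , drop = FALSE]
}
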