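#' Two-sided exact Poisson rate test
#'
#' Tests an observed count `x` against a fixed expected rate by the
#' point-probability method: the p-value sums the Poisson masses of every
#' outcome `k >= 0` whose probability does not exceed that of the observed
#' count, allowing a relative tolerance `tau` when comparing masses to
#' absorb floating-point ties. Outcomes at a mode of the distribution give
#' p = 1. The result is capped at 1.
#'
#' This is the cohort-vs-population comparison at the heart of the pipeline:
#' with `x` damaging-allele copies observed on `n` chromosomes and population
#' allele frequency `f`, the null expectation is `n * f`.
#'
#' @param x Non-negative observed count(s); vectorized.
#' @param expected Positive expected rate(s) under the null; recycled against
#'   `x`. A rate of 0 is a domain error — floor frequencies first (see
#'   [test_known_loci()]).
#' @param tau Relative tolerance for the mass comparison (default `1e-7`).
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @examples
#' exact_poisson_test(2, 2)    # observed at the mode: p = 1
#' exact_poisson_test(10, 2)   # strong enrichment
#' @export
exact_poisson_test <- function(x, expected, tau = 1e-7) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop_input("x must be non-negative integer counts")
  }
  if (any(!is.finite(expected)) || any(expected <= 0)) {
    stop_input("expected rate must be positive; floor population frequencies first")
  }
  n <- max(length(x), length(expected))
  x <- rep_len(x, n); expected <- rep_len(expected, n)
  vapply(seq_len(n), function(i) pois_two_sided(x[i], expected[i], tau),
         numeric(1))
}

# Point-probability two-sided p for a single (x, r) pair. The opposite tail
# is accumulated by locating the outermost outcome whose mass still exceeds
# the observed mass; masses are unimodal in k, so a single scan from the
# mode suffices.
pois_two_sided <- function(x, r, tau) {
  if (x == r) return(1)
  d <- dpois(x, r) * (1 + tau)
  if (x < r) {
    # observed in the lower tail: add the matching upper tail
    hi <- ceiling(2 * r - x)
    while (dpois(hi, r) > d) hi <- 2 * hi
    k <- seq.int(ceiling(r), hi)
    n_above <- sum(dpois(k, r) <= d)
    p <- ppois(x, r) + ppois(hi - n_above, r, lower.tail = FALSE)
  } else {
    # observed in the upper tail: add the matching lower tail
    k <- seq.int(0, floor(r))
    n_below <- sum(dpois(k, r) <= d)
    p <- ppois(n_below - 1, r) + ppois(x - 1, r, lower.tail = FALSE)
  }
  min(p, 1)
}

#' Frequency-test loci with a population frequency record
#'
#' For each filtered locus with a known population frequency `f`, compares
#' the observed cohort damaging-allele count `x` (on `2 * called_samples`
#' chromosomes) with the null expectation `n_chrom * f` by
#' [exact_poisson_test()]. Frequencies of exactly 0 (alleles recorded but
#' never seen in the reference) are floored at `floor`, by default
#' `1/(2 * ref_cohort_size)` — one chromosome in the reference set — so the
#' rate stays positive. The alternative counting unit compares homozygote
#' counts with the Hardy-Weinberg expectation `called_samples * f^2`.
#'
#' @param filtered Data frame of known loci from [partition_known_novel()].
#' @param popfreq Population-frequency data frame; every locus's damaging
#'   allele must have a record (a missing one is a consistency error).
#' @param floor Positive frequency floor; `NULL` (default) derives
#'   `1/(2 * ref_cohort_size)` per record.
#' @param unit `"allele"` (default) to test allele counts on chromosomes, or
#'   `"homozygote"` to test homozygote counts against `f^2`.
#' @param bh Also report Benjamini-Hochberg q-values (default `FALSE`; the
#'   default output reports raw p only).
#' @return Data frame of class `locus_tests`, sorted by ascending p-value:
#'   locus columns plus `x`, `n_chrom`, `f`, `expected`, `p_value`,
#'   `direction` (`enriched`/`depleted`/`null`), and `q_value` when
#'   `bh = TRUE`.
#' @export
test_known_loci <- function(filtered, popfreq, floor = NULL,
                            unit = c("allele", "homozygote"), bh = FALSE) {
  unit <- match.arg(unit)
  if (!is.null(floor) && (!is.numeric(floor) || floor <= 0)) {
    stop_input("frequency floor must be positive")
  }
  fkey <- locus_allele_key(filtered$chrom, filtered$pos,
                           filtered$damaging_allele)
  pkey <- locus_allele_key(popfreq$chrom, popfreq$pos, popfreq$allele)
  hit <- match(fkey, pkey)
  if (anyNA(hit)) {
    stop_input("no population frequency for supposedly known locus %s",
               fkey[which(is.na(hit))[1L]])
  }
  f <- popfreq$freq[hit]
  fl <- floor %||% (1 / (2 * popfreq$ref_cohort_size[hit]))
  f_floored <- pmax(f, fl)
  if (unit == "allele") {
    x <- filtered$cohort_allele_count
    n_chrom <- 2L * filtered$called_samples
    expected <- n_chrom * f_floored
  } else {
    x <- filtered$hom_count
    n_chrom <- 2L * filtered$called_samples
    expected <- filtered$called_samples * f_floored^2
  }
  res <- filtered
  res$x <- x
  res$n_chrom <- n_chrom
  res$f <- f
  res$expected <- expected
  res$p_value <- if (nrow(res)) exact_poisson_test(x, expected) else numeric()
  res$direction <- ifelse(x > expected, "enriched",
                          ifelse(x < expected, "depleted", "null"))
  if (bh) res$q_value <- adjust_pvalues_bh(res$p_value)
  res <- res[order(res$p_value, res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("locus_tests", "data.frame")
  res
}

#' @export
print.locus_tests <- function(x, n = 10L, ...) {
  cat(sprintf("locus_tests: %d loci (%d enriched, %d depleted at face value)\n",
              nrow(x), sum(x$direction == "enriched"),
              sum(x$direction == "depleted")))
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("... %d more loci\n", nrow(x) - n))
  invisible(x)
}

#' Hardy-Weinberg expected homozygote frequency
#'
#' Under Hardy-Weinberg equilibrium the expected frequency of the homozygous
#' genotype is the square of the allele frequency; the expected number of
#' homozygotes in a cohort of `n` persons is `n * f^2`.
#'
#' @param f Allele frequency (or vector), in `[0, 1]`.
#' @return `f^2`.
#' @examples
#' hwe_expected_homozygote_freq(0.7006194)       # ~0.49 of the population
#' 48 * hwe_expected_homozygote_freq(0.7006194)  # expected homozygotes among 48
#' @export
hwe_expected_homozygote_freq <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop_input("allele frequency must lie in [0, 1]")
  }
  f^2
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper around
#' [stats::p.adjust()] with input validation, kept as the single adjustment
#' point for both locus tests and category enrichment.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order, `q >= p` elementwise.
#' @export
adjust_pvalues_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
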