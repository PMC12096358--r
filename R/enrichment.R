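#' Assign loci to genes by interval overlap
#'
#' A locus at 1-based position `p` is assigned to every gene whose 0-based
#' half-open interval satisfies `start <= p - 1 < end`; overlapping genes
#' each receive the locus. Loci falling in no gene are reported in an
#' intergenic sink, so no locus is ever silently dropped.
#'
#' @param loci Data frame with at least `chrom` and `pos` columns (e.g. the
#'   output of [test_known_loci()] or [novel_recurrence_filter()]).
#' @param genes Gene annotation data frame from [read_gene_annotation()].
#' @return List of class `gene_hits` with elements `assignments` (locus rows
#'   plus `gene_id` and `symbol`, one row per (locus, gene) pair), `genes`
#'   (per-gene locus tallies), and `intergenic` (locus rows in no gene).
#' @export
assign_loci_to_genes <- function(loci, genes) {
  if (nrow(loci) == 0L) {
    return(structure(list(assignments = cbind(loci,
                            data.frame(gene_id = character(),
                                       symbol = character())),
                          genes = data.frame(gene_id = character(),
                                             symbol = character(),
                                             n_loci = integer()),
                          intergenic = loci),
                     class = "gene_hits"))
  }
  locus_gr <- GenomicRanges::GRanges(loci$chrom,
                                     IRanges::IRanges(loci$pos, loci$pos))
  gene_iv <- interval_to_one_based(genes$start, genes$end)
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(gene_iv$start,
                                                     gene_iv$end))
  ov <- GenomicRanges::findOverlaps(locus_gr, gene_gr)
  li <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  assignments <- cbind(loci[li, , drop = FALSE],
                       data.frame(gene_id = genes$gene_id[gi],
                                  symbol = genes$symbol[gi],
                                  stringsAsFactors = FALSE))
  rownames(assignments) <- NULL
  tab <- table(factor(assignments$gene_id, levels = unique(genes$gene_id)))
  hit <- tab > 0L
  per_gene <- data.frame(gene_id = names(tab)[hit],
                         symbol = genes$symbol[match(names(tab)[hit],
                                                     genes$gene_id)],
                         n_loci = as.integer(tab[hit]),
                         stringsAsFactors = FALSE)
  intergenic <- loci[setdiff(seq_len(nrow(loci)), unique(li)), , drop = FALSE]
  rownames(intergenic) <- NULL
  structure(list(assignments = assignments, genes = per_gene,
                 intergenic = intergenic),
            class = "gene_hits")
}

#' @export
print.gene_hits <- function(x, ...) {
  cat(sprintf("gene_hits: %d loci in %d genes, %d intergenic\n",
              nrow(x$assignments), nrow(x$genes), nrow(x$intergenic)))
  invisible(x)
}

#' Fisher exact enrichment of one category
#'
#' Builds the 2x2 table (in gene list / not) x (in category / not) over a
#' background gene universe and computes the exact hypergeometric p-value,
#' one-sided for enrichment by default. The odds ratio is the cross-product
#' ratio, with the Haldane-Anscombe 0.5 correction applied when (and only
#' when) a cell is zero.
#'
#' @param gene_list Character vector of prioritized gene identifiers (must be
#'   a subset of `background`).
#' @param category Character vector of category members (subset of
#'   `background`).
#' @param background Character vector, the gene universe; must be non-empty.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return One-row data frame: `in_list_in_cat`, `in_list_not_cat`,
#'   `not_list_in_cat`, `not_list_not_cat`, `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(gene_list, category, background,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  if (length(background) == 0L) stop_input("empty background gene universe")
  gene_list <- unique(gene_list); category <- unique(category)
  if (!all(gene_list %in% background)) {
    stop_input("gene list contains identifiers outside the background")
  }
  if (!all(category %in% background)) {
    stop_input("category contains identifiers outside the background")
  }
  a <- length(intersect(gene_list, category))
  b <- length(gene_list) - a
  cc <- length(category) - a
  d <- length(background) - a - b - cc
  # hypergeometric: a successes drawing |list| from |category| white balls
  p <- if (alternative == "greater") {
    phyper(a - 1L, a + cc, b + d, a + b, lower.tail = FALSE)
  } else {
    dh <- dhyper(0:min(a + b, a + cc), a + cc, b + d, a + b)
    sum(dh[dh <= dhyper(a, a + cc, b + d, a + b) * (1 + 1e-7)])
  }
  cells <- c(a, b, cc, d)
  if (any(cells == 0L)) cells <- cells + 0.5
  data.frame(in_list_in_cat = a, in_list_not_cat = b, not_list_in_cat = cc,
             not_list_not_cat = d,
             odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
             p_value = min(p, 1), stringsAsFactors = FALSE)
}

#' Enrichment over a whole category database
#'
#' Runs [fisher_enrichment()] per category, adjusts across all tested
#' categories by Benjamini-Hochberg, and sorts by q-value then p-value —
#' the layout of a standard enrichment report (category, gene counts, odds
#' ratio, p, FDR). Category members outside the background are dropped
#' before testing.
#'
#' @param gene_list Prioritized gene identifiers (subset of `background`).
#' @param categories Named list of gene-identifier vectors (see
#'   [read_gene_sets()]).
#' @param background The gene universe.
#' @param alpha Significance level for the `significant` flag on the
#'   q-value (default 0.05, i.e. FDR < 5\%).
#' @param alternative Passed to [fisher_enrichment()].
#' @return Data frame of class `enrichment_results`: `category`, the 2x2
#'   cells, `n_genes` (= `in_list_in_cat`), `odds_ratio`, `p_value`,
#'   `q_value`, `significant`; sorted ascending by (`q_value`, `p_value`).
#' @export
enrich_all <- function(gene_list, categories, background, alpha = 0.05,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_input("alpha must lie in (0, 1)")
  }
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(categories[[nm]], background)
    cbind(data.frame(category = nm, stringsAsFactors = FALSE),
          fisher_enrichment(gene_list, cat_genes, background, alternative))
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- cbind(data.frame(category = character()),
                 fisher_enrichment(character(), character(), "g")[0, ])
  }
  res$n_genes <- res$in_list_in_cat
  res$q_value <- adjust_pvalues_bh(res$p_value)
  res$significant <- res$q_value < alpha
  res <- res[order(res$q_value, res$p_value, res$category), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_results", "data.frame")
  res
}

#' @export
print.enrichment_results <- function(x, n = 10L, ...) {
  cat(sprintf("enrichment_results: %d categories, %d significant at FDR < 5%%\n",
              nrow(x), sum(x$significant)))
  cols <- c("category", "n_genes", "odds_ratio", "p_value", "q_value")
  print.data.frame(utils::head(as.data.frame(x)[cols], n))
  invisible(x)
}
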