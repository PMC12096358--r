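test_that("locus-to-gene assignment is half-open and never drops loci", {
  genes <- data.frame(gene_id = c("G1", "G2", "G3"),
                      symbol = c("G1", "G2", "G3"), chrom = "chr1",
                      start = c(100L, 150L, 500L), end = c(200L, 250L, 600L),
                      strand = "+", stringsAsFactors = FALSE)
  loci <- data.frame(chrom = "chr1",
                     pos = c(200L, 201L, 101L, 100L, 999L),
                     stringsAsFactors = FALSE)
  hits <- assign_loci_to_genes(loci, genes)
  by_pos <- split(hits$assignments$gene_id, hits$assignments$pos)
  # interval (100,200) covers 1-based 101..200: start <= p-1 < end
  expect_setequal(by_pos[["200"]], c("G1", "G2"))   # overlapping genes: both
  expect_setequal(by_pos[["201"]], "G2")            # one past G1's half-open end
  expect_setequal(by_pos[["101"]], "G1")            # first covered base
  expect_false("100" %in% names(by_pos))            # pos 100 -> 0-based 99 < start
  # partition: every locus assigned or in the intergenic sink
  expect_setequal(c(hits$assignments$pos, hits$intergenic$pos), loci$pos)
  expect_setequal(hits$intergenic$pos, c(100L, 999L))
})

test_that("Fisher enrichment matches the frozen enumeration oracle", {
  bg <- sprintf("G%03d", 1:100)
  gene_list <- bg[1:10]
  category <- c(bg[1:5], bg[51:55])   # 10 genes, 5 in the list
  res <- fisher_enrichment(gene_list, category, bg)
  expect_equal(res$in_list_in_cat, 5L)
  expect_equal(res$in_list_not_cat, 5L)
  expect_equal(res$not_list_in_cat, 5L)
  expect_equal(res$not_list_not_cat, 85L)
  # value frozen from exhaustive enumeration of more-extreme tables
  expect_equal(res$p_value, 6.7162774826505e-04, tolerance = 1e-12)
  expect_equal(res$odds_ratio, (5 * 85) / (5 * 5))
})

test_that("Fisher boundary cases behave per contract", {
  bg <- sprintf("G%02d", 1:40)
  # no overlap with a small category: p = 1 under the enrichment alternative
  none <- fisher_enrichment(bg[1:10], bg[31:33], bg)
  expect_equal(none$p_value, 1)
  expect_equal(none$in_list_in_cat, 0L)
  # zero cell triggers the Haldane-Anscombe correction
  expect_equal(none$odds_ratio, (0.5 * 27.5) / (10.5 * 3.5))
  # category = background is uninformative
  all_cat <- fisher_enrichment(bg[1:10], bg, bg)
  expect_equal(all_cat$in_list_in_cat, 10L)
  expect_equal(all_cat$p_value, 1)
  expect_error(fisher_enrichment("G1", "G1", character()), "empty background")
  expect_error(fisher_enrichment("X1", bg[1:3], bg), "outside the background")
})

test_that("enrichment p is monotone in the overlap at fixed margins", {
  bg <- sprintf("G%03d", 1:120)
  p <- vapply(2:10, function(a) {
    gene_list <- c(bg[seq_len(a)], bg[60:(60 + 10 - a - 1)])  # size 10
    fisher_enrichment(gene_list, bg[1:10], bg)$p_value
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("table margins are conserved across random instances", {
  set.seed(7)
  bg <- sprintf("G%03d", 1:200)
  for (i in 1:25) {
    gl <- sample(bg, sample(5:50, 1))
    ct <- sample(bg, sample(5:80, 1))
    res <- fisher_enrichment(gl, ct, bg)
    expect_equal(res$in_list_in_cat + res$in_list_not_cat +
                   res$not_list_in_cat + res$not_list_not_cat, 200L)
    expect_equal(res$in_list_in_cat + res$in_list_not_cat, length(gl))
    expect_equal(res$in_list_in_cat + res$not_list_in_cat, length(ct))
  }
})

test_that("enrich_all adjusts across categories and flags planted signal", {
  bg <- sprintf("G%03d", 1:100)
  cats <- split(bg, rep(1:10, each = 10))
  names(cats) <- sprintf("CAT%02d", 1:10)
  # single category: q = p
  single <- enrich_all(bg[1:10], cats["CAT01"], bg)
  expect_equal(single$q_value, single$p_value)
  # gene list concentrated in CAT01: flagged at q < 0.05, sorted first
  res <- enrich_all(c(bg[1:8], bg[15], bg[25]), cats, bg)
  expect_equal(res$category[1L], "CAT01")
  expect_true(res$significant[1L])
  expect_true(!is.unsorted(res$q_value))
  expect_true(all(res$q_value >= res$p_value - 1e-15))
})

test_that("permuted gene lists are almost never flagged", {
  set.seed(11)
  bg <- sprintf("G%03d", 1:100)
  cats <- split(bg, rep(1:10, each = 10))
  names(cats) <- sprintf("CAT%02d", 1:10)
  flagged <- vapply(1:40, function(i) {
    any(enrich_all(sample(bg, 10), cats, bg)$significant)
  }, logical(1))
  expect_lte(mean(flagged), 0.05)
})
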