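test_that("polymorphic positions require one non-reference call", {
  gm <- make_gm(list(c("0/0", "0/0", "0/0"),    # monomorphic reference
                     c("0/0", "0/1", "0/0"),    # one heterozygote suffices
                     c("./.", "./.", "./."),    # all missing: no evidence
                     c("1/1", "1/1", "1/1")))   # alt-fixed still polymorphic
  expect_equal(find_polymorphic_positions(gm), c(2L, 4L))
})

test_that("damaging filter requires homozygosity for the DELETERIOUS allele", {
  gm <- make_gm(list(c("1/1", "0/0", "0/0", "0/0"),   # one damaging homozygote
                     c("0/1", "0/1", "0/1", "0/1"),   # carriers only
                     c("1/1", "1/1", "0/1", "./.")))  # two homs, one het, one NA
  ann <- make_damage(gm)
  fl <- damaging_homozygote_filter(gm, ann, min_hom = 1)
  expect_equal(fl$pos, gm$loci$pos[c(1, 3)])
  expect_equal(fl$hom_count, c(1L, 2L))
  expect_equal(fl$het_count, c(0L, 1L))
  expect_equal(fl$called_samples, c(4L, 3L))
  expect_equal(fl$cohort_allele_count, 2L * fl$hom_count + fl$het_count)

  # no DELETERIOUS annotation anywhere -> empty result
  tol <- make_damage(gm, prediction = "TOLERATED")
  expect_equal(nrow(damaging_homozygote_filter(gm, tol)), 0L)

  # heterozygous-only carriers are excluded however many there are
  het_only <- damaging_homozygote_filter(make_gm(list(rep("0/1", 10))),
                                         make_damage(make_gm(list(rep("0/1", 10)))))
  expect_equal(nrow(het_only), 0L)
})

test_that("two damaging alts at one locus yield one record per allele", {
  gm <- make_gm(list(c("1/1", "2/2", "1/2", "0/0")), alt = "G,T")
  ann <- rbind(
    data.frame(chrom = "chr1", pos = gm$loci$pos, ref = "A", alt = "G",
               prediction = "DELETERIOUS", gene = NA, stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", pos = gm$loci$pos, ref = "A", alt = "T",
               prediction = "DELETERIOUS", gene = NA, stringsAsFactors = FALSE))
  fl <- damaging_homozygote_filter(gm, ann)
  expect_equal(nrow(fl), 2L)
  expect_setequal(fl$damaging_allele, c("G", "T"))
  # the compound heterozygote (1/2) counts as het for each allele, not hom
  expect_equal(fl$hom_count, c(1L, 1L))
  expect_equal(fl$het_count, c(1L, 1L))
})

test_that("filter is monotone in min_hom and exact on planted counts", {
  cfg <- cohort_config(n_samples = 30, n_loci = 20, seed = 5)
  gm <- generate_cohort_genotypes(generate_population(cfg))
  planted <- list(c(hom = 0L, het = 4L), c(hom = 1L, het = 0L),
                  c(hom = 7L, het = 3L), c(hom = 8L, het = 0L),
                  c(hom = 12L, het = 6L))
  for (i in seq_along(planted)) {
    gm <- plant_genotypes(gm, i, hom = planted[[i]]["hom"],
                          het = planted[[i]]["het"], missing = 2L)
  }
  ann <- make_damage(gm, seq_along(planted))
  for (m in 1:3) {
    fl <- damaging_homozygote_filter(gm, ann, min_hom = m)
    want <- Filter(function(i) planted[[i]]["hom"] >= m, seq_along(planted))
    expect_equal(fl$pos, gm$loci$pos[want])
    expect_equal(fl$hom_count,
                 unname(vapply(planted[want], `[`, integer(1), "hom")))
    expect_equal(fl$het_count,
                 unname(vapply(planted[want], `[`, integer(1), "het")))
    expect_true(all(fl$called_samples == 28L))
    # monotonicity: stricter threshold selects a subset
    fl_next <- damaging_homozygote_filter(gm, ann, min_hom = m + 1)
    expect_true(all(fl_next$pos %in% fl$pos))
  }
})

test_that("filter cascade is idempotent on its own output", {
  cfg <- cohort_config(n_loci = 200, n_spiked = 5, seed = 9)
  gm <- generate_cohort_genotypes(generate_population(cfg))
  pop <- generate_population(cfg)
  fl <- damaging_homozygote_filter(gm, pop$damage)
  keep <- match(locus_key(fl$chrom, fl$pos), locus_key(gm$loci$chrom, gm$loci$pos))
  gm_kept <- exocohort:::subset_loci(gm, keep)
  fl2 <- damaging_homozygote_filter(gm_kept, pop$damage)
  expect_equal(fl2, fl)
  nv <- novel_recurrence_filter(fl, k = 2)
  expect_equal(novel_recurrence_filter(nv, k = 2), nv)
})

test_that("known/novel partition is a conservation law keyed on frequency records", {
  gm <- make_gm(list(c("1/1", "0/0"), c("1/1", "0/1"), c("1/1", "1/1")),
                id = c("rs117004691", NA, NA))
  fl <- damaging_homozygote_filter(gm, make_damage(gm))
  pf <- make_popfreq(gm, 1L, freq = 0.0001539)
  parts <- partition_known_novel(fl, pf)
  expect_equal(parts$known$pos, gm$loci$pos[1])
  expect_true(all(parts$known$is_known))
  expect_false(any(parts$novel$is_known))
  # conservation: known U novel = input, disjoint
  expect_setequal(c(parts$known$pos, parts$novel$pos), fl$pos)
  expect_length(intersect(parts$known$pos, parts$novel$pos), 0L)
  # empty frequency list -> everything novel
  all_novel <- partition_known_novel(fl, make_popfreq(gm, integer(), numeric()))
  expect_equal(nrow(all_novel$known), 0L)
  expect_equal(nrow(all_novel$novel), nrow(fl))
})

test_that("novel recurrence boundary retains 8 and drops 7 of 48", {
  cfg <- cohort_config(n_samples = 48, n_loci = 3, freq_weights = c(absent = 1),
                       seed = 2)
  gm <- generate_cohort_genotypes(generate_population(cfg))
  gm <- plant_genotypes(gm, 1, hom = 7L)
  gm <- plant_genotypes(gm, 2, hom = 8L)
  gm <- plant_genotypes(gm, 3, hom = 20L)   # strong recurrent novel locus
  fl <- damaging_homozygote_filter(gm, make_damage(gm))
  novel <- partition_known_novel(fl, make_popfreq(gm, integer(), numeric()))$novel
  kept <- novel_recurrence_filter(novel, k = 8)
  expect_equal(kept$hom_count, c(8L, 20L))
  # monotone: raising k never adds loci
  expect_true(all(novel_recurrence_filter(novel, k = 9)$pos %in% kept$pos))
  expect_error(novel_recurrence_filter(novel, k = 0), "k must be")
})
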