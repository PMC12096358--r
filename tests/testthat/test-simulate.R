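test_that("generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_loci = 300, n_spiked = 4, phenotype_effect = 1,
                       seed = 13)
  p1 <- generate_population(cfg); p2 <- generate_population(cfg)
  expect_identical(p1, p2)
  g1 <- generate_cohort_genotypes(p1); g2 <- generate_cohort_genotypes(p2)
  expect_identical(g1, g2)
  ph1 <- generate_phenotypes(cfg, g1, target_locus = 1L)
  ph2 <- generate_phenotypes(cfg, g2, target_locus = 1L)
  expect_identical(ph1, ph2)

  d1 <- file.path(tempdir(), "sim_det_a"); d2 <- file.path(tempdir(), "sim_det_b")
  simulate_cohort(cfg, d1); simulate_cohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("population structure follows the configuration", {
  cfg <- cohort_config(n_loci = 2000, deleterious_fraction = 1,
                       n_spiked = 10, spike_in_planted = TRUE, seed = 3)
  pop <- generate_population(cfg)
  # absent-class loci carry no frequency record (novel downstream)
  absent <- pop$loci[pop$loci$class == "absent", ]
  expect_gt(nrow(absent), 0)
  expect_false(any(locus_key(absent$chrom, absent$pos) %in%
                     locus_key(pop$popfreq$chrom, pop$popfreq$pos)))
  # deleterious_fraction = 1: every alt labeled DELETERIOUS
  expect_true(all(pop$damage$prediction == "DELETERIOUS"))
  # frequency classes live on their supports
  expect_true(all(pop$loci$freq[pop$loci$class == "common"] >= 0.05))
  expect_true(all(pop$loci$freq[pop$loci$class == "rare"] <= 0.01))
  spiked <- pop$loci[pop$loci$class == "spiked", ]
  expect_equal(nrow(spiked), 10L)
  expect_true(all(spiked$freq <= 1e-3 & spiked$freq > 0))
  # spikes confined to genes of the planted category
  expect_true(all(spiked$gene_id %in% pop$categories[[pop$planted_category]]))
  # genes tile without overlap
  genes <- pop$genes[order(pop$genes$start), ]
  expect_true(all(genes$end[-nrow(genes)] <= genes$start[-1]))
})

test_that("degenerate cohort frequencies fix the genotypes", {
  all_ref <- cohort_config(n_loci = 50, freq_weights = c(absent = 1), seed = 2)
  gm0 <- generate_cohort_genotypes(generate_population(all_ref))
  expect_true(all(gm0$allele1 == 0L) && all(gm0$allele2 == 0L))
  all_alt <- cohort_config(n_loci = 50, freq_weights = c(common = 1),
                           common_range = c(1, 1), seed = 2)
  gm1 <- generate_cohort_genotypes(generate_population(all_alt))
  expect_true(all(gm1$allele1 == 1L) && all(gm1$allele2 == 1L))
})

test_that("genotype frequencies follow Hardy-Weinberg at the drawn frequency", {
  cfg <- cohort_config(n_samples = 4000, n_loci = 3,
                       freq_weights = c(common = 1),
                       common_range = c(0.3, 0.3), seed = 8)
  gm <- generate_cohort_genotypes(generate_population(cfg))
  hom_alt <- rowMeans(gm$allele1 == 1L & gm$allele2 == 1L)
  het <- rowMeans(gm$allele1 != gm$allele2)
  tol3sd <- 3 * sqrt(0.09 * 0.91 / 4000)
  expect_true(all(abs(hom_alt - 0.3^2) < tol3sd))
  expect_true(all(abs(het - 2 * 0.3 * 0.7) < 3 * sqrt(0.42 * 0.58 / 4000)))
})

test_that("phenotype generation shifts carriers by the configured effect", {
  cfg <- cohort_config(n_samples = 2000, n_loci = 5, phenotype_effect = 2,
                       n_spiked = 1, spike_cohort_freq = 0.5, seed = 4)
  pop <- generate_population(cfg)
  gm <- generate_cohort_genotypes(pop)
  target <- which(pop$loci$class == "spiked")
  ph <- generate_phenotypes(cfg, gm, target_locus = target)
  carrier <- gm$allele1[target, ] > 0L | gm$allele2[target, ] > 0L
  gap <- mean(ph$measure_1[carrier]) - mean(ph$measure_1[!carrier])
  expect_equal(gap, 2 * cfg$pheno_sd, tolerance = 0.1)
  # no target: groups exchangeable in expectation
  ph0 <- generate_phenotypes(cfg, gm, target_locus = NULL)
  gap0 <- mean(ph0$measure_1[carrier]) - mean(ph0$measure_1[!carrier])
  expect_lt(abs(gap0), 2)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_samples = 0), "n_samples")
  expect_error(cohort_config(n_spiked = 10, n_loci = 5), "n_spiked")
  expect_error(cohort_config(spike_cohort_freq = 1.5), "\\[0, 1\\]")
  expect_error(cohort_config(n_loci = 100, genome_length = 50), "positions")
  expect_error(cohort_config(deleterious_fraction = -0.1), "deleterious")
  expect_error(plant_genotypes(make_gm(list(rep("0/0", 3))), 1, hom = 4),
               "exceed")
})
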