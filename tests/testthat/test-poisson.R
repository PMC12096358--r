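test_that("exact Poisson p-values match frozen enumeration oracles", {
  # value frozen from brute-force tail enumeration over k = 0..1000
  expect_equal(exact_poisson_test(10, 2), 4.64980750172638e-05,
               tolerance = 1e-12)
  # observed at the mode: every outcome is included
  expect_equal(exact_poisson_test(2, 2.0), 1)
  # near-zero expectation: the mass at 0 dominates
  expect_equal(exact_poisson_test(0, 0.001), 1)
  expect_error(exact_poisson_test(1, 0), "positive")
  expect_error(exact_poisson_test(-1, 2), "non-negative")
  expect_error(exact_poisson_test(1.5, 2), "non-negative")
})

test_that("exact Poisson test agrees with an independent implementation", {
  set.seed(42)
  for (i in 1:50) {
    r <- runif(1, 0.01, 30)
    x <- rpois(1, sample(c(r, 4 * r, r / 4), 1))
    expect_equal(exact_poisson_test(x, r),
                 stats::poisson.test(x, r = r)$p.value, tolerance = 1e-12,
                 info = sprintf("x=%d r=%g", x, r))
  }
})

test_that("p-value is 1 at the mode and tails are monotone", {
  for (r in c(0.3, 1.7, 2, 5.2, 9)) {
    mode <- floor(r)
    expect_equal(exact_poisson_test(mode, r), 1, info = sprintf("r=%g", r))
    p_hi <- exact_poisson_test(mode:(mode + 15), r)
    expect_true(all(diff(p_hi) <= 1e-12), info = sprintf("upper tail r=%g", r))
    if (mode > 0) {
      p_lo <- exact_poisson_test(mode:0, r)
      expect_true(all(diff(p_lo) <= 1e-12), info = sprintf("lower tail r=%g", r))
    }
  }
})

test_that("known-locus testing floors frequencies and orients directions", {
  gm <- make_gm(list(c("0/0", "0/1"), c("0/0", "0/1"), c("0/0", "0/1")))
  fl <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                   id = NA_character_, ref = "A", alt = "G",
                   damaging_allele = "G",
                   hom_count = c(21L, 2L, 24L), het_count = c(0L, 0L, 0L),
                   called_samples = 48L,
                   cohort_allele_count = c(42L, 4L, 48L),
                   is_known = TRUE, stringsAsFactors = FALSE)
  pf <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                   id = NA_character_, allele = "G",
                   freq = c(0, 0.7006194, 0.5),
                   ref_cohort_size = 163190, stringsAsFactors = FALSE)
  res <- test_known_loci(fl, pf)
  r100 <- res[res$pos == 100L, ]
  # recorded-but-unseen allele floored at one chromosome in 163,190 persons
  expect_equal(r100$expected, 96 * 1 / (2 * 163190), tolerance = 1e-12)
  expect_equal(r100$p_value, brute_poisson_p(42, 96 / (2 * 163190)),
               tolerance = 1e-10)
  expect_lt(r100$p_value, 1e-100)
  expect_equal(r100$direction, "enriched")
  # common damaging allele nearly absent from the cohort: depleted
  r200 <- res[res$pos == 200L, ]
  expect_equal(r200$direction, "depleted")
  expect_equal(r200$p_value, brute_poisson_p(4, 96 * 0.7006194),
               tolerance = 1e-10)
  # cohort count matching expectation: p = 1, direction null
  r300 <- res[res$pos == 300L, ]
  expect_equal(r300$p_value, 1)
  expect_equal(r300$direction, "null")
  # results sorted ascending by p
  expect_true(!is.unsorted(res$p_value))
  # a "known" locus without a record is a consistency error
  expect_error(test_known_loci(fl, pf[-1, ]), "no population frequency")
})

test_that("homozygote counting unit tests against the HWE expectation", {
  fl <- data.frame(chrom = "chr1", pos = 100L, id = NA_character_, ref = "A",
                   alt = "G", damaging_allele = "G", hom_count = 10L,
                   het_count = 5L, called_samples = 48L,
                   cohort_allele_count = 25L, is_known = TRUE,
                   stringsAsFactors = FALSE)
  pf <- data.frame(chrom = "chr1", pos = 100L, id = NA_character_,
                   allele = "G", freq = 0.2, ref_cohort_size = 163190,
                   stringsAsFactors = FALSE)
  res <- test_known_loci(fl, pf, unit = "homozygote")
  expect_equal(res$x, 10L)
  expect_equal(res$expected, 48 * 0.2^2, tolerance = 1e-12)
  expect_equal(res$p_value, brute_poisson_p(10, 48 * 0.04), tolerance = 1e-10)
})

test_that("HWE homozygote expectation is the squared allele frequency", {
  expect_identical(hwe_expected_homozygote_freq(0), 0)
  expect_identical(hwe_expected_homozygote_freq(1), 1)
  f <- 0.7006194
  expect_equal(hwe_expected_homozygote_freq(f), f^2)
  expect_equal(48 * hwe_expected_homozygote_freq(f), 23.56, tolerance = 1e-2)
  expect_error(hwe_expected_homozygote_freq(1.2), "\\[0, 1\\]")
})

test_that("BH adjustment reproduces the step-up computation and its laws", {
  expect_equal(adjust_pvalues_bh(0.05), 0.05)               # m = 1 identity
  # hand step-up: q_(i) = min_j>=i min(1, p_(j) * 4 / j)
  expect_equal(adjust_pvalues_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    q <- adjust_pvalues_bh(p)
    expect_true(all(q >= p - 1e-15))                        # q >= p elementwise
    expect_true(all(diff(q[order(p)]) >= -1e-15))           # order-preserving
    perm <- sample(length(p))
    expect_equal(adjust_pvalues_bh(p[perm]), q[perm])       # equivariant
  }
  expect_error(adjust_pvalues_bh(c(0.2, 1.4)), "\\[0, 1\\]")
})
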