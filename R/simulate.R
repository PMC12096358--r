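#' Configuration of a synthetic exome cohort
#'
#' Describes the statistical structure the analysis assumes: a diploid
#' cohort genotyped under Hardy-Weinberg equilibrium at reference-population
#' allele frequencies, a spiked subset of loci at elevated cohort frequency,
#' TOLERATED/DELETERIOUS damage labels, gene annotation with a category
#' database, and genotype-shifted Gaussian phenotypes.
#'
#' Defaults mirror the study design the pipeline targets: a 48-person
#' cohort; a frequency spectrum mixing common (`f ~ U(0.05, 0.5)`), rare
#' (`f ~ U(1e-4, 0.01)`) and reference-absent (`f = 0`, no frequency
#' record, hence "novel") alleles; spiked loci are rare in the population
#' (`f <= spike_pop_freq_max`) but at `spike_cohort_freq` in the cohort.
#'
#' @param n_samples Cohort size N (default 48).
#' @param n_loci Total loci L (default 2000).
#' @param freq_weights Mixture weights for the `common`, `rare` and `absent`
#'   frequency classes (default 0.45/0.45/0.10); normalized to sum to 1.
#' @param common_range,rare_range Uniform supports of the common and rare
#'   population-frequency classes.
#' @param deleterious_fraction Share of alternative alleles labeled
#'   DELETERIOUS (default 0.3, roughly the fraction of coding substitutions
#'   a damage annotator flags).
#' @param n_spiked Number of loci with elevated cohort frequency (default 0).
#' @param spike_cohort_freq Cohort allele frequency at spiked loci (default
#'   0.3); genotypes still follow Hardy-Weinberg at this frequency.
#' @param spike_pop_freq_max Upper bound of the population frequency of
#'   spiked loci (default 1e-3).
#' @param spike_in_planted Confine spiked loci to genes of the planted
#'   category (default `FALSE`).
#' @param n_genes,genome_length Annotation layout: `n_genes` non-overlapping
#'   genes tiled over a `genome_length`-bp synthetic chromosome, each gene
#'   covering 80\% of its tile.
#' @param n_categories Number of gene categories; the first is the
#'   "planted" category used by ground-truth enrichment tests.
#' @param phenotype_effect Carrier-group mean shift in units of the
#'   phenotype SD (dominant coding; default 0).
#' @param n_measures Number of quantitative measures (default 3).
#' @param pheno_mean,pheno_sd Baseline phenotype distribution (default
#'   Normal(50, 10)).
#' @param seed RNG seed; every generator function derives its stream from
#'   it, making all outputs reproducible.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 48, n_loci = 2000,
                          freq_weights = c(common = 0.45, rare = 0.45,
                                           absent = 0.10),
                          common_range = c(0.05, 0.5),
                          rare_range = c(1e-4, 0.01),
                          deleterious_fraction = 0.3,
                          n_spiked = 0, spike_cohort_freq = 0.3,
                          spike_pop_freq_max = 1e-3,
                          spike_in_planted = FALSE,
                          n_genes = 100, genome_length = 1e6,
                          n_categories = 10,
                          phenotype_effect = 0, n_measures = 3,
                          pheno_mean = 50, pheno_sd = 10,
                          seed = 1) {
  cfg <- list(n_samples = n_samples, n_loci = n_loci,
              freq_weights = freq_weights, common_range = common_range,
              rare_range = rare_range,
              deleterious_fraction = deleterious_fraction,
              n_spiked = n_spiked, spike_cohort_freq = spike_cohort_freq,
              spike_pop_freq_max = spike_pop_freq_max,
              spike_in_planted = spike_in_planted,
              n_genes = n_genes, genome_length = genome_length,
              n_categories = n_categories,
              phenotype_effect = phenotype_effect, n_measures = n_measures,
              pheno_mean = pheno_mean, pheno_sd = pheno_sd, seed = seed)
  for (nm in c("n_samples", "n_loci", "n_spiked", "n_genes", "n_categories",
               "n_measures")) {
    if (!is_count(cfg[[nm]])) stop_input("%s must be a non-negative count", nm)
  }
  if (cfg$n_samples < 1) stop_input("n_samples must be >= 1")
  if (cfg$n_spiked > cfg$n_loci) stop_input("n_spiked exceeds n_loci")
  freqs <- c(cfg$freq_weights, cfg$common_range, cfg$rare_range,
             cfg$spike_cohort_freq, cfg$spike_pop_freq_max)
  if (any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > 1)) {
    stop_input("frequencies and mixture weights must lie in [0, 1]")
  }
  if (cfg$deleterious_fraction < 0 || cfg$deleterious_fraction > 1) {
    stop_input("deleterious_fraction must lie in [0, 1]")
  }
  if (cfg$n_loci > cfg$genome_length) {
    stop_input("n_loci exceeds the number of genome positions")
  }
  if (cfg$n_genes * 2 > cfg$genome_length && cfg$n_genes > 0) {
    stop_input("gene tiling does not fit the genome length")
  }
  if (cfg$pheno_sd <= 0) stop_input("pheno_sd must be positive")
  if (sum(cfg$freq_weights) <= 0) stop_input("freq_weights must not all be 0")
  cfg$freq_weights <- cfg$freq_weights / sum(cfg$freq_weights)
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic reference population and annotation set
#'
#' Places loci uniformly (without replacement) on a synthetic chromosome,
#' tiles non-overlapping genes over it, draws population allele frequencies
#' from the configured mixture (absent-class loci get no frequency record
#' and are therefore novel downstream), labels alternative alleles
#' DELETERIOUS with probability `deleterious_fraction` (spiked loci always),
#' and partitions genes into categories with the first designated as the
#' planted category.
#'
#' @param cfg A [cohort_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return List of class `cohort_population`: `loci` (with per-locus class,
#'   frequency and damage flag — the simulation ground truth), `popfreq`,
#'   `damage`, `genes`, `categories`, `planted_category`, `config`.
#' @export
generate_population <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  # gene tiling: n_genes equal tiles, gene covers the first 80% of its tile
  if (cfg$n_genes > 0) {
    tile <- as.integer(cfg$genome_length %/% cfg$n_genes)
    gstart <- (seq_len(cfg$n_genes) - 1L) * tile
    genes <- data.frame(gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
                        symbol = sprintf("SYN%04d", seq_len(cfg$n_genes)),
                        chrom = "chr1", start = gstart,
                        end = gstart + max(1L, as.integer(0.8 * tile)),
                        strand = "+", stringsAsFactors = FALSE)
  } else {
    genes <- data.frame(gene_id = character(), symbol = character(),
                        chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
  }
  cat_of_gene <- rep(seq_len(max(cfg$n_categories, 1L)),
                     length.out = max(cfg$n_genes, 0L))
  categories <- split(genes$gene_id, sprintf("CAT%02d", cat_of_gene))
  planted <- if (length(categories)) names(categories)[1L] else NA_character_

  pos <- sort(sample.int(cfg$genome_length, cfg$n_loci))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_loci, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "",
                USE.NAMES = FALSE)
  cls <- sample(names(cfg$freq_weights), cfg$n_loci, replace = TRUE,
                prob = cfg$freq_weights)
  # spiked loci: optionally confined to planted-category genes
  if (cfg$n_spiked > 0) {
    candidates <- seq_len(cfg$n_loci)
    if (cfg$spike_in_planted) {
      pg <- genes[genes$gene_id %in% categories[[planted]], , drop = FALSE]
      inside <- rep(FALSE, cfg$n_loci)
      for (g in seq_len(nrow(pg))) {
        inside <- inside | (pos - 1L >= pg$start[g] & pos - 1L < pg$end[g])
      }
      candidates <- which(inside)
    }
    if (length(candidates) < cfg$n_spiked) {
      stop_input("not enough candidate loci to place %d spikes", cfg$n_spiked)
    }
    spike_i <- sort(sample(candidates, cfg$n_spiked))
    cls[spike_i] <- "spiked"
  }
  freq <- numeric(cfg$n_loci)
  freq[cls == "common"] <- runif(sum(cls == "common"), cfg$common_range[1],
                                 cfg$common_range[2])
  freq[cls == "rare"] <- runif(sum(cls == "rare"), cfg$rare_range[1],
                               cfg$rare_range[2])
  freq[cls == "spiked"] <- runif(sum(cls == "spiked"), cfg$rare_range[1],
                                 cfg$spike_pop_freq_max)
  freq[cls == "absent"] <- 0
  has_record <- cls != "absent"
  id <- ifelse(has_record, sprintf("rs9%07d", seq_len(cfg$n_loci)),
               NA_character_)
  deleterious <- rbinom(cfg$n_loci, 1L, cfg$deleterious_fraction) == 1L
  deleterious[cls == "spiked"] <- TRUE

  gene_hit <- rep(NA_character_, cfg$n_loci)
  if (cfg$n_genes > 0) {
    tile_i <- pmin((pos - 1L) %/% tile + 1L, cfg$n_genes)
    in_gene <- (pos - 1L) >= genes$start[tile_i] &
      (pos - 1L) < genes$end[tile_i]
    gene_hit[in_gene] <- genes$gene_id[tile_i[in_gene]]
  }
  loci <- data.frame(chrom = rep("chr1", cfg$n_loci), pos = pos, id = id,
                     ref = ref, alt = alt,
                     class = cls, freq = freq, deleterious = deleterious,
                     gene_id = gene_hit, stringsAsFactors = FALSE)
  popfreq <- data.frame(chrom = rep("chr1", sum(has_record)),
                        pos = pos[has_record],
                        id = id[has_record], allele = alt[has_record],
                        freq = freq[has_record],
                        ref_cohort_size = rep(163190, sum(has_record)),
                        stringsAsFactors = FALSE)
  damage <- data.frame(chrom = rep("chr1", cfg$n_loci), pos = pos,
                       ref = ref, alt = alt,
                       prediction = ifelse(deleterious, "DELETERIOUS",
                                           "TOLERATED"),
                       gene = gene_hit, stringsAsFactors = FALSE)
  structure(list(loci = loci, popfreq = popfreq, damage = damage,
                 genes = genes, categories = categories,
                 planted_category = planted, config = cfg),
            class = "cohort_population")
}

#' @export
print.cohort_population <- function(x, ...) {
  cat(sprintf(paste0("cohort_population: %d loci (%s), %d genes, ",
                     "%d categories (planted: %s)\n"),
              nrow(x$loci),
              paste(sprintf("%d %s", as.integer(table(x$loci$class)),
                            names(table(x$loci$class))), collapse = ", "),
              nrow(x$genes), length(x$categories), x$planted_category))
  invisible(x)
}

#' Draw cohort genotypes under Hardy-Weinberg equilibrium
#'
#' Each sample's two allele copies at a locus are independent Bernoulli
#' draws at the locus's cohort allele frequency — the population frequency
#' for null loci, `spike_cohort_freq` for spiked loci, 0 for absent-class
#' loci — so genotype frequencies follow `(1-f)^2`, `2f(1-f)`, `f^2`.
#'
#' @param population A [generate_population()] result.
#' @param seed RNG seed (default `config seed + 1`, a separate stream from
#'   the population draw).
#' @return A [genotype_matrix()] with samples `S01`, `S02`, ...
#' @export
generate_cohort_genotypes <- function(population,
                                      seed = population$config$seed + 1) {
  stopifnot(inherits(population, "cohort_population"))
  cfg <- population$config
  set.seed(seed)
  loci <- population$loci
  f <- ifelse(loci$class == "spiked", cfg$spike_cohort_freq, loci$freq)
  L <- nrow(loci); N <- cfg$n_samples
  a1 <- matrix(rbinom(L * N, 1L, f), L, N)   # f recycles along loci
  a2 <- matrix(rbinom(L * N, 1L, f), L, N)
  samples <- sprintf("S%03d", seq_len(N))
  genotype_matrix(samples, loci[c("chrom", "pos", "id", "ref", "alt")],
                  a1, a2)
}

#' Plant exact genotype counts at a locus
#'
#' Deterministic companion to the Hardy-Weinberg draw: overwrites the calls
#' at one locus so that exactly `hom` samples are homozygous for the first
#' alternative allele, the next `het` are heterozygous, the next `missing`
#' are missing, and the rest are homozygous reference. Used to exercise
#' filter boundaries with known tallies.
#'
#' @param gm A [genotype_matrix()].
#' @param locus_index Locus row to overwrite.
#' @param hom,het,missing Planted counts; their sum must not exceed the
#'   cohort size.
#' @return The modified [genotype_matrix()].
#' @export
plant_genotypes <- function(gm, locus_index, hom = 0, het = 0, missing = 0) {
  if (!is_count(locus_index) || locus_index < 1 || locus_index > n_loci(gm)) {
    stop_input("locus_index must index a locus of the genotype matrix")
  }
  if (!is_count(hom) || !is_count(het) || !is_count(missing)) {
    stop_input("planted counts must be non-negative")
  }
  N <- n_samples(gm)
  if (hom + het + missing > N) stop_input("planted counts exceed cohort size")
  a1 <- c(rep(1L, hom), rep(0L, het), rep(NA_integer_, missing),
          rep(0L, N - hom - het - missing))
  a2 <- c(rep(1L, hom), rep(1L, het), rep(NA_integer_, missing),
          rep(0L, N - hom - het - missing))
  gm$allele1[locus_index, ] <- a1
  gm$allele2[locus_index, ] <- a2
  gm
}

#' Generate genotype-shifted Gaussian phenotypes
#'
#' Every measure is drawn from Normal(`pheno_mean`, `pheno_sd`); carriers of
#' the risk (alternative) allele at `target_locus` — dominant coding — are
#' shifted by `phenotype_effect * pheno_sd`. With `target_locus = NULL` or
#' `phenotype_effect = 0` the groups are exchangeable.
#'
#' @param cfg A [cohort_config()].
#' @param gm A [genotype_matrix()] for the cohort.
#' @param target_locus Locus index in `gm`, or `NULL` for no effect.
#' @param seed RNG seed (default `cfg$seed + 2`).
#' @return Wide phenotype data frame (`sample` plus `measure_1`, ...).
#' @export
generate_phenotypes <- function(cfg, gm, target_locus = NULL,
                                seed = cfg$seed + 2) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  N <- n_samples(gm)
  shift <- numeric(N)
  if (!is.null(target_locus) && cfg$phenotype_effect != 0) {
    if (!is_count(target_locus) || target_locus < 1 ||
        target_locus > n_loci(gm)) {
      stop_input("target_locus must index a locus of the genotype matrix")
    }
    carrier <- !is.na(gm$allele1[target_locus, ]) &
      (gm$allele1[target_locus, ] > 0L | gm$allele2[target_locus, ] > 0L)
    shift <- cfg$phenotype_effect * cfg$pheno_sd * as.numeric(carrier)
  }
  out <- data.frame(sample = gm$samples, stringsAsFactors = FALSE)
  for (m in seq_len(cfg$n_measures)) {
    out[[sprintf("measure_%d", m)]] <-
      rnorm(N, cfg$pheno_mean, cfg$pheno_sd) + shift
  }
  out
}

#' Write a complete synthetic input set
#'
#' Generates population, genotypes and phenotypes and writes them in the
#' formats the pipeline reads — cohort VCF, damage-annotation TSV,
#' FREQ-dialect population VCF, gene BED, category GMT, phenotype TSV — so
#' that the round trip through [run_pipeline()] is the integration test.
#' Every file header records the seed.
#'
#' @param cfg A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return List of class `cohort_sim`: `paths` (named file paths),
#'   `population`, `genotypes`, `phenotypes`, `target_locus`, and `truth`
#'   (keys of spiked loci).
#' @export
simulate_cohort <- function(cfg, dir) {
  stopifnot(inherits(cfg, "cohort_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- generate_population(cfg)
  gm <- generate_cohort_genotypes(pop)
  spiked_i <- which(pop$loci$class == "spiked")
  target <- if (length(spiked_i)) spiked_i[1L] else NULL
  pheno <- generate_phenotypes(cfg, gm, target_locus = target)
  seed_note <- sprintf("exocohort_seed=%d", cfg$seed)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             damage = file.path(dir, "damage_annotations.tsv"),
             popfreq = file.path(dir, "population_freq.vcf"),
             genes = file.path(dir, "genes.bed"),
             categories = file.path(dir, "categories.gmt"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  write_cohort_vcf(gm, paths[["vcf"]], header_comments = seed_note)
  write_tsv(pop$damage, paths[["damage"]], comments = seed_note)
  ref_map <- setNames(pop$popfreq_ref %||%
                        pop$loci$ref[match(locus_key(pop$popfreq$chrom,
                                                     pop$popfreq$pos),
                                           locus_key(pop$loci$chrom,
                                                     pop$loci$pos))],
                      locus_key(pop$popfreq$chrom, pop$popfreq$pos))
  write_population_frequencies(pop$popfreq, paths[["popfreq"]], ref = ref_map,
                               header_comments = seed_note)
  write_gene_bed(pop$genes, paths[["genes"]], header_comments = seed_note)
  write_gene_sets(pop$categories, paths[["categories"]])
  write_phenotypes(pheno, paths[["phenotypes"]], header_comments = seed_note)
  structure(list(paths = paths, population = pop, genotypes = gm,
                 phenotypes = pheno, target_locus = target,
                 truth = locus_allele_key(pop$loci$chrom, pop$loci$pos,
                                          pop$loci$alt)[spiked_i]),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("cohort_sim: %d samples x %d loci, %d spiked; files in %s\n",
              n_samples(x$genotypes), n_loci(x$genotypes), length(x$truth),
              dirname(x$paths[[1L]])))
  invisible(x)
}
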