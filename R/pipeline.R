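#' Run the full prioritization pipeline
#'
#' Orchestrates the analysis end-to-end from files on disk: read all inputs;
#' count polymorphic positions; keep loci with at least `min_hom` homozygous
#' DELETERIOUS genotypes; partition them by presence in the population
#' frequency set; exact-Poisson-test the known loci against population
#' expectation; apply the recurrence rule (`hom_count >= k`) to novel loci;
#' collapse the surviving candidate loci to genes; test category enrichment;
#' and, when phenotypes are supplied, run the dominant-model association at
#' one locus. Every stage is also exported as a library function.
#'
#' All outputs are TSVs with commented headers plus a `run_summary.txt` of
#' counts, parameters and input checksums; nothing in the outputs depends on
#' anything but (inputs, parameters), so identical invocations produce
#' byte-identical files. A stage failure aborts with a stage-named error and
#' removes partial outputs.
#'
#' @param vcf,damage,popfreq,genes Paths to the cohort VCF, damage-annotation
#'   TSV, population-frequency VCF, and gene annotation (BED/GFF3).
#' @param categories Optional path to a GMT category database; `NULL` skips
#'   enrichment.
#' @param phenotypes Optional path to a phenotype TSV; `NULL` skips
#'   association.
#' @param out_dir Output directory (created if needed).
#' @param min_hom,k Filter thresholds; defaults 1 and 8 (the cohort rules
#'   for 48 samples).
#' @param freq_floor Positive floor for zero population frequencies; `NULL`
#'   derives `1/(2 * ref_cohort_size)` (see [test_known_loci()]).
#' @param unit Counting unit for the rate test, `"allele"` or
#'   `"homozygote"`.
#' @param freq_dialect Population-frequency VCF dialect (see
#'   [read_population_frequencies()]).
#' @param locus_selection How known loci enter the candidate gene list:
#'   `"p"` (default) takes raw `p < alpha`, matching the convention of
#'   reporting unadjusted locus p-values; `"q"` takes BH `q < alpha`, the
#'   stricter choice appropriate when many thousands of loci are tested.
#' @param alpha Significance level (default 0.05).
#' @param background Enrichment background: `"annotation"` (all genes in the
#'   annotation, default) or `"polymorphic"` (genes containing at least one
#'   polymorphic position).
#' @param t_variant t-test variant for association (`"pooled"` or
#'   `"welch"`).
#' @param assoc_locus Length-2 vector `c(chrom, pos)` selecting the
#'   association locus; `NULL` uses the top-ranked tested locus.
#' @param seed Optional integer recorded in the run summary (the pipeline
#'   itself draws no random numbers).
#' @param snv_only Passed to [read_cohort_vcf()].
#' @return Object of class `exocohort_run` with the per-stage results
#'   (`tests`, `filtered`, `novel_recurrent`, `gene_hits`, `enrichment`,
#'   `association`), the `counts` vector, effective `params`, and output
#'   `paths`.
#' @export
run_pipeline <- function(vcf, damage, popfreq, genes, categories = NULL,
                         phenotypes = NULL, out_dir,
                         min_hom = 1, k = 8, freq_floor = NULL,
                         unit = c("allele", "homozygote"),
                         freq_dialect = "freq",
                         locus_selection = c("p", "q"), alpha = 0.05,
                         background = c("annotation", "polymorphic"),
                         t_variant = c("pooled", "welch"),
                         assoc_locus = NULL, seed = NULL, snv_only = TRUE) {
  unit <- match.arg(unit)
  locus_selection <- match.arg(locus_selection)
  background <- match.arg(background)
  t_variant <- match.arg(t_variant)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_input("alpha must lie in (0, 1)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage_name <- "setup"
  stage <- function(name, expr) {
    stage_name <<- name
    expr
  }
  emit <- function(df, file, what) {
    path <- file.path(out_dir, file)
    write_tsv(as.data.frame(df), path, comments = c("exocohort", what))
    written <<- c(written, path)
    path
  }
  run <- tryCatch({
    inputs <- c(vcf = vcf, damage = damage, popfreq = popfreq, genes = genes,
                categories = categories, phenotypes = phenotypes)
    gm <- stage("read_cohort_vcf", read_cohort_vcf(vcf, snv_only = snv_only))
    ann <- stage("read_damage_annotations", read_damage_annotations(damage))
    pf <- stage("read_population_frequencies",
                read_population_frequencies(popfreq, dialect = freq_dialect))
    gene_tab <- stage("read_gene_annotation", read_gene_annotation(genes))
    cats <- if (!is.null(categories)) {
      stage("read_gene_sets", read_gene_sets(categories))
    }
    pheno <- if (!is.null(phenotypes)) {
      stage("read_phenotypes", read_phenotypes(phenotypes))
    }

    poly_idx <- stage("polymorphic", find_polymorphic_positions(gm))
    gm_poly <- subset_loci(gm, poly_idx)
    filtered <- stage("damaging_homozygote_filter",
                      damaging_homozygote_filter(gm_poly, ann,
                                                 min_hom = min_hom))
    parts <- stage("partition_known_novel",
                   partition_known_novel(filtered, pf))
    tests <- stage("test_known_loci",
                   test_known_loci(parts$known, pf, floor = freq_floor,
                                   unit = unit, bh = TRUE))
    recurrent <- stage("novel_recurrence_filter",
                       novel_recurrence_filter(parts$novel, k = k))
    sig_known <- if (locus_selection == "p") {
      tests[tests$p_value < alpha, , drop = FALSE]
    } else {
      tests[tests$q_value < alpha, , drop = FALSE]
    }
    shared <- intersect(names(sig_known), names(recurrent))
    candidates <- rbind(sig_known[shared], recurrent[shared])
    hits <- stage("assign_loci_to_genes",
                  assign_loci_to_genes(candidates, gene_tab))
    bg <- if (background == "annotation") {
      unique(gene_tab$gene_id)
    } else {
      unique(assign_loci_to_genes(gm$loci[poly_idx, , drop = FALSE],
                                  gene_tab)$assignments$gene_id)
    }
    enr <- if (!is.null(cats)) {
      stage("enrich_all",
            enrich_all(hits$genes$gene_id, cats, bg, alpha = alpha))
    }
    assoc <- assoc_note <- NULL
    if (!is.null(pheno)) {
      if (is.null(assoc_locus) && nrow(tests)) {
        assoc_locus <- c(tests$chrom[1L], tests$pos[1L])
      }
      if (is.null(assoc_locus)) {
        assoc_note <- "no testable locus for association"
      } else {
        i <- which(gm$loci$chrom == assoc_locus[1L] &
                     gm$loci$pos == as.integer(assoc_locus[2L]))
        allele <- tests$damaging_allele[match(
          locus_key(assoc_locus[1L], assoc_locus[2L]),
          locus_key(tests$chrom, tests$pos))]
        if (is.na(allele) && length(i) == 1L) {
          allele <- strsplit(gm$loci$alt[i], ",", fixed = TRUE)[[1]][1L]
        }
        assoc <- tryCatch(
          stage("associate_dominant",
                associate_dominant(gm, pheno, assoc_locus[1L],
                                   as.integer(assoc_locus[2L]), allele,
                                   variant = t_variant, alpha = alpha)),
          error = function(e) {
            assoc_note <<- conditionMessage(e)
            NULL
          })
      }
    }

    emit(filtered, "filtered_loci.tsv", "loci with homozygous damaging genotypes")
    emit(as.data.frame(tests), "locus_tests.tsv",
         "exact Poisson tests of known loci vs population frequency")
    emit(recurrent, "novel_recurrent.tsv",
         sprintf("novel loci homozygous-damaging in >= %d samples", k))
    emit(hits$genes, "gene_hits.tsv", "genes containing candidate loci")
    emit(hits$assignments, "gene_assignments.tsv",
         "candidate locus to gene assignments")
    if (!is.null(enr)) {
      emit(as.data.frame(enr), "enrichment.tsv",
           "category enrichment of the candidate gene list")
    }
    if (!is.null(assoc)) {
      emit(as.data.frame(assoc), "association.tsv",
           "dominant-model genotype-phenotype association")
    }

    counts <- c(n_samples = n_samples(gm), n_loci_input = n_loci(gm),
                n_polymorphic = length(poly_idx),
                n_filtered = nrow(filtered),
                n_known = nrow(parts$known), n_novel = nrow(parts$novel),
                n_tested = nrow(tests),
                n_significant_known = nrow(sig_known),
                n_novel_recurrent = nrow(recurrent),
                n_candidate = nrow(candidates),
                n_genes_hit = nrow(hits$genes),
                n_intergenic = nrow(hits$intergenic),
                n_categories_tested = if (is.null(enr)) 0L else nrow(enr),
                n_categories_significant =
                  if (is.null(enr)) 0L else sum(enr$significant),
                n_association_measures =
                  if (is.null(assoc)) 0L else nrow(assoc))
    params <- list(min_hom = min_hom, k = k, freq_floor = freq_floor,
                   unit = unit, freq_dialect = freq_dialect,
                   locus_selection = locus_selection, alpha = alpha,
                   background = background, t_variant = t_variant,
                   snv_only = snv_only, seed = seed)
    summary_path <- file.path(out_dir, "run_summary.txt")
    writeLines(c("# exocohort run summary",
                 sprintf("%s\t%d", names(counts), counts),
                 sprintf("param.%s\t%s", names(params),
                         vapply(params, function(p)
                           if (is.null(p)) "default" else as.character(p), "")),
                 if (!is.null(assoc_note)) sprintf("note.association\t%s",
                                                   assoc_note),
                 sprintf("input.%s.md5\t%s", names(inputs),
                         unname(tools::md5sum(inputs)))),
               summary_path)
    written <- c(written, summary_path)
    structure(list(counts = counts, params = params, filtered = filtered,
                   tests = tests, novel_recurrent = recurrent,
                   gene_hits = hits, enrichment = enr, association = assoc,
                   association_note = assoc_note,
                   paths = written, out_dir = out_dir),
              class = "exocohort_run")
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage_name,
                 conditionMessage(e)), call. = FALSE)
  })
  run
}

#' @export
print.exocohort_run <- function(x, ...) {
  cat("exocohort pipeline run\n")
  cat(sprintf("  %-24s %d\n", names(x$counts), x$counts), sep = "")
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}

#' @export
summary.exocohort_run <- function(object, n = 5L, ...) {
  print(object)
  if (nrow(object$tests)) {
    cat("\nTop frequency-tested loci:\n")
    cols <- c("chrom", "pos", "id", "damaging_allele", "x", "n_chrom", "f",
              "expected", "p_value", "direction")
    print.data.frame(utils::head(as.data.frame(object$tests)[cols], n))
  }
  if (!is.null(object$enrichment) && nrow(object$enrichment)) {
    cat("\nTop enriched categories:\n")
    cols <- c("category", "n_genes", "odds_ratio", "p_value", "q_value")
    print.data.frame(utils::head(as.data.frame(object$enrichment)[cols], n))
  }
  if (!is.null(object$association)) {
    cat("\nAssociation:\n")
    print(object$association)
  }
  invisible(object)
}
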