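#' Dominant-model sample partition at a locus
#'
#' Splits the cohort into non-carriers (no copy of the risk allele, e.g. the
#' AA genotype) and carriers (at least one copy, AG/GG pooled). Samples with
#' missing calls are excluded. A partition with an empty side is flagged
#' degenerate and the association is skipped downstream.
#'
#' @param gm A [genotype_matrix()].
#' @param chrom,pos Locus coordinates (1-based).
#' @param risk_allele Allele string whose carriers form group B.
#' @return List with `non_carriers` and `carriers` (sample identifier
#'   vectors), `labels` (genotype-style group labels), and `degenerate`.
#' @export
dominant_groups <- function(gm, chrom, pos, risk_allele) {
  i <- which(gm$loci$chrom == chrom & gm$loci$pos == pos)
  if (length(i) != 1L) stop_input("locus %s:%s not in the genotype matrix",
                                  chrom, pos)
  ai <- allele_index(gm, i, risk_allele)
  if (is.na(ai)) stop_input("allele %s not present at locus %s:%s",
                            risk_allele, chrom, pos)
  copies <- (gm$allele1[i, ] == ai) + (gm$allele2[i, ] == ai)
  non <- gm$samples[!is.na(copies) & copies == 0L]
  car <- gm$samples[!is.na(copies) & copies >= 1L]
  other <- setdiff(locus_alleles(gm, i), risk_allele)[1L]
  list(non_carriers = non, carriers = car,
       labels = c(paste0(other, other),
                  sprintf("%s%s/%s%s", other, risk_allele,
                          risk_allele, risk_allele)),
       degenerate = length(non) == 0L || length(car) == 0L)
}

#' Two-sample t-test with group summaries
#'
#' Pooled-variance Student's t (default) or Welch's t with Satterthwaite
#' degrees of freedom, computed from the textbook formulas so that the
#' degenerate zero-variance contracts are explicit: equal means with zero
#' variance in both groups give p = 1; unequal means with zero variance give
#' p = 0 and are flagged. Summaries are mean, sample standard deviation
#' (n - 1 denominator), and size per group.
#'
#' @param values_a,values_b Numeric vectors; `NA`s dropped; each group needs
#'   at least 2 values.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return One-row data frame: `m_a`, `sd_a`, `n_a`, `m_b`, `sd_b`, `n_b`,
#'   `t_stat`, `df`, `p_value`, `degenerate`.
#' @export
two_sample_t <- function(values_a, values_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop_input("each group needs at least 2 non-missing values")
  }
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b); va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    equal <- ma == mb
    return(data.frame(m_a = ma, sd_a = 0, n_a = na, m_b = mb, sd_b = 0,
                      n_b = nb, t_stat = if (equal) 0 else Inf * sign(ma - mb),
                      df = NA_real_, p_value = if (equal) 1 else 0,
                      degenerate = TRUE))
  }
  if (variant == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t_stat <- (ma - mb) / se
  data.frame(m_a = ma, sd_a = sqrt(va), n_a = na, m_b = mb, sd_b = sqrt(vb),
             n_b = nb, t_stat = t_stat, df = df,
             p_value = 2 * pt(-abs(t_stat), df), degenerate = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' Reported as a per-group diagnostic next to each t-test; never used as an
#' automatic gate on the analysis.
#'
#' @param values Numeric vector, 3 to 5000 non-missing values, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 3L || length(v) > 5000L) {
    stop_input("Shapiro-Wilk needs between 3 and 5000 values, got %d",
               length(v))
  }
  if (var(v) == 0) stop_input("Shapiro-Wilk is undefined for a constant sample")
  s <- shapiro.test(v)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Genotype-phenotype association under the dominant model
#'
#' For each quantitative measure, compares carriers of the risk allele with
#' non-carriers by a two-sample t-test, reporting group summaries (M, sigma,
#' n), the test statistic and two-sided p, and per-group Shapiro-Wilk
#' normality p-values as diagnostics. No multiplicity correction is applied
#' across measures by default; `bh = TRUE` adds Benjamini-Hochberg q-values.
#'
#' @param gm A [genotype_matrix()].
#' @param phenotypes Wide phenotype data frame from [read_phenotypes()].
#' @param chrom,pos,risk_allele Locus and risk allele defining the grouping.
#' @param measures Measures to test; defaults to every non-`sample` column.
#' @param variant t-test variant, see [two_sample_t()].
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param bh Add BH q-values across measures (default `FALSE`).
#' @return Data frame of class `association_results`, one row per measure.
#' @export
associate_dominant <- function(gm, phenotypes, chrom, pos, risk_allele,
                               measures = NULL, variant = c("pooled", "welch"),
                               alpha = 0.05, bh = FALSE) {
  variant <- match.arg(variant)
  grp <- dominant_groups(gm, chrom, pos, risk_allele)
  if (grp$degenerate) {
    stop_input("monomorphic partition at %s:%s for allele %s: association skipped",
               chrom, pos, risk_allele)
  }
  measures <- measures %||% setdiff(names(phenotypes), "sample")
  sw_p <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 3L && length(v) <= 5000L && var(v) > 0)
      shapiro_wilk(v)$p else NA_real_
  }
  rows <- lapply(measures, function(m) {
    va <- phenotypes[[m]][match(grp$non_carriers, phenotypes$sample)]
    vb <- phenotypes[[m]][match(grp$carriers, phenotypes$sample)]
    tt <- two_sample_t(va, vb, variant)
    cbind(data.frame(measure = m, group_a = grp$labels[1L],
                     group_b = grp$labels[2L], stringsAsFactors = FALSE),
          tt,
          data.frame(normality_p_a = sw_p(va), normality_p_b = sw_p(vb)))
  })
  res <- do.call(rbind, rows)
  res$significant <- res$p_value < alpha
  if (bh) res$q_value <- adjust_pvalues_bh(res$p_value)
  rownames(res) <- NULL
  class(res) <- c("association_results", "data.frame")
  res
}

#' @export
print.association_results <- function(x, ...) {
  cat(sprintf("association_results: %d measures, %s vs %s\n",
              nrow(x), x$group_a[1L], x$group_b[1L]))
  d <- data.frame(measure = x$measure,
                  group_a = sprintf("%.2f+/-%.2f (n=%d)", x$m_a, x$sd_a, x$n_a),
                  group_b = sprintf("%.2f+/-%.2f (n=%d)", x$m_b, x$sd_b, x$n_b),
                  t = round(x$t_stat, 3), p = signif(x$p_value, 3))
  print.data.frame(d)
  invisible(x)
}
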