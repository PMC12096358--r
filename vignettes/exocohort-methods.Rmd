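---
title: "Methods: cohort-vs-population prioritization of damaging variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-vs-population prioritization of damaging variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistical model

`exocohort` addresses a design that is common in small clinical sequencing
studies: a cohort of a few dozen patients, exome-sequenced, compared not
against matched sequenced controls but against a very large public
reference population for which only allele frequencies are available. The
package treats the reference as fixed truth and asks, locus by locus,
whether the cohort's damaging-allele count is compatible with the
population frequency.

For a locus with damaging-allele frequency $f$ in the reference and $m$
successfully genotyped cohort members, the observed allele count $x$
(counted as $2 \cdot \mathrm{hom} + \mathrm{het}$ on $n = 2m$ chromosomes)
is modelled as Poisson with rate $r = n f$. The two-sided p-value uses the
point-probability rule: every outcome whose Poisson mass does not exceed
the observed mass (within relative tolerance $\tau = 10^{-7}$) contributes,

$$p = \sum_{k \,:\, P(k) \le P(x)(1+\tau)} \frac{e^{-r} r^k}{k!},$$

capped at 1, and equal to 1 when $x$ is a mode of the distribution. The
Poisson approximation to the binomial count is excellent in the regime the
pipeline cares about (rare alleles, $n \approx 96$), and the exact
discrete test is conservative — its null rejection rate at
$\alpha = 0.05$ stays below $\alpha$, which the test-suite verifies
empirically on 20,000 null loci.

Three modelling commitments deserve explicit statement:

* **One-sample, not two-sample.** The reference cohort (by default sized
  163,190 persons, the scale of the European frequency set the pipeline is
  designed around) is three orders of magnitude larger than a typical
  study cohort, so its sampling error is negligible and the frequency is
  treated as a known rate. A two-sample rate comparison is out of scope.
* **Alleles, not homozygotes, as the default counting unit.** A frequency
  difference is a statement about alleles; counting chromosomes uses all
  carrier information. Because the selection rule is about homozygotes, a
  homozygote-count mode is available (`unit = "homozygote"`), testing
  $\mathrm{hom}$ against the Hardy–Weinberg expectation $m f^2$.
* **Frequency flooring.** A recorded allele with $f = 0$ (present in
  dbSNP, never seen in the reference) would give a degenerate rate. Such
  frequencies are floored at $1/(2 \cdot 163{,}190)$ — one chromosome in
  the reference — which is the smallest frequency the reference could have
  resolved. The floor is configurable and is derived per record from
  `ref_cohort_size` when the frequency file provides it.

## The filtering cascade

The cascade runs strictly in this order, each stage consuming the previous
one's output:

1. polymorphic positions (≥ 1 non-reference allele in ≥ 1 non-missing
   call);
2. damaging-homozygote filter: ≥ `min_hom` (default 1) samples homozygous
   for a `DELETERIOUS`-labelled allele. Homozygosity is for *that specific
   allele*; a compound heterozygote carrying two different damaging
   alternatives is counted as heterozygous for each, because the
   functional argument for recessive-style damage requires both copies of
   one allele to be affected;
3. known/novel partition by presence of a frequency record for the
   damaging allele;
4. exact Poisson test for known loci; novel loci instead face a recurrence
   rule, `hom_count >= k` with `k = 8` by default — an absolute count
   (8 of 48), not a fraction, because a recurrence argument is about the
   number of independent homozygous observations, not a rate.

Missing genotypes are excluded from `called_samples` and from all counts.
Ploidy is fixed at 2: hemizygous X calls emitted by callers as diploid
genotypes are counted as such, a simplification that slightly inflates
X-linked allele counts in mixed-sex cohorts (see Limitations).

## Gene collapsing and enrichment

Candidate loci — known loci passing the significance threshold plus
recurrent novel loci — are assigned to genes by interval overlap. Variant
positions are 1-based (VCF convention); gene intervals are 0-based
half-open (BED convention; GFF3 input is converted on read). A locus at
position $p$ belongs to a gene interval $[s, e)$ iff $s \le p - 1 < e$;
overlapping genes each receive the locus, and unassigned loci are kept in
an intergenic sink rather than dropped. Enrichment of each category is the
one-sided Fisher exact test on the 2×2 table over a background universe,
with Benjamini–Hochberg adjustment across categories and an FDR < 5% flag.
The odds ratio uses the Haldane–Anscombe 0.5 correction exactly when a
cell is zero.

Two open choices were settled as follows:

* **Background.** The default background is all genes in the annotation.
  The alternative (`background = "polymorphic"`), all genes containing at
  least one polymorphic position, is stricter and defensible; both are
  explicit options because enrichment conclusions can hinge on this
  choice.
* **Locus selection for the gene list.** By default, known loci enter the
  candidate list at raw $p < \alpha$, matching the convention of reporting
  unadjusted locus p-values in this kind of study. With tens of thousands
  of loci that rule floods the gene list with type-I hits (≈ 5% of null
  loci), so for ground-truth simulations and any genome-scale run the
  `locus_selection = "q"` option selects at BH $q < \alpha$ instead; the
  package's planted-category simulations use it for exactly this reason.

## Association

The association stage mirrors the dominant-model tables of clinical
genetics papers: carriers of ≥ 1 risk allele vs non-carriers, one
quantitative measure at a time, summarised as $M \pm \sigma$ (sample SD,
$n-1$ denominator) with a two-sample t-test. The default is the pooled-
variance Student's t; Welch's variant is a flag. Shapiro–Wilk p-values are
reported per group as diagnostics but never gate the analysis — with
groups of 15–30 the normality test has little power, and silently
switching tests based on it would make the procedure harder to reason
about. Degenerate inputs have defined behaviour: equal-mean zero-variance
groups give $p = 1$; unequal-mean zero-variance groups give $p = 0$ and a
`degenerate` flag; a monomorphic partition refuses to test. No
multiplicity correction is applied across measures by default (BH by
flag).

## The synthetic-cohort generator

The generator produces the statistical structure the analysis assumes, at
the study conditions: `n_samples = 48`; population frequencies drawn from
a mixture of common ($f \sim U(0.05, 0.5)$), rare
($f \sim U(10^{-4}, 0.01)$) and reference-absent ($f = 0$, no frequency
record) classes with weights 0.45/0.45/0.10; damage labels Bernoulli with
`deleterious_fraction = 0.3`, roughly the share of coding substitutions a
SIFT-style annotator calls damaging; genotypes drawn under
Hardy–Weinberg at the locus frequency. Spiked loci model the signal of
interest — rare in the population ($f \le 10^{-3}$) but at cohort allele
frequency 0.3, with genotypes still Hardy–Weinberg — and can be confined
to the genes of one planted category for enrichment ground truth.
Phenotypes are Gaussian, Normal(50, 10) per measure, with carriers
shifted by `phenotype_effect` standard deviations under dominant coding.

Reproducibility: each generator stage seeds its own stream derived from
the config seed (population: `seed`; genotypes: `seed + 1`; phenotypes:
`seed + 2`), so any stage can be regenerated independently and file
outputs are byte-identical across runs; every written file records the
seed in its header. A deterministic `plant_genotypes()` mode overwrites
one locus with exact homozygote/heterozygote/missing counts for filter
boundary tests.

What the generator deliberately does **not** emulate: linkage
disequilibrium (loci are independent), genotyping and annotation error,
depth- or quality-dependent missingness, relatedness and population
substructure, indels, and multi-chromosome genomes (one synthetic
chromosome by default). Passing tests therefore demonstrate correctness of
the pipeline's logic and calibration under its stated model — not
robustness to the correlated noise of real exome data.

## Numerical and engineering choices

* The exact Poisson p-value mirrors the standard point-probability
  algorithm: the opposite tail is located by scanning outward from the
  distribution's mode, relying on unimodality of the Poisson mass
  function; the relative tolerance $10^{-7}$ absorbs floating-point ties.
  The test-suite checks it against brute-force tail enumeration on a grid
  of 408 $(x, r)$ pairs to $10^{-10}$, and against an independent
  implementation on random cases to $10^{-12}$.
* Fisher p-values come from the hypergeometric tail; the test-suite checks
  them against exhaustive enumeration of all tables with the observed
  margins (backgrounds up to 200) to $10^{-12}$.
* Ties in result ordering are broken by (q, p, category) for enrichment
  and (p, chrom, pos) for locus tests, keeping outputs deterministic.
* Multi-allelic VCF records are kept whole in the genotype matrix;
  annotation and frequency joins are per (locus, allele). Only SNVs are
  admitted by default (`snv_only = FALSE` to admit indels), since damage
  labels and frequency records in the supported dialects are
  SNV-oriented.
* The pipeline is a pure function of (inputs, parameters): no timestamps
  or RNG enter any output, which is what makes byte-identical re-runs a
  testable contract.

Test problem sizes are the package's own choice of desk-scale defaults:
calibration uses 20,000 null loci and 10,000 t-test replicates;
ground-truth recovery uses 20 cohorts of 20,000 loci with 20 spiked loci
each. At these sizes the whole suite runs in a few minutes on one core.

## Known limitations

* The binomial count is approximated by a Poisson rate; at common alleles
  ($nf$ comparable to $n$) the approximation overstates the variance and
  the test loses power, which is acceptable for a screen aimed at rare
  damaging alleles.
* Treating the reference frequency as exact ignores its (small) sampling
  error and any ancestry mismatch between cohort and reference; a
  mismatched reference will produce systematic false enrichment that no
  within-pipeline correction can detect.
* Hemizygous X genotypes are counted as diploid, inflating X-linked
  counts in male samples.
* The recurrence rule for novel loci is a heuristic with no p-value; its
  threshold `k` trades sensitivity against the multiple-testing burden it
  implicitly avoids.
* Enrichment results depend on the chosen background and on annotation
  quality; the Fisher test assumes genes are exchangeable units, ignoring
  gene length — longer genes collect more candidate loci and can inflate
  categories of long genes.
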