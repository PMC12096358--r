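# Independent oracles: brute-force enumerations written against first
# principles, sharing no code path with the package implementation.

# Two-sided exact Poisson p by full enumeration of the outcome space.
# Masses computed on the log scale from the density definition, never via
# dpois; every outcome whose mass is <= the observed mass (relative
# tolerance tau) contributes.
brute_poisson_p <- function(x, rate, tau = 1e-7) {
  kmax <- ceiling(rate + 50 * sqrt(rate) + 100)
  k <- 0:kmax
  mass <- exp(k * log(rate) - rate - lgamma(k + 1))
  min(1, sum(mass[mass <= mass[x + 1] * (1 + tau)]))
}

# One-sided (enrichment) Fisher p by enumeration of all 2x2 tables with the
# observed margins; table probabilities from the hypergeometric definition
# via log-binomial coefficients, never via dhyper/phyper.
brute_fisher_greater <- function(a, list_size, cat_size, background) {
  support <- max(0, list_size + cat_size - background):min(list_size, cat_size)
  lp <- lchoose(cat_size, support) +
    lchoose(background - cat_size, list_size - support) -
    lchoose(background, list_size)
  sum(exp(lp[support >= a]))
}

# Pooled two-sample t from the textbook definition (summary-statistics
# route, no shared code with two_sample_t()).
brute_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), na + nb - 2))
}
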