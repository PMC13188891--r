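# Independent oracles and small fixture builders used across the suite.

# Exact tail probability of the one-sided two-proportion test under the
# pooled null, by full enumeration over the first binomial and the exact
# CDF of the second: P(X1/n1 - X2/n2 >= observed difference).
exact_two_binomial_p <- function(x1, n1, x2, n2) {
  p <- (x1 + x2) / (n1 + n2)
  d <- x1 / n1 - x2 / n2
  a <- 0:n1
  k <- floor(n2 * (a / n1 - d) + 1e-9)
  sum(stats::dbinom(a, n1, p) * stats::pbinom(k, n2, p))
}

# One-chromosome, one-marker map: the cheapest scaffold for genotype-level
# simulations (dominance backcrosses, segregation checks).
tiny_map <- function() {
  build_genome_map(1, 1e6, 50, marker_spacing = 5e5)
}
tiny_causal <- list(chrom = "chr1", pos = 5e5)

# Small multi-chromosome map for scan-level tests.
scan_map <- function(n_chrom = 4, markers = 50) {
  build_genome_map(n_chrom, 1e6, 50, marker_spacing = 1e6 %/% markers)
}

# Direct Gaussian-mixture KDE evaluation (independent of stats::density)
# for verifying peak locations.
gauss_kde <- function(x, bw, grid) {
  vapply(grid, function(g) mean(stats::dnorm((g - x) / bw)) / bw, numeric(1))
}
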