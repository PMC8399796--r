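# Independent oracles used across the suite. They deliberately use only
# elementary operations (pmf summation, the expected-count formula, ECDF
# sweeps, rank-then-Pearson) so they stay independent of the code paths
# they check.

# brute-force upper binomial tail: sum the pmf terms
binom_tail_oracle <- function(depth, alt, rate) {
  if (alt == 0) return(1)
  sum(dbinom(alt:depth, depth, rate))
}

# Pearson chi-square statistic and p from the expected-count formula
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(chi_square = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# two-sample KS statistic via an explicit ECDF sweep
ks_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

# Spearman rho as Pearson correlation of average ranks
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

# quick record-table builder for hand fixtures
rec <- function(chrom, pos, ref = "A", alt = "T", zygosity = "het",
                depth = 20L, alt_reads = 10L, effect = "intergenic") {
  variant_records(chrom, pos, ref, alt, zygosity, depth, alt_reads, effect)
}

# a tiny quality-passing trio wrapped into a partition via the real code
make_partition <- function(h, m, s, ...) {
  partition_specific(h, m, s, ...)
}

# scaled-down generator config used by several tests (small genome so the
# per-test cost stays low)
small_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(
    chromosomes = data.frame(name = paste0("c", 1:6), length = rep(2e7, 6),
                             stringsAsFactors = FALSE),
    father_specific_per_chrom = 800L,
    mother_specific_per_chrom = 800L,
    population_factor = 5,
    causal_chromosomes = c("c2", "c5"),
    n_genes_per_chrom = 5L,
    seed = 1L
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}
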