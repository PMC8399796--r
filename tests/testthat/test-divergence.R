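test_that("NG86 sites and differences match hand-enumerated codon counts", {
  # identical sequences: zero divergence
  ng0 <- ng86_pair("AAATTT", "AAATTT")
  expect_equal(ng0$dN, 0)
  expect_equal(ng0$dS, 0)

  # per-codon synonymous + nonsynonymous sites are exactly 3
  for (codon in c("AAA", "TTT", "CTG", "CGG", "ATG", "TGG", "GGG")) {
    ng <- ng86_pair(codon, codon)
    expect_equal(ng$S_sites + ng$N_sites, 3, tolerance = 1e-12)
  }
  # hand enumeration: Lys AAA has one synonymous change (AAA->AAG) among 9,
  # so 1/3 synonymous site; Trp TGG has none
  expect_equal(ng86_pair("AAA", "AAA")$S_sites, 1 / 3, tolerance = 1e-12)
  expect_equal(ng86_pair("TGG", "TGG")$S_sites, 0)

  # ten AAA codons plus TTT vs TTC: hand-enumerated NG86 fractions.
  # S = 10 * 1/3 + 1/3 = 11/3 (Phe TTT: only position 3 TTT->TTC is
  # synonymous); the single difference is synonymous.
  a <- paste(c(rep("AAA", 10), "TTT"), collapse = "")
  b <- paste(c(rep("AAA", 10), "TTC"), collapse = "")
  ng <- ng86_pair(a, b)
  expect_equal(ng$S_sites, 11 / 3, tolerance = 1e-12)
  expect_equal(ng$N_sites, 33 - 11 / 3, tolerance = 1e-12)
  expect_equal(ng$S_diffs, 1)
  expect_equal(ng$N_diffs, 0)
  expect_equal(ng$dN, 0)
  expect_gt(ng$dS, 0)
  # frozen value of -(3/4) log(1 - (4/3) * (3/11))
  expect_equal(ng$dS, -0.75 * log(1 - 4 / 11), tolerance = 1e-12)
})

test_that("multi-hit codons average over stop-free substitution pathways", {
  # CCT (Pro) vs CAA (Gln), positions 2 and 3 differ. Pathways:
  #   CCT -> CAT (Pro->His, nonsyn) -> CAA (His->Gln, nonsyn):   0 syn, 2 nonsyn
  #   CCT -> CCA (Pro->Pro, syn)    -> CAA (Pro->Gln, nonsyn):   1 syn, 1 nonsyn
  # average: Sd = 0.5, Nd = 1.5 (no stop codon on either pathway)
  ng <- ng86_pair("CCT", "CAA")
  expect_equal(ng$S_diffs, 0.5)
  expect_equal(ng$N_diffs, 1.5)
})

test_that("NG86 is symmetric and validates its inputs", {
  set.seed(31)
  op <- simulate_ortholog_pair(60, 0.2, 0.05)
  f <- ng86_pair(op$cds_a, op$cds_b)
  r <- ng86_pair(op$cds_b, op$cds_a)
  expect_equal(f$dN, r$dN)
  expect_equal(f$dS, r$dS)
  expect_error(ng86_pair("AAA", "AAAAAA"), "length")
  expect_error(ng86_pair("AAAA", "AAAT"), "divisible")
  expect_error(ng86_pair("TGAAAA", "TGAAAA"), "stop")
  # shared terminal stop codons are tolerated
  expect_silent(ng86_pair("AAATAA", "AAGTAA"))
  # ambiguous codons are excluded and counted
  ngx <- ng86_pair("AAANNN", "AAANNN")
  expect_equal(ngx$codons_used, 1L)
  expect_equal(ngx$codons_excluded, 1L)
})

test_that("evolved ortholog pairs recover their target dN and dS", {
  op <- simulate_ortholog_pair(3334, target_dS = 0.3, target_dN = 0.03,
                               seed = 404)
  ng <- ng86_pair(op$cds_a, op$cds_b)
  expect_lt(abs(ng$dS - 0.3) / 0.3, 0.15)
  expect_lt(abs(ng$dN - 0.03) / 0.03, 0.15)
})

test_that("KS comparison agrees with an explicit ECDF sweep", {
  expect_equal(ks_compare(1:5, 1:5)$D, 0)
  expect_equal(ks_compare(1:5, 101:105)$D, 1)
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  expect_equal(ks_compare(a, b)$D, ks_oracle(a, b), tolerance = 1e-12)
  set.seed(41)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  expect_equal(ks_compare(x, y)$D, ks_oracle(x, y), tolerance = 1e-12)
  expect_error(ks_compare(numeric(0), 1:3), "empty")
})

test_that("rank correlation matches rank-then-Pearson, ties averaged", {
  expect_equal(rank_correlation(1:10, (1:10)^2)$rho, 1)
  expect_equal(rank_correlation(1:10, -(1:10))$rho, -1)
  x <- c(1, 2, 2, 3, 5)
  y <- c(2, 1, 4, 4, 6)
  expect_equal(rank_correlation(x, y)$rho, spearman_oracle(x, y),
               tolerance = 1e-12)
  cons <- rank_correlation(rep(1, 5), 1:5)
  expect_true(cons$degenerate)
  expect_true(is.na(cons$rho))
})

test_that("mis/syn table counts specific SNP effects per gene", {
  genes <- gene_intervals(c("G1", "G2", "G3"), "c1",
                          c(100L, 1000L, 2000L), c(500L, 1500L, 2500L))
  spec <- variant_records(
    "c1", c(150L, 160L, 170L, 180L, 1100L, 1150L, 2100L),
    ref = "A", alt = c("T", "G", "C", "AT", "T", "G", "T"),
    effect = c("missense", "missense", "missense", "missense",
               "synonymous", "missense", "missense")
  )
  part <- structure(list(specific = spec, nonspecific = spec[0, ],
                         totals = c(specific = nrow(spec), nonspecific = 0L),
                         match_mode = "allele"),
                    class = "trio_partition")
  ms <- mis_syn_table(part, genes)
  ms <- ms[order(ms$gene_id), ]
  # G1: 3 missense SNPs (the Indel never counts), 0 synonymous -> no ratio
  expect_equal(ms$mis_count, c(3L, 1L, 1L))
  expect_equal(ms$syn_count, c(0L, 1L, 0L))
  expect_equal(ms$mis_syn_ratio, c(NA, 1, NA))
  # relaxed mode still requires a synonymous anchor
  ms2 <- mis_syn_table(part, genes, require_both = FALSE)
  expect_equal(sum(!is.na(ms2$mis_syn_ratio)), 1L)
})

test_that("missense load tracks divergence across genes when seeded that way", {
  # genes with higher dN (less conserved) receive proportionally more
  # specific missense mutations relative to synonymous ones
  set.seed(55)
  n_genes <- 40
  width <- 1000L
  starts <- seq(1L, by = 2000L, length.out = n_genes)
  genes <- gene_intervals(sprintf("G%02d", 1:n_genes), "c1",
                          starts, starts + width - 1L)
  dN <- exp(seq(log(0.005), log(0.3), length.out = n_genes))
  mis <- rpois(n_genes, 2 + 60 * dN)
  syn <- rpois(n_genes, 4) + 1
  pos <- integer(0); eff <- character(0)
  for (i in seq_len(n_genes)) {
    k <- mis[i] + syn[i]
    pos <- c(pos, starts[i] + seq_len(k))
    eff <- c(eff, rep(c("missense", "synonymous"), c(mis[i], syn[i])))
  }
  spec <- variant_records("c1", pos, "A", "T", effect = eff)
  part <- structure(list(specific = spec, nonspecific = spec[0, ],
                         totals = c(specific = nrow(spec), nonspecific = 0L),
                         match_mode = "allele"),
                    class = "trio_partition")
  ms <- mis_syn_table(part, genes)
  merged <- merge(ms, data.frame(gene_id = genes$gene_id, dN = dN))
  merged <- merged[!is.na(merged$mis_syn_ratio), ]
  res <- rank_correlation(merged$dN, merged$mis_syn_ratio)
  expect_gt(res$rho, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("gene divergence joins ortholog pairs with their CDS", {
  op1 <- simulate_ortholog_pair(80, 0.2, 0.02, seed = 1)
  op2 <- simulate_ortholog_pair(80, 0.2, 0.1, seed = 2)
  pairs <- data.frame(gene_id_a = c("pigA", "pigB"),
                      gene_id_b = c("oxA", "oxB"))
  div <- gene_divergence(pairs,
                         c(pigA = op1$cds_a, pigB = op2$cds_a),
                         c(oxA = op1$cds_b, oxB = op2$cds_b))
  expect_equal(div$gene_id, c("pigA", "pigB"))
  expect_true(all(div$dS >= 0))
  expect_error(gene_divergence(pairs, c(pigA = op1$cds_a),
                               c(oxA = op1$cds_b, oxB = op2$cds_b)),
               "missing CDS")
})
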