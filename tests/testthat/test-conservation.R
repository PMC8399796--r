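toy_map <- function() {
  site_map(data.frame(
    source_chrom = c("chr1", "chr1"),
    source_start = c(100L, 300L),
    target_chrom = c("B1", "B2"),
    target_start = c(500L, 900L),
    length = c(50L, 5L),
    strand = c("+", "-"),
    stringsAsFactors = FALSE
  ))
}

test_that("site mapping translates offsets, strand-aware", {
  m <- toy_map()
  expect_equal(map_site("chr1", 110, m)$target_pos, 510)
  expect_equal(map_site("chr1", 110, m)$target_chrom, "B1")
  # outside every block: unmapped
  expect_true(is.na(map_site("chr1", 99, m)$target_pos))
  expect_true(is.na(map_site("chr2", 110, m)$target_pos))
  # minus-strand block, all five positions enumerated by hand:
  # source 300,301,302,303,304 -> target 904,903,902,901,900
  got <- map_site(rep("chr1", 5), 300:304, m)
  expect_equal(got$target_pos, c(904, 903, 902, 901, 900))
  expect_equal(got$target_chrom, rep("B2", 5))
})

test_that("site mapping is injective per block and inverts cleanly", {
  m <- toy_map()
  src <- c(100:149, 300:304)
  fwd <- map_site(rep("chr1", length(src)), src, m)
  expect_false(any(duplicated(paste(fwd$target_chrom, fwd$target_pos))))
  back <- map_site(fwd$target_chrom, fwd$target_pos, invert_site_map(m))
  expect_equal(back$target_pos, src)
  expect_equal(back$target_chrom, rep("chr1", length(src)))
})

test_that("site maps reject overlap and malformed blocks", {
  bad <- data.frame(source_chrom = "chr1", source_start = c(100L, 120L),
                    target_chrom = "B", target_start = c(1L, 500L),
                    length = c(50L, 10L), strand = "+",
                    stringsAsFactors = FALSE)
  expect_error(site_map(bad), "overlap")
  bad2 <- data.frame(source_chrom = "chr1", source_start = 100L,
                     target_chrom = "B", target_start = 1L,
                     length = 0L, strand = "+", stringsAsFactors = FALSE)
  expect_error(site_map(bad2), "block 1")
  f <- tempfile(fileext = ".tsv")
  write.table(toy_map(), f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(map_site("chr1", 120, read_site_map(f))$target_pos, 520)
})

test_that("conservation calls compare bases and exclude ambiguity codes", {
  expect_true(conserved_at("A", "A"))
  expect_false(conserved_at("A", "G"))
  expect_true(is.na(conserved_at("A", "N")))
  expect_equal(conserved_at(c("a", "C"), c("A", "T")), c(TRUE, FALSE))
})

test_that("conserved-fraction contrast matches the hand oracle", {
  cand <- rep(c(TRUE, FALSE), c(80, 20))
  nonc <- rep(c(TRUE, FALSE), c(50, 50))
  res <- conserved_fraction_contrast(cand, nonc)
  oracle <- chisq_oracle(matrix(c(80, 20, 50, 50), 2, byrow = TRUE))
  expect_equal(res$chi_square, oracle$chi_square, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p_value, tolerance = 1e-12)
  # equal fractions: p = 1
  same <- conserved_fraction_contrast(rep(c(TRUE, FALSE), 50),
                                      rep(c(TRUE, FALSE), 80))
  expect_equal(same$p_value, 1)
  # ambiguity exclusions are counted
  res2 <- conserved_fraction_contrast(c(cand, NA, NA), nonc)
  expect_equal(res2$n_excluded, 2L)
})

test_that("seeded candidate-site conservation excess is detected", {
  set.seed(88)
  cand <- runif(200) < 0.8
  nonc <- runif(500) < 0.5
  res <- conserved_fraction_contrast(cand, nonc)
  expect_gt(res$fractions["candidate", "conserved"],
            res$fractions["noncandidate", "conserved"])
  expect_lt(res$p_value, 0.05)
})

test_that("records are assigned to genes, flanks, or left unassigned", {
  genes <- gene_intervals(c("BMP7", "FAR", "OV1", "OV2"), "chr17",
                          c(1000L, 900000L, 5000L, 5200L),
                          c(2000L, 901000L, 5400L, 5600L))
  r <- rec("chr17", c(1500L, 2001L, 300000L, 5300L))
  a <- assign_to_genes(r, genes, window = 50000L)
  r1 <- a[a$record == 1, ]
  expect_equal(r1$status, "genic")
  expect_equal(r1$gene_id, "BMP7")
  # 1 bp past the interval end: intergenic but associated
  r2 <- a[a$record == 2, ]
  expect_equal(r2$status[r2$gene_id == "BMP7"], "intergenic")
  # far from everything: unassigned
  r3 <- a[a$record == 3, ]
  expect_equal(r3$status, "unassigned")
  expect_true(is.na(r3$gene_id))
  # overlapping two genes: assigned to both and flagged
  r4 <- a[a$record == 4, ]
  expect_setequal(r4$gene_id, c("OV1", "OV2"))
  expect_true(all(r4$n_genes == 2L))
})

test_that("clade codon patterns classify conservation structure", {
  # everyone identical
  all_same <- clade_codon_pattern(rep("CGG", 10),
                                  rep(c("mammals", "fishes"), each = 5))
  expect_equal(all_same$pattern, "conserved_everywhere")
  # the headline structure: an arginine codon fixed in mammals, variable
  # in lower vertebrates (one derived mammal lineage carrying CCG does not
  # flip the clade, because the majority codon anchors the identity)
  codons <- c(rep("CGG", 11), "CCG",
              c("AAA", "GAT", "TTG", "CCA", "GGC", "ATC", "CAA", "TGT",
                "ACT", "GTA"))
  clades <- rep(c("mammals", "fishes"), c(12, 10))
  prof <- clade_codon_pattern(codons, clades)
  expect_equal(prof$pattern, "clade_conserved")
  mam <- prof$per_clade[prof$per_clade$clade == "mammals", ]
  expect_equal(mam$majority_codon, "CGG")
  expect_equal(mam$identity_fraction, 11 / 12)
  # everyone different
  vara <- clade_codon_pattern(c("AAA", "AAC", "AAG", "CCA", "CCG", "CCT"),
                              rep(c("mammals", "fishes"), each = 3))
  expect_equal(vara$pattern, "variable_everywhere")
  # species order within clades is irrelevant
  set.seed(12)
  o <- sample(length(codons))
  prof2 <- clade_codon_pattern(codons[o], clades[o])
  expect_equal(prof2$pattern, prof$pattern)
  pc1 <- prof$per_clade[order(prof$per_clade$clade), ]
  pc2 <- prof2$per_clade[order(prof2$per_clade$clade), ]
  rownames(pc1) <- rownames(pc2) <- NULL
  expect_equal(pc1, pc2)
  expect_error(clade_codon_pattern("AAA", "fishes", focal_clade = "mammals"),
               "focal clade")
})

test_that("simulated clade columns are mostly focal-clade conserved", {
  cols <- simulate_clade_columns(100, seed = 606)
  pats <- vapply(split(cols, cols$column), function(d) {
    clade_codon_pattern(d$codon, d$clade)$pattern
  }, character(1))
  expect_gte(mean(pats == "clade_conserved"), 0.8)
})

test_that("clade alignment round-trips through FASTA with clade tags", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">human clade=mammals", "CGGAAA",
               ">zebrafish clade=fishes", "CCGAAA"), f)
  aln <- read_clade_alignment(f)
  expect_equal(aln$clade, c("mammals", "fishes"))
  col1 <- alignment_codon_column(aln, 1)
  expect_equal(col1$codon, c("CGG", "CCG"))
  expect_equal(alignment_codon_column(aln, 2)$codon, c("AAA", "AAA"))
})

test_that("clade branch rates are hand-checkable path sums", {
  tree <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
  labels <- c(A = "mammals", B = "mammals", C = "fishes", D = "fishes")
  rates <- clade_branch_rates(tree, labels)
  # root-to-tip: A = 2, B = 3, C = 5, D = 6 -> means 2.5 and 5.5
  expect_equal(rates$mean_root_to_tip[rates$clade == "mammals"], 2.5)
  expect_equal(rates$mean_root_to_tip[rates$clade == "fishes"], 5.5)
  expect_equal(rates$ratio_to_reference[rates$clade == "fishes"], 2.2)

  # ultrametric tree: all clade means equal
  ultra <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ru <- clade_branch_rates(ultra, labels)
  expect_equal(ru$mean_root_to_tip, rep(2, 2))

  # doubling branch lengths doubles means, ratios unchanged
  t2 <- tree; t2$edge.length <- 2 * t2$edge.length
  r2 <- clade_branch_rates(t2, labels)
  expect_equal(r2$mean_root_to_tip, 2 * rates$mean_root_to_tip)
  expect_equal(r2$ratio_to_reference, rates$ratio_to_reference)

  t3 <- tree; t3$edge.length[2] <- NA
  expect_error(clade_branch_rates(t3, labels), "branch length")
  expect_error(clade_branch_rates(tree, labels[-1]), "without clade label")
})
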