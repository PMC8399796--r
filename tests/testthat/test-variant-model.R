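test_that("zygosity parsing follows the genotype-code convention", {
  expect_equal(parse_zygosity(c("0/1", "1/0", "1/1", "0|1", "./.", "0/0")),
               c("het", "het", "hom", "het", NA, NA))
  # against a specific ALT index of a decomposed multi-allelic row
  expect_equal(parse_zygosity("1/2", alt_index = 2), "het")
  expect_equal(parse_zygosity("2/2", alt_index = 2), "hom")
  expect_error(parse_zygosity("0/2", n_alt = 1), "allele index")
})

test_that("variant typing splits SNPs from Indels and rejects non-variants", {
  expect_equal(classify_variant_type(c("A", "A", "ACG"), c("T", "AT", "A")),
               c("SNP", "Indel", "Indel"))
  expect_error(classify_variant_type("A", "A"), "not a variant")
  expect_error(classify_variant_type("", "A"), "non-empty")
})

test_that("quality filter uses strict thresholds and fails unknown support", {
  r <- variant_records(
    chrom = rep("chr1", 5), pos = 1:5, ref = "A", alt = "T",
    zygosity = "het",
    depth = c(20L, 10L, 50L, 11L, NA),
    alt_reads = c(10L, 5L, 3L, 4L, NA)
  )
  expect_equal(passes_quality_filter(r), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # monotonicity: raising either threshold never admits more records
  set.seed(11)
  d <- rpois(500, 20)
  big <- variant_records("chr1", 1:500, "A", "T", "het",
                         depth = d,
                         alt_reads = pmin(rbinom(500, 30, 0.3), d))
  n_pass <- function(d, a) sum(passes_quality_filter(big, d, a))
  for (d in c(5, 10, 15)) for (a in c(1, 3, 6)) {
    expect_lte(n_pass(d + 1, a), n_pass(d, a))
    expect_lte(n_pass(d, a + 1), n_pass(d, a))
  }
})

test_that("sequencing-error tail equals brute-force pmf summation", {
  expect_equal(sequencing_error_tail(20, 0, 0.5), 1.0)
  expect_equal(sequencing_error_tail(2, 2, 0.5), 0.25)
  for (depth in c(1, 5, 20, 35, 50)) {
    for (rate in c(0.01, 0.1, 0.5)) {
      alts <- unique(c(0, 1, depth %/% 2, depth))
      for (alt in alts) {
        expect_equal(sequencing_error_tail(depth, alt, rate),
                     binom_tail_oracle(depth, alt, rate),
                     tolerance = 1e-12)
      }
    }
  }
  # non-increasing in alt_count at fixed depth and rate
  tails <- sequencing_error_tail(30, 0:30, 0.05)
  expect_true(all(diff(tails) <= 1e-15))
  expect_error(sequencing_error_tail(20, 10, 0), "error_rate")
  expect_error(sequencing_error_tail(20, 25, 0.01), "alt_count")
})

test_that("the depth-20/alt-10 call is far beyond sequencing error", {
  # the headline site: 1% error rate cannot plausibly produce 10 of 20
  # alternate reads
  expect_lt(sequencing_error_tail(20, 10, 0.01), 1e-10)
})

test_that("coding-effect classification keys on annotation terms", {
  expect_equal(
    classify_coding_effect(c(
      "T|missense_variant|MODERATE|BMP7|b7",
      "T|synonymous_variant|LOW|X|x",
      "T|intergenic_region|MODIFIER|.|.",
      "T|intron_variant|MODIFIER|X|x",
      NA, ""
    )),
    c("missense", "synonymous", "intergenic", "other_genic",
      "intergenic", "intergenic")
  )
  # first (most severe) annotation wins; ANN= prefix tolerated
  expect_equal(classify_coding_effect(
    "ANN=T|missense_variant|a|b,T|synonymous_variant|c|d"), "missense")
  expect_equal(classify_coding_effect(
    "T|missense_variant&splice_region_variant|x"), "missense")
  expect_equal(suppressMessages(classify_coding_effect("T|weird_term_xyz|x")),
               "other_genic")
})

test_that("VCF reader maps fields, decomposes multi-allelic rows, skips no-calls", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "H", sep = "\t"),
    paste("chr1", "100", ".", "A", "T", ".", ".",
          "ANN=T|missense_variant|x", "GT:DP:AD", "0/1:20:10,10", sep = "\t"),
    paste("chr1", "150", ".", "A", "T,G", ".", ".", ".",
          "GT:DP:AD", "1/2:30:2,14,14", sep = "\t"),
    paste("chr1", "200", ".", "A", "T", ".", ".", ".", "GT", "./.", sep = "\t")
  ), f)
  r <- read_vcf(f, "H")
  expect_equal(nrow(r), 3L)  # 1 + 2 decomposed, no-call skipped
  expect_equal(r$pos, c(100L, 150L, 150L))
  expect_equal(r$alt, c("T", "T", "G"))
  expect_equal(r$zygosity, c("het", "het", "het"))
  expect_equal(r$depth, c(20L, 30L, 30L))
  expect_equal(r$alt_reads, c(10L, 14L, 14L))
  expect_equal(r$effect[1], "missense")
  expect_error(read_vcf(f, "nope"), "available")
})

test_that("records lacking AD have unknown support and fail the filter", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "X", sep = "\t"),
    paste("chr1", "10", ".", "C", "G", ".", ".", ".", "GT:DP", "0/1:40",
          sep = "\t")
  ), f)
  r <- read_vcf(f, "X")
  expect_true(is.na(r$alt_reads))
  expect_false(passes_quality_filter(r))
})

test_that("writing then re-reading a VCF reproduces the records", {
  set.seed(5)
  n <- 200
  d <- rpois(n, 20)
  r <- variant_records(
    chrom = sample(c("chr1", "chr2"), n, TRUE), pos = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "TT"), n, TRUE), alt = "TAA",
    zygosity = sample(c("het", "hom"), n, TRUE),
    depth = d, alt_reads = pmin(rbinom(n, 10, 0.8), d),
    effect = sample(c("missense", "synonymous", "other_genic", "intergenic"),
                    n, TRUE)
  )
  f <- tempfile(fileext = ".vcf")
  write_vcf(r, f, "H")
  expect_equal(as.data.frame(read_vcf(f, "H")), as.data.frame(r))
})

test_that("gene intervals validate coordinates and flag candidates", {
  g <- gene_intervals(c("BMP7", "OTHER"), c("chr17", "chr1"),
                      c(100L, 5L), c(200L, 50L))
  expect_equal(g$is_candidate, c(TRUE, FALSE))
  expect_error(gene_intervals("X", "chr1", 10, 5), "start")

  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr17", "src", "gene", "100", "200", ".", "+", ".",
          'gene_id "BMP7"; gene_name "BMP7";', sep = "\t"),
    paste("chr1", "src", "exon", "10", "40", ".", "+", ".",
          'gene_id "OTHER";', sep = "\t"),
    paste("chr1", "src", "exon", "60", "90", ".", "+", ".",
          'gene_id "OTHER";', sep = "\t")
  ), gtf)
  g2 <- read_gene_intervals(gtf)
  g2 <- g2[order(g2$gene_id), ]
  expect_equal(g2$gene_id, c("BMP7", "OTHER"))
  expect_equal(g2$start[g2$gene_id == "OTHER"], 10L)
  expect_equal(g2$end[g2$gene_id == "OTHER"], 90L)
  expect_true(g2$is_candidate[g2$gene_id == "BMP7"])
})
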