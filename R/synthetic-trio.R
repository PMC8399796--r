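# Synthetic trio generator. Emulates the statistical structure the trio
# analysis relies on: diploid parents with haplotype-resolved variant sets,
# whole-chromosome Mendelian assortment, de novo mutations at a per-
# nucleotide per-generation rate, and per-site read support (depth ~ 20,
# ~10 alternate reads at heterozygous sites). The father is never
# "sequenced": his variants are observable only through transmission,
# exactly as in the study design.

.default_chromosomes <- function() {
  data.frame(
    name = c(paste0("chr", 1:18), "chrX"),
    length = rep(1.3e8, 19),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic trio generator
#'
#' Defaults encode the modeled study conditions: 18 autosomes plus X
#' (~2.5 Gb haploid genome), two causal chromosomes (chr7, chr17), 5,000
#' private variants per parent per chromosome with 10x as many
#' population-shared variants, a de novo rate of 1e-8 per nucleotide per
#' generation, mean site depth 20 with a 1% sequencing error rate, and
#' heterozygous fractions of 0.7 for population variants and 0.9 for
#' parent-private variants.
#'
#' @param chromosomes `data.frame` with columns `name`, `length`.
#' @param father_specific_per_chrom,mother_specific_per_chrom number of
#'   parent-private variants seeded per chromosome.
#' @param population_factor population-shared variants per chromosome, as a
#'   multiple of `father_specific_per_chrom`.
#' @param causal_chromosomes chromosomes on which the proband is forced to
#'   receive the father's haplotype A and the sibling haplotype B.
#' @param de_novo_rate per-nucleotide per-generation mutation rate.
#' @param mean_depth,error_rate read-support model parameters.
#' @param het_population,het_private probability that a variant is
#'   heterozygous (rather than homozygous) in a carrier parent.
#' @param indel_fraction fraction of seeded variants that are Indels.
#' @param n_genes_per_chrom,gene_length toy gene annotation emitted with the
#'   trio (the six candidate genes are placed on chr7/chr17 when present).
#' @param seed RNG seed; identical configs give byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chromosomes = .default_chromosomes(),
                       father_specific_per_chrom = 5000L,
                       mother_specific_per_chrom = 5000L,
                       population_factor = 10,
                       causal_chromosomes = c("chr7", "chr17"),
                       de_novo_rate = 1e-8,
                       mean_depth = 20,
                       error_rate = 0.01,
                       het_population = 0.7,
                       het_private = 0.9,
                       indel_fraction = 0.1,
                       n_genes_per_chrom = 20L,
                       gene_length = 20000L,
                       seed = 1L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)),
            all(chromosomes$length >= 1))
  bad <- setdiff(causal_chromosomes, chromosomes$name)
  if (length(bad)) {
    stop("causal chromosome(s) absent from chromosome list: ",
         paste(bad, collapse = ", "))
  }
  rates <- c(de_novo_rate, error_rate, het_population, het_private,
             indel_fraction)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  structure(list(
    chromosomes = chromosomes,
    father_specific_per_chrom = as.integer(father_specific_per_chrom),
    mother_specific_per_chrom = as.integer(mother_specific_per_chrom),
    population_factor = population_factor,
    causal_chromosomes = causal_chromosomes,
    de_novo_rate = de_novo_rate,
    mean_depth = mean_depth,
    error_rate = error_rate,
    het_population = het_population,
    het_private = het_private,
    indel_fraction = indel_fraction,
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    gene_length = as.integer(gene_length),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate one paternal gamete's chromosome assortment
#'
#' Draws, independently for each chromosome (Mendel's independent
#' assortment), which of the father's two homologs ("A" or "B") enters the
#' gamete, each with probability 0.5; causal chromosomes are forced to "A".
#'
#' @param chromosomes chromosome names.
#' @param causal_chromosomes chromosomes forced to homolog "A".
#' @param n number of gametes (meioses) to draw.
#' @return an `n x length(chromosomes)` character matrix of "A"/"B".
#' @export
simulate_meiosis <- function(chromosomes, causal_chromosomes = character(0),
                             n = 1L) {
  k <- length(chromosomes)
  m <- matrix(sample(c("A", "B"), n * k, replace = TRUE), nrow = n,
              dimnames = list(NULL, chromosomes))
  m[, chromosomes %in% causal_chromosomes] <- "A"
  m
}

#' Simulate per-site read support
#'
#' Depth is Poisson with mean `mean_depth`; at heterozygous sites the
#' alternate-read count is Binomial(depth, 0.5) (so the mean alternate
#' support is half the mean depth), at homozygous sites it is the depth
#' minus a Binomial(depth, `error_rate`) count of miscalled reads.
#'
#' @param zygosity character vector of `"het"` / `"hom"`.
#' @param mean_depth,error_rate model parameters.
#' @return `data.frame` with `depth`, `alt_reads`.
#' @export
simulate_read_support <- function(zygosity, mean_depth = 20,
                                  error_rate = 0.01) {
  n <- length(zygosity)
  depth <- stats::rpois(n, mean_depth)
  alt <- integer(n)
  het <- !is.na(zygosity) & zygosity == "het"
  alt[het] <- stats::rbinom(sum(het), depth[het], 0.5)
  alt[!het] <- depth[!het] - stats::rbinom(sum(!het), depth[!het], error_rate)
  data.frame(depth = depth, alt_reads = alt)
}

# Toy gene annotation: evenly spaced fixed-length genes per chromosome,
# with the six candidate genes taking over the first three slots of chr7
# and chr17 when those chromosomes exist.
.sim_genes <- function(config) {
  chroms <- config$chromosomes
  out <- lapply(seq_len(nrow(chroms)), function(i) {
    n <- config$n_genes_per_chrom
    if (n == 0L) return(NULL)
    len <- chroms$length[i]
    starts <- unique(pmax(1L, as.integer(round(
      seq(0.05 * len, 0.9 * len, length.out = n)))))
    data.frame(
      gene_id = sprintf("GENE_%s_%02d", chroms$name[i], seq_along(starts)),
      chrom = chroms$name[i],
      start = starts,
      end = pmin(as.integer(len), starts + config$gene_length - 1L),
      stringsAsFactors = FALSE
    )
  })
  genes <- do.call(rbind, out)
  for (assign in list(c("chr7", "BMP5", "BMP6", "FOXF2"),
                      c("chr17", "BMP2", "BMP7", "RSPO4"))) {
    idx <- which(genes$chrom == assign[1])
    take <- head(idx, 3)
    genes$gene_id[take] <- assign[-1][seq_along(take)]
  }
  gene_intervals(genes$gene_id, genes$chrom, genes$start, genes$end)
}

# effect assignment for seeded variants: genic SNPs draw a coding effect,
# genic Indels are other_genic, everything else intergenic
.sim_effects <- function(chrom, pos, vtype, genes) {
  eff <- rep("intergenic", length(pos))
  if (is.null(genes) || !nrow(genes)) return(eff)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L)),
    .genes_to_granges(genes), select = "first")
  genic <- !is.na(hits)
  snp <- genic & vtype == "SNP"
  eff[snp] <- sample(c("missense", "synonymous", "other_genic"),
                     sum(snp), replace = TRUE, prob = c(0.25, 0.25, 0.5))
  eff[genic & vtype != "SNP"] <- "other_genic"
  eff
}

.sim_alleles <- function(n, indel_fraction) {
  ref <- sample(.bases, n, replace = TRUE)
  # alternate base: one of the three others, drawn by cyclic offset
  alt <- .bases[(match(ref, .bases) - 1L +
                   sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
  is_indel <- stats::runif(n) < indel_fraction
  if (any(is_indel)) {
    k <- sum(is_indel)
    ins <- stats::runif(k) < 0.5
    ext_len <- sample.int(3L, k, replace = TRUE)
    ext_mat <- matrix(sample(.bases, 3L * k, replace = TRUE), nrow = k)
    ext <- substr(paste0(ext_mat[, 1], ext_mat[, 2], ext_mat[, 3]),
                  1L, ext_len)
    # insertions extend ALT, deletions extend REF (anchored VCF style)
    wi <- which(is_indel)
    alt[wi[ins]] <- paste0(ref[wi[ins]], ext[ins])
    ref[wi[!ins]] <- paste0(ref[wi[!ins]], ext[!ins])
  }
  list(ref = unname(ref), alt = unname(alt))
}

# haplotype code per parent: 0 = absent, 1/2 = het on that haplotype,
# 3 = homozygous (both haplotypes)
.hap_code <- function(carrier, het_prob) {
  n <- length(carrier)
  code <- integer(n)
  het <- carrier & stats::runif(n) < het_prob
  hom <- carrier & !het
  code[het] <- sample(1:2, sum(het), replace = TRUE)
  code[hom] <- 3L
  code
}

#' Simulate a mother / sibling / proband trio
#'
#' Each parent carries two haplotypes per chromosome. Variants are seeded in
#' three classes: population variants present in both parents,
#' mother-private and father-private variants, each heterozygous in the
#' carrier with the configured probability (a heterozygous variant sits on
#' one random haplotype, a homozygous one on both). Each offspring receives
#' one maternal haplotype per chromosome, drawn independently per offspring
#' and per chromosome; the paternal homolog is drawn once per chromosome
#' and shared by the two offspring -- modeling the inferred scenario in
#' which the two sperm complements coincide except where forced apart --
#' with causal chromosomes forced to homolog A for the proband and B for
#' the sibling. Marginally every homolog is transmitted with probability
#' 0.5. De novo mutations are added to each offspring at the configured
#' rate, and every emitted genotype gets simulated read support.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_trio`: `mother`, `sibling`, `proband`
#'   (`variant_records`), `genes` (a [gene_intervals()] table), `truth`
#'   (list with `assortment` per-chromosome haplotype choices, `variants`
#'   per-variant origins and haplotype codes, `de_novo` per-offspring
#'   de novo records) and `config`.
#' @export
simulate_trio <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- config$chromosomes
  genes <- .sim_genes(config)

  n_pop <- as.integer(round(config$population_factor *
                              config$father_specific_per_chrom))
  n_f <- config$father_specific_per_chrom
  n_m <- config$mother_specific_per_chrom

  assort <- data.frame(
    chrom = chroms$name,
    causal = chroms$name %in% config$causal_chromosomes,
    stringsAsFactors = FALSE
  )
  assort$father_to_H <- ifelse(assort$causal, 1L, sample(1:2, nrow(chroms),
                                                         replace = TRUE))
  assort$father_to_S <- ifelse(assort$causal, 2L, assort$father_to_H)
  assort$mother_to_H <- sample(1:2, nrow(chroms), replace = TRUE)
  assort$mother_to_S <- sample(1:2, nrow(chroms), replace = TRUE)

  # hot path: plain vectors with integer chromosome codes; data.frames are
  # only assembled once per individual at the end
  per_chrom <- lapply(seq_len(nrow(chroms)), function(i) {
    total <- n_pop + n_f + n_m
    if (total == 0L) return(NULL)
    if (total > chroms$length[i]) stop("more variants than positions on ",
                                       chroms$name[i])
    pos <- sort(sample.int(chroms$length[i], total))
    klass <- sample(rep(c("population", "father", "mother"),
                        c(n_pop, n_f, n_m)))
    al <- .sim_alleles(total, config$indel_fraction)
    het_prob <- rep(config$het_private, total)
    het_prob[klass == "population"] <- config$het_population
    list(chrom_i = rep(i, total), pos = pos, ref = al$ref, alt = al$alt,
         klass = klass,
         mother_hap = .hap_code(klass %in% c("population", "mother"), het_prob),
         father_hap = .hap_code(klass %in% c("population", "father"), het_prob))
  })
  per_chrom <- Filter(Negate(is.null), per_chrom)
  v <- lapply(setNames(nm = names(per_chrom[[1]])), function(f) {
    unlist(lapply(per_chrom, `[[`, f), use.names = FALSE)
  })
  v$vtype <- classify_variant_type(v$ref, v$alt)
  v$effect <- .sim_effects(chroms$name[v$chrom_i], v$pos, v$vtype, genes)
  seeded_key <- v$chrom_i * 1e9 + v$pos

  carried <- function(hap_code, chosen) hap_code == 3L | hap_code == chosen
  ai <- v$chrom_i
  copies <- list(
    # mother's own genotype: hap code 3 = hom, 1/2 = het
    mother = (v$mother_hap > 0L) + (v$mother_hap == 3L),
    sibling = carried(v$mother_hap, assort$mother_to_S[ai]) +
      carried(v$father_hap, assort$father_to_S[ai]),
    proband = carried(v$mother_hap, assort$mother_to_H[ai]) +
      carried(v$father_hap, assort$father_to_H[ai])
  )

  total_len <- sum(chroms$length)
  build_individual <- function(cp, with_de_novo) {
    idx <- which(cp > 0L)
    dn <- NULL
    if (with_de_novo && config$de_novo_rate > 0) {
      n_dn <- stats::rpois(1, config$de_novo_rate * 2 * total_len)
      if (n_dn > 0) {
        dn_chrom_i <- sample.int(nrow(chroms), n_dn, replace = TRUE,
                                 prob = chroms$length)
        dn_pos <- vapply(dn_chrom_i, function(ci) {
          sample.int(chroms$length[ci], 1)
        }, numeric(1))
        dn_al <- .sim_alleles(n_dn, config$indel_fraction)
        dn_vtype <- classify_variant_type(dn_al$ref, dn_al$alt)
        dn <- data.frame(
          chrom = chroms$name[dn_chrom_i], pos = as.integer(dn_pos),
          ref = dn_al$ref, alt = dn_al$alt, class = "de_novo",
          vtype = dn_vtype,
          effect = .sim_effects(chroms$name[dn_chrom_i], dn_pos, dn_vtype,
                                genes),
          stringsAsFactors = FALSE
        )
        # collisions with seeded sites are simply dropped; at genome scale
        # they are vanishingly rare
        dn <- dn[!(dn_chrom_i * 1e9 + dn_pos) %in% seeded_key, , drop = FALSE]
      }
    }
    n_dn <- if (is.null(dn)) 0L else nrow(dn)
    rec <- data.frame(
      chrom = c(chroms$name[v$chrom_i[idx]], dn$chrom),
      pos = as.integer(c(v$pos[idx], dn$pos)),
      ref = c(v$ref[idx], dn$ref),
      alt = c(v$alt[idx], dn$alt),
      zygosity = c(c("het", "hom")[cp[idx]], rep("het", n_dn)),
      stringsAsFactors = FALSE
    )
    # seeded variants are already chromosome-grouped and position-sorted;
    # a numeric key keeps the ordering cost low
    o <- order(c(seeded_key[idx], match(dn$chrom, chroms$name) * 1e9 + dn$pos))
    rec <- rec[o, , drop = FALSE]
    rs <- simulate_read_support(rec$zygosity, config$mean_depth,
                                config$error_rate)
    rec$depth <- rs$depth
    rec$alt_reads <- rs$alt_reads
    rec$vtype <- c(v$vtype[idx], dn$vtype)[o]
    rec$effect <- c(v$effect[idx], dn$effect)[o]
    rownames(rec) <- NULL
    class(rec) <- c("variant_records", "data.frame")
    list(records = rec, de_novo = dn)
  }

  mother <- build_individual(copies$mother, with_de_novo = FALSE)
  sibling <- build_individual(copies$sibling, with_de_novo = TRUE)
  proband <- build_individual(copies$proband, with_de_novo = TRUE)

  structure(list(
    mother = mother$records,
    sibling = sibling$records,
    proband = proband$records,
    genes = genes,
    truth = list(
      assortment = assort,
      variants = data.frame(
        chrom = chroms$name[v$chrom_i], pos = v$pos, ref = v$ref,
        alt = v$alt, class = v$klass, mother_hap = v$mother_hap,
        father_hap = v$father_hap, stringsAsFactors = FALSE
      ),
      de_novo = list(sibling = sibling$de_novo, proband = proband$de_novo)
    ),
    config = config
  ), class = "sim_trio")
}

#' Add de novo mutations to a set of offspring records
#'
#' Draws the count from Poisson(`rate x diploid genome length`), places the
#' mutations uniformly along the genome (proportionally to chromosome
#' length), makes them heterozygous, and attaches simulated read support.
#'
#' @param records a `variant_records` table (may be empty).
#' @param config a [sim_config()] supplying the rate, chromosome table and
#'   read-support parameters.
#' @return list with `records` (input plus de novo calls) and `de_novo`
#'   (the new calls only, `truth`-style).
#' @export
add_de_novo <- function(records, config) {
  chroms <- config$chromosomes
  total_len <- sum(chroms$length)
  n_dn <- stats::rpois(1, config$de_novo_rate * 2 * total_len)
  if (n_dn == 0) {
    return(list(records = records,
                de_novo = records[0, , drop = FALSE]))
  }
  dn_chrom <- sample(chroms$name, n_dn, replace = TRUE, prob = chroms$length)
  dn_pos <- vapply(dn_chrom, function(cn) {
    sample.int(chroms$length[match(cn, chroms$name)], 1)
  }, numeric(1))
  # re-draw collisions with existing record positions
  if (nrow(records)) {
    for (tries in 1:5) {
      clash <- paste(dn_chrom, dn_pos) %in% paste(records$chrom, records$pos)
      if (!any(clash)) break
      dn_pos[clash] <- vapply(dn_chrom[clash], function(cn) {
        sample.int(chroms$length[match(cn, chroms$name)], 1)
      }, numeric(1))
    }
  }
  al <- .sim_alleles(n_dn, config$indel_fraction)
  rs <- simulate_read_support(rep("het", n_dn), config$mean_depth,
                              config$error_rate)
  dn <- variant_records(dn_chrom, dn_pos, al$ref, al$alt, "het",
                        rs$depth, rs$alt_reads)
  list(records = validate_variant_records(rbind(records, dn)), de_novo = dn)
}

#' Simulate an in-frame ortholog CDS pair with target divergence
#'
#' Starts from a random stop-free coding sequence and derives the second
#' sequence by, per codon, introducing a random synonymous single-nucleotide
#' change with probability `pS x S_c` and a nonsynonymous one (never
#' creating a stop) with probability `pN x N_c`, where `S_c`/`N_c` are the
#' codon's synonymous/nonsynonymous site counts and `pS`/`pN` are the
#' difference proportions whose Jukes-Cantor correction equals the target
#' `dS`/`dN`. [ng86_pair()] then recovers the targets up to counting noise.
#'
#' @param n_codons number of codons.
#' @param target_dS,target_dN target substitution rates (Jukes-Cantor
#'   scale); must be small enough that the implied per-codon change
#'   probabilities stay below 1.
#' @param seed optional RNG seed.
#' @return list with `cds_a`, `cds_b` (character strings of length
#'   `3 * n_codons`).
#' @export
simulate_ortholog_pair <- function(n_codons, target_dS = 0, target_dN = 0,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (target_dS < 0 || target_dN < 0) stop("targets must be >= 0")
  jc_inv <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  pS <- jc_inv(target_dS)
  pN <- jc_inv(target_dN)

  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  if (is.null(.lt_state$syn_sites)) {
    .lt_state$syn_sites <- vapply(sense, .syn_sites_codon, numeric(1))
  }
  S_c <- .lt_state$syn_sites
  N_c <- 3 - S_c
  if (any(pS * S_c > 1) || any(pN * N_c > 1)) {
    stop("targets too large for the per-codon change model")
  }

  neighbors <- function(codon) {
    out <- character(0)
    for (p in 1:3) for (b in setdiff(.bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      out <- c(out, mut)
    }
    out
  }
  syn_nb <- lapply(sense, function(cd) {
    nb <- neighbors(cd)
    nb[Biostrings::GENETIC_CODE[nb] == Biostrings::GENETIC_CODE[cd]]
  })
  nonsyn_nb <- lapply(sense, function(cd) {
    nb <- neighbors(cd)
    nb[Biostrings::GENETIC_CODE[nb] != Biostrings::GENETIC_CODE[cd] &
         Biostrings::GENETIC_CODE[nb] != "*"]
  })
  names(syn_nb) <- names(nonsyn_nb) <- sense

  anc <- sample(sense, n_codons, replace = TRUE)
  der <- anc
  hit_s <- stats::runif(n_codons) < pS * S_c[anc]
  for (i in which(hit_s)) {
    nb <- syn_nb[[der[i]]]
    if (length(nb)) der[i] <- sample(nb, 1)
  }
  hit_n <- stats::runif(n_codons) < pN * N_c[anc]
  for (i in which(hit_n)) {
    nb <- nonsyn_nb[[der[i]]]
    if (length(nb)) der[i] <- sample(nb, 1)
  }
  list(cds_a = paste(anc, collapse = ""), cds_b = paste(der, collapse = ""))
}

#' Simulate clade-labeled alignment codon columns
#'
#' Each column starts from one ancestral codon; every species substitutes it
#' (for a random different stop-free codon) with its clade's substitution
#' probability. With a low focal-clade rate and high rates elsewhere this
#' reproduces the "conserved in the focal clade, variable outside it"
#' pattern.
#'
#' @param n_columns number of alignment columns.
#' @param clade_sizes named integer vector: species per clade. Defaults use
#'   clades large enough (>= 6 species) that a fully variable clade is
#'   unlikely to look conserved by chance.
#' @param sub_prob named numeric vector: per-species substitution
#'   probability per clade.
#' @param seed optional RNG seed.
#' @return `data.frame` with `column`, `species`, `clade`, `codon`.
#' @export
simulate_clade_columns <- function(n_columns,
                                   clade_sizes = c(mammals = 12, birds = 8,
                                                   reptiles = 6,
                                                   amphibians = 6,
                                                   fishes = 10),
                                   sub_prob = c(mammals = 0.02, birds = 0.5,
                                                reptiles = 0.5,
                                                amphibians = 0.5,
                                                fishes = 0.5),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(clade_sizes) %in% names(sub_prob)))
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  clade <- rep(names(clade_sizes), clade_sizes)
  species <- paste0(clade, "_", unlist(lapply(clade_sizes, seq_len)))
  out <- lapply(seq_len(n_columns), function(j) {
    anc <- sample(sense, 1)
    cod <- rep(anc, length(species))
    sub <- stats::runif(length(species)) < sub_prob[clade]
    cod[sub] <- sample(setdiff(sense, anc), sum(sub), replace = TRUE)
    data.frame(column = j, species = species, clade = clade, codon = cod,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a simulated trio to disk
#'
#' Emits plain-text `M.vcf`, `S.vcf`, `H.vcf`, the toy `genes.gtf`, and the
#' simulation truth as sidecar TSVs (`truth_assortment.tsv`,
#' `truth_variants.tsv`) -- never inside the VCFs, so the pipeline cannot
#' peek at it.
#'
#' @param sim a [simulate_trio()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_trio <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_trio"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$mother, file.path(dir, "M.vcf"), sample = "M")
  write_vcf(sim$sibling, file.path(dir, "S.vcf"), sample = "S")
  write_vcf(sim$proband, file.path(dir, "H.vcf"), sample = "H")
  g <- sim$genes
  gtf <- paste(g$chrom, "limbtrace", "gene", g$start, g$end, ".", "+", ".",
               sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_id),
               sep = "\t")
  writeLines(gtf, file.path(dir, "genes.gtf"))
  utils::write.table(sim$truth$assortment,
                     file.path(dir, "truth_assortment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$variants,
                     file.path(dir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
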