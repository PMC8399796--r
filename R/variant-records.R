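#' Construct a table of variant records
#'
#' The central data structure of the package is a plain `data.frame` with one
#' row per called alternate allele and columns `chrom`, `pos` (1-based),
#' `ref`, `alt`, `zygosity` (`"het"`, `"hom"` or `NA` when undefined),
#' `depth` (total read depth, `NA` when unknown), `alt_reads` (reads
#' supporting the alternate allele, `NA` when unknown), `vtype` (`"SNP"` or
#' `"Indel"`) and `effect` (`"missense"`, `"synonymous"`, `"other_genic"` or
#' `"intergenic"`).
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions (`>= 1`).
#' @param ref,alt reference and alternate allele strings.
#' @param zygosity `"het"`, `"hom"` or `NA`.
#' @param depth,alt_reads read support; `NA` when the caller did not report it.
#' @param effect coding-effect class; derived annotations may be passed
#'   through [classify_coding_effect()] first.
#' @return a `data.frame` of class `variant_records`.
#' @export
variant_records <- function(chrom, pos, ref, alt,
                            zygosity = NA_character_,
                            depth = NA_integer_,
                            alt_reads = NA_integer_,
                            effect = NA_character_) {
  n <- length(pos)
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    zygosity = rep_len(as.character(zygosity), n),
    depth = rep_len(as.integer(depth), n),
    alt_reads = rep_len(as.integer(alt_reads), n),
    stringsAsFactors = FALSE
  )
  df$vtype <- classify_variant_type(df$ref, df$alt)
  eff <- rep_len(as.character(effect), n)
  df$effect <- ifelse(is.na(eff), "intergenic", eff)
  validate_variant_records(df)
}

#' @rdname variant_records
#' @param df a data.frame with the columns listed above (e.g. assembled by
#'   hand or subset from another record table); checked and classed.
#' @export
validate_variant_records <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("chrom", "pos", "ref", "alt", "zygosity", "depth",
                "alt_reads", "vtype", "effect")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("variant records lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df)) {
    if (any(df$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
    bad <- !is.na(df$alt_reads) & !is.na(df$depth) &
      (df$alt_reads < 0L | df$alt_reads > df$depth)
    if (any(bad)) stop("alt_reads must lie in [0, depth]")
    if (!all(df$zygosity %in% c("het", "hom", NA_character_))) {
      stop("zygosity must be 'het', 'hom' or NA")
    }
  }
  class(df) <- unique(c("variant_records", class(df)))
  df
}

#' Classify a variant as SNP or Indel
#'
#' A variant is a SNP iff both alleles are single bases; anything else
#' (insertion, deletion, block substitution) is treated as an Indel.
#'
#' @param ref,alt allele strings (vectorized).
#' @return character vector of `"SNP"` / `"Indel"`.
#' @export
classify_variant_type <- function(ref, alt) {
  ref <- as.character(ref); alt <- as.character(alt)
  if (any(!nzchar(ref)) || any(!nzchar(alt)) || anyNA(ref) || anyNA(alt)) {
    stop("allele strings must be non-empty")
  }
  if (any(ref == alt)) stop("ref and alt are identical: not a variant")
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "Indel")
}

#' Parse a VCF genotype string into a zygosity call
#'
#' `"0/1"` (or `"1/0"`, or the phased forms with `|`) is heterozygous,
#' `"1/1"` homozygous, `"./."` undefined. For records decomposed from
#' multi-allelic rows the zygosity is computed against a specific alternate
#' allele index: the number of genotype alleles equal to `alt_index`
#' determines the call (2 = hom, 1 = het, 0 = undefined).
#'
#' @param genotype genotype strings in `a/b` or `a|b` form (vectorized).
#' @param alt_index alternate-allele index the zygosity refers to (default 1).
#' @param n_alt number of ALT alleles at the site; when supplied, genotype
#'   allele indices larger than it raise an error.
#' @return character vector of `"het"`, `"hom"` or `NA`.
#' @export
parse_zygosity <- function(genotype, alt_index = 1L, n_alt = NULL) {
  parts <- strsplit(as.character(genotype), "[/|]")
  vapply(parts, function(al) {
    if (length(al) != 2L || any(al == ".")) return(NA_character_)
    ai <- suppressWarnings(as.integer(al))
    if (anyNA(ai)) stop("malformed genotype: ", paste(al, collapse = "/"))
    if (!is.null(n_alt) && any(ai > n_alt)) {
      stop("genotype references allele index ", max(ai),
           " but the site has only ", n_alt, " ALT allele(s)")
    }
    copies <- sum(ai == alt_index)
    if (copies == 2L) "hom" else if (copies == 1L) "het" else NA_character_
  }, character(1))
}

#' Quality filter on read support
#'
#' The filter requires strictly more than `min_depth` covering reads and
#' strictly more than `min_alt` alternate-supporting reads (defaults match
#' coverage > 10 and alternate count > 3). Records with unknown depth or
#' alternate count fail the filter rather than pass, so unsupported calls
#' never inflate the specific set.
#'
#' @param records a `variant_records` data.frame.
#' @param min_depth,min_alt strict lower bounds.
#' @return logical vector, one element per record.
#' @export
passes_quality_filter <- function(records, min_depth = 10L, min_alt = 3L) {
  ok <- !is.na(records$depth) & !is.na(records$alt_reads) &
    records$depth > min_depth & records$alt_reads > min_alt
  ok
}

#' @rdname passes_quality_filter
#' @return `filter_variants()` returns the subset of passing records.
#' @export
filter_variants <- function(records, min_depth = 10L, min_alt = 3L) {
  validate_variant_records(records[passes_quality_filter(records, min_depth, min_alt), ,
                                   drop = FALSE])
}

#' Upper-tail probability of the sequencing-error binomial test
#'
#' Probability of observing at least `alt_count` alternate reads out of
#' `depth` if every alternate read were an independent sequencing error with
#' probability `error_rate`: `P(X >= alt_count)` for
#' `X ~ Binomial(depth, error_rate)`. Small values mean the call is unlikely
#' to be an artifact.
#'
#' @param depth total reads at the site.
#' @param alt_count alternate-supporting reads (`0 <= alt_count <= depth`).
#' @param error_rate per-read error probability in (0, 1); default 1%.
#' @return upper-tail probabilities (vectorized).
#' @export
sequencing_error_tail <- function(depth, alt_count, error_rate = 0.01) {
  if (any(error_rate <= 0 | error_rate >= 1)) {
    stop("error_rate must lie strictly between 0 and 1")
  }
  if (any(alt_count < 0 | alt_count > depth)) {
    stop("alt_count must lie in [0, depth]")
  }
  stats::pbinom(alt_count - 1, size = depth, prob = error_rate,
                lower.tail = FALSE)
}

# ---- coding-effect classification --------------------------------------

.effect_map <- c(
  missense_variant = "missense",
  synonymous_variant = "synonymous",
  stop_retained_variant = "synonymous",
  intergenic_region = "intergenic",
  intergenic_variant = "intergenic"
)

#' Map an effect-annotation string to a coding-effect class
#'
#' Accepts ANN-style pipe-delimited annotation strings (the `ANN=` prefix and
#' trailing INFO keys are tolerated). Only the first -- most severe --
#' annotation of a comma-separated list is used; `&`-joined terms are
#' scanned in order. `missense_variant` maps to `"missense"`,
#' `synonymous_variant` to `"synonymous"`, intergenic terms (or an absent
#' annotation) to `"intergenic"` and every other genic term to
#' `"other_genic"`. Unknown terms map to `"other_genic"` with a one-time
#' message per term.
#'
#' @param annotation character vector of annotation strings (NA/empty allowed).
#' @return character vector of effect classes.
#' @export
classify_coding_effect <- function(annotation) {
  ann <- as.character(annotation)
  uniq <- unique(ann)
  cls <- vapply(uniq, .classify_one_effect, character(1), USE.NAMES = FALSE)
  cls[match(ann, uniq)]
}

.classify_one_effect <- function(a) {
  if (is.na(a) || !nzchar(a)) return("intergenic")
  a <- sub("^.*ANN=", "", a)
  a <- sub(";.*$", "", a)
  first <- strsplit(a, ",", fixed = TRUE)[[1]][1]
  fields <- strsplit(first, "|", fixed = TRUE)[[1]]
  term_field <- if (length(fields) >= 2L) fields[2] else fields[1]
  terms <- strsplit(term_field, "&", fixed = TRUE)[[1]]
  for (term in terms) {
    if (term %in% names(.effect_map)) return(unname(.effect_map[term]))
    if (grepl("intergenic", term)) return("intergenic")
  }
  known_genic <- c(
    "intron_variant", "stop_gained", "stop_lost", "start_lost",
    "splice_acceptor_variant", "splice_donor_variant", "splice_region_variant",
    "frameshift_variant", "inframe_insertion", "inframe_deletion",
    "disruptive_inframe_deletion", "disruptive_inframe_insertion",
    "5_prime_UTR_variant", "3_prime_UTR_variant",
    "upstream_gene_variant", "downstream_gene_variant",
    "non_coding_transcript_exon_variant", "coding_sequence_variant"
  )
  for (term in terms) {
    if (!(term %in% known_genic) && is.null(.lt_state[[paste0("eff_", term)]])) {
      .lt_state[[paste0("eff_", term)]] <- TRUE
      message("unrecognized annotation term '", term, "' treated as other_genic")
    }
  }
  "other_genic"
}

# ---- VCF reader / writer ------------------------------------------------

#' Read variant records for one sample from a VCF file
#'
#' Wraps [vcfR::read.vcfR()] and maps the calls for `sample` into a
#' [variant_records()] table. Multi-allelic rows are decomposed into one
#' record per ALT allele, with zygosity computed against that allele's
#' index; rows with a missing genotype are skipped. Depth (`DP`) and
#' alternate read count (`AD`) are taken from the per-sample fields and set
#' to `NA` when absent, which downstream quality filtering treats as a
#' failure. Coding effects come from the `ANN` INFO key when present.
#'
#' @param path a VCF 4.x file.
#' @param sample sample name; may be omitted for single-sample files.
#' @return a `variant_records` data.frame (input order preserved).
#' @export
read_vcf <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  samples <- colnames(gt)[-1]
  if (is.null(sample)) {
    if (length(samples) != 1L) {
      stop("VCF has ", length(samples), " samples (",
           paste(samples, collapse = ", "), "); supply `sample`")
    }
    sample <- samples
  }
  if (!sample %in% samples) {
    stop("sample '", sample, "' not in VCF; available: ",
         paste(samples, collapse = ", "))
  }
  n <- nrow(fix)
  if (is.null(n) || n == 0L) {
    return(variant_records(character(0), integer(0), character(0), character(0)))
  }

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop("malformed VCF row (non-numeric POS) at record ",
         which(is.na(pos))[1])
  }
  fmt <- gt[, "FORMAT"]
  if (length(unique(fmt)) == 1L) {
    # constant FORMAT: split the sample column once
    keys <- strsplit(fmt[1], ":", fixed = TRUE)[[1]]
    cols <- data.table::tstrsplit(gt[, sample], ":", fixed = TRUE)
    pick <- function(key) {
      i <- match(key, keys)
      if (is.na(i) || i > length(cols)) rep(NA_character_, n) else cols[[i]]
    }
    gt_str <- pick("GT")
    dp_str <- pick("DP")
    ad_str <- pick("AD")
  } else {
    formats <- strsplit(fmt, ":", fixed = TRUE)
    fields <- strsplit(gt[, sample], ":", fixed = TRUE)
    get_field <- function(key) {
      mapply(function(f, x) {
        i <- match(key, f)
        if (is.na(i) || i > length(x)) NA_character_ else x[i]
      }, formats, fields, USE.NAMES = FALSE)
    }
    gt_str <- get_field("GT")
    dp_str <- get_field("DP")
    ad_str <- get_field("AD")
  }

  keep <- !is.na(gt_str) & gt_str != "." & !grepl("^\\.[/|]\\.$", gt_str)
  idx0 <- which(keep)
  if (!length(idx0)) {
    return(variant_records(character(0), integer(0), character(0), character(0)))
  }

  alt_list <- strsplit(fix[idx0, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  row_of <- rep(idx0, n_alt)      # original row index per expanded record
  rep_of <- rep(seq_along(idx0), n_alt)
  k <- sequence(n_alt)            # ALT index per expanded record

  gt_parts <- data.table::tstrsplit(gt_str[idx0], "[/|]")
  if (length(gt_parts) != 2L) {
    # haploid or malformed genotypes present: fall back per-row
    allele_mat <- do.call(rbind, lapply(strsplit(gt_str[idx0], "[/|]"),
                                        function(a) {
      ai <- suppressWarnings(as.integer(a))
      if (length(ai) != 2L) c(NA_integer_, NA_integer_) else ai
    }))
  } else {
    allele_mat <- cbind(suppressWarnings(as.integer(gt_parts[[1]])),
                        suppressWarnings(as.integer(gt_parts[[2]])))
  }
  max_gt <- pmax(allele_mat[, 1], allele_mat[, 2])
  over <- which(!is.na(max_gt) & max_gt > n_alt)
  if (length(over)) {
    stop("genotype at record ", idx0[over[1]], " references allele index ",
         max_gt[over[1]], " but the row has ", n_alt[over[1]], " ALT allele(s)")
  }
  copies <- (allele_mat[rep_of, 1] == k) + (allele_mat[rep_of, 2] == k)
  zyg <- ifelse(copies == 2L, "hom", ifelse(copies == 1L, "het", NA_character_))

  depth <- suppressWarnings(as.integer(dp_str[idx0]))[rep_of]
  ad_cols <- data.table::tstrsplit(ifelse(is.na(ad_str[idx0]), "",
                                          ad_str[idx0]), ",", fixed = TRUE)
  ad_mat <- do.call(cbind, lapply(ad_cols, function(x) {
    suppressWarnings(as.integer(x))
  }))
  j <- k + 1L
  ok_j <- j <= ncol(ad_mat)
  alt_reads <- rep(NA_integer_, length(row_of))
  alt_reads[ok_j] <- ad_mat[cbind(rep_of[ok_j], j[ok_j])]
  # a reported AD can exceed DP on malformed rows; treat as unknown support
  bad_ad <- !is.na(alt_reads) & !is.na(depth) & alt_reads > depth
  alt_reads[bad_ad] <- NA_integer_

  info <- fix[idx0, "INFO"]
  ann <- ifelse(grepl("ANN=", info, fixed = TRUE),
                sub(".*ANN=([^;]*).*", "\\1", info), NA_character_)
  eff <- classify_coding_effect(ann)[rep_of]

  variant_records(
    chrom = fix[row_of, "CHROM"],
    pos = pos[row_of],
    ref = fix[row_of, "REF"],
    alt = unlist(alt_list),
    zygosity = zyg,
    depth = depth,
    alt_reads = alt_reads,
    effect = eff
  )
}

.effect_to_term <- c(
  missense = "missense_variant",
  synonymous = "synonymous_variant",
  other_genic = "intron_variant",
  intergenic = "intergenic_region"
)

#' Write variant records to a plain-text VCF 4.2 file
#'
#' One row per record (no multi-allelic re-collapsing), with `GT:DP:AD`
#' per-sample fields and the coding effect carried in an `ANN` INFO key, so
#' that [read_vcf()] round-trips records with defined genotypes.
#'
#' @param records a `variant_records` data.frame.
#' @param path output file.
#' @param sample sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample = "SAMPLE") {
  records <- validate_variant_records(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=limbtrace",
    '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotation">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  writeLines(header, con)
  if (nrow(records)) {
    gt <- ifelse(is.na(records$zygosity), "./.",
                 ifelse(records$zygosity == "hom", "1/1", "0/1"))
    dp <- ifelse(is.na(records$depth), ".", as.character(records$depth))
    ad <- ifelse(is.na(records$depth) | is.na(records$alt_reads), ".",
                 paste0(records$depth - records$alt_reads, ",",
                        records$alt_reads))
    ann <- paste0("ANN=", records$alt, "|",
                  .effect_to_term[records$effect], "|MODIFIER|.|.")
    writeLines(paste(records$chrom, records$pos, ".", records$ref,
                     records$alt, ".", "PASS", ann,
                     "GT:DP:AD", paste(gt, dp, ad, sep = ":"),
                     sep = "\t"), con)
  }
  invisible(path)
}

# ---- gene intervals -----------------------------------------------------

.default_candidates <- c("BMP2", "BMP5", "BMP6", "BMP7", "FOXF2", "RSPO4")

#' Build a gene-interval table
#'
#' @param gene_id gene identifiers.
#' @param chrom,start,end 1-based inclusive genomic spans.
#' @param candidate_genes gene identifiers flagged as phenotype candidates;
#'   defaults to the six hindlimb-development candidates BMP2, BMP5, BMP6,
#'   BMP7, FOXF2 and RSPO4.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `is_candidate`.
#' @export
gene_intervals <- function(gene_id, chrom, start, end,
                           candidate_genes = .default_candidates) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("gene interval start must be <= end")
  if (any(start < 1L)) stop("gene interval coordinates are 1-based (>= 1)")
  data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = start,
    end = end,
    is_candidate = as.character(gene_id) %in% candidate_genes,
    stringsAsFactors = FALSE
  )
}

#' Read gene intervals from a GTF file
#'
#' Uses [rtracklayer::import()]; if the file carries `gene` features those
#' are used directly, otherwise one interval per `gene_id` is formed as the
#' range of its features.
#'
#' @param path a GTF file with `gene_id` attributes.
#' @inheritParams gene_intervals
#' @return see [gene_intervals()].
#' @export
read_gene_intervals <- function(path, candidate_genes = .default_candidates) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  # one interval per gene_id: the enclosing range of its features (a `gene`
  # feature, when present, already spans the rest)
  if (anyDuplicated(df$gene_id)) {
    sp <- split(df, df$gene_id)
    df <- do.call(rbind, lapply(sp, function(d) {
      data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                 start = min(d$start), end = max(d$end),
                 stringsAsFactors = FALSE)
    }))
    rownames(df) <- NULL
  }
  gene_intervals(df$gene_id, df$chrom, df$start, df$end, candidate_genes)
}

.genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    gene_id = genes$gene_id
  )
}

.records_to_granges <- function(records) {
  GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$pos,
                              width = pmax(nchar(records$ref), 1L))
  )
}
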