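#' Partition the proband's variants into proband-specific and non-specific sets
#'
#' A proband (H) variant is *specific* when no matching variant exists in
#' either the mother (M) or the sibling (S). Matching is by
#' `(chrom, pos, ref, alt)` in `"allele"` mode (the default) or by
#' `(chrom, pos)` in `"position"` mode. Presence in M or S counts regardless
#' of the genotype there: a site that is heterozygous in the mother still
#' makes the proband's call non-specific, because the contrast is about
#' presence in the pedigree, not about genotype.
#'
#' @param proband,mother,sibling `variant_records` tables (normally already
#'   quality-filtered with [filter_variants()]).
#' @param match_mode `"allele"` or `"position"`.
#' @return an object of class `trio_partition`: a list with elements
#'   `specific`, `nonspecific` (both `variant_records`), `totals` (named
#'   counts) and `match_mode`.
#' @export
partition_specific <- function(proband, mother, sibling,
                               match_mode = c("allele", "position")) {
  match_mode <- match.arg(match_mode)
  if (!nrow(proband)) stop("proband variant set is empty")
  .check_chrom_names(proband$chrom, mother$chrom, sibling$chrom)

  keys <- if (match_mode == "allele") c("chrom", "pos", "ref", "alt") else
    c("chrom", "pos")
  h <- data.table::as.data.table(proband[, keys, drop = FALSE])
  other <- data.table::rbindlist(list(
    data.table::as.data.table(mother[, keys, drop = FALSE]),
    data.table::as.data.table(sibling[, keys, drop = FALSE])
  ))
  hit <- other[h, on = keys, which = TRUE, mult = "first"]
  specific <- is.na(hit)

  out <- list(
    specific = validate_variant_records(proband[specific, , drop = FALSE]),
    nonspecific = validate_variant_records(proband[!specific, , drop = FALSE]),
    totals = c(specific = sum(specific), nonspecific = sum(!specific)),
    match_mode = match_mode
  )
  class(out) <- "trio_partition"
  out
}

#' @export
print.trio_partition <- function(x, ...) {
  tot <- sum(x$totals)
  cat(sprintf(
    "trio partition (%s match): %d specific (%.1f%%), %d non-specific of %d\n",
    x$match_mode, x$totals[["specific"]], percent_specific(x),
    x$totals[["nonspecific"]], tot))
  invisible(x)
}

#' Proband-specific percentage of a partition
#'
#' `100 * |specific| / (|specific| + |nonspecific|)`, reported to one
#' decimal place.
#'
#' @param partition a `trio_partition`, or the specific count.
#' @param total total variant count when `partition` is a plain count.
#' @export
percent_specific <- function(partition, total = NULL) {
  if (inherits(partition, "trio_partition")) {
    s <- partition$totals[["specific"]]
    total <- sum(partition$totals)
  } else {
    s <- as.numeric(partition)
    if (is.null(total)) stop("supply the total count")
  }
  round(100 * s / total, 1)
}

#' Contrast a two-level category between specific and non-specific variants
#'
#' Builds the 2x2 table (specific/non-specific x category) and runs a
#' Pearson chi-square test on 1 df (no continuity correction unless
#' requested). Used for the heterozygous/homozygous, Indel/SNP and
#' missense/synonymous contrasts. Records for which the labeler returns `NA`
#' are excluded and counted.
#'
#' @param partition a `trio_partition`.
#' @param labeler either the name of a record column (e.g. `"zygosity"`,
#'   `"vtype"`) or a function mapping a `variant_records` table to a
#'   character vector with exactly two distinct non-`NA` values.
#' @param correct apply the Yates continuity correction.
#' @return a `contingency_result`: 2x2 `table`, `chi_square`, `p_value`,
#'   row-wise `fractions`, `n_excluded`, and `degenerate` flag (`TRUE` with
#'   undefined p-value when a margin is zero).
#' @export
category_contrast <- function(partition, labeler, correct = FALSE) {
  stopifnot(inherits(partition, "trio_partition"))
  lab_fun <- if (is.character(labeler) && length(labeler) == 1L) {
    col <- labeler
    function(r) as.character(r[[col]])
  } else {
    match.fun(labeler)
  }
  ls <- lab_fun(partition$specific)
  ln <- lab_fun(partition$nonspecific)
  levels <- sort(unique(c(ls[!is.na(ls)], ln[!is.na(ln)])))
  if (length(levels) != 2L) {
    stop("labeler must yield exactly two category values; got: ",
         paste(levels, collapse = ", "))
  }
  tab <- rbind(
    specific = table(factor(ls, levels = levels)),
    nonspecific = table(factor(ln, levels = levels))
  )
  res <- .contingency_2x2(unclass(tab), correct = correct)
  res$n_excluded <- sum(is.na(ls)) + sum(is.na(ln))
  res
}

#' Labeler restricting the effect contrast to missense/synonymous SNPs
#'
#' Returns `"missense"` / `"synonymous"` for SNPs with those effects and
#' `NA` otherwise, for use with [category_contrast()].
#'
#' @param records a `variant_records` table.
#' @export
label_mis_syn <- function(records) {
  out <- records$effect
  out[records$vtype != "SNP" | !out %in% c("missense", "synonymous")] <- NA
  out
}

#' Split genes into proband-specific and non-specific sets
#'
#' A gene is *specific* when at least one specific variant overlaps it and no
#' non-specific variant does; genes touched by any variant but not specific
#' are non-specific; genes with no overlapping variant are excluded.
#'
#' @param partition a `trio_partition`.
#' @param genes a [gene_intervals()] table.
#' @return list with character vectors `specific_genes` and
#'   `nonspecific_genes`.
#' @export
gene_specific_sets <- function(partition, genes) {
  stopifnot(inherits(partition, "trio_partition"))
  ggr <- .genes_to_granges(genes)
  hit_s <- GenomicRanges::countOverlaps(ggr, .records_to_granges(partition$specific)) > 0
  hit_n <- GenomicRanges::countOverlaps(ggr, .records_to_granges(partition$nonspecific)) > 0
  list(
    specific_genes = genes$gene_id[hit_s & !hit_n],
    nonspecific_genes = genes$gene_id[(hit_s | hit_n) & !(hit_s & !hit_n)]
  )
}
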