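#' Per-chromosome enrichment of proband-specific variants
#'
#' For chromosome *i* with specific count `H_i` and non-specific count `N_i`,
#' the specific frequency is `F_Hi = H_i / sum(H)` and the non-specific
#' frequency `F_Ni = N_i / sum(N)`, both normalized over the supplied
#' chromosome list only. The enrichment is `F_Hi / F_Ni`; values above 1 mark
#' chromosomes carrying an excess share of specific variation, the signature
#' of a paternal homolog transmitted to the proband but not to the sibling.
#' Each chromosome also gets a chi-square p-value from
#' [chromosome_chi_square()].
#'
#' @param partition a `trio_partition`.
#' @param chromosomes chromosomes to analyze; must cover every chromosome in
#'   the partition. Default: all chromosomes present, sorted.
#' @param vtype optional restriction to `"SNP"` or `"Indel"` records.
#' @return a `data.frame` with columns `chrom`, `H_i`, `N_i`, `F_Hi`, `F_Ni`,
#'   `enrichment` (NA, flagged, where `N_i = 0`), `chi_square`, `p_value`.
#' @export
chromosome_enrichment <- function(partition, chromosomes = NULL, vtype = NULL) {
  stopifnot(inherits(partition, "trio_partition"))
  spec <- partition$specific
  nons <- partition$nonspecific
  if (!is.null(vtype)) {
    spec <- spec[spec$vtype == vtype, , drop = FALSE]
    nons <- nons[nons$vtype == vtype, , drop = FALSE]
  }
  if (!nrow(spec) || !nrow(nons)) {
    stop("both the specific and non-specific sets must be non-empty")
  }
  present <- unique(c(spec$chrom, nons$chrom))
  if (is.null(chromosomes)) {
    chromosomes <- sort(present)
  } else {
    extra <- setdiff(present, chromosomes)
    if (length(extra)) {
      stop("chromosome list does not cover: ", paste(extra, collapse = ", "))
    }
  }
  H <- as.numeric(table(factor(spec$chrom, levels = chromosomes)))
  N <- as.numeric(table(factor(nons$chrom, levels = chromosomes)))
  F_H <- H / sum(H)
  F_N <- N / sum(N)
  enr <- ifelse(N > 0, F_H / F_N, NA_real_)
  chi <- vapply(seq_along(chromosomes), function(i) {
    r <- .enrichment_chisq(H, N, i)
    c(r$chi_square, r$p_value)
  }, numeric(2))
  data.frame(
    chrom = chromosomes, H_i = H, N_i = N, F_Hi = F_H, F_Ni = F_N,
    enrichment = enr, chi_square = chi[1, ], p_value = chi[2, ],
    stringsAsFactors = FALSE
  )
}

.enrichment_chisq <- function(H, N, i) {
  tab <- matrix(c(H[i], N[i], sum(H) - H[i], sum(N) - N[i]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("target", "others"),
                                c("specific", "nonspecific")))
  .contingency_2x2(tab, correct = FALSE)
}

#' Chi-square test for one chromosome against all others
#'
#' Tests whether the target chromosome's split between specific and
#' non-specific variants differs from that of all remaining chromosomes
#' pooled, via a Pearson chi-square on the 2x2 table
#' `(target vs others) x (specific vs non-specific)`, 1 df, no continuity
#' correction. A zero margin yields an undefined (NA) p-value.
#'
#' @param H,N named numeric vectors of specific / non-specific counts per
#'   chromosome (same names, length >= 2).
#' @param chrom the target chromosome name.
#' @return a `contingency_result`.
#' @export
chromosome_chi_square <- function(H, N, chrom) {
  if (length(H) < 2L || length(H) != length(N)) {
    stop("H and N must be equal-length vectors covering >= 2 chromosomes")
  }
  if (!is.null(names(N)) && !identical(names(H), names(N))) {
    N <- N[names(H)]
  }
  i <- match(chrom, names(H))
  if (is.na(i)) stop("chromosome '", chrom, "' not among counts")
  .enrichment_chisq(as.numeric(H), as.numeric(N), i)
}

#' Call the differentially transmitted chromosomes
#'
#' A chromosome is called when its enrichment exceeds `min_enrichment` AND
#' its chi-square p-value is below `alpha`. Following the source analysis,
#' p-values are not corrected for the ~19 chromosomes tested by default; a
#' Bonferroni option is provided.
#'
#' @param enrichment the table from [chromosome_enrichment()].
#' @param alpha significance level (default 0.05).
#' @param min_enrichment enrichment threshold (default 1.0, strict).
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#' @return chromosome names, sorted by decreasing enrichment.
#' @export
infer_transmitted <- function(enrichment, alpha = 0.05, min_enrichment = 1.0,
                              p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  p <- enrichment$p_value
  if (p_adjust == "bonferroni") p <- pmin(1, p * nrow(enrichment))
  sel <- !is.na(enrichment$enrichment) & !is.na(p) &
    enrichment$enrichment > min_enrichment & p < alpha
  called <- enrichment[sel, , drop = FALSE]
  called$chrom[order(called$enrichment, decreasing = TRUE)]
}
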