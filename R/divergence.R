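# Nei-Gojobori (1986) counting estimator of dN/dS, with Jukes-Cantor
# correction. Synonymous sites: at each codon position, the fraction of the
# three possible single-nucleotide changes that preserve the amino acid;
# changes creating a stop codon count as nonsynonymous, so per-codon
# synonymous + nonsynonymous sites always sum to exactly 3. Differences in
# codons hit more than once are averaged over all shortest substitution
# pathways, excluding pathways that pass through a stop codon (if every
# pathway does, all are kept with stop steps scored nonsynonymous).

.bases <- c("A", "C", "G", "T")

.codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

.syn_sites_codon <- function(codon) {
  aa <- .codon_aa(codon)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(.bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (identical(.codon_aa(mut), aa)) s <- s + 1 / 3
    }
  }
  s
}

.perm_list <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .perm_list(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

# syn/nonsyn difference counts between two codons, pathway-averaged
.codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- .perm_list(pos)
  score_path <- function(order, drop_stop = TRUE) {
    cur <- c1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (drop_stop && .codon_aa(nxt) == "*") return(NULL)
      if (.codon_aa(cur) != "*" && .codon_aa(cur) == .codon_aa(nxt)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  scored <- Filter(Negate(is.null), lapply(paths, score_path))
  if (!length(scored)) {
    scored <- lapply(paths, score_path, drop_stop = FALSE)
  }
  colMeans(do.call(rbind, scored))
}

.split_codons <- function(x) {
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' Nei-Gojobori dN/dS between a pair of in-frame coding sequences
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the
#' two sequences) and differences per codon pair (averaged over all
#' shortest substitution pathways, excluding those through stop codons),
#' then applies the Jukes-Cantor correction
#' `d = -(3/4) * log(1 - (4/3) * p)` to each proportion. Proportions of
#' 3/4 or more make the corrected rate undefined (NA, flagged).
#'
#' @param cds_a,cds_b equal-length, gap-free, in-frame coding sequences
#'   (character strings or anything coercible via `as.character`); length
#'   must be divisible by 3 and internal stop codons are an error. A shared
#'   terminal stop codon is ignored. Codons containing non-ACGT characters
#'   in either sequence are excluded and counted.
#' @return list with `dN`, `dS`, proportions `pN`, `pS`, site counts
#'   `N_sites`, `S_sites`, difference counts `N_diffs`, `S_diffs`,
#'   `codons_used`, `codons_excluded`, and `saturated` (TRUE when a
#'   proportion reached the Jukes-Cantor ceiling).
#' @export
ng86_pair <- function(cds_a, cds_b) {
  a <- toupper(as.character(cds_a))
  b <- toupper(as.character(cds_b))
  if (nchar(a) != nchar(b)) stop("coding sequences differ in length")
  if (nchar(a) %% 3 != 0) stop("sequence length must be divisible by 3")
  if (nchar(a) == 0) stop("empty sequence")
  ca <- .split_codons(a)
  cb <- .split_codons(b)
  n <- length(ca)

  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  aa_a <- ifelse(clean, .codon_aa(ifelse(clean, ca, "AAA")), NA)
  aa_b <- ifelse(clean, .codon_aa(ifelse(clean, cb, "AAA")), NA)
  # a shared terminal stop is tolerated and dropped
  if (n > 1 && clean[n] && aa_a[n] == "*" && aa_b[n] == "*") {
    clean[n] <- FALSE
  }
  if (any(clean & (aa_a == "*" | aa_b == "*"))) {
    stop("internal stop codon at codon ",
         which(clean & (aa_a == "*" | aa_b == "*"))[1])
  }

  ca <- ca[clean]; cb <- cb[clean]
  if (!length(ca)) stop("no usable codons")

  syn_cache <- .lt_state$syn_sites %||% {
    codons <- names(Biostrings::GENETIC_CODE)
    sense <- codons[Biostrings::GENETIC_CODE != "*"]
    .lt_state$syn_sites <- vapply(sense, .syn_sites_codon, numeric(1))
    .lt_state$syn_sites
  }
  S <- (sum(syn_cache[ca]) + sum(syn_cache[cb])) / 2
  N <- 3 * length(ca) - S

  diff_idx <- which(ca != cb)
  sd_nd <- c(sd = 0, nd = 0)
  if (length(diff_idx)) {
    pairs <- paste(ca[diff_idx], cb[diff_idx])
    for (pr in unique(pairs)) {
      cs <- strsplit(pr, " ")[[1]]
      sd_nd <- sd_nd + sum(pairs == pr) * .codon_path_diffs(cs[1], cs[2])
    }
  }
  pS <- if (S > 0) sd_nd[["sd"]] / S else NA_real_
  pN <- if (N > 0) sd_nd[["nd"]] / N else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  }
  list(
    dN = jc(pN), dS = jc(pS), pN = pN, pS = pS,
    N_sites = N, S_sites = S,
    N_diffs = sd_nd[["nd"]], S_diffs = sd_nd[["sd"]],
    codons_used = length(ca), codons_excluded = n - length(ca),
    saturated = isTRUE(pN >= 0.75) || isTRUE(pS >= 0.75)
  )
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic p-value, as used to
#' compare per-gene dN distributions between gene sets.
#'
#' @param values_a,values_b non-empty numeric samples.
#' @return list with `D` and `p_value`.
#' @export
ks_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(values_a, values_b, exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Spearman rank correlation
#'
#' Average ranks on ties; p-value from the t approximation. A constant
#' vector makes rho undefined (NA, flagged).
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return list with `rho`, `p_value` and `degenerate` flag.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need paired samples with n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = unname(ct$p.value),
       degenerate = FALSE)
}

#' Per-gene missense and synonymous counts of proband-specific SNPs
#'
#' Counts proband-specific missense and synonymous SNPs overlapping each
#' gene (Indels never contribute). The mis/syn ratio -- the per-gene proxy
#' for how tolerant the gene is to amino-acid-changing mutations -- is
#' emitted only for genes with both counts at least 1 (set
#' `require_both = FALSE` to require only `syn_count >= 1`).
#'
#' @param partition a `trio_partition`.
#' @param genes a [gene_intervals()] table.
#' @param require_both require both missense and synonymous counts >= 1 for
#'   the ratio (default), otherwise only synonymous >= 1.
#' @return `data.frame` with `gene_id`, `mis_count`, `syn_count`,
#'   `mis_syn_ratio` (NA where undefined); genes with neither count are
#'   dropped.
#' @export
mis_syn_table <- function(partition, genes, require_both = TRUE) {
  stopifnot(inherits(partition, "trio_partition"))
  spec <- partition$specific
  spec <- spec[spec$vtype == "SNP" &
                 spec$effect %in% c("missense", "synonymous"), , drop = FALSE]
  ggr <- .genes_to_granges(genes)
  count_eff <- function(eff) {
    GenomicRanges::countOverlaps(
      ggr, .records_to_granges(spec[spec$effect == eff, , drop = FALSE]))
  }
  mis <- count_eff("missense")
  syn <- count_eff("synonymous")
  keep <- mis + syn > 0
  ok <- if (require_both) mis >= 1 & syn >= 1 else syn >= 1
  data.frame(
    gene_id = genes$gene_id[keep],
    mis_count = mis[keep],
    syn_count = syn[keep],
    mis_syn_ratio = ifelse(ok[keep], mis[keep] / syn[keep], NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Read an ortholog-pair table
#'
#' Two-column TSV (`gene_id_a`, `gene_id_b`) naming, for each gene of the
#' anchor species, its ortholog in the comparison species. Pairing is an
#' explicit input: no homology search is performed.
#'
#' @param path TSV file with a header.
#' @return `data.frame` with columns `gene_id_a`, `gene_id_b`.
#' @export
read_ortholog_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ortholog table needs two columns")
  names(df)[1:2] <- c("gene_id_a", "gene_id_b")
  df[, 1:2]
}

#' Per-gene divergence from ortholog CDS pairs
#'
#' Runs [ng86_pair()] on each ortholog pair. CDS inputs are named sequence
#' sets (e.g. from [Biostrings::readDNAStringSet()]), keyed by the gene ids
#' of the pairing table.
#'
#' @param pairs `data.frame` from [read_ortholog_pairs()].
#' @param cds_a,cds_b named character vectors or `DNAStringSet`s with the
#'   coding sequences of the two species.
#' @return `data.frame` with `gene_id` (anchor species), `dN`, `dS`, `pN`,
#'   `pS`.
#' @export
gene_divergence <- function(pairs, cds_a, cds_b) {
  cds_a <- setNames(as.character(cds_a), names(cds_a))
  cds_b <- setNames(as.character(cds_b), names(cds_b))
  miss_a <- setdiff(pairs$gene_id_a, names(cds_a))
  miss_b <- setdiff(pairs$gene_id_b, names(cds_b))
  if (length(miss_a) || length(miss_b)) {
    stop("missing CDS for: ", paste(c(miss_a, miss_b), collapse = ", "))
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ng86_pair(cds_a[[pairs$gene_id_a[i]]], cds_b[[pairs$gene_id_b[i]]])
  })
  data.frame(
    gene_id = pairs$gene_id_a,
    dN = vapply(res, `[[`, numeric(1), "dN"),
    dS = vapply(res, `[[`, numeric(1), "dS"),
    pN = vapply(res, `[[`, numeric(1), "pN"),
    pS = vapply(res, `[[`, numeric(1), "pS"),
    stringsAsFactors = FALSE
  )
}
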