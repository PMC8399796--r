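# Orthologous-site mapping uses a minimal block format instead of UCSC
# chain files: one block per line maps `length` consecutive source
# positions to a target assembly, strand-aware. 1-based starts throughout.

#' Build / validate a site map
#'
#' @param blocks `data.frame` with columns `source_chrom`, `source_start`,
#'   `target_chrom`, `target_start`, `length` (>= 1) and `strand`
#'   (`"+"`/`"-"`). Blocks must not overlap on the source assembly.
#' @return the validated `data.frame`, class `site_map`.
#' @export
site_map <- function(blocks) {
  required <- c("source_chrom", "source_start", "target_chrom",
                "target_start", "length", "strand")
  miss <- setdiff(required, names(blocks))
  if (length(miss)) stop("site map lacks columns: ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(blocks))) {
    if (is.na(blocks$length[i]) || blocks$length[i] < 1) {
      stop("malformed site map block ", i, ": length must be >= 1")
    }
    if (!blocks$strand[i] %in% c("+", "-")) {
      stop("malformed site map block ", i, ": strand must be '+' or '-'")
    }
    if (is.na(blocks$source_start[i]) || blocks$source_start[i] < 1 ||
        is.na(blocks$target_start[i]) || blocks$target_start[i] < 1) {
      stop("malformed site map block ", i, ": starts are 1-based")
    }
  }
  # non-overlap on source
  for (chr in unique(blocks$source_chrom)) {
    b <- blocks[blocks$source_chrom == chr, , drop = FALSE]
    o <- order(b$source_start)
    ends <- b$source_start[o] + b$length[o] - 1
    if (nrow(b) > 1 && any(b$source_start[o][-1] <= ends[-nrow(b)])) {
      j <- which(b$source_start[o][-1] <= ends[-nrow(b)])[1]
      stop("site map blocks overlap on source ", chr,
           " (block index ", j + 1L, " in source order)")
    }
  }
  class(blocks) <- unique(c("site_map", class(blocks)))
  blocks
}

#' Read a site map from TSV
#'
#' @param path TSV with header `source_chrom, source_start, target_chrom,
#'   target_start, length, strand`.
#' @return a [site_map()].
#' @export
read_site_map <- function(path) {
  site_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Map source coordinates to the target assembly
#'
#' A position inside a block is offset-translated (reversed within the
#' block for minus-strand blocks); positions outside every block are
#' unmapped (`NA`).
#'
#' @param chrom,pos source coordinates (vectorized, 1-based).
#' @param map a [site_map()].
#' @return `data.frame` with `target_chrom`, `target_pos` (`NA` when
#'   unmapped).
#' @export
map_site <- function(chrom, pos, map) {
  stopifnot(inherits(map, "site_map"))
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  tchrom <- rep(NA_character_, length(pos))
  tpos <- rep(NA_real_, length(pos))
  for (i in seq_along(pos)) {
    b <- which(map$source_chrom == chrom[i] &
                 map$source_start <= pos[i] &
                 pos[i] <= map$source_start + map$length - 1)
    if (length(b)) {
      b <- b[1]
      off <- pos[i] - map$source_start[b]
      tchrom[i] <- map$target_chrom[b]
      tpos[i] <- if (map$strand[b] == "+") {
        map$target_start[b] + off
      } else {
        map$target_start[b] + map$length[b] - 1 - off
      }
    }
  }
  data.frame(target_chrom = tchrom, target_pos = tpos,
             stringsAsFactors = FALSE)
}

#' Invert a site map
#'
#' Swaps the source and target roles; strand is preserved (minus-strand
#' blocks invert to minus-strand blocks), so
#' `map_site()` through a map and then its inverse round-trips.
#'
#' @param map a [site_map()].
#' @return a [site_map()].
#' @export
invert_site_map <- function(map) {
  site_map(data.frame(
    source_chrom = map$target_chrom,
    source_start = map$target_start,
    target_chrom = map$source_chrom,
    target_start = map$source_start,
    length = map$length,
    strand = map$strand,
    stringsAsFactors = FALSE
  ))
}

#' Is a site conserved between two species?
#'
#' A position is conserved when the anchor-species reference base is
#' identical to the orthologous base in the comparison species. Ambiguity
#' codes (anything outside A/C/G/T) make the call undefined (`NA`), and such
#' sites are excluded and counted by downstream contrasts.
#'
#' @param source_base,target_base upper-case single bases (vectorized).
#' @return logical vector (`NA` = undefined).
#' @export
conserved_at <- function(source_base, target_base) {
  a <- toupper(as.character(source_base))
  b <- toupper(as.character(target_base))
  ok <- a %in% .bases & b %in% .bases
  ifelse(ok, a == b, NA)
}

#' Contrast conserved fractions between candidate and non-candidate sites
#'
#' 2x2 chi-square of (candidate vs non-candidate) x (conserved vs not).
#' `NA` conservation calls (ambiguity codes) are excluded and counted.
#'
#' @param candidate_sites,noncandidate_sites logical vectors of conservation
#'   calls (from [conserved_at()]).
#' @return a `contingency_result` with an `n_excluded` element.
#' @export
conserved_fraction_contrast <- function(candidate_sites, noncandidate_sites) {
  n_excl <- sum(is.na(candidate_sites)) + sum(is.na(noncandidate_sites))
  cc <- candidate_sites[!is.na(candidate_sites)]
  nn <- noncandidate_sites[!is.na(noncandidate_sites)]
  tab <- matrix(c(sum(cc), sum(!cc), sum(nn), sum(!nn)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("candidate", "noncandidate"),
                                c("conserved", "not_conserved")))
  res <- .contingency_2x2(tab, correct = FALSE)
  res$n_excluded <- n_excl
  res
}

#' Assign variant records to genes or flanking regions
#'
#' A record inside a gene interval is `genic` for that gene; a record
#' within `window` bp of an interval (but inside none) is `intergenic` yet
#' associated with the nearby gene(s); anything else is `unassigned`.
#' Records overlapping several genes get one row per gene, with
#' `n_genes > 1` flagging the ambiguity.
#'
#' @param records a `variant_records` table.
#' @param genes a [gene_intervals()] table.
#' @param window flanking distance in bp (default 50 kb).
#' @return `data.frame` with `record` (row index into `records`),
#'   `gene_id` (`NA` when unassigned), `status` (`genic` / `intergenic` /
#'   `unassigned`) and `n_genes`.
#' @export
assign_to_genes <- function(records, genes, window = 50000L) {
  stopifnot(window >= 0)
  rgr <- .records_to_granges(records)
  ggr <- .genes_to_granges(genes)
  inside <- GenomicRanges::findOverlaps(rgr, ggr)
  near <- GenomicRanges::findOverlaps(rgr, ggr, maxgap = window)
  res <- data.frame(
    record = S4Vectors::queryHits(near),
    gene_id = genes$gene_id[S4Vectors::subjectHits(near)],
    status = "intergenic",
    stringsAsFactors = FALSE
  )
  key_in <- paste(S4Vectors::queryHits(inside), S4Vectors::subjectHits(inside))
  key_near <- paste(S4Vectors::queryHits(near), S4Vectors::subjectHits(near))
  res$status[key_near %in% key_in] <- "genic"
  # genic assignment wins: drop intergenic associations of records that are
  # genic somewhere
  genic_rec <- unique(res$record[res$status == "genic"])
  res <- res[res$status == "genic" | !(res$record %in% genic_rec), , drop = FALSE]
  missing <- setdiff(seq_len(nrow(records)), res$record)
  if (length(missing)) {
    res <- rbind(res, data.frame(record = missing, gene_id = NA_character_,
                                 status = "unassigned",
                                 stringsAsFactors = FALSE))
  }
  res <- res[order(res$record), , drop = FALSE]
  cnt <- table(res$record[res$status == "genic"])
  res$n_genes <- ifelse(res$status == "genic",
                        as.integer(cnt[as.character(res$record)]), 0L)
  rownames(res) <- NULL
  res
}

#' Clade-partitioned codon conservation pattern for one alignment column
#'
#' Per clade, the identity fraction is the share of its species carrying the
#' clade's majority codon (so one derived lineage cannot flip a clade to
#' variable). The column pattern is `conserved_everywhere` when every clade
#' reaches `identity_threshold`, `clade_conserved` when the focal clade
#' reaches it and every other clade stays below it, `variable_everywhere`
#' when all clades stay below it, and `other` otherwise.
#'
#' @param codons one codon (or residue) per species.
#' @param clades clade label per species.
#' @param focal_clade the clade whose private conservation is of interest
#'   (default `"mammals"`).
#' @param identity_threshold identity fraction at or above which a clade
#'   counts as conserved (default 0.9).
#' @return list of class `clade_codon_profile`: `per_clade` data.frame
#'   (`clade`, `n_species`, `n_distinct`, `majority_codon`,
#'   `identity_fraction`) and `pattern`.
#' @export
clade_codon_pattern <- function(codons, clades, focal_clade = "mammals",
                                identity_threshold = 0.9) {
  codons <- toupper(as.character(codons))
  clades <- as.character(clades)
  if (length(codons) != length(clades)) stop("one clade label per species")
  empty <- setdiff(unique(clades), clades[nzchar(codons)])
  keep <- nzchar(codons) & !is.na(codons)
  codons <- codons[keep]; clades <- clades[keep]
  if (!length(codons)) stop("no species with codons")

  per <- lapply(split(codons, clades), function(cs) {
    tab <- sort(table(cs), decreasing = TRUE)
    data.frame(n_species = length(cs), n_distinct = length(tab),
               majority_codon = names(tab)[1],
               identity_fraction = as.numeric(tab[1]) / length(cs),
               stringsAsFactors = FALSE)
  })
  per_clade <- cbind(data.frame(clade = names(per), stringsAsFactors = FALSE),
                     do.call(rbind, per))
  rownames(per_clade) <- NULL

  if (!focal_clade %in% per_clade$clade) {
    stop("focal clade '", focal_clade, "' has no species")
  }
  conserved <- per_clade$identity_fraction >= identity_threshold
  focal <- per_clade$clade == focal_clade
  pattern <- if (all(conserved)) {
    "conserved_everywhere"
  } else if (conserved[focal] && !any(conserved[!focal])) {
    "clade_conserved"
  } else if (!any(conserved)) {
    "variable_everywhere"
  } else {
    "other"
  }
  structure(list(per_clade = per_clade, pattern = pattern,
                 focal_clade = focal_clade,
                 identity_threshold = identity_threshold,
                 excluded_clades = empty),
            class = "clade_codon_profile")
}

#' @export
print.clade_codon_profile <- function(x, ...) {
  cat("clade codon profile: pattern =", x$pattern,
      sprintf("(focal = %s, threshold = %.2f)\n",
              x$focal_clade, x$identity_threshold))
  print(x$per_clade)
  invisible(x)
}

#' Read a clade-labeled alignment from FASTA
#'
#' Sequence descriptions carry the clade as `clade=<name>`.
#'
#' @param path FASTA file.
#' @return `data.frame` with `species`, `clade`, `sequence`.
#' @export
read_clade_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  nm <- names(seqs)
  clade <- sub(".*clade=([^ ]+).*", "\\1", nm)
  clade[!grepl("clade=", nm)] <- NA_character_
  data.frame(
    species = sub("[ ].*$", "", nm),
    clade = clade,
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
}

#' Extract one codon column from a clade alignment
#'
#' @param alignment from [read_clade_alignment()].
#' @param codon_index 1-based codon (column) index.
#' @return `data.frame` with `species`, `clade`, `codon`.
#' @export
alignment_codon_column <- function(alignment, codon_index) {
  start <- (codon_index - 1L) * 3L + 1L
  data.frame(
    species = alignment$species,
    clade = alignment$clade,
    codon = substr(alignment$sequence, start, start + 2L),
    stringsAsFactors = FALSE
  )
}

#' Mean root-to-tip path length per clade
#'
#' For a rooted tree with branch lengths, averages the root-to-tip path
#' length over each clade's leaves and reports each clade's mean relative
#' to a reference clade (mammals by default) -- a direct, model-free
#' summary of per-clade evolutionary rate on a fixed topology.
#'
#' @param tree an [ape::read.tree()] `phylo` object (rooted, with branch
#'   lengths).
#' @param clade_labels named character vector mapping every tip label to a
#'   clade.
#' @param reference_clade clade used as the rate denominator.
#' @return `data.frame` with `clade`, `n_tips`, `mean_root_to_tip`,
#'   `ratio_to_reference`.
#' @export
clade_branch_rates <- function(tree, clade_labels,
                               reference_clade = "mammals") {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    i <- which(is.na(tree$edge.length))[1]
    stop("missing branch length on edge ", tree$edge[i, 1], "->",
         tree$edge[i, 2])
  }
  tips <- tree$tip.label
  miss <- setdiff(tips, names(clade_labels))
  if (length(miss)) {
    stop("tips without clade label: ", paste(miss, collapse = ", "))
  }
  depth <- ape::node.depth.edgelength(tree)[seq_along(tips)]
  clade <- unname(clade_labels[tips])
  agg <- tapply(depth, clade, mean)
  if (!reference_clade %in% names(agg)) {
    stop("reference clade '", reference_clade, "' not present")
  }
  data.frame(
    clade = names(agg),
    n_tips = as.integer(table(clade)[names(agg)]),
    mean_root_to_tip = as.numeric(agg),
    ratio_to_reference = as.numeric(agg) / agg[[reference_clade]],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
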