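#' Default pipeline configuration
#'
#' A fully synthetic, seeded run: a scaled-down trio (19 chromosomes, 2,000
#' private variants per parent per chromosome, 6,000 population variants
#' per chromosome -- a lower shared:private ratio than the generator
#' default so that proband-specific genes, which need a gene free of
#' non-specific variants, actually occur at demo scale) plus synthetic
#' ortholog pairs and clade columns for the divergence and conservation
#' stages. Runs in about half a minute.
#'
#' @param seed seed applied to every stochastic stage.
#' @param out_dir where VCFs, tables and the JSON report are written.
#' @return a named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = tempfile("limbtrace_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("simulate", "classify", "enrich", "diverge", "conserve"),
    sim = sim_config(
      father_specific_per_chrom = 2000L,
      mother_specific_per_chrom = 2000L,
      population_factor = 3,
      seed = as.integer(seed)
    ),
    min_depth = 10L,
    min_alt = 3L,
    error_rate = 0.01,
    match_mode = "allele",
    alpha = 0.05,
    min_enrichment = 1.0,
    window = 50000L,
    ortholog_codons = 200L,
    conserved_prob_candidate = 0.8,
    conserved_prob_noncandidate = 0.5,
    identity_threshold = 0.9
  )
}

.stage_order <- c("simulate", "classify", "enrich", "diverge", "conserve")

#' Run the full trio analysis pipeline
#'
#' Orchestrates simulate -> classify -> enrich -> diverge -> conserve and
#' assembles a machine-readable report. The simulate stage writes the trio
#' VCFs, toy gene GTF and truth sidecars to `out_dir`; classify reads the
#' VCFs back (so the full file path is exercised), quality-filters and
#' partitions; enrich computes per-chromosome enrichment and the
#' transmitted-chromosome call; diverge scores synthetic ortholog pairs
#' with the Nei-Gojobori estimator and contrasts specific vs non-specific
#' genes; conserve runs the conserved-fraction contrast around candidate
#' genes, a clade codon profile and clade branch rates on a synthetic tree.
#' Later stages require the earlier ones: asking for `enrich` without
#' `classify` is an error. Reruns with the same config give an identical
#' report.
#'
#' @param config list from [default_pipeline_config()] (fields may be
#'   overridden).
#' @return list of class `run_report`; also written as `report.json` and
#'   `tables/*.tsv` under `config$out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  stages <- intersect(.stage_order, config$stages)
  need <- function(s) {
    pre <- .stage_order[seq_len(match(s, .stage_order) - 1)]
    missing <- setdiff(setdiff(pre, "diverge"), stages)
    if (s %in% stages && length(missing)) {
      stop("stage '", s, "' requires stage(s): ",
           paste(missing, collapse = ", "))
    }
  }
  for (s in c("classify", "enrich", "diverge", "conserve")) need(s)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tdir <- file.path(config$out_dir, "tables")
  dir.create(tdir, showWarnings = FALSE)
  report <- list(settings = config[setdiff(names(config), "sim")])
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name) {
    message(sprintf("[limbtrace] %s done at %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  emit <- function(df, name) {
    utils::write.table(df, file.path(tdir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  sim <- NULL
  genes <- NULL
  if ("simulate" %in% stages) {
    sim <- simulate_trio(config$sim)
    write_sim_trio(sim, config$out_dir)
    genes <- sim$genes
    report$simulate <- list(
      seed = config$sim$seed,
      causal_chromosomes = config$sim$causal_chromosomes,
      n_variants = c(mother = nrow(sim$mother), sibling = nrow(sim$sibling),
                     proband = nrow(sim$proband))
    )
    log_stage("simulate")
  }

  part <- NULL
  if ("classify" %in% stages) {
    read_in <- function(f, s) read_vcf(file.path(config$out_dir, f), s)
    H <- filter_variants(read_in("H.vcf", "H"), config$min_depth, config$min_alt)
    M <- filter_variants(read_in("M.vcf", "M"), config$min_depth, config$min_alt)
    S <- filter_variants(read_in("S.vcf", "S"), config$min_depth, config$min_alt)
    if (is.null(genes)) {
      genes <- read_gene_intervals(file.path(config$out_dir, "genes.gtf"))
    }
    part <- partition_specific(H, M, S, match_mode = config$match_mode)
    write_vcf(part$specific, file.path(config$out_dir, "H_specific.vcf"), "H")
    write_vcf(part$nonspecific,
              file.path(config$out_dir, "H_nonspecific.vcf"), "H")
    contrasts <- list(
      zygosity = category_contrast(part, "zygosity"),
      vtype = category_contrast(part, "vtype"),
      mis_syn = category_contrast(part, label_mis_syn)
    )
    report$classify <- list(
      filter = c(min_depth = config$min_depth, min_alt = config$min_alt),
      totals = as.list(part$totals),
      percent_specific = percent_specific(part),
      error_tail_depth20_alt10 = sequencing_error_tail(20, 10,
                                                       config$error_rate),
      contrasts = lapply(contrasts, function(x) {
        list(table = x$table, chi_square = x$chi_square, p_value = x$p_value)
      })
    )
    for (nm in names(contrasts)) {
      emit(as.data.frame(contrasts[[nm]]$table), paste0("contrast_", nm))
    }
    log_stage("classify")
  }

  if ("enrich" %in% stages) {
    enr <- chromosome_enrichment(part)
    enr$called_transmitted <- enr$chrom %in%
      infer_transmitted(enr, config$alpha, config$min_enrichment)
    emit(enr, "chromosome_enrichment")
    for (vt in c("SNP", "Indel")) {
      emit(chromosome_enrichment(part, vtype = vt),
           paste0("chromosome_enrichment_", vt))
    }
    report$enrich <- list(
      enrichment = enr,
      transmitted = infer_transmitted(enr, config$alpha,
                                      config$min_enrichment)
    )
    log_stage("enrich")
  }

  if ("diverge" %in% stages) {
    gs <- gene_specific_sets(part, genes)
    # synthetic ortholog pairs: one per gene, gene-specific true dN drawn
    # log-uniformly, dS fixed near the genome-wide average
    gene_ids <- genes$gene_id
    true_dN <- exp(stats::runif(length(gene_ids), log(0.005), log(0.25)))
    div <- do.call(rbind, lapply(seq_along(gene_ids), function(i) {
      pair <- simulate_ortholog_pair(config$ortholog_codons,
                                     target_dS = 0.3, target_dN = true_dN[i])
      ng <- ng86_pair(pair$cds_a, pair$cds_b)
      data.frame(gene_id = gene_ids[i], dN = ng$dN, dS = ng$dS,
                 stringsAsFactors = FALSE)
    }))
    ms <- mis_syn_table(part, genes)
    div <- merge(div, ms, by = "gene_id", all.x = TRUE)
    div$specific_gene <- ifelse(div$gene_id %in% gs$specific_genes, "specific",
                                ifelse(div$gene_id %in% gs$nonspecific_genes,
                                       "nonspecific", "no_variant"))
    emit(div, "gene_divergence")
    dn_s <- div$dN[div$specific_gene == "specific" & !is.na(div$dN)]
    dn_n <- div$dN[div$specific_gene == "nonspecific" & !is.na(div$dN)]
    ksr <- if (length(dn_s) && length(dn_n)) ks_compare(dn_s, dn_n) else NULL
    corr_set <- div[!is.na(div$mis_syn_ratio) & !is.na(div$dN), , drop = FALSE]
    rho <- if (nrow(corr_set) >= 3) {
      rank_correlation(corr_set$dN, corr_set$mis_syn_ratio)
    } else NULL
    report$diverge <- list(
      n_genes = nrow(div),
      n_specific_genes = length(gs$specific_genes),
      n_nonspecific_genes = length(gs$nonspecific_genes),
      ks_dN_specific_vs_nonspecific = ksr,
      spearman_dN_vs_mis_syn = rho
    )
    log_stage("diverge")
  }

  if ("conserve" %in% stages) {
    asg <- assign_to_genes(part$specific, genes, window = config$window)
    cand <- genes$gene_id[genes$is_candidate]
    on_candidate <- asg$record[!is.na(asg$gene_id) & asg$gene_id %in% cand]
    status <- ifelse(seq_len(nrow(part$specific)) %in% on_candidate,
                     "candidate", "noncandidate")
    # synthetic orthologous bases: candidate-associated sites conserved with
    # the configured (higher) probability
    p_cons <- ifelse(status == "candidate", config$conserved_prob_candidate,
                     config$conserved_prob_noncandidate)
    target_base <- ifelse(stats::runif(length(p_cons)) < p_cons,
                          part$specific$ref,
                          vapply(part$specific$ref, function(r) {
                            sample(setdiff(.bases, substr(r, 1, 1)), 1)
                          }, character(1)))
    cons <- conserved_at(substr(part$specific$ref, 1, 1),
                         substr(target_base, 1, 1))
    contrast <- conserved_fraction_contrast(cons[status == "candidate"],
                                            cons[status == "noncandidate"])
    cols <- simulate_clade_columns(1)
    profile <- clade_codon_pattern(cols$codon, cols$clade,
                                   identity_threshold = config$identity_threshold)
    tree <- .synthetic_clade_tree()
    rates <- clade_branch_rates(tree$tree, tree$labels)
    emit(rates, "clade_branch_rates")
    report$conserve <- list(
      n_specific_on_candidate = sum(status == "candidate"),
      conserved_fraction = list(table = contrast$table,
                                chi_square = contrast$chi_square,
                                p_value = contrast$p_value),
      clade_pattern = profile$pattern,
      clade_branch_rates = rates
    )
    log_stage("conserve")
  }

  class(report) <- "run_report"
  json <- jsonlite::toJSON(.report_for_json(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
  writeLines(json, file.path(config$out_dir, "report.json"))
  report
}

# matrices/tables do not serialize helpfully by default
.report_for_json <- function(x) {
  if (inherits(x, "run_report")) x <- unclass(x)
  if (is.table(x) || is.matrix(x)) {
    return(apply(x, 1, function(r) as.list(r), simplify = FALSE))
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, .report_for_json))
  x
}

# fixed synthetic vertebrate tree for the branch-rate demonstration:
# short within-mammal branches, long branches outside
.synthetic_clade_tree <- function() {
  txt <- paste0(
    "((human:0.02,(pig:0.015,ox:0.016):0.01):0.05,",
    "((chicken:0.22,eagle:0.2):0.08,",
    "((lizard:0.3,seaturtle:0.28):0.06,",
    "(frog:0.45,(zebrafish:0.5,medaka:0.52):0.1):0.05):0.04):0.03);")
  tree <- ape::read.tree(text = txt)
  labels <- c(human = "mammals", pig = "mammals", ox = "mammals",
              chicken = "birds", eagle = "birds",
              lizard = "reptiles", seaturtle = "reptiles",
              frog = "amphibians", zebrafish = "fishes", medaka = "fishes")
  list(tree = tree, labels = labels)
}

#' @export
print.run_report <- function(x, ...) {
  cat("limbtrace run report\n")
  if (!is.null(x$classify)) {
    cat(sprintf("  specific: %d of %d (%.1f%%)\n",
                x$classify$totals$specific,
                x$classify$totals$specific + x$classify$totals$nonspecific,
                x$classify$percent_specific))
  }
  if (!is.null(x$enrich)) {
    cat("  transmitted call:",
        paste(x$enrich$transmitted, collapse = ", "), "\n")
  }
  if (!is.null(x$conserve)) {
    cat("  clade codon pattern:", x$conserve$clade_pattern, "\n")
  }
  invisible(x)
}
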