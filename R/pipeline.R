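#' Pipeline configuration
#'
#' Bundles the stage thresholds and the simulation scenario for
#' [run_pipeline()].  The defaults are the thresholds used throughout the
#' analysis: 0.90 metazoan majority for scaffold retention, 0.40/0.50
#' reconciliation rules, member-scan e-value cutoffs 1e-20 (strict) and
#' 1e-10 (relaxed), self-synteny analysis thresholds 1e-5 and 1e-60, and
#' repeat-read cutoffs 0.50/0.25.
#'
#' @param sim a [sim_config()].
#' @param scenario duplication scenario applied to the base genome:
#'   `"wgd"`, `"tandem"` or `"none"`.
#' @param min_metazoan scaffold-retention threshold.
#' @param min_containment,min_mean_overlap round-1 reconciliation rules.
#' @param evalue_cutoff_strict,evalue_cutoff_relaxed member-scan cutoffs.
#' @param evalue_thresholds self-synteny analysis thresholds.
#' @param repeat_cutoffs named vector `c(high = , mild = )` of repeat-read
#'   class boundaries.
#' @param min_cell minimum contribution percentage for a partner call.
#' @param out_dir optional output directory for on-disk artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            scenario = c("wgd", "tandem", "none"),
                            min_metazoan = 0.90,
                            min_containment = 0.40,
                            min_mean_overlap = 0.50,
                            evalue_cutoff_strict = 1e-20,
                            evalue_cutoff_relaxed = 1e-10,
                            evalue_thresholds = c(1e-5, 1e-60),
                            repeat_cutoffs = c(high = 0.50, mild = 0.25),
                            min_cell = 5,
                            out_dir = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(sim, "sim_config"))
  in01 <- c(min_metazoan = min_metazoan, min_containment = min_containment,
            min_mean_overlap = min_mean_overlap, repeat_cutoffs)
  if (any(in01 < 0 | in01 > 1))
    stop("thresholds outside [0, 1]: ",
         paste(names(in01)[in01 < 0 | in01 > 1], collapse = ", "))
  if (repeat_cutoffs["mild"] >= repeat_cutoffs["high"])
    stop("repeat mild cutoff must be below the high cutoff")
  if (any(c(evalue_cutoff_strict, evalue_cutoff_relaxed,
            evalue_thresholds) <= 0))
    stop("e-value cutoffs must be positive")
  structure(list(
    sim = sim, scenario = scenario, min_metazoan = min_metazoan,
    min_containment = min_containment, min_mean_overlap = min_mean_overlap,
    evalue_cutoff_strict = evalue_cutoff_strict,
    evalue_cutoff_relaxed = evalue_cutoff_relaxed,
    evalue_thresholds = evalue_thresholds,
    repeat_cutoffs = repeat_cutoffs, min_cell = min_cell,
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full simulate-and-screen pipeline
#'
#' Simulates a genome under the configured duplication scenario together
#' with taxonomic hits, annotation evidence and a self-alignment table, then
#' runs the analysis stages in order — decontamination, three-round
#' annotation reconciliation, and the self-synteny screen — and returns a
#' machine-readable report comparing each stage's output against the
#' simulator's ground truth.  Stage seeds are derived deterministically from
#' the simulation seed, so re-running with the same configuration gives an
#' identical report.  When `out_dir` is set, the layout (TSV), annotation
#' (GFF3), taxonomic hits (TSV), self-hit table (TSV) and the report (JSON)
#' are written there.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`; see Details in the package
#'   vignette.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  base <- simulate_base_genome(sim)
  scen <- switch(config$scenario,
    wgd = apply_wgd(base, sim$wgd_retention, seed = sim$seed + 1L),
    tandem = apply_tandem(base, sim$tandem_rate, sim$tandem_max_copies,
                          seed = sim$seed + 2L),
    none = list(genome = base, truth = empty_truth())
  )
  genome <- scen$genome
  truth <- scen$truth

  # --- decontamination ------------------------------------------------
  tax <- emit_tax_hits(genome, sim$contaminant_fraction,
                       sim$hits_per_scaffold, seed = sim$seed + 3L)
  summaries <- summarize_scaffold_taxonomy(tax$hits)
  flags <- flag_contaminant_scaffolds(summaries, genome$layout$chrom,
                                      config$min_metazoan)
  renaming <- renumber_scaffolds(flags$keep, flags$remove)
  kept_layout <- assembly_layout(
    unname(renaming[flags$keep]),
    genome$layout$length[match(flags$keep, genome$layout$chrom)])
  kept_genes <- genome$genes[genome$genes$chrom %in% flags$keep, ,
                             drop = FALSE]
  kept_genes$chrom <- unname(renaming[kept_genes$chrom])
  clean <- annotation_set(kept_layout, kept_genes)
  truth_pairs_kept <- truth$pairs[
    truth$pairs$gene1 %in% clean$genes$gene_id &
      truth$pairs$gene2 %in% clean$genes$gene_id, , drop = FALSE]
  decontam_report <- list(
    n_scaffolds = nrow(genome$layout),
    removed = flags$remove,
    truth_contaminants = tax$truth$contaminant_scaffolds,
    false_removals = setdiff(flags$remove,
                             tax$truth$contaminant_scaffolds),
    missed = setdiff(tax$truth$contaminant_scaffolds, flags$remove)
  )

  # --- annotation reconciliation ---------------------------------------
  ev <- emit_annotation_evidence(clean, sim$evidence_noise,
                                 seed = sim$seed + 4L)
  annot <- reconcile_round1(ev$models_r1, ev$clusters, clean$layout,
                            config$min_containment, config$min_mean_overlap)
  annot <- incorporate_novel_models(annot, ev$models_r2, "r2_")
  annot <- reconcile_denovo(annot, ev$denovo_maps)
  annot <- finalize_annotation(annot)
  annot_report <- list(
    n_true_genes = n_genes(clean),
    n_clusters = nrow(ev$clusters),
    n_models_r1 = nrow(ev$models_r1),
    n_genes_final = n_genes(annot),
    source_counts = as.list(attr(annot, "source_counts"))
  )

  # --- self-synteny screen ---------------------------------------------
  hits <- emit_self_hits(clean, truth_restrict(truth, clean),
                         sim$wgd_detectability, sim$spurious_hit_rate,
                         seed = sim$seed + 5L)
  gene_counts <- table(factor(clean$genes$chrom,
                              levels = clean$layout$chrom))
  gene_counts <- stats::setNames(as.numeric(gene_counts),
                                 clean$layout$chrom)
  synteny <- lapply(config$evalue_thresholds, function(th) {
    pairs <- filter_self_hits(hits, clean, evalue_threshold = th)
    mat <- contribution_matrix(pairs, gene_counts)
    list(threshold = th, n_pairs = nrow(pairs),
         summary = summarize_contributions(mat),
         signal = score_duplication_signal(mat, config$min_cell))
  })
  names(synteny) <- format(config$evalue_thresholds, scientific = TRUE)

  report <- structure(list(
    config = config,
    decontam = decontam_report,
    annotation = annot_report,
    synteny = synteny,
    truth_pair_count = nrow(truth_pairs_kept)
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_layout(clean$layout, file.path(config$out_dir, "layout.tsv"))
    write_gff3(annot, file.path(config$out_dir, "annotation.gff3"))
    write_tax_hits(tax$hits, file.path(config$out_dir, "tax_hits.tsv"))
    write_hits_table(hits, file.path(config$out_dir, "self_hits.tsv"))
    jsonlite::write_json(report_to_json(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

truth_restrict <- function(truth, genome) {
  keep <- truth$pairs$gene1 %in% genome$genes$gene_id &
    truth$pairs$gene2 %in% genome$genes$gene_id
  truth$pairs <- truth$pairs[keep, , drop = FALSE]
  truth$gene_to_source <-
    truth$gene_to_source[names(truth$gene_to_source) %in%
                           genome$genes$gene_id]
  truth
}

report_to_json <- function(report) {
  syn <- lapply(report$synteny, function(s) list(
    threshold = s$threshold, n_pairs = s$n_pairs,
    offdiag_mean = s$summary$offdiag_mean,
    offdiag_max = s$summary$offdiag_max,
    diag_mean = s$summary$diag_mean,
    contrast_ratio = if (is.finite(s$summary$contrast_ratio))
      s$summary$contrast_ratio else "Inf",
    n_partner_calls = sum(!is.na(s$signal$partners$partner)),
    n_mutual_pairs = nrow(s$signal$matching)
  ))
  list(
    scenario = report$config$scenario,
    seed = report$config$sim$seed,
    decontam = report$decontam,
    annotation = report$annotation,
    synteny = syn,
    truth_pair_count = report$truth_pair_count
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> scenario:", x$config$scenario, "\n")
  cat("  decontam: removed", length(x$decontam$removed), "of",
      x$decontam$n_scaffolds, "scaffolds (",
      length(x$decontam$false_removals), "false removals )\n")
  cat("  annotation:", x$annotation$n_genes_final, "genes vs",
      x$annotation$n_true_genes, "true\n")
  for (nm in names(x$synteny)) {
    s <- x$synteny[[nm]]
    cat(sprintf("  synteny @ %s: %d pairs, offdiag mean %.2f%%, %d mutual partner pairs\n",
                nm, s$n_pairs, s$summary$offdiag_mean,
                nrow(s$signal$matching)))
  }
  invisible(x)
}
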