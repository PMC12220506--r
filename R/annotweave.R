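transcripts_granges <- function(clusters) {
  if (!nrow(clusters))
    return(GenomicRanges::GRanges())
  n_tr <- vapply(clusters$transcripts, nrow, integer(1))
  idx <- rep(seq_len(nrow(clusters)), n_tr)
  tr <- do.call(rbind, clusters$transcripts[n_tr > 0])
  GenomicRanges::GRanges(
    seqnames = clusters$chrom[idx],
    ranges = IRanges::IRanges(start = tr$start, end = tr$end),
    strand = clusters$strand[idx],
    cluster_idx = idx
  )
}

models_granges <- function(models) {
  GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start, end = models$end),
    strand = models$strand,
    model_idx = seq_len(nrow(models))
  )
}

# Per-(model, candidate cluster) merge statistics.  A cluster is a candidate
# for a model when at least one of its transcripts overlaps the model span
# on the same strand and chromosome.
merge_statistics <- function(models, clusters) {
  empty <- data.frame(model_idx = integer(0), cluster_idx = integer(0),
                      n_candidates = integer(0),
                      containment_fraction = numeric(0),
                      mean_overlap = numeric(0))
  if (!nrow(models) || !nrow(clusters)) return(empty)
  tr_gr <- transcripts_granges(clusters)
  mod_gr <- models_granges(models)
  ov <- GenomicRanges::findOverlaps(mod_gr, tr_gr, ignore.strand = FALSE)
  if (!length(ov)) return(empty)
  mi <- S4Vectors::queryHits(ov)
  ti <- S4Vectors::subjectHits(ov)
  ci <- tr_gr$cluster_idx[ti]
  m_s <- models$start[mi]; m_e <- models$end[mi]
  t_s <- GenomicRanges::start(tr_gr)[ti]
  t_e <- GenomicRanges::end(tr_gr)[ti]
  olen <- overlap_len(m_s, m_e, t_s, t_e)
  frac <- olen / pmin(m_e - m_s + 1, t_e - t_s + 1)
  contained <- (t_s <= m_s & t_e >= m_e) | (m_s <= t_s & m_e >= t_e)
  key <- paste(mi, ci)
  agg <- data.frame(
    model_idx = as.integer(vapply(strsplit(unique(key), " "), `[`,
                                  character(1), 1)),
    cluster_idx = as.integer(vapply(strsplit(unique(key), " "), `[`,
                                    character(1), 2))
  )
  sums <- tapply(frac, key, sum)[unique(key)]
  ncon <- tapply(contained, key, sum)[unique(key)]
  n_tr <- vapply(clusters$transcripts, nrow, integer(1))
  agg$containment_fraction <- as.numeric(ncon) / n_tr[agg$cluster_idx]
  agg$mean_overlap <- as.numeric(sums) / n_tr[agg$cluster_idx]
  cand <- table(agg$model_idx)
  agg$n_candidates <- as.integer(cand[as.character(agg$model_idx)])
  agg
}

apply_merge_rules <- function(stats, min_containment, min_mean_overlap) {
  rule <- rep("none", nrow(stats))
  single <- stats$n_candidates == 1
  rule[single & stats$containment_fraction >= min_containment] <-
    "single-cluster-containment"
  fallback <- rule == "none" & stats$mean_overlap > min_mean_overlap
  rule[fallback] <- "mean-overlap"
  stats$rule_fired <- rule
  stats
}

#' Test a gene model for significant overlap with transcript clusters
#'
#' Candidate clusters share the model's chromosome and strand and overlap it
#' by at least 1 bp.  When the model overlaps transcripts from exactly one
#' cluster, the containment rule fires if at least `min_containment` of the
#' cluster's transcripts fully contain the model or are fully contained
#' within it; failing that (and always, when several clusters overlap), the
#' mean-overlap rule fires if the average per-transcript overlap fraction
#' exceeds `min_mean_overlap`.  Overlap fractions divide the intersection
#' length by the shorter of the two intervals, so full containment scores
#' 1.0.
#'
#' @param model one-row gene-model data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param clusters transcript-cluster data.frame (`cluster_id`, `chrom`,
#'   `strand`, list column `transcripts`).
#' @param min_containment containment-rule threshold (default 0.4).
#' @param min_mean_overlap mean-overlap-rule threshold (default 0.5,
#'   strict).
#' @return data.frame with one row per candidate cluster: `model_id`,
#'   `cluster_id`, `rule_fired` (`single-cluster-containment`,
#'   `mean-overlap` or `none`), `containment_fraction`, `mean_overlap`.
#' @export
significant_overlap <- function(model, clusters, min_containment = 0.4,
                                min_mean_overlap = 0.5) {
  model <- as.data.frame(model)
  stopifnot(nrow(model) == 1)
  stats <- merge_statistics(model, clusters)
  stats <- apply_merge_rules(stats, min_containment, min_mean_overlap)
  data.frame(model_id = rep(model$gene_id, nrow(stats)),
             cluster_id = clusters$cluster_id[stats$cluster_idx],
             rule_fired = stats$rule_fired,
             containment_fraction = stats$containment_fraction,
             mean_overlap = stats$mean_overlap,
             stringsAsFactors = FALSE)
}

cluster_to_genes <- function(clusters) {
  if (!nrow(clusters)) {
    g <- data.frame(gene_id = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0),
                    strand = character(0), source = character(0),
                    stringsAsFactors = FALSE)
    g$exons <- list()
    return(g)
  }
  span <- t(vapply(clusters$transcripts, function(tr)
    c(min(tr$start), max(tr$end)), numeric(2)))
  g <- data.frame(gene_id = clusters$cluster_id, chrom = clusters$chrom,
                  start = span[, 1], end = span[, 2],
                  strand = clusters$strand, source = "iso",
                  stringsAsFactors = FALSE)
  g$exons <- lapply(clusters$transcripts, function(tr) {
    red <- IRanges::reduce(IRanges::IRanges(tr$start, tr$end))
    data.frame(start = IRanges::start(red), end = IRanges::end(red))
  })
  g
}

#' Round-1 reconciliation: transcript clusters versus ab initio models
#'
#' Treats every transcript cluster as a gene and keeps only the ab initio
#' models with no significant overlap (see [significant_overlap()]) against
#' any cluster.  The conservation law `genes = clusters + retained models`
#' holds exactly and is asserted on every run.
#'
#' @param models round-1 ab initio gene models (data.frame as in
#'   [emit_annotation_evidence()]).
#' @param clusters transcript clusters.
#' @param layout an [assembly_layout()] covering both inputs.
#' @param min_containment,min_mean_overlap rule thresholds.
#' @return An [annotation_set()] with cluster-derived genes (source `iso`)
#'   and retained models; the per-model decisions are attached as attribute
#'   `decisions`.
#' @export
reconcile_round1 <- function(models, clusters, layout,
                             min_containment = 0.4, min_mean_overlap = 0.5) {
  stats <- merge_statistics(models, clusters)
  stats <- apply_merge_rules(stats, min_containment, min_mean_overlap)
  dropped_idx <- unique(stats$model_idx[stats$rule_fired != "none"])
  retained <- models[setdiff(seq_len(nrow(models)), dropped_idx), ,
                     drop = FALSE]
  genes <- rbind(cluster_to_genes(clusters), retained)
  rownames(genes) <- NULL
  out <- annotation_set(layout, genes)
  stopifnot(n_genes(out) == nrow(clusters) + nrow(retained))
  attr(out, "decisions") <- data.frame(
    model_id = models$gene_id[stats$model_idx],
    cluster_id = clusters$cluster_id[stats$cluster_idx],
    rule_fired = stats$rule_fired,
    containment_fraction = stats$containment_fraction,
    mean_overlap = stats$mean_overlap,
    stringsAsFactors = FALSE
  )
  out
}

#' Mask evidence covered by an existing annotation
#'
#' Retains exactly the evidence intervals with zero overlap (any strand)
#' against any annotated gene span, mirroring `bedtools intersect -v`.
#'
#' @param evidence data.frame with `chrom`, `start`, `end` columns.
#' @param annotation an [annotation_set()].
#' @return the subset of `evidence` rows kept.
#' @export
mask_annotated_evidence <- function(evidence, annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  if (!nrow(evidence)) return(evidence)
  ev_gr <- GenomicRanges::GRanges(evidence$chrom,
                                  IRanges::IRanges(evidence$start,
                                                   evidence$end))
  hit <- IRanges::overlapsAny(ev_gr, genes_granges(annotation),
                                    ignore.strand = TRUE)
  evidence[!hit, , drop = FALSE]
}

exons_granges <- function(genes) {
  ex <- exon_table(genes)
  GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end),
                         strand = ex$strand, gene_id = ex$gene_id)
}

#' Incorporate novel gene models by exon-level cross-referencing
#'
#' A new model is added if and only if none of its exons overlaps (same
#' strand) any exon of an existing gene; accepted ids receive `id_prefix`.
#'
#' @param annotation an [annotation_set()].
#' @param new_models gene-model data.frame.
#' @param id_prefix prefix for accepted ids (e.g. `"r2_"`).
#' @return the augmented [annotation_set()].
#' @export
incorporate_novel_models <- function(annotation, new_models,
                                     id_prefix = "r2_") {
  stopifnot(inherits(annotation, "annotation_set"))
  if (!nrow(new_models)) return(annotation)
  existing_ex <- exons_granges(annotation$genes)
  new_ex <- exon_table(new_models)
  new_gr <- GenomicRanges::GRanges(new_ex$chrom,
                                   IRanges::IRanges(new_ex$start, new_ex$end),
                                   strand = new_ex$strand)
  clash <- IRanges::overlapsAny(new_gr, existing_ex,
                                      ignore.strand = FALSE)
  clashing_models <- unique(new_ex$gene_id[clash])
  accepted <- new_models[!new_models$gene_id %in% clashing_models, ,
                         drop = FALSE]
  if (!nrow(accepted)) return(annotation)
  accepted$gene_id <- paste0(id_prefix, accepted$gene_id)
  dup <- intersect(accepted$gene_id, annotation$genes$gene_id)
  if (length(dup))
    stop("duplicate gene ids after prefixing: ",
         paste(utils::head(dup), collapse = ", "))
  genes <- rbind(annotation$genes, accepted)
  rownames(genes) <- NULL
  annotation_set(annotation$layout, genes)
}

# Same-strand connected components of intervals (per chromosome+strand).
overlap_components <- function(df) {
  comp <- integer(nrow(df))
  next_comp <- 0L
  for (grp in split(seq_len(nrow(df)), paste(df$chrom, df$strand))) {
    ir <- IRanges::IRanges(df$start[grp], df$end[grp])
    red <- IRanges::reduce(ir)
    hit <- IRanges::findOverlaps(ir, red, select = "first")
    comp[grp] <- next_comp + hit
    next_comp <- next_comp + length(red)
  }
  comp
}

#' Rescue gene loci from de novo transcriptome mappings
#'
#' Complete-ORF transcript mappings from several developmental stages are
#' reconciled into new gene models: mappings overlapping the existing
#' annotation (any strand) are discarded first; the remainder are grouped
#' into same-strand overlapping loci across stages.  A locus becomes a gene
#' when it contains a mapping from the anchor stage or, when
#' `keep_nonanchor_loci` is `TRUE`, when at least `min_stage_support`
#' distinct non-anchor stages agree on it.  New genes span the union of
#' their mappings and receive ascending ids `at_DN<number>`; residual
#' same-strand overlaps among new genes are resolved by keeping the longer
#' model (ties: lexicographically smaller id).
#'
#' @param annotation an [annotation_set()].
#' @param stage_maps named list of per-stage gene-model data.frames.
#' @param anchor_stage name of the anchor stage within `stage_maps`.
#' @param keep_nonanchor_loci keep loci unsupported by the anchor stage when
#'   enough non-anchor stages agree (default `TRUE`).
#' @param min_stage_support distinct non-anchor stages required for such
#'   loci (default 2).
#' @param id_prefix prefix of the new ids (default `"at_DN"`).
#' @return the augmented [annotation_set()].
#' @export
reconcile_denovo <- function(annotation, stage_maps,
                             anchor_stage = "instarIII",
                             keep_nonanchor_loci = TRUE,
                             min_stage_support = 2, id_prefix = "at_DN") {
  stopifnot(inherits(annotation, "annotation_set"))
  if (!anchor_stage %in% names(stage_maps))
    stop("unknown anchor stage: ", anchor_stage)
  pooled <- do.call(rbind, Map(function(df, st) {
    if (!nrow(df)) return(NULL)
    df$stage <- st
    df
  }, stage_maps, names(stage_maps)))
  if (is.null(pooled) || !nrow(pooled)) return(annotation)
  pooled <- mask_annotated_evidence(pooled, annotation)
  if (!nrow(pooled)) return(annotation)
  comp <- overlap_components(pooled)
  keep_comp <- vapply(split(pooled$stage, comp), function(st) {
    anchor_stage %in% st ||
      (keep_nonanchor_loci &&
         length(unique(setdiff(st, anchor_stage))) >= min_stage_support)
  }, logical(1))
  sel <- comp %in% as.integer(names(keep_comp)[keep_comp])
  if (!any(sel)) return(annotation)
  pooled <- pooled[sel, , drop = FALSE]
  comp <- comp[sel]
  new_genes <- do.call(rbind, lapply(split(seq_along(comp), comp),
                                     function(idx) {
    d <- pooled[idx, , drop = FALSE]
    ex <- exon_table(d)
    red <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    g <- data.frame(gene_id = NA_character_, chrom = d$chrom[1],
                    start = min(d$start), end = max(d$end),
                    strand = d$strand[1], source = "denovo",
                    stringsAsFactors = FALSE)
    g$exons <- list(data.frame(start = IRanges::start(red),
                               end = IRanges::end(red)))
    g
  }))
  ord <- order(match(new_genes$chrom, annotation$layout$chrom),
               new_genes$start)
  new_genes <- new_genes[ord, , drop = FALSE]
  new_genes$gene_id <- paste0(id_prefix, seq_len(nrow(new_genes)))
  new_genes <- resolve_residual_overlaps(new_genes)
  genes <- rbind(annotation$genes, new_genes)
  rownames(genes) <- NULL
  annotation_set(annotation$layout, genes)
}

# Keep the longer model among same-strand overlapping ones (tie:
# lexicographically smaller id).
resolve_residual_overlaps <- function(genes) {
  if (nrow(genes) < 2) return(genes)
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  ov <- GenomicRanges::findOverlaps(gr, ignore.strand = FALSE,
                                    drop.self = TRUE, drop.redundant = TRUE)
  if (!length(ov)) return(genes)
  len <- genes$end - genes$start + 1
  drop <- logical(nrow(genes))
  for (k in seq_along(ov)) {
    i <- S4Vectors::queryHits(ov)[k]
    j <- S4Vectors::subjectHits(ov)[k]
    if (drop[i] || drop[j]) next
    loser <- if (len[i] != len[j]) {
      if (len[i] < len[j]) i else j
    } else if (genes$gene_id[i] > genes$gene_id[j]) i else j
    drop[loser] <- TRUE
  }
  genes[!drop, , drop = FALSE]
}

#' Sort and finalize an annotation
#'
#' Orders genes by assembly chromosome order, then start position, then id,
#' and warns (listing the pairs) when same-strand overlapping genes remain:
#' such residuals are candidates for manual merging and are deliberately not
#' resolved automatically.
#'
#' @param annotation an [annotation_set()].
#' @return the sorted [annotation_set()], with a `source_counts` attribute
#'   tabulating genes per source class.
#' @export
finalize_annotation <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  g <- annotation$genes
  ord <- order(match(g$chrom, annotation$layout$chrom), g$start, g$gene_id)
  g <- g[ord, , drop = FALSE]
  rownames(g) <- NULL
  out <- annotation_set(annotation$layout, g)
  gr <- genes_granges(out)
  ov <- GenomicRanges::findOverlaps(gr, ignore.strand = FALSE,
                                    drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov)) {
    pairs <- paste(g$gene_id[S4Vectors::queryHits(ov)],
                   g$gene_id[S4Vectors::subjectHits(ov)], sep = "/")
    warning("same-strand overlapping genes remain (candidates for manual ",
            "merge): ", paste(utils::head(pairs, 20), collapse = ", "))
  }
  attr(out, "source_counts") <- table(g$source)
  out
}
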