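#' Expected gene-cluster definition
#'
#' @param name cluster name (e.g. `"Hox"`).
#' @param members ordered character vector of member labels; the order is
#'   the ancestral genomic order (e.g. `Hox1` ... `Hox10`).
#' @return list of class `expected_cluster`.
#' @export
expected_cluster <- function(name, members) {
  members <- as.character(members)
  if (!length(members)) stop("members must be non-empty")
  if (anyDuplicated(members)) stop("members must be unique")
  structure(list(name = name, members = members),
            class = "expected_cluster")
}

#' The ten ancestral arthropod Hox cluster members
#'
#' Ordered member labels of the arthropod Hox cluster, `Hox1` (labial)
#' through `Hox10` (Abdominal-B), including `Hox9` (abdominal-A), whose
#' absence from an otherwise intact cluster is a diagnostic gene loss.
#' @return an [expected_cluster()].
#' @export
hox_cluster <- function() {
  expected_cluster("Hox", paste0("Hox", 1:10))
}

#' Map member-query alignment hits onto gene models
#'
#' Hits below the e-value cutoff are kept and mapped to the gene model
#' overlapping the hit location (ties broken by larger overlap, then gene
#' id); per member and gene model only the best e-value is retained.  Hits
#' overlapping no gene model are recorded in the `unmapped` attribute, not
#' dropped silently.  Running twice with a strict (1e-20) and a relaxed
#' (1e-10) cutoff reproduces the usual two-pass scan.
#'
#' @param hits data.frame with columns `member`, `chrom`, `start`, `end`,
#'   `evalue`.
#' @param annotation an [annotation_set()].
#' @param evalue_cutoff keep hits with `evalue < evalue_cutoff`
#'   (default 1e-20).
#' @return data.frame (`member`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `evalue`), one row per member/gene pair, with attribute
#'   `unmapped` holding the unplaceable hits.
#' @export
assign_members_from_hits <- function(hits, annotation,
                                     evalue_cutoff = 1e-20) {
  stopifnot(inherits(annotation, "annotation_set"))
  req <- c("member", "chrom", "start", "end", "evalue")
  if (!all(req %in% names(hits)))
    stop("hits must have columns: ", paste(req, collapse = ", "))
  hits <- hits[hits$evalue < evalue_cutoff, , drop = FALSE]
  empty <- data.frame(member = character(0), gene_id = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(structure(empty, unmapped = hits))
  hit_gr <- GenomicRanges::GRanges(hits$chrom,
                                   IRanges::IRanges(hits$start, hits$end))
  gene_gr <- genes_granges(annotation)
  ov <- GenomicRanges::findOverlaps(hit_gr, gene_gr, ignore.strand = TRUE)
  hi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  unmapped <- hits[setdiff(seq_len(nrow(hits)), unique(hi)), , drop = FALSE]
  if (!length(hi)) return(structure(empty, unmapped = unmapped))
  g <- annotation$genes
  olen <- overlap_len(hits$start[hi], hits$end[hi], g$start[gi], g$end[gi])
  # best gene per hit: largest overlap, then gene id
  ord <- order(hi, -olen, g$gene_id[gi])
  first <- !duplicated(hi[ord])
  hi <- hi[ord][first]; gi <- gi[ord][first]
  cand <- data.frame(member = hits$member[hi], gene_id = g$gene_id[gi],
                     chrom = g$chrom[gi], start = g$start[gi],
                     end = g$end[gi], strand = g$strand[gi],
                     evalue = hits$evalue[hi], stringsAsFactors = FALSE)
  # best e-value per (member, gene)
  ord <- order(cand$member, cand$gene_id, cand$evalue)
  cand <- cand[ord, , drop = FALSE]
  keep <- !duplicated(cand[, c("member", "gene_id")])
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, unmapped = unmapped)
}

#' Assess the integrity of a conserved gene cluster
#'
#' Reports per-member copy numbers, missing members, chromosome usage,
#' genomic ordering, strand uniformity and span.  Ordering is evaluated over
#' single-copy members only (multi-copy members such as tandem-expanded
#' paralogs do not break it) and accepts a uniformly reversed cluster, so an
#' ascending cluster on the minus strand counts as ordered; orientation is
#' reported separately through `strand_uniform`.
#'
#' @param assignment output of [assign_members_from_hits()].
#' @param expected an [expected_cluster()].
#' @return list of class `cluster_report`: `name`, `copy_number` (named
#'   integer over expected members), `missing`, `chromosomes`,
#'   `single_chromosome`, `ordered`, `breakpoints`, `strand_uniform`,
#'   `span` (`NA` unless `single_chromosome`), `span_start`, `span_end`,
#'   `member_genes` (assignment rows).
#' @export
assess_cluster <- function(assignment, expected) {
  stopifnot(inherits(expected, "expected_cluster"))
  a <- assignment[assignment$member %in% expected$members, , drop = FALSE]
  copy_number <- stats::setNames(integer(length(expected$members)),
                                 expected$members)
  tab <- table(a$member)
  copy_number[names(tab)] <- as.integer(tab)
  missing <- expected$members[copy_number == 0]
  chroms <- unique(a$chrom)
  single_chrom <- length(chroms) == 1
  strand_uniform <- nrow(a) > 0 && length(unique(a$strand)) == 1

  # order over single-copy members, on the chromosome holding most of them
  single <- names(copy_number)[copy_number == 1]
  s <- a[a$member %in% single, , drop = FALSE]
  ordered <- NA
  breakpoints <- NA_integer_
  if (nrow(s) >= 2) {
    modal <- names(which.max(table(s$chrom)))
    s <- s[s$chrom == modal, , drop = FALSE]
    if (nrow(s) >= 2) {
      s <- s[order((s$start + s$end) / 2), , drop = FALSE]
      idx <- match(s$member, expected$members)
      asc_viol <- sum(diff(idx) < 0)
      desc_viol <- sum(diff(idx) > 0)
      breakpoints <- min(asc_viol, desc_viol)
      ordered <- breakpoints == 0L
    }
  }
  span <- span_start <- span_end <- NA_real_
  if (single_chrom && nrow(a)) {
    span_start <- min(a$start)
    span_end <- max(a$end)
    span <- span_end - span_start
  }
  structure(list(
    name = expected$name, copy_number = copy_number, missing = missing,
    chromosomes = chroms, single_chromosome = single_chrom,
    ordered = ordered, breakpoints = breakpoints,
    strand_uniform = strand_uniform, span = span,
    span_start = span_start, span_end = span_end, member_genes = a
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report> ", x$name, ": ",
      sum(x$copy_number > 0), "/", length(x$copy_number),
      " members present (", sum(x$copy_number), " copies)\n", sep = "")
  if (length(x$missing))
    cat("  missing: ", paste(x$missing, collapse = ", "), "\n", sep = "")
  cat("  chromosomes: ", paste(x$chromosomes, collapse = ", "),
      "; ordered: ", x$ordered, "; strand uniform: ", x$strand_uniform,
      if (!is.na(x$span)) paste0("; span: ", format(x$span, big.mark = ",")),
      "\n", sep = "")
  invisible(x)
}

#' Detect syntenic blocks of cluster members
#'
#' Groups assigned members by chromosome; co-location on one chromosome is
#' the only requirement (intervening non-member genes and strand are
#' ignored).  Within a block, members are listed in coordinate order.
#'
#' @param assignment output of [assign_members_from_hits()].
#' @return data.frame with one row per chromosome holding members: `chrom`,
#'   `n_genes` (assigned copies on the chromosome), list column `members`
#'   (labels in coordinate order, one per copy) and `member_string`
#'   (comma-collapsed).  Every assigned copy appears in exactly one block.
#' @export
detect_syntenic_blocks <- function(assignment) {
  if (!nrow(assignment)) {
    out <- data.frame(chrom = character(0), n_genes = integer(0),
                      member_string = character(0), stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  blocks <- lapply(split(assignment, assignment$chrom), function(d) {
    d <- d[order((d$start + d$end) / 2), , drop = FALSE]
    b <- data.frame(chrom = d$chrom[1], n_genes = nrow(d),
                    member_string = paste(d$member, collapse = ","),
                    stringsAsFactors = FALSE)
    b$members <- list(d$member)
    b
  })
  out <- do.call(rbind, blocks)
  out <- out[order(-out$n_genes, out$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find non-member gene models inside a cluster span
#'
#' Lists the annotated genes lying inside the cluster span that are not
#' cluster members, together with the flanking members on each side — e.g.
#' a putative gene sitting between two Hox genes.
#'
#' @param annotation an [annotation_set()].
#' @param report a [assess_cluster()] report with a defined span
#'   (single-chromosome cluster).
#' @return data.frame with `gene_id`, `start`, `end`, `left_member`,
#'   `right_member`.
#' @export
find_intervening_models <- function(annotation, report) {
  stopifnot(inherits(report, "cluster_report"))
  if (!report$single_chromosome || is.na(report$span))
    stop("cluster span undefined: members are not on a single chromosome")
  chrom <- report$chromosomes
  g <- annotation$genes
  inside <- g$chrom == chrom & g$start >= report$span_start &
    g$end <= report$span_end & !g$gene_id %in% report$member_genes$gene_id
  g <- g[inside, , drop = FALSE]
  if (!nrow(g))
    return(data.frame(gene_id = character(0), start = numeric(0),
                      end = numeric(0), left_member = character(0),
                      right_member = character(0), stringsAsFactors = FALSE))
  m <- report$member_genes
  m <- m[order(m$start), , drop = FALSE]
  mid <- (g$start + g$end) / 2
  left <- vapply(mid, function(x) {
    before <- which(m$end <= x)
    if (length(before)) m$member[max(before)] else NA_character_
  }, character(1))
  right <- vapply(mid, function(x) {
    after <- which(m$start >= x)
    if (length(after)) m$member[min(after)] else NA_character_
  }, character(1))
  out <- data.frame(gene_id = g$gene_id, start = g$start, end = g$end,
                    left_member = left, right_member = right,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Completeness of an expected label set
#'
#' Fraction of expected labels that were found, as used for conserved
#' microRNA family tallies (e.g. 45 of 47 families gives 95.7%).
#'
#' @param found character vector of found labels.
#' @param expected character vector of expected labels (non-empty).
#' @return list with `fraction`, `percent` (rounded to one decimal),
#'   `missing`, `n_found`, `n_expected`.
#' @export
completeness_score <- function(found, expected) {
  expected <- unique(as.character(expected))
  if (!length(expected)) stop("expected must be non-empty")
  found <- unique(as.character(found))
  inter <- intersect(found, expected)
  frac <- length(inter) / length(expected)
  list(fraction = frac, percent = round(100 * frac, 1),
       missing = setdiff(expected, found),
       n_found = length(inter), n_expected = length(expected))
}

#' Flag gene models with byte-identical nucleotide sequences
#'
#' Pairs of gene models whose nucleotide sequences are exactly identical
#' hint at a misassembly and are flagged for manual review.  By default only
#' same-chromosome pairs are flagged (the misassembly suspicion is
#' positional); set `same_chromosome_only = FALSE` to widen the scope.
#'
#' @param annotation an [annotation_set()].
#' @param sequences named character vector, gene id to nucleotide sequence.
#' @param same_chromosome_only restrict to same-chromosome pairs.
#' @return data.frame with `gene1`, `gene2`, `chrom1`, `chrom2`.
#' @export
flag_identical_duplicates <- function(annotation, sequences,
                                      same_chromosome_only = TRUE) {
  stopifnot(inherits(annotation, "annotation_set"))
  g <- annotation$genes
  have <- g$gene_id %in% names(sequences)
  if (!all(have))
    warning("no sequence for ", sum(!have), " gene(s); skipped: ",
            paste(utils::head(g$gene_id[!have]), collapse = ", "))
  g <- g[have, , drop = FALSE]
  seqs <- as.character(sequences[g$gene_id])
  out <- data.frame(gene1 = character(0), gene2 = character(0),
                    chrom1 = character(0), chrom2 = character(0),
                    stringsAsFactors = FALSE)
  for (idx in split(seq_len(nrow(g)), seqs)) {
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      if (same_chromosome_only && g$chrom[i] != g$chrom[j]) next
      out <- rbind(out, data.frame(
        gene1 = min(g$gene_id[i], g$gene_id[j]),
        gene2 = max(g$gene_id[i], g$gene_id[j]),
        chrom1 = g$chrom[i], chrom2 = g$chrom[j],
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out[order(out$gene1, out$gene2), , drop = FALSE]
}
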