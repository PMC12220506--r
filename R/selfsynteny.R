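resolve_positions <- function(positions) {
  if (inherits(positions, "annotation_set")) positions <- positions$genes
  req <- c("gene_id", "chrom", "start", "end")
  if (!all(req %in% names(positions)))
    stop("positions must have columns: ", paste(req, collapse = ", "))
  positions
}

#' Reduce an all-vs-all self-alignment to gene-level paralog pairs
#'
#' Applies the four filtering steps used to turn a raw protein self-search
#' into countable paralog pairs: (1) sequence-level rows are collapsed to
#' directed gene pairs, keeping the best-scoring alignment per pair (by
#' bitscore by default, so isoform-level duplicates are not counted twice);
#' (2) self-pairs (query gene = target gene) are dropped; (3) the e-value
#' threshold is applied; (4) per query gene and target chromosome only the
#' best pair by e-value survives, so one gene contributes at most one pair
#' per target chromosome.  An e-value of exactly 0 is the most significant
#' possible value; ties are broken by higher bitscore, then lexicographic
#' target id.
#'
#' @param hits 13-column self-alignment table (see [read_hits_table()]).
#' @param positions gene positions: an [annotation_set()] or a data.frame
#'   with `gene_id`, `chrom`, `start`, `end`.
#' @param evalue_threshold keep pairs with `evalue <= evalue_threshold`.
#' @param seq_to_gene function mapping sequence ids to gene ids (default
#'   strips the `.p<k>` isoform suffix) or a named character vector.
#' @param best_by collapse step criterion: `"bitscore"` (default) or
#'   `"evalue"`.
#' @param per_chromosome_best apply step (4)?  Disable to keep every
#'   gene-level pair, e.g. when plotting a grid of all collapsed pairs; the
#'   contribution matrix should always be built with the step enabled, as
#'   otherwise gene-family expansions inflate chromosome-pair connections.
#' @return data.frame of paralog pairs: `query_gene`, `target_gene`,
#'   `evalue`, `bitscore`, `query_chrom`, `target_chrom`,
#'   `same_chromosome`.
#' @export
filter_self_hits <- function(hits, positions, evalue_threshold = 1e-5,
                             seq_to_gene = default_seq_to_gene,
                             best_by = c("bitscore", "evalue"),
                             per_chromosome_best = TRUE) {
  best_by <- match.arg(best_by)
  positions <- resolve_positions(positions)
  to_gene <- if (is.function(seq_to_gene)) seq_to_gene else
    function(ids) unname(seq_to_gene[ids])
  empty <- data.frame(query_gene = character(0), target_gene = character(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      query_chrom = character(0), target_chrom = character(0),
                      same_chromosome = logical(0), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  qg <- to_gene(hits$query)
  tg <- to_gene(hits$target)
  chrom_of <- stats::setNames(positions$chrom, positions$gene_id)
  unresolved <- unique(c(qg, tg)[is.na(c(qg, tg)) |
                                   !c(qg, tg) %in% positions$gene_id])
  if (length(unresolved))
    stop("sequence ids unresolvable to positioned genes: ",
         paste(utils::head(unresolved), collapse = ", "))
  d <- data.frame(query_gene = qg, target_gene = tg,
                  evalue = hits$evalue, bitscore = hits$bitscore,
                  stringsAsFactors = FALSE)
  # (1) best row per directed gene pair
  ord <- if (best_by == "bitscore")
    order(d$query_gene, d$target_gene, -d$bitscore, d$evalue) else
      order(d$query_gene, d$target_gene, d$evalue, -d$bitscore)
  d <- d[ord, , drop = FALSE]
  d <- d[!duplicated(d[, c("query_gene", "target_gene")]), , drop = FALSE]
  # (2) drop self-pairs
  d <- d[d$query_gene != d$target_gene, , drop = FALSE]
  # (3) e-value threshold
  d <- d[d$evalue <= evalue_threshold, , drop = FALSE]
  if (!nrow(d)) return(empty)
  d$query_chrom <- unname(chrom_of[d$query_gene])
  d$target_chrom <- unname(chrom_of[d$target_gene])
  # (4) per query gene and target chromosome, keep the best e-value
  if (per_chromosome_best) {
    ord <- order(d$query_gene, d$target_chrom, d$evalue, -d$bitscore,
                 d$target_gene)
    d <- d[ord, , drop = FALSE]
    d <- d[!duplicated(d[, c("query_gene", "target_chrom")]), , drop = FALSE]
  }
  d$same_chromosome <- d$query_chrom == d$target_chrom
  rownames(d) <- NULL
  d
}

#' Linearized genome coordinate of genes
#'
#' Places a gene on the single linear axis obtained by concatenating the
#' chromosomes in assembly order: the coordinate is the cumulative length of
#' all preceding chromosomes plus the midpoint between the gene start and
#' end positions.
#'
#' @param positions data.frame with `chrom`, `start`, `end` (or an
#'   [annotation_set()]).
#' @param layout an [assembly_layout()].
#' @return numeric vector of linear coordinates.
#' @export
linear_coordinate <- function(positions, layout) {
  if (inherits(positions, "annotation_set")) positions <- positions$genes
  stopifnot(inherits(layout, "assembly_layout"))
  k <- match(positions$chrom, layout$chrom)
  if (anyNA(k))
    stop("unknown chromosome(s): ",
         paste(utils::head(unique(positions$chrom[is.na(k)])), collapse = ", "))
  layout$offset[k] + (positions$start + positions$end) / 2
}

#' Build the self-synteny Oxford grid
#'
#' One point per paralog pair: the target gene's linear coordinate on the
#' x-axis, the query gene's on the y-axis, with a `same_chromosome` flag for
#' diagonal coloring.
#'
#' @param pairs output of [filter_self_hits()].
#' @param positions gene positions (see [filter_self_hits()]).
#' @param layout an [assembly_layout()].
#' @return data.frame with `x`, `y`, `query_gene`, `target_gene`,
#'   `same_chromosome`.
#' @export
build_oxford_grid <- function(pairs, positions, layout) {
  positions <- resolve_positions(positions)
  if (!nrow(pairs))
    return(data.frame(x = numeric(0), y = numeric(0),
                      query_gene = character(0), target_gene = character(0),
                      same_chromosome = logical(0), stringsAsFactors = FALSE))
  idx_q <- match(pairs$query_gene, positions$gene_id)
  idx_t <- match(pairs$target_gene, positions$gene_id)
  if (anyNA(idx_q) || anyNA(idx_t))
    stop("pairs reference genes absent from positions")
  data.frame(
    x = linear_coordinate(positions[idx_t, ], layout),
    y = linear_coordinate(positions[idx_q, ], layout),
    query_gene = pairs$query_gene,
    target_gene = pairs$target_gene,
    same_chromosome = pairs$same_chromosome,
    stringsAsFactors = FALSE
  )
}

#' Chromosome-pair paralog contribution matrix
#'
#' Summarizes the Oxford grid as a K x K percentage matrix.  In the default
#' `"caption"` mode, cell (x, y) is the percentage of genes on chromosome x
#' that have a surviving paralog pair to a gene on chromosome y, normalized
#' by the gene count of x; `"donor"` mode normalizes by the gene count of
#' the source chromosome y instead.  Cells count distinct genes, not pairs,
#' so a gene with one retained hit per target chromosome contributes at most
#' 1 to each cell; diagonal cells are computed the same way from
#' same-chromosome pairs.
#'
#' @param pairs output of [filter_self_hits()].
#' @param gene_counts named numeric vector: genes per chromosome, in
#'   assembly order; its names define the matrix dimensions.
#' @param mode normalization mode, `"caption"` (default) or `"donor"`.
#' @return K x K numeric matrix of percentages (class
#'   `contribution_matrix`, attribute `mode`).
#' @export
contribution_matrix <- function(pairs, gene_counts,
                                mode = c("caption", "donor")) {
  mode <- match.arg(mode)
  chroms <- names(gene_counts)
  if (is.null(chroms)) stop("gene_counts must be named by chromosome")
  K <- length(chroms)
  m <- matrix(0, K, K, dimnames = list(chroms, chroms))
  if (nrow(pairs)) {
    bad <- unique(c(pairs$query_chrom, pairs$target_chrom))
    bad <- bad[!bad %in% chroms | gene_counts[bad] <= 0]
    if (length(bad))
      stop("chromosomes with incident pairs but no positive gene count: ",
           paste(utils::head(bad), collapse = ", "))
    key <- paste(pairs$query_chrom, pairs$target_chrom)
    n_genes <- tapply(pairs$query_gene, key,
                      function(g) length(unique(g)))
    xy <- do.call(rbind, strsplit(names(n_genes), " "))
    denom <- if (mode == "caption") gene_counts[xy[, 1]] else
      gene_counts[xy[, 2]]
    m[cbind(match(xy[, 1], chroms), match(xy[, 2], chroms))] <-
      100 * as.numeric(n_genes) / as.numeric(denom)
  }
  structure(m, mode = mode, class = c("contribution_matrix", "matrix",
                                      "array"))
}

#' Summary statistics of a contribution matrix
#'
#' @param matrix a [contribution_matrix()] (K >= 2).
#' @return list with `offdiag_mean`, `offdiag_min`, `offdiag_max`,
#'   `diag_mean` and `contrast_ratio` (diagonal mean over off-diagonal
#'   mean; `Inf` when the off-diagonal mean is 0).
#' @export
summarize_contributions <- function(matrix) {
  if (nrow(matrix) != ncol(matrix)) stop("matrix must be square")
  if (nrow(matrix) < 2)
    stop("off-diagonal statistics undefined for a 1 x 1 matrix")
  off <- matrix[row(matrix) != col(matrix)]
  dg <- diag(matrix)
  off_mean <- mean(off)
  list(offdiag_mean = off_mean, offdiag_min = min(off),
       offdiag_max = max(off), diag_mean = mean(dg),
       contrast_ratio = if (off_mean == 0) Inf else mean(dg) / off_mean)
}

#' Per-chromosome paralog content across an e-value threshold sweep
#'
#' For each threshold, the fraction of genes on each chromosome with a
#' surviving cross-chromosome paralog pair.  Fractions are monotonically
#' non-increasing as the threshold gets stricter, because the surviving
#' pair set at a stricter threshold is a subset of the permissive set.
#'
#' @param hits 13-column self-alignment table.
#' @param positions gene positions (see [filter_self_hits()]).
#' @param gene_counts named numeric vector of genes per chromosome.
#' @param thresholds numeric vector of e-value thresholds (any order;
#'   reported from permissive to strict).
#' @param seq_to_gene sequence-to-gene mapping (see [filter_self_hits()]).
#' @return data.frame with `threshold`, `chrom`, `fraction`.
#' @export
paralog_content_distribution <- function(hits, positions, gene_counts,
                                         thresholds = c(1e-5, 1e-60),
                                         seq_to_gene = default_seq_to_gene) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  chroms <- names(gene_counts)
  out <- lapply(thresholds, function(th) {
    pairs <- filter_self_hits(hits, positions, evalue_threshold = th,
                              seq_to_gene = seq_to_gene)
    cross <- pairs[!pairs$same_chromosome, , drop = FALSE]
    n <- vapply(chroms, function(ch)
      length(unique(cross$query_gene[cross$query_chrom == ch])), numeric(1))
    data.frame(threshold = th, chrom = chroms,
               fraction = as.numeric(n) / as.numeric(gene_counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Score duplication signal in a contribution matrix
#'
#' Operationalizes the WGD expectation of strong off-diagonal signal
#' connecting duplicated chromosome pairs: for each chromosome, the best
#' off-diagonal partner (arg-max cell) is reported, with partners below
#' `min_cell` percent reported as none, and a greedy mutual-best matching is
#' assembled genome-wide (pairs ranked by cell value; each chromosome used
#' once).
#'
#' @param matrix a [contribution_matrix()] with K >= 2.
#' @param min_cell minimum off-diagonal percentage for a partner call
#'   (default 5).
#' @return list with `partners` (data.frame `chrom`, `partner`, `value`;
#'   `partner` is `NA` below `min_cell`) and `matching` (data.frame
#'   `chrom1`, `chrom2`, `value` of mutual-best calls).
#' @export
score_duplication_signal <- function(matrix, min_cell = 5) {
  if (nrow(matrix) != ncol(matrix) || nrow(matrix) < 2)
    stop("matrix must be square with K >= 2")
  chroms <- rownames(matrix)
  off <- matrix
  diag(off) <- -Inf
  best_j <- apply(off, 1, which.max)
  best_v <- off[cbind(seq_along(best_j), best_j)]
  partner <- ifelse(best_v >= min_cell, chroms[best_j], NA_character_)
  partners <- data.frame(chrom = chroms, partner = partner,
                         value = as.numeric(best_v),
                         stringsAsFactors = FALSE)
  mutual <- which(!is.na(partner) &
                    partner[match(partner, chroms)] == chroms)
  matching <- data.frame(chrom1 = character(0), chrom2 = character(0),
                         value = numeric(0), stringsAsFactors = FALSE)
  if (length(mutual)) {
    cand <- data.frame(chrom1 = chroms[mutual], chrom2 = partner[mutual],
                       value = best_v[mutual], stringsAsFactors = FALSE)
    cand <- cand[cand$chrom1 < cand$chrom2, , drop = FALSE]
    cand <- cand[order(-cand$value, cand$chrom1), , drop = FALSE]
    used <- character(0)
    for (i in seq_len(nrow(cand))) {
      if (cand$chrom1[i] %in% used || cand$chrom2[i] %in% used) next
      matching <- rbind(matching, cand[i, , drop = FALSE])
      used <- c(used, cand$chrom1[i], cand$chrom2[i])
    }
    rownames(matching) <- NULL
  }
  list(partners = partners, matching = matching)
}

#' Minimal Oxford grid plot
#'
#' Base-graphics dot plot of the grid points with chromosome boundary lines;
#' same-chromosome points are drawn in red, cross-chromosome points in grey.
#'
#' @param grid output of [build_oxford_grid()].
#' @param layout an [assembly_layout()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `grid`.
#' @export
plot_oxford_grid <- function(grid, layout, ...) {
  total <- sum(layout$length)
  graphics::plot(grid$x, grid$y, pch = 16, cex = 0.4,
                 col = ifelse(grid$same_chromosome, "red", "grey40"),
                 xlim = c(0, total), ylim = c(0, total),
                 xlab = "target position (bp)", ylab = "query position (bp)",
                 ...)
  bounds <- c(layout$offset, total)
  graphics::abline(v = bounds, h = bounds, col = "grey85", lwd = 0.5)
  invisible(grid)
}
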