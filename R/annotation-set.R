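#' Assembly layout: ordered chromosomes with lengths
#'
#' Builds the ordered-chromosome table that anchors every genome-wide
#' computation in the package.  Chromosome order is the assembly order and is
#' preserved everywhere; cumulative offsets place each chromosome on the
#' linearized genome axis used by the Oxford grid.
#'
#' @param chrom character vector of chromosome/scaffold names, in assembly
#'   order.
#' @param length integer vector of chromosome lengths in bases.
#' @return A `data.frame` of class `assembly_layout` with columns `chrom`,
#'   `length` and `offset`, where `offset[k]` is the sum of the lengths of
#'   all preceding chromosomes.
#' @examples
#' assembly_layout(c("chr1", "chr2"), c(100L, 50L))
#' @export
assembly_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length))
    stop("chrom and length must have equal length")
  if (anyDuplicated(chrom))
    stop("duplicate chromosome names in layout: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive and finite")
  out <- data.frame(
    chrom = chrom,
    length = length,
    offset = cumsum(c(0, length[-base::length(length)])),
    stringsAsFactors = FALSE
  )
  class(out) <- c("assembly_layout", "data.frame")
  out
}

#' @export
print.assembly_layout <- function(x, ...) {
  cat("<assembly_layout> ", nrow(x), " chromosomes, total ",
      format(sum(x$length), big.mark = ","), " bp\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more)\n", sep = "")
  invisible(x)
}

empty_exons <- function(n) {
  replicate(n, data.frame(start = numeric(0), end = numeric(0)),
            simplify = FALSE)
}

single_exons <- function(start, end) {
  Map(function(s, e) data.frame(start = s, end = e), start, end)
}

#' Gene annotation container
#'
#' The shared substrate of all analysis stages: an ordered chromosome layout
#' plus a table of gene records.  Coordinates are 1-based inclusive (the
#' GFF3 on-disk convention) throughout the package.
#'
#' @param layout an [assembly_layout()].
#' @param genes a `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (one of `"+"`/`"-"`) and optionally `source` (one of
#'   `iso`, `braker1`, `braker2`, `denovo`, `sim`), `family`, and a list
#'   column `exons` of per-gene `data.frame(start, end)` exon tables.  A
#'   missing `exons` column defaults to a single exon spanning the gene.
#' @return A list of class `annotation_set` with elements `layout` and
#'   `genes`.
#' @export
annotation_set <- function(layout, genes) {
  stopifnot(inherits(layout, "assembly_layout"))
  req <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols))
    stop("genes table lacks columns: ", paste(missing_cols, collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!nrow(genes)) {
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        strand = character(0), source = character(0),
                        stringsAsFactors = FALSE)
    genes$exons <- list()
  }
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids: ",
         paste(utils::head(unique(genes$gene_id[duplicated(genes$gene_id)])),
               collapse = ", "))
  bad_chrom <- setdiff(unique(genes$chrom), layout$chrom)
  if (length(bad_chrom))
    stop("genes on chromosomes absent from layout: ",
         paste(utils::head(bad_chrom), collapse = ", "))
  if (any(genes$start > genes$end))
    stop("gene with start > end")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' ('.' is not accepted by strand-gated operations)")
  if (is.null(genes$source)) genes$source <- rep("sim", nrow(genes))
  if (is.null(genes$exons))
    genes$exons <- single_exons(genes$start, genes$end)
  rownames(genes) <- NULL
  structure(list(layout = layout, genes = genes), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", nrow(x$genes), " genes on ", nrow(x$layout),
      " chromosomes\n", sep = "")
  src <- table(x$genes$source)
  if (length(src))
    cat("  sources: ",
        paste(names(src), as.integer(src), sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Number of genes in an annotation set
#' @param x an `annotation_set`.
#' @return integer gene count.
#' @export
n_genes <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  nrow(x$genes)
}

# GRanges view of the gene spans (used by all interval algebra internally).
genes_granges <- function(x) {
  g <- x$genes
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand,
    gene_id = g$gene_id
  )
}

# Flat exon table (one row per exon) for exon-level overlap tests.
exon_table <- function(genes) {
  if (!nrow(genes))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  n_ex <- vapply(genes$exons, nrow, integer(1))
  idx <- rep(seq_len(nrow(genes)), n_ex)
  ex <- do.call(rbind, genes$exons[n_ex > 0])
  data.frame(gene_id = genes$gene_id[idx], chrom = genes$chrom[idx],
             start = ex$start, end = ex$end, strand = genes$strand[idx],
             stringsAsFactors = FALSE)
}

# Interval intersection length for 1-based inclusive coordinates.
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}
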