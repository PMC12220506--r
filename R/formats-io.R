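HIT_COLUMNS <- c("query", "target", "fident", "alnlen", "mismatches",
                 "gapopens", "qstart", "qend", "tstart", "tend", "evalue",
                 "bitscore", "qlen")

#' Read a 13-column all-vs-all self-alignment table
#'
#' Tab-separated, no header; the columns hold, in order: query sequence
#' identifier, target sequence identifier, fraction of identical matches,
#' alignment length, mismatches, gap-open events, query start/end, target
#' start/end, e-value, bit score, and query sequence length.  Scientific
#' notation e-values are parsed exactly; rows with the wrong number of
#' fields are fatal, naming the offending row.
#'
#' @param path file path.
#' @param n_columns expected field count (default 13).
#' @return data.frame with typed columns named as above.
#' @export
read_hits_table <- function(path, n_columns = 13) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(nf != n_columns)
  if (length(bad))
    stop("row(s) with ", paste(unique(nf[bad]), collapse = "/"),
         " fields instead of ", n_columns, ": line ",
         paste(utils::head(bad), collapse = ", "))
  out <- utils::read.table(path, sep = "\t", quote = "",
                           col.names = HIT_COLUMNS,
                           colClasses = c("character", "character",
                                          rep("numeric", 11)),
                           stringsAsFactors = FALSE)
  int_cols <- c("alnlen", "mismatches", "gapopens", "qstart", "qend",
                "tstart", "tend", "qlen")
  out[int_cols] <- lapply(out[int_cols], as.integer)
  out
}

#' Write a self-alignment table
#' @param hits data.frame with the 13 standard columns.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_hits_table <- function(hits, path) {
  stopifnot(all(HIT_COLUMNS %in% names(hits)))
  out <- hits[HIT_COLUMNS]
  # full double precision so e-values round-trip exactly
  for (col in c("fident", "evalue", "bitscore"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a chromosome-length table
#'
#' Two tab-separated columns (name, length), FASTA-index style, in assembly
#' order.
#' @param path file path.
#' @return [read_layout()]: an [assembly_layout()].
#' @export
read_layout <- function(path) {
  d <- utils::read.table(path, sep = "\t", quote = "",
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"),
                         stringsAsFactors = FALSE)
  assembly_layout(d$chrom, d$length)
}

#' @rdname read_layout
#' @param layout an [assembly_layout()].
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "assembly_layout"))
  utils::write.table(layout[, c("chrom", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a taxonomic hit table
#'
#' Tab-separated with a header; requires `scaffold_id` and `hit_id` plus
#' either `is_metazoan` (logical) or `lineage` (string); an optional `score`
#' column is retained for reporting.
#' @param path file path.
#' @return data.frame of taxonomic hits.
#' @export
read_tax_hits <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("scaffold_id", "hit_id") %in% names(d)))
    stop("tax hit table needs scaffold_id and hit_id columns")
  if (!any(c("is_metazoan", "lineage") %in% names(d)))
    stop("tax hit table needs an is_metazoan or lineage column")
  d
}

#' @rdname read_tax_hits
#' @param hits data.frame of taxonomic hits.
#' @export
write_tax_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

annotation_to_granges <- function(annotation) {
  g <- annotation$genes
  lay <- annotation$layout
  gene_gr <- GenomicRanges::GRanges(
    seqnames = factor(g$chrom, levels = lay$chrom),
    ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand,
    type = "gene", ID = g$gene_id, Parent = NA_character_,
    gene_source = g$source
  )
  ex <- exon_table(g)
  ex_gr <- GenomicRanges::GRanges(
    seqnames = factor(ex$chrom, levels = lay$chrom),
    ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand,
    type = "exon",
    ID = paste0(ex$gene_id, ".exon",
                stats::ave(seq_len(nrow(ex)), ex$gene_id, FUN = seq_along)),
    Parent = ex$gene_id, gene_source = NA_character_
  )
  gr <- c(gene_gr, ex_gr)
  GenomeInfoDb::seqlengths(gr) <-
    stats::setNames(as.integer(ceiling(lay$length)), lay$chrom)
  gr
}

#' Write an annotation set as GFF3
#'
#' Genes become `gene` features carrying their source class in a
#' `gene_source` attribute; exons become `exon` children.  Chromosome
#' lengths are emitted as `##sequence-region` pragmas so the layout
#' round-trips.
#'
#' @param annotation an [annotation_set()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  gr <- annotation_to_granges(annotation)
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer does not emit sequence-region pragmas; add them so the
  # layout (lengths and order) survives the round trip
  lines <- readLines(path)
  pragmas <- sprintf("##sequence-region %s 1 %d",
                     annotation$layout$chrom,
                     as.integer(ceiling(annotation$layout$length)))
  writeLines(c(lines[1], pragmas, lines[-1]), path)
  invisible(path)
}

#' Read a GFF3 gene annotation
#'
#' Reads `gene` features (with optional `exon` children linked by `Parent`)
#' into an [annotation_set()].  The layout is taken from the
#' `##sequence-region` pragmas; when they are absent a `layout` must be
#' supplied.  Genes with strand `"."` are rejected, as all strand-gated
#' operations require an oriented gene.  Out-of-order exons are normalized
#' (sorted) with a warning.
#'
#' @param path GFF3 file path.
#' @param layout optional [assembly_layout()] overriding the pragmas.
#' @return an [annotation_set()].
#' @export
read_gff3 <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(layout)) {
    header <- grep("^##sequence-region",
                   readLines(path, n = 10000L), value = TRUE)
    if (!length(header))
      stop("GFF3 has no ##sequence-region pragmas; supply layout=")
    fields <- strsplit(trimws(header), "[ \t]+")
    layout <- assembly_layout(
      vapply(fields, `[`, character(1), 2),
      as.numeric(vapply(fields, `[`, character(1), 4)))
  }
  is_gene <- as.character(gr$type) == "gene"
  genes_gr <- gr[is_gene]
  if (!length(genes_gr))
    return(annotation_set(layout, data.frame(
      gene_id = character(0), chrom = character(0), start = numeric(0),
      end = numeric(0), strand = character(0))))
  strand <- as.character(GenomicRanges::strand(genes_gr))
  if (any(strand == "*"))
    stop("gene(s) with unknown strand '.': ",
         paste(utils::head(genes_gr$ID[strand == "*"]), collapse = ", "))
  src <- if (!is.null(genes_gr$gene_source)) genes_gr$gene_source else
    rep("sim", length(genes_gr))
  src[is.na(src)] <- "sim"
  genes <- data.frame(
    gene_id = genes_gr$ID,
    chrom = as.character(GenomicRanges::seqnames(genes_gr)),
    start = GenomicRanges::start(genes_gr),
    end = GenomicRanges::end(genes_gr),
    strand = strand, source = src, stringsAsFactors = FALSE
  )
  ex_gr <- gr[as.character(gr$type) == "exon"]
  exons <- stats::setNames(single_exons(genes$start, genes$end),
                           genes$gene_id)
  if (length(ex_gr)) {
    parent <- as.character(unlist(ex_gr$Parent))
    ex_df <- data.frame(parent = parent,
                        start = GenomicRanges::start(ex_gr),
                        end = GenomicRanges::end(ex_gr),
                        stringsAsFactors = FALSE)
    warned <- FALSE
    for (gid in unique(ex_df$parent)) {
      d <- ex_df[ex_df$parent == gid, c("start", "end")]
      if (is.unsorted(d$start)) warned <- TRUE
      d <- d[order(d$start), , drop = FALSE]
      rownames(d) <- NULL
      exons[[gid]] <- d
    }
    if (warned) warning("out-of-order exons normalized")
  }
  genes$exons <- exons[genes$gene_id]
  annotation_set(layout, genes)
}

#' Write a gene-model table (e.g. evidence models) as GFF3
#' @param models gene-model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `source`, optional `exons`).
#' @param layout an [assembly_layout()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_models_gff3 <- function(models, layout, path) {
  write_gff3(annotation_set(layout, models), path)
}
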