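# Shared fixture builders and independent oracles.

toy_layout <- function(n = 2, len = 1e5) {
  assembly_layout(paste0("chr", seq_len(n)), rep(len, n))
}

make_models <- function(ids, chrom, start, end, strand = "+",
                        source = "braker1", exons = NULL) {
  df <- data.frame(gene_id = ids, chrom = chrom, start = start, end = end,
                   strand = strand, source = source,
                   stringsAsFactors = FALSE)
  df$exons <- if (is.null(exons))
    Map(function(s, e) data.frame(start = s, end = e), df$start, df$end)
  else exons
  df
}

make_cluster <- function(id, chrom, strand, starts, ends) {
  cl <- data.frame(cluster_id = id, chrom = chrom, strand = strand,
                   stringsAsFactors = FALSE)
  cl$transcripts <- list(data.frame(start = starts, end = ends))
  cl
}

make_hit <- function(query, target, evalue, bitscore = 100,
                     fident = 0.5, plen = 100) {
  data.frame(query = query, target = target, fident = fident, alnlen = plen,
             mismatches = 0L, gapopens = 0L, qstart = 1L, qend = plen,
             tstart = 1L, tend = plen, evalue = evalue, bitscore = bitscore,
             qlen = plen, stringsAsFactors = FALSE)
}

# Exhaustive, loop-based re-implementation of the paralog-pair filter.
# Deliberately naive: used as the independent oracle for filter_self_hits.
brute_force_filter <- function(hits, positions, threshold,
                               per_chromosome_best = TRUE) {
  chrom_of <- stats::setNames(positions$chrom, positions$gene_id)
  qg <- default_seq_to_gene(hits$query)
  tg <- default_seq_to_gene(hits$target)
  # best row per directed gene pair by bitscore (tie: smaller e-value)
  best <- list()
  for (i in seq_len(nrow(hits))) {
    key <- paste(qg[i], tg[i])
    cur <- best[[key]]
    if (is.null(cur) || hits$bitscore[i] > cur$bitscore ||
        (hits$bitscore[i] == cur$bitscore && hits$evalue[i] < cur$evalue)) {
      best[[key]] <- list(q = qg[i], t = tg[i], evalue = hits$evalue[i],
                          bitscore = hits$bitscore[i])
    }
  }
  rows <- Filter(function(r) r$q != r$t && r$evalue <= threshold, best)
  if (per_chromosome_best) {
    kept <- list()
    for (r in rows) {
      key <- paste(r$q, chrom_of[r$t])
      cur <- kept[[key]]
      better <- is.null(cur) || r$evalue < cur$evalue ||
        (r$evalue == cur$evalue && r$bitscore > cur$bitscore) ||
        (r$evalue == cur$evalue && r$bitscore == cur$bitscore &&
           r$t < cur$t)
      if (better) kept[[key]] <- r
    }
    rows <- kept
  }
  if (!length(rows))
    return(data.frame(query_gene = character(0), target_gene = character(0)))
  out <- data.frame(
    query_gene = vapply(rows, `[[`, character(1), "q"),
    target_gene = vapply(rows, `[[`, character(1), "t"),
    evalue = vapply(rows, `[[`, numeric(1), "evalue"),
    stringsAsFactors = FALSE
  )
  out[order(out$query_gene, out$target_gene), , drop = FALSE]
}

random_hits_table <- function(seed, n_genes = 12, n_chrom = 3,
                              n_rows = 200) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  positions <- data.frame(
    gene_id = genes,
    chrom = paste0("chr", sample(seq_len(n_chrom), n_genes, replace = TRUE)),
    start = seq_len(n_genes) * 1000,
    end = seq_len(n_genes) * 1000 + 500,
    stringsAsFactors = FALSE
  )
  hits <- make_hit(
    query = paste0(sample(genes, n_rows, replace = TRUE), ".p",
                   sample(1:2, n_rows, replace = TRUE)),
    target = paste0(sample(genes, n_rows, replace = TRUE), ".p",
                    sample(1:2, n_rows, replace = TRUE)),
    evalue = 10^stats::runif(n_rows, -60, -2),
    bitscore = sample(40:400, n_rows, replace = TRUE)
  )
  list(hits = hits, positions = positions)
}

pair_key <- function(q, t) paste(q, t)

# Plant a named 10-member gene cluster into a fresh genome: one member
# deleted, one member in two copies, coordinates optionally reversed.
plant_cluster_fixture <- function(seed, reversed = FALSE) {
  set.seed(seed)
  members <- paste0("M", 1:10)
  deleted <- "M9"
  multi <- "M5"
  strand <- sample(c("+", "-"), 1)
  lay <- assembly_layout(c("chr1", "chr2"), c(1e6, 1e6))
  # member gene coordinates in expected order (or uniformly reversed)
  present <- setdiff(members, deleted)
  slots <- seq_along(present)
  starts <- 10000 + (slots - 1) * 20000 + sample(0:5000, length(slots))
  if (reversed) starts <- rev(starts)
  genes <- data.frame(
    gene_id = paste0("gene_", present), chrom = "chr1", start = starts,
    end = starts + 2000, strand = strand, source = "sim",
    stringsAsFactors = FALSE
  )
  # second copy of the multi-copy member, adjacent to the first
  first <- genes[genes$gene_id == paste0("gene_", multi), ]
  copy <- first
  copy$gene_id <- paste0("gene_", multi, "_b")
  copy$start <- first$end + 100
  copy$end <- copy$start + 2000
  # unrelated bystander genes on another chromosome
  other <- data.frame(
    gene_id = paste0("bg", 1:5), chrom = "chr2",
    start = seq(1e4, 5e4, length.out = 5),
    end = seq(1e4, 5e4, length.out = 5) + 1500,
    strand = "+", source = "sim", stringsAsFactors = FALSE
  )
  genes <- rbind(genes, copy, other)
  genes$exons <- Map(function(s, e) data.frame(start = s, end = e),
                     genes$start, genes$end)
  annot <- annotation_set(lay, genes)
  # strong hits at each member copy, plus sub-cutoff and unmappable noise
  mem_of_gene <- sub("_b$", "", sub("^gene_", "", genes$gene_id))
  is_member <- genes$gene_id %in% c(paste0("gene_", present),
                                    paste0("gene_", multi, "_b"))
  hits <- data.frame(
    member = mem_of_gene[is_member], chrom = genes$chrom[is_member],
    start = genes$start[is_member] + 10, end = genes$start[is_member] + 500,
    evalue = 10^stats::runif(sum(is_member), -60, -25),
    stringsAsFactors = FALSE
  )
  weak <- data.frame(member = "M1", chrom = "chr2", start = 12000,
                     end = 12400, evalue = 1e-12, stringsAsFactors = FALSE)
  intergenic <- data.frame(member = "M2", chrom = "chr2", start = 9e5,
                           end = 9e5 + 300, evalue = 1e-40,
                           stringsAsFactors = FALSE)
  list(annotation = annot, hits = rbind(hits, weak, intergenic),
       members = members, deleted = deleted, multi = multi,
       strand = strand, reversed = reversed)
}
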