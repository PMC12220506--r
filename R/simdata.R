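#' Simulation configuration
#'
#' Collects the free parameters of the synthetic genome/evidence simulator.
#' Defaults describe the standard screening scenario used throughout the
#' package's validation: 10 chromosomes of 1 Mb carrying 200 genes each,
#' half of all duplicates retained after a simulated whole-genome
#' duplication (WGD), and a 90% chance that a true paralog pair yields a
#' passing alignment hit.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of every chromosome, in bases.
#' @param n_genes_per_chromosome genes placed on each chromosome.
#' @param gene_length_range two-element vector, uniform sampling range of
#'   gene lengths in bases.
#' @param seed integer seed; identical configurations (including the seed)
#'   give byte-identical simulator output.
#' @param wgd_retention probability that a gene keeps its duplicate after a
#'   simulated WGD.
#' @param wgd_detectability probability that a true paralog pair yields a
#'   passing self-alignment hit.
#' @param tandem_rate probability per gene of seeding a tandem array.
#' @param tandem_max_copies maximum total copies in a tandem array (>= 2).
#' @param spurious_hit_rate expected spurious alignment hits per gene.
#' @param contaminant_fraction probability that a scaffold is a contaminant.
#' @param hits_per_scaffold taxonomic hits drawn per scaffold.
#' @param evidence_noise list with elements `p_cluster_cover`, `p_fusion`,
#'   `p_split`, `p_novel`; see [emit_annotation_evidence()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 10L,
                       chromosome_length = 1e6,
                       n_genes_per_chromosome = 200L,
                       gene_length_range = c(1000, 4000),
                       seed = 1L,
                       wgd_retention = 0.5,
                       wgd_detectability = 0.9,
                       tandem_rate = 0.2,
                       tandem_max_copies = 3L,
                       spurious_hit_rate = 0.05,
                       contaminant_fraction = 0.05,
                       hits_per_scaffold = 20L,
                       evidence_noise = list(p_cluster_cover = 1, p_fusion = 0,
                                             p_split = 0, p_novel = 0)) {
  probs <- c(wgd_retention = wgd_retention,
             wgd_detectability = wgd_detectability,
             tandem_rate = tandem_rate,
             contaminant_fraction = contaminant_fraction,
             unlist(evidence_noise))
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  counts <- c(n_chromosomes = n_chromosomes,
              chromosome_length = chromosome_length,
              n_genes_per_chromosome = n_genes_per_chromosome,
              hits_per_scaffold = hits_per_scaffold)
  if (any(counts <= 0)) stop("counts must be positive")
  if (tandem_max_copies < 2) stop("tandem_max_copies must be >= 2")
  if (length(gene_length_range) != 2 || gene_length_range[1] > gene_length_range[2]
      || gene_length_range[1] < 1)
    stop("gene_length_range must be an increasing pair of positive lengths")
  if (spurious_hit_rate < 0) stop("spurious_hit_rate must be non-negative")
  need <- c("p_cluster_cover", "p_fusion", "p_split", "p_novel")
  if (!all(need %in% names(evidence_noise)))
    stop("evidence_noise needs: ", paste(need, collapse = ", "))
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = chromosome_length,
    n_genes_per_chromosome = as.integer(n_genes_per_chromosome),
    gene_length_range = gene_length_range,
    seed = as.integer(seed),
    wgd_retention = wgd_retention,
    wgd_detectability = wgd_detectability,
    tandem_rate = tandem_rate,
    tandem_max_copies = as.integer(tandem_max_copies),
    spurious_hit_rate = spurious_hit_rate,
    contaminant_fraction = contaminant_fraction,
    hits_per_scaffold = as.integer(hits_per_scaffold),
    evidence_noise = evidence_noise[need]
  ), class = "sim_config")
}

empty_truth <- function() {
  structure(list(
    pairs = data.frame(gene1 = character(0), gene2 = character(0),
                       origin = character(0), stringsAsFactors = FALSE),
    gene_to_source = character(0),
    contaminant_scaffolds = character(0)
  ), class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table> ", nrow(x$pairs), " paralog pairs (",
      paste(names(table(x$pairs$origin)), as.integer(table(x$pairs$origin)),
            sep = "=", collapse = ", "),
      "); ", length(x$contaminant_scaffolds), " contaminant scaffolds\n",
      sep = "")
  invisible(x)
}

merge_truth <- function(a, b) {
  structure(list(
    pairs = rbind(a$pairs, b$pairs),
    gene_to_source = c(a$gene_to_source, b$gene_to_source),
    contaminant_scaffolds = union(a$contaminant_scaffolds,
                                  b$contaminant_scaffolds)
  ), class = "truth_table")
}

#' Simulate a base genome with non-overlapping genes
#'
#' Genes are packed left to right with randomly apportioned inter-gene gaps
#' (at least 1 bp between neighbours), each with a unique id, random strand,
#' and a unique family label.  The Mersenne-Twister generator is seeded once
#' per call, so identical configurations give identical genomes.
#'
#' @param config a [sim_config()].
#' @return An [annotation_set()] whose genes carry a `family` column.
#' @export
simulate_base_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  K <- config$n_chromosomes
  L <- config$chromosome_length
  n <- config$n_genes_per_chromosome
  rng <- config$gene_length_range
  chroms <- paste0("chr", seq_len(K))
  per_chrom <- vector("list", K)
  next_id <- 1L
  for (k in seq_len(K)) {
    len <- floor(stats::runif(n, rng[1], rng[2] + 1))
    extra <- L - sum(len) - (n - 1)
    if (extra < 0)
      stop("cannot place ", n, " genes of total length ", sum(len),
           " on a chromosome of length ", L, " without overlap")
    w <- stats::runif(n + 1)
    add <- floor(extra * w / sum(w))
    gap <- if (n > 1) c(add[1], 1 + add[2:n]) else add[1]  # >=1 bp between genes
    start <- cumsum(gap) + cumsum(c(0, len[-n])) + 1
    ids <- sprintf("g%05d", seq(next_id, next_id + n - 1L))
    next_id <- next_id + n
    per_chrom[[k]] <- data.frame(
      gene_id = ids, chrom = chroms[k],
      start = start, end = start + len - 1,
      strand = sample(c("+", "-"), n, replace = TRUE),
      source = "sim", family = paste0("fam_", ids),
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, per_chrom)
  genes$exons <- single_exons(genes$start, genes$end)
  annotation_set(assembly_layout(chroms, rep(L, K)), genes)
}

#' Apply a simulated whole-genome duplication
#'
#' Every chromosome `i` gains a homolog `i_B` of equal length, appended after
#' all original chromosomes in assembly order.  Each gene is copied onto the
#' homolog (at its original coordinates) independently with probability
#' `retention`; empty homolog chromosomes are kept.  All retained duplicates
#' are recorded as truth pairs with origin `"wgd"`.
#'
#' @param genome an [annotation_set()].
#' @param retention per-gene duplicate retention probability.
#' @param seed integer seed.
#' @return list with elements `genome` (duplicated annotation) and `truth`
#'   (a `truth_table`).
#' @export
apply_wgd <- function(genome, retention, seed) {
  stopifnot(inherits(genome, "annotation_set"))
  if (retention < 0 || retention > 1) stop("retention must be in [0, 1]")
  withr::local_seed(seed)
  lay <- genome$layout
  new_lay <- assembly_layout(c(lay$chrom, paste0(lay$chrom, "_B")),
                             c(lay$length, lay$length))
  g <- genome$genes
  keep <- stats::runif(nrow(g)) < retention
  dup <- g[keep, , drop = FALSE]
  truth <- empty_truth()
  if (nrow(dup)) {
    dup$chrom <- paste0(dup$chrom, "_B")
    new_ids <- paste0(dup$gene_id, "_w")
    truth$pairs <- data.frame(gene1 = dup$gene_id, gene2 = new_ids,
                              origin = "wgd", stringsAsFactors = FALSE)
    truth$gene_to_source <- stats::setNames(dup$gene_id, new_ids)
    dup$gene_id <- new_ids
  }
  out <- rbind(g, dup)
  rownames(out) <- NULL
  list(genome = annotation_set(new_lay, out), truth = truth)
}

#' Apply simulated tandem duplications
#'
#' Each gene independently seeds a tandem array with probability `rate`; the
#' array holds between 2 and `max_copies` total copies, placed immediately
#' adjacent to the source gene on the same chromosome and strand.  Inserted
#' copies shift all downstream genes rightwards and extend the chromosome,
#' so adjacency is always satisfiable.  Truth pairs connect every copy to
#' its source gene with origin `"tandem"`.
#'
#' @param genome an [annotation_set()].
#' @param rate per-gene array seeding probability.
#' @param max_copies maximum total copies per array (>= 2).
#' @param seed integer seed.
#' @return list with elements `genome` and `truth`.
#' @export
apply_tandem <- function(genome, rate, max_copies, seed) {
  stopifnot(inherits(genome, "annotation_set"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (max_copies < 2) stop("max_copies must be >= 2")
  withr::local_seed(seed)
  g <- genome$genes
  ord <- order(match(g$chrom, genome$layout$chrom), g$start)
  g <- g[ord, , drop = FALSE]
  seeds_array <- stats::runif(nrow(g)) < rate
  extra_n <- ifelse(seeds_array,
                    if (max_copies == 2) 1L
                    else sample(seq_len(max_copies - 1L), nrow(g), replace = TRUE),
                    0L)
  rows <- vector("list", nrow(g))
  pairs <- vector("list", nrow(g))
  added_by_chrom <- stats::setNames(numeric(nrow(genome$layout)),
                                    genome$layout$chrom)
  shift <- 0
  cur_chrom <- NA_character_
  for (i in seq_len(nrow(g))) {
    gi <- g[i, , drop = FALSE]
    if (!identical(gi$chrom, cur_chrom)) { shift <- 0; cur_chrom <- gi$chrom }
    len <- gi$end - gi$start + 1
    gi$start <- gi$start + shift
    gi$end <- gi$end + shift
    gi$exons <- list(data.frame(start = gi$start, end = gi$end))
    out_i <- gi
    if (extra_n[i] > 0) {
      for (j in seq_len(extra_n[i])) {
        cp <- gi
        cp$gene_id <- paste0(g$gene_id[i], "_t", j)
        cp$start <- gi$end + 1 + (j - 1) * len
        cp$end <- cp$start + len - 1
        cp$exons <- list(data.frame(start = cp$start, end = cp$end))
        out_i <- rbind(out_i, cp)
      }
      pairs[[i]] <- data.frame(
        gene1 = g$gene_id[i],
        gene2 = paste0(g$gene_id[i], "_t", seq_len(extra_n[i])),
        origin = "tandem", stringsAsFactors = FALSE
      )
      shift <- shift + extra_n[i] * len
      added_by_chrom[gi$chrom] <- added_by_chrom[gi$chrom] + extra_n[i] * len
    }
    rows[[i]] <- out_i
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  truth <- empty_truth()
  pair_df <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (!is.null(pair_df)) {
    truth$pairs <- pair_df
    truth$gene_to_source <- stats::setNames(pair_df$gene1, pair_df$gene2)
  }
  new_lay <- assembly_layout(genome$layout$chrom,
                             genome$layout$length +
                               added_by_chrom[genome$layout$chrom])
  list(genome = annotation_set(new_lay, out), truth = truth)
}

protein_length <- function(gene_len) pmax(50, round(gene_len / 3))

hit_row <- function(query, target, fident, plen, evalue, bitscore) {
  data.frame(query = query, target = target, fident = fident,
             alnlen = plen, mismatches = round(plen * (1 - fident)),
             gapopens = 0L, qstart = 1L, qend = plen, tstart = 1L,
             tend = plen, evalue = evalue, bitscore = bitscore,
             qlen = plen, stringsAsFactors = FALSE)
}

#' Emit a synthetic all-vs-all protein self-alignment table
#'
#' Stands in for an all-against-all protein search over the predicted
#' proteome.  Every gene receives a perfect self-hit (e-value 0).  Each
#' truth pair yields a reciprocal pair of strong hits (log10 e-value uniform
#' on \[-80, -20\]) with probability `detectability`; spurious hits between
#' random non-truth gene pairs carry weak e-values (log10 uniform on
#' \[-10, -4\]).  Some pairs additionally emit a second isoform-level row to
#' exercise downstream gene-level collapsing.  Sequence ids are
#' `<gene_id>.p<k>`; [default_seq_to_gene()] strips the suffix.
#'
#' @param genome an [annotation_set()].
#' @param truth a `truth_table` whose pairs reference genes in `genome`.
#' @param detectability probability a truth pair is recovered.
#' @param spurious_hit_rate expected spurious hits per gene.
#' @param seed integer seed.
#' @param isoform_rate probability that a recovered pair emits an extra
#'   isoform-level row.
#' @return A 13-column `data.frame` (query, target, fident, alnlen,
#'   mismatches, gapopens, qstart, qend, tstart, tend, evalue, bitscore,
#'   qlen).
#' @export
emit_self_hits <- function(genome, truth, detectability, spurious_hit_rate,
                           seed, isoform_rate = 0.25) {
  stopifnot(inherits(genome, "annotation_set"),
            inherits(truth, "truth_table"))
  if (detectability < 0 || detectability > 1)
    stop("detectability must be in [0, 1]")
  bad <- setdiff(c(truth$pairs$gene1, truth$pairs$gene2),
                 genome$genes$gene_id)
  if (length(bad))
    stop("truth pairs reference unknown genes: ",
         paste(utils::head(bad), collapse = ", "))
  withr::local_seed(seed)
  g <- genome$genes
  plen <- stats::setNames(protein_length(g$end - g$start + 1), g$gene_id)
  seqid <- function(gene, k = 1L) paste0(gene, ".p", k)

  rows <- list(
    hit_row(seqid(g$gene_id), seqid(g$gene_id), 1.0, unname(plen[g$gene_id]),
            0, 2 * unname(plen[g$gene_id]))
  )
  tp <- truth$pairs
  if (nrow(tp)) {
    det <- stats::runif(nrow(tp)) < detectability
    tp <- tp[det, , drop = FALSE]
    if (nrow(tp)) {
      log10e <- stats::runif(nrow(tp), -80, -20)
      fid <- stats::runif(nrow(tp), 0.4, 0.9)
      pl <- pmin(plen[tp$gene1], plen[tp$gene2])
      bits <- round(60 - 2 * log10e)
      rows <- c(rows, list(
        hit_row(seqid(tp$gene1), seqid(tp$gene2), fid, unname(pl),
                10^log10e, bits),
        hit_row(seqid(tp$gene2), seqid(tp$gene1), fid, unname(pl),
                10^log10e, bits)
      ))
      iso <- stats::runif(nrow(tp)) < isoform_rate
      if (any(iso)) {
        rows <- c(rows, list(
          hit_row(seqid(tp$gene1[iso], 2L), seqid(tp$gene2[iso], 1L),
                  fid[iso] * 0.95, unname(pl[iso]),
                  10^(log10e[iso] + 5), round(50 - 2 * log10e[iso]))
        ))
      }
    }
  }
  n_sp <- stats::rpois(1, spurious_hit_rate * nrow(g))
  if (n_sp > 0 && nrow(g) >= 2) {
    q <- sample(g$gene_id, n_sp, replace = TRUE)
    t <- sample(g$gene_id, n_sp, replace = TRUE)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    truth_keys <- key(truth$pairs$gene1, truth$pairs$gene2)
    ok <- q != t & !(key(q, t) %in% truth_keys)
    if (any(ok)) {
      log10e <- stats::runif(sum(ok), -10, -4)
      rows <- c(rows, list(
        hit_row(seqid(q[ok]), seqid(t[ok]), stats::runif(sum(ok), 0.2, 0.4),
                unname(pmin(plen[q[ok]], plen[t[ok]])), 10^log10e,
                round(30 - 2 * log10e))
      ))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default sequence-id to gene-id mapping
#'
#' Strips the isoform suffix (`.p<k>`) that [emit_self_hits()] attaches to
#' its sequence identifiers.
#' @param ids character vector of sequence ids.
#' @return character vector of gene ids.
#' @export
default_seq_to_gene <- function(ids) sub("\\.p[0-9]+$", "", ids)

#' Emit noisy annotation evidence for a simulated genome
#'
#' Produces the heterogeneous evidence that the reconciliation stage
#' consumes: full-length transcript clusters (one per covered gene, 1-5
#' transcripts jittered inside the gene), round-1 ab initio models (with
#' optional fusion of same-strand neighbours and splitting of single genes),
#' round-2 models and per-stage de novo transcript mappings for genes
#' withheld from round-1 evidence.
#'
#' @param genome an [annotation_set()].
#' @param noise list with probabilities `p_cluster_cover` (a gene gets a
#'   transcript cluster), `p_fusion` (a model fuses two same-strand
#'   neighbours), `p_split` (a model is split in two), `p_novel` (a gene is
#'   withheld from round-1 evidence and surfaces in round 2 or the de novo
#'   transcriptomes instead).
#' @param seed integer seed.
#' @return list with elements `clusters` (data.frame with list column
#'   `transcripts`), `models_r1`, `models_r2` (gene-model data.frames),
#'   `denovo_maps` (named list of per-stage gene-model data.frames; the
#'   anchor stage is `"instarIII"`), and `truth` (data.frame mapping
#'   evidence ids to source genes).
#' @export
emit_annotation_evidence <- function(genome, noise, seed) {
  stopifnot(inherits(genome, "annotation_set"))
  p <- noise
  need <- c("p_cluster_cover", "p_fusion", "p_split", "p_novel")
  if (!all(need %in% names(p)))
    stop("noise needs: ", paste(need, collapse = ", "))
  if (any(unlist(p[need]) < 0 | unlist(p[need]) > 1))
    stop("noise probabilities must be in [0, 1]")
  withr::local_seed(seed)

  g <- genome$genes
  ord <- order(match(g$chrom, genome$layout$chrom), g$start)
  g <- g[ord, , drop = FALSE]
  n <- nrow(g)

  withheld <- stats::runif(n) < p$p_novel
  to_r2 <- withheld & stats::runif(n) < 0.5
  to_denovo <- withheld & !to_r2
  covered <- !withheld & stats::runif(n) < p$p_cluster_cover

  truth <- list()
  model_row <- function(id, chrom, start, end, strand, source,
                        exons = list(data.frame(start = start, end = end))) {
    df <- data.frame(gene_id = id, chrom = chrom, start = start, end = end,
                     strand = strand, source = source,
                     stringsAsFactors = FALSE)
    df$exons <- exons
    df
  }

  # Transcript clusters
  clusters <- vector("list", n)
  pb <- 0L
  for (i in which(covered)) {
    pb <- pb + 1L
    len <- g$end[i] - g$start[i] + 1
    ntr <- sample(1:5, 1)
    jit_s <- floor(stats::runif(ntr, 0, 0.1 * len))
    jit_e <- floor(stats::runif(ntr, 0, 0.1 * len))
    ts <- pmin(g$start[i] + jit_s, g$end[i] - 1)
    te <- pmax(g$end[i] - jit_e, ts + 1)
    cl <- data.frame(cluster_id = paste0("PB.", pb), chrom = g$chrom[i],
                     strand = g$strand[i], stringsAsFactors = FALSE)
    cl$transcripts <- list(data.frame(start = ts, end = te))
    clusters[[i]] <- cl
    truth[[length(truth) + 1L]] <- data.frame(
      evidence_id = paste0("PB.", pb), kind = "cluster",
      gene_id = g$gene_id[i], stringsAsFactors = FALSE)
  }
  clusters <- do.call(rbind, clusters[!vapply(clusters, is.null, logical(1))])
  if (is.null(clusters)) {
    clusters <- data.frame(cluster_id = character(0), chrom = character(0),
                           strand = character(0), stringsAsFactors = FALSE)
    clusters$transcripts <- list()
  }

  # Round-1 ab initio models: walk genes in order; fuse, split, or copy.
  models_r1 <- list()
  gnum <- 0L
  i <- 1L
  while (i <= n) {
    if (withheld[i]) { i <- i + 1L; next }
    fuse_ok <- i < n && !withheld[i + 1L] &&
      g$chrom[i + 1L] == g$chrom[i] && g$strand[i + 1L] == g$strand[i]
    u <- stats::runif(1)
    if (fuse_ok && u < p$p_fusion) {
      gnum <- gnum + 1L
      id <- paste0("g", gnum)
      models_r1[[length(models_r1) + 1L]] <- model_row(
        id, g$chrom[i], g$start[i], g$end[i + 1L], g$strand[i], "braker1",
        exons = list(data.frame(start = c(g$start[i], g$start[i + 1L]),
                                end = c(g$end[i], g$end[i + 1L]))))
      truth[[length(truth) + 1L]] <- data.frame(
        evidence_id = id, kind = "fused_model",
        gene_id = paste(g$gene_id[i], g$gene_id[i + 1L], sep = ","),
        stringsAsFactors = FALSE)
      i <- i + 2L
      next
    }
    if (stats::runif(1) < p$p_split) {
      mid <- floor((g$start[i] + g$end[i]) / 2)
      for (part in 1:2) {
        gnum <- gnum + 1L
        id <- paste0("g", gnum)
        s <- if (part == 1) g$start[i] else mid + 2
        e <- if (part == 1) mid else g$end[i]
        models_r1[[length(models_r1) + 1L]] <- model_row(
          id, g$chrom[i], s, e, g$strand[i], "braker1")
        truth[[length(truth) + 1L]] <- data.frame(
          evidence_id = id, kind = "split_model", gene_id = g$gene_id[i],
          stringsAsFactors = FALSE)
      }
    } else {
      gnum <- gnum + 1L
      id <- paste0("g", gnum)
      models_r1[[length(models_r1) + 1L]] <- model_row(
        id, g$chrom[i], g$start[i], g$end[i], g$strand[i], "braker1")
      truth[[length(truth) + 1L]] <- data.frame(
        evidence_id = id, kind = "model", gene_id = g$gene_id[i],
        stringsAsFactors = FALSE)
    }
    i <- i + 1L
  }
  models_r1 <- if (length(models_r1)) do.call(rbind, models_r1) else
    model_row(character(0), character(0), numeric(0), numeric(0),
              character(0), character(0), exons = list())[0, ]

  # Round-2 models and per-stage de novo mappings for withheld genes.
  models_r2 <- list()
  for (i in which(to_r2)) {
    gnum <- gnum + 1L
    id <- paste0("g", gnum)
    models_r2[[length(models_r2) + 1L]] <- model_row(
      id, g$chrom[i], g$start[i], g$end[i], g$strand[i], "braker2")
    truth[[length(truth) + 1L]] <- data.frame(
      evidence_id = id, kind = "r2_model", gene_id = g$gene_id[i],
      stringsAsFactors = FALSE)
  }
  models_r2 <- if (length(models_r2)) do.call(rbind, models_r2) else
    models_r1[0, ]

  stages <- c("instarII", "instarIII", "instarV")
  denovo_maps <- stats::setNames(vector("list", length(stages)), stages)
  dn <- 0L
  for (st in stages) denovo_maps[[st]] <- list()
  for (i in which(to_denovo)) {
    dn <- dn + 1L
    for (st in stages) {
      id <- paste0("DN", dn, "_", st)
      denovo_maps[[st]][[length(denovo_maps[[st]]) + 1L]] <- model_row(
        id, g$chrom[i], g$start[i], g$end[i], g$strand[i], "denovo")
    }
    truth[[length(truth) + 1L]] <- data.frame(
      evidence_id = paste0("DN", dn), kind = "denovo", gene_id = g$gene_id[i],
      stringsAsFactors = FALSE)
  }
  for (st in stages) {
    denovo_maps[[st]] <- if (length(denovo_maps[[st]]))
      do.call(rbind, denovo_maps[[st]]) else models_r1[0, ]
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(evidence_id = character(0), kind = character(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  rownames(models_r1) <- rownames(models_r2) <- rownames(truth) <- NULL
  list(clusters = clusters, models_r1 = models_r1, models_r2 = models_r2,
       denovo_maps = denovo_maps, truth = truth)
}

#' Emit synthetic per-scaffold taxonomic hit tables
#'
#' Each scaffold is labelled a contaminant with probability
#' `contaminant_fraction`; its hits are then metazoan with probability
#' `metazoan_fraction_contam` (contaminants) or `metazoan_fraction_clean`
#' (clean scaffolds).
#'
#' @param genome an [annotation_set()] (scaffolds are its chromosomes).
#' @param contaminant_fraction per-scaffold contamination probability.
#' @param hits_per_scaffold hits drawn per scaffold.
#' @param metazoan_fraction_clean,metazoan_fraction_contam per-hit metazoan
#'   probabilities for clean/contaminant scaffolds.
#' @param seed integer seed.
#' @return list with `hits` (data.frame: scaffold_id, hit_id, is_metazoan,
#'   score) and `truth` (a `truth_table` with `contaminant_scaffolds` set).
#' @export
emit_tax_hits <- function(genome, contaminant_fraction, hits_per_scaffold,
                          metazoan_fraction_clean = 0.95,
                          metazoan_fraction_contam = 0.5, seed) {
  stopifnot(inherits(genome, "annotation_set"))
  fr <- c(contaminant_fraction, metazoan_fraction_clean,
          metazoan_fraction_contam)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  withr::local_seed(seed)
  scaff <- genome$layout$chrom
  contam <- stats::runif(length(scaff)) < contaminant_fraction
  p_met <- ifelse(contam, metazoan_fraction_contam, metazoan_fraction_clean)
  hits <- do.call(rbind, lapply(seq_along(scaff), function(i) {
    data.frame(
      scaffold_id = scaff[i],
      hit_id = paste0(scaff[i], "_hit", seq_len(hits_per_scaffold)),
      is_metazoan = stats::runif(hits_per_scaffold) < p_met[i],
      score = round(stats::runif(hits_per_scaffold, 50, 500)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(hits) <- NULL
  truth <- empty_truth()
  truth$contaminant_scaffolds <- scaff[contam]
  list(hits = hits, truth = truth)
}

#' Emit synthetic read repeat-annotation profiles
#'
#' @param n_reads number of reads.
#' @param repeat_fraction_sampler function of `n` returning repeat-masked
#'   fractions in \[0, 1\] (default uniform).
#' @param seed integer seed.
#' @param read_length_range uniform sampling range of read lengths.
#' @return data.frame with `read_id`, `read_length`, `repeat_bases`,
#'   `repeat_fraction` (`repeat_bases / read_length`).
#' @export
emit_read_repeat_profiles <- function(n_reads,
                                      repeat_fraction_sampler = stats::runif,
                                      seed,
                                      read_length_range = c(1000, 20000)) {
  if (n_reads <= 0) stop("n_reads must be positive")
  withr::local_seed(seed)
  len <- floor(stats::runif(n_reads, read_length_range[1],
                            read_length_range[2] + 1))
  frac <- repeat_fraction_sampler(n_reads)
  if (any(frac < 0 | frac > 1))
    stop("repeat_fraction_sampler returned fractions outside [0, 1]")
  rb <- round(frac * len)
  data.frame(read_id = paste0("read", seq_len(n_reads)),
             read_length = len, repeat_bases = rb,
             repeat_fraction = rb / len, stringsAsFactors = FALSE)
}
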