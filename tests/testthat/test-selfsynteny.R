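toy_positions <- function() {
  data.frame(
    gene_id = c("g1", "t1", "t2", "u1"),
    chrom = c("chr1", "chr2", "chr2", "chr1"),
    start = c(10, 10, 500, 900),
    end = c(20, 20, 600, 1000),
    stringsAsFactors = FALSE
  )
}

test_that("self-hit filtering applies the four reduction steps", {
  pos <- toy_positions()
  # a table of nothing but self-hits filters to nothing
  selfed <- make_hit(paste0(pos$gene_id, ".p1"), paste0(pos$gene_id, ".p2"),
                     evalue = 0, bitscore = 500)
  expect_equal(nrow(filter_self_hits(selfed, pos)), 0)

  # two isoform rows for one pair: the higher bitscore survives
  dup <- rbind(make_hit("g1.p1", "t1.p1", 1e-30, bitscore = 100),
               make_hit("g1.p2", "t1.p1", 1e-28, bitscore = 80))
  out <- filter_self_hits(dup, pos)
  expect_equal(nrow(out), 1)
  expect_equal(out$bitscore, 100)

  # per query gene and target chromosome only the best e-value survives
  two_on_chr2 <- rbind(make_hit("g1.p1", "t1.p1", 1e-30),
                       make_hit("g1.p1", "t2.p1", 1e-10))
  out2 <- filter_self_hits(two_on_chr2, pos)
  expect_equal(out2$target_gene, "t1")
  out2b <- filter_self_hits(two_on_chr2, pos, per_chromosome_best = FALSE)
  expect_equal(nrow(out2b), 2)

  # unresolvable sequence ids name the offenders
  expect_error(filter_self_hits(make_hit("nope.p1", "t1.p1", 1e-30), pos),
               "nope")
})

test_that("filtering agrees with the brute-force oracle on random tables", {
  for (s in 1:100) {
    tbl <- random_hits_table(s)
    for (th in c(1e-5, 1e-30)) {
      fast <- filter_self_hits(tbl$hits, tbl$positions,
                               evalue_threshold = th)
      slow <- brute_force_filter(tbl$hits, tbl$positions, th)
      fast <- fast[order(fast$query_gene, fast$target_gene), ]
      expect_equal(unname(fast$query_gene), unname(slow$query_gene))
      expect_equal(unname(fast$target_gene), unname(slow$target_gene))
      expect_equal(unname(fast$evalue), unname(slow$evalue))
    }
  }
})

test_that("stricter thresholds give subsets, and fractions never increase", {
  tbl <- random_hits_table(424, n_genes = 20, n_rows = 400)
  thresholds <- c(1e-3, 1e-10, 1e-30, 1e-50)
  pairs <- lapply(thresholds, function(th)
    filter_self_hits(tbl$hits, tbl$positions, evalue_threshold = th))
  for (i in seq_along(pairs)[-1]) {
    expect_true(all(
      pair_key(pairs[[i]]$query_gene, pairs[[i]]$target_gene) %in%
        pair_key(pairs[[i - 1]]$query_gene, pairs[[i - 1]]$target_gene)))
  }
  counts <- table(factor(tbl$positions$chrom,
                         levels = unique(tbl$positions$chrom)))
  dist <- paralog_content_distribution(
    tbl$hits, tbl$positions, stats::setNames(as.numeric(counts),
                                             names(counts)),
    thresholds = thresholds)
  for (ch in names(counts)) {
    fr <- dist$fraction[dist$chrom == ch]
    expect_true(all(diff(fr) <= 0))   # permissive -> strict ordering
  }
})

test_that("linear coordinates follow the cumulative-offset equation", {
  lay <- assembly_layout(c("c1", "c2", "c3"), c(100, 50, 80))
  pos <- data.frame(chrom = c("c1", "c2", "c3"),
                    start = c(10, 10, 0), end = c(20, 20, 30))
  expect_equal(linear_coordinate(pos, lay), c(15, 115, 165))
  expect_error(
    linear_coordinate(data.frame(chrom = "cX", start = 1, end = 2), lay),
    "unknown chromosome")
})

test_that("grid points compose pair coordinates and respect the extent", {
  lay <- assembly_layout(c("chr1", "chr2"), c(100, 1000))
  pos <- data.frame(gene_id = c("a", "b"), chrom = c("chr1", "chr2"),
                    start = c(10, 10), end = c(20, 20),
                    stringsAsFactors = FALSE)
  pairs <- data.frame(query_gene = "a", target_gene = "b", evalue = 1e-30,
                      bitscore = 100, query_chrom = "chr1",
                      target_chrom = "chr2", same_chromosome = FALSE,
                      stringsAsFactors = FALSE)
  grid <- build_oxford_grid(pairs, pos, lay)
  expect_equal(grid$x, 115)
  expect_equal(grid$y, 15)
  expect_equal(nrow(build_oxford_grid(pairs[0, ], pos, lay)), 0)

  # bijection and extent on a simulated screen
  g <- simulate_base_genome(sim_config(n_chromosomes = 3,
                                       n_genes_per_chromosome = 40,
                                       seed = 14))
  w <- apply_wgd(g, 0.5, 3)
  hits <- emit_self_hits(w$genome, w$truth, 0.9, 0.2, 4)
  p <- filter_self_hits(hits, w$genome, 1e-5)
  gr <- build_oxford_grid(p, w$genome, w$genome$layout)
  expect_equal(nrow(gr), nrow(p))
  total <- sum(w$genome$layout$length)
  expect_true(all(gr$x > 0 & gr$x < total & gr$y > 0 & gr$y < total))
})

test_that("a symmetric hit table yields an exactly symmetric grid", {
  tbl <- random_hits_table(77, n_genes = 10, n_rows = 150)
  hits <- tbl$hits
  mirrored <- hits
  mirrored$query <- hits$target
  mirrored$target <- hits$query
  sym <- rbind(hits, mirrored)
  pairs <- filter_self_hits(sym, tbl$positions, 1e-5,
                            per_chromosome_best = FALSE)
  keys <- pair_key(pairs$query_gene, pairs$target_gene)
  rev_keys <- pair_key(pairs$target_gene, pairs$query_gene)
  expect_setequal(keys, rev_keys)
})

test_that("contribution cells count distinct genes over the donor pool", {
  counts <- c(chrA = 10, chrB = 5)
  expect_true(all(contribution_matrix(
    data.frame(query_gene = character(0), target_gene = character(0),
               evalue = numeric(0), bitscore = numeric(0),
               query_chrom = character(0), target_chrom = character(0),
               same_chromosome = logical(0)), counts) == 0))

  pairs <- data.frame(
    query_gene = c("a1", "a2"), target_gene = c("b1", "b2"),
    evalue = 1e-30, bitscore = 100,
    query_chrom = "chrA", target_chrom = "chrB",
    same_chromosome = FALSE, stringsAsFactors = FALSE
  )
  m <- contribution_matrix(pairs, counts)
  expect_equal(m["chrA", "chrB"], 20)   # 2 of 10 genes
  expect_equal(m["chrB", "chrA"], 0)
  # donor mode normalizes by the source chromosome instead
  md <- contribution_matrix(pairs, counts, mode = "donor")
  expect_equal(md["chrA", "chrB"], 40)  # 2 of 5 genes on the donor

  expect_error(contribution_matrix(pairs, c(chrA = 10, chrB = 0)),
               "gene count")
})

test_that("contribution summaries handle degenerate shapes", {
  m <- matrix(0, 3, 3, dimnames = list(paste0("c", 1:3), paste0("c", 1:3)))
  diag(m) <- 40
  s <- summarize_contributions(m)
  expect_equal(s$offdiag_mean, 0)
  expect_equal(s$contrast_ratio, Inf)

  flat <- matrix(2, 3, 3)
  s2 <- summarize_contributions(flat)
  expect_equal(s2$offdiag_mean, 2)
  expect_equal(s2$offdiag_min, 2)
  expect_equal(s2$offdiag_max, 2)
  expect_equal(s2$contrast_ratio, 1)

  expect_error(summarize_contributions(matrix(1, 1, 1)), "1 x 1")
})

test_that("single-chromosome genomes have zero cross-chromosome content", {
  g <- simulate_base_genome(sim_config(n_chromosomes = 1,
                                       n_genes_per_chromosome = 30,
                                       seed = 5))
  t1 <- apply_tandem(g, 0.3, 2, 6)
  hits <- emit_self_hits(t1$genome, t1$truth, 1, 0, 7)
  counts <- stats::setNames(nrow(t1$genome$genes), t1$genome$layout$chrom)
  dist <- paralog_content_distribution(hits, t1$genome, counts,
                                       thresholds = c(1e-5, 1e-60))
  expect_true(all(dist$fraction == 0))
})

test_that("duplication scoring recovers structure and ignores noise floors", {
  # block-structured matrix from a noise-free WGD simulation
  g <- simulate_base_genome(sim_config(n_chromosomes = 4,
                                       n_genes_per_chromosome = 50,
                                       seed = 31))
  w <- apply_wgd(g, 1, 32)
  hits <- emit_self_hits(w$genome, w$truth, 1, 0, 33)
  pairs <- filter_self_hits(hits, w$genome, 1e-5)
  counts <- table(factor(w$genome$genes$chrom,
                         levels = w$genome$layout$chrom))
  m <- contribution_matrix(pairs, stats::setNames(as.numeric(counts),
                                                  names(counts)))
  sig <- score_duplication_signal(m, 5)
  expect_equal(nrow(sig$matching), 4)
  for (k in seq_len(nrow(sig$matching)))
    expect_equal(sig$matching$chrom2[k],
                 paste0(sig$matching$chrom1[k], "_B"))

  # diagonal-only matrix yields no partner calls
  diag_only <- matrix(0, 3, 3, dimnames = list(paste0("c", 1:3),
                                               paste0("c", 1:3)))
  diag(diag_only) <- 30
  sig2 <- score_duplication_signal(diag_only, 5)
  expect_true(all(is.na(sig2$partners$partner)))
  expect_equal(nrow(sig2$matching), 0)
})
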