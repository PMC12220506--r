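hox_fixture <- function(missing_member = "Hox9", strand = "-") {
  lay <- assembly_layout(c("chr56", "chr3"), c(2e6, 1e6))
  members <- setdiff(paste0("Hox", 1:10), missing_member)
  starts <- 100000 + (seq_along(members) - 1) * 120000
  genes <- make_models(paste0("hx_", members), "chr56", starts,
                       starts + 5000, strand = strand)
  bystander <- make_models("bg1", "chr3", 1000, 2000)
  annot <- annotation_set(lay, rbind(genes, bystander))
  hits <- data.frame(member = members, chrom = "chr56",
                     start = starts + 100, end = starts + 600,
                     evalue = 1e-30, stringsAsFactors = FALSE)
  list(annotation = annot, hits = hits, members = members, starts = starts)
}

test_that("member hits map to overlapping gene models with two-pass cutoffs", {
  fx <- hox_fixture()
  asg <- assign_members_from_hits(fx$hits, fx$annotation)
  expect_equal(nrow(asg), 9)
  expect_true(all(asg$gene_id == paste0("hx_", asg$member)))

  # a 1e-15 hit is discarded at the strict cutoff, retained at the relaxed
  weak <- data.frame(member = "NK7", chrom = "chr3", start = 1100,
                     end = 1500, evalue = 1e-15, stringsAsFactors = FALSE)
  strict <- assign_members_from_hits(weak, fx$annotation, 1e-20)
  expect_equal(nrow(strict), 0)
  relaxed <- assign_members_from_hits(weak, fx$annotation, 1e-10)
  expect_equal(relaxed$gene_id, "bg1")

  # hits overlapping no gene model are recorded as unmapped, not fatal
  stray <- data.frame(member = "Hox1", chrom = "chr3", start = 9e5,
                      end = 9e5 + 100, evalue = 1e-40,
                      stringsAsFactors = FALSE)
  asg2 <- assign_members_from_hits(rbind(fx$hits, stray), fx$annotation)
  expect_equal(nrow(asg2), 9)
  expect_equal(nrow(attr(asg2, "unmapped")), 1)

  # per member and gene, only the best e-value survives
  dup <- rbind(fx$hits[1, ], transform(fx$hits[1, ], evalue = 1e-50))
  asg3 <- assign_members_from_hits(dup, fx$annotation)
  expect_equal(nrow(asg3), 1)
  expect_equal(asg3$evalue, 1e-50)
})

test_that("an intact cluster missing one member is assessed correctly", {
  fx <- hox_fixture()
  asg <- assign_members_from_hits(fx$hits, fx$annotation)
  rep <- assess_cluster(asg, hox_cluster())
  expect_equal(rep$missing, "Hox9")
  expect_true(rep$single_chromosome)
  expect_true(rep$ordered)
  expect_equal(rep$breakpoints, 0L)
  expect_true(rep$strand_uniform)
  expect_equal(rep$span, max(fx$starts) + 5000 - min(fx$starts))

  # all ten members present leaves nothing missing
  fx10 <- hox_fixture(missing_member = character(0))
  asg10 <- assign_members_from_hits(fx10$hits, fx10$annotation)
  expect_length(assess_cluster(asg10, hox_cluster())$missing, 0)

  # a uniformly reversed cluster still counts as ordered
  fxr <- hox_fixture()
  fxr$hits$start <- rev(fxr$hits$start)
  fxr$hits$end <- rev(fxr$hits$end)
  asgr <- assign_members_from_hits(fxr$hits, fxr$annotation)
  expect_true(assess_cluster(asgr, hox_cluster())$ordered)
})

test_that("the ordered flag agrees with a brute-force permutation check", {
  set.seed(23)
  members <- paste0("M", 1:8)
  expected <- expected_cluster("toy", members)
  for (i in 1:30) {
    perm <- sample(8)
    starts <- 1000 + perm * 10000
    asg <- data.frame(member = members, gene_id = paste0("g", 1:8),
                      chrom = "chr1", start = starts, end = starts + 500,
                      strand = "+", evalue = 1e-30, stringsAsFactors = FALSE)
    rep <- assess_cluster(asg, expected)
    # brute force: member sequence along coordinates vs both orientations
    seq_along_coord <- members[order(starts)]
    brute <- identical(seq_along_coord, members) ||
      identical(seq_along_coord, rev(members))
    expect_identical(rep$ordered, brute)
  }
})

test_that("syntenic blocks partition the assignment by chromosome", {
  # mirrors a fragmented NK-type cluster: one large block, two small ones,
  # a tandem-expanded member, and dispersed singletons
  asg <- data.frame(
    member = c("NK5", "NK1", "Hhex", "Msx", "Msx", "Msx", "Msx",
               "NK3", "NK4", "Tlx", "Emx", "Emx", "Lbx", "NK7",
               "NK6", "Noto"),
    gene_id = paste0("g", 1:16),
    chrom = c(rep("chr6", 7), rep("chr48", 3), rep("chr16", 2),
              rep("chr38", 2), "chr2", "chr11"),
    start = c(seq(1e4, 7e4, by = 1e4), seq(1e4, 3e4, by = 1e4),
              c(1e4, 2e4), c(1e4, 2e4), 1e4, 1e4),
    stringsAsFactors = FALSE
  )
  asg$end <- asg$start + 1000
  asg$strand <- "+"
  asg$evalue <- 1e-30
  blocks <- detect_syntenic_blocks(asg)
  expect_equal(nrow(blocks), 6)
  expect_equal(blocks$member_string[blocks$chrom == "chr6"],
               "NK5,NK1,Hhex,Msx,Msx,Msx,Msx")
  expect_equal(blocks$member_string[blocks$chrom == "chr48"], "NK3,NK4,Tlx")
  expect_equal(blocks$member_string[blocks$chrom == "chr16"], "Emx,Emx")
  expect_equal(blocks$member_string[blocks$chrom == "chr38"], "Lbx,NK7")
  # partition: every assigned copy appears in exactly one block
  expect_equal(sum(blocks$n_genes), nrow(asg))

  # members on all-different chromosomes form only size-1 blocks
  sine <- data.frame(member = c("Six1/2", "Six3/6", "Six4/5"),
                     gene_id = paste0("s", 1:3),
                     chrom = c("chr13", "chr3", "chr56"),
                     start = 1e4, end = 1.1e4, strand = "+", evalue = 1e-30,
                     stringsAsFactors = FALSE)
  expect_true(all(detect_syntenic_blocks(sine)$n_genes == 1))

  empty <- sine[0, ]
  expect_equal(nrow(detect_syntenic_blocks(empty)), 0)
})

test_that("intervening gene models inside the cluster span are reported", {
  fx <- hox_fixture()
  # plant an extra model between Hox3 and Hox4 (the Dfd position)
  extra_start <- fx$starts[3] + 60000
  extra <- make_models("r2_g3735", "chr56", extra_start, extra_start + 2000)
  outside <- make_models("far", "chr56", 1.9e6, 1.9e6 + 1000)
  genes <- rbind(fx$annotation$genes, extra, outside)
  annot <- annotation_set(fx$annotation$layout, genes)
  asg <- assign_members_from_hits(fx$hits, annot)
  rep <- assess_cluster(asg, hox_cluster())
  intervening <- find_intervening_models(annot, rep)
  expect_equal(intervening$gene_id, "r2_g3735")
  expect_equal(intervening$left_member, "Hox3")
  expect_equal(intervening$right_member, "Hox4")

  # span undefined on a multi-chromosome cluster is an error
  split_hits <- fx$hits
  split_hits$chrom[1] <- "chr3"
  split_hits$start[1] <- 1100; split_hits$end[1] <- 1500
  asg2 <- assign_members_from_hits(split_hits, annot)
  rep2 <- assess_cluster(asg2, hox_cluster())
  expect_error(find_intervening_models(annot, rep2), "span undefined")
})

test_that("completeness scores report printed-precision percentages", {
  fams <- paste0("fam", 1:47)
  sc <- completeness_score(fams[1:45], fams)
  expect_equal(sc$percent, 95.7)
  expect_equal(sc$missing, fams[46:47])
  expect_equal(completeness_score(fams, fams)$percent, 100)
  expect_equal(completeness_score(fams[1:42], fams)$percent, 89.4)
})

test_that("identical nucleotide sequences on one chromosome are flagged", {
  lay <- toy_layout(2)
  genes <- make_models(c("hlxA", "hlxB", "otherchrom", "near"),
                       c("chr1", "chr1", "chr2", "chr1"),
                       start = c(1000, 9000, 1000, 20000),
                       end = c(2000, 10000, 2000, 21000))
  annot <- annotation_set(lay, genes)
  seqs <- c(hlxA = "ACGTACGT", hlxB = "ACGTACGT", otherchrom = "ACGTACGT",
            near = "ACGTACGA")
  flagged <- flag_identical_duplicates(annot, seqs)
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$gene1, "hlxA")
  expect_equal(flagged$gene2, "hlxB")
  # widening scope picks up the cross-chromosome copy too
  wide <- flag_identical_duplicates(annot, seqs, same_chromosome_only = FALSE)
  expect_equal(nrow(wide), 3)
  # missing sequences are skipped with a warning
  expect_warning(
    flag_identical_duplicates(annot, seqs[c("hlxA", "hlxB")]),
    "no sequence")
})

test_that("planted clusters are recovered exactly across seeds", {
  for (s in 1:10) {
    fx <- plant_cluster_fixture(s, reversed = s %% 2 == 0)
    asg <- assign_members_from_hits(fx$hits, fx$annotation, 1e-20)
    rep <- assess_cluster(asg, expected_cluster("toy", fx$members))
    expect_equal(rep$missing, fx$deleted)
    expect_equal(unname(rep$copy_number[fx$multi]), 2L)
    expect_true(all(rep$copy_number[setdiff(fx$members,
                                            c(fx$deleted, fx$multi))] == 1))
    expect_true(rep$single_chromosome)
    expect_true(rep$ordered)
    expect_true(rep$strand_uniform)
    expect_equal(nrow(attr(asg, "unmapped")), 1)   # the intergenic decoy
  }
})
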