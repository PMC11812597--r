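# Locus grouping, gene assignment, power-matched selection, and the
# block-level comparison, checked against hand-traced fixtures and
# random-input invariants.

toy_hits <- function() {
  data.frame(
    variant = c("v1", "v2", "v3", "v4"),
    chrom = "chr1",
    pos = c(1e6, 1.8e6, 2.7e6, 1e7),
    pval = c(1e-30, 1e-10, 1e-9, 1e-8)
  )
}

test_that("hand-traced hits group into two loci via transitive closure", {
  loci <- group_loci(toy_hits())
  expect_identical(nrow(loci), 2L)
  # most significant locus: v3 joins through v2 (0.9 Mb), despite being
  # 1.7 Mb from the seed
  expect_setequal(loci$members[[1]], c("v1", "v2", "v3"))
  expect_identical(loci$members[[2]], "v4")
  expect_identical(loci$start[1], 1e6)
  expect_identical(loci$end[1], 2.7e6)
  expect_identical(loci$min_pval[1], 1e-30)
})

test_that("degenerate inputs group sensibly", {
  single <- group_loci(data.frame(variant = "v", chrom = "chr2", pos = 5,
                                  pval = 0.5))
  expect_identical(nrow(single), 1L)
  two_chr <- group_loci(data.frame(variant = c("a", "b"),
                                   chrom = c("chr1", "chr2"),
                                   pos = c(100, 100), pval = c(1e-9, 1e-9)))
  expect_identical(nrow(two_chr), 2L)
  expect_error(group_loci(rbind(toy_hits(), toy_hits())), "duplicate")
})

test_that("random hit sets satisfy the locus invariants", {
  for (rep in 1:100) {
    set.seed(rep)
    n <- sample(2:40, 1)
    hits <- data.frame(
      variant = paste0("v", 1:n),
      chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
      pos = sample(1:2e7, n),
      pval = 10^-runif(n, 8, 30)
    )
    loci <- group_loci(hits)
    # partition: every hit in exactly one locus
    all_members <- unlist(loci$members)
    expect_setequal(all_members, hits$variant)
    expect_identical(length(all_members), n)
    # cross-locus hits on one chromosome are > window apart
    for (cc in unique(loci$chrom)) {
      sub <- loci[loci$chrom == cc]
      if (nrow(sub) < 2) next
      for (i in 1:(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
        pi <- hits$pos[hits$variant %in% sub$members[[i]]]
        pj <- hits$pos[hits$variant %in% sub$members[[j]]]
        expect_gt(min(abs(outer(pi, pj, "-"))), 1e6)
      }
    }
    # row order of the input is irrelevant
    perm <- hits[sample(n), ]
    loci2 <- group_loci(perm)
    expect_identical(loci$members, loci2$members)
  }
})

toy_genes <- function() {
  data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    start = c(1.5e6, 2.7e6 + 1, 5e5, 1e6, 9e6),
    end = c(1.6e6, 3.0e6, 9.99e5 + 1, 1.1e6, 9.5e6)
  )
}

test_that("gene assignment uses inclusive interval overlap", {
  loci <- assign_genes(group_loci(toy_hits()), toy_genes())
  # g1 inside; g2 shares the single boundary base 2.7e6+1? starts 1 bp after
  # the span end, so it must NOT be assigned; g3 ends 1 bp before the span
  expect_setequal(loci$genes[[1]], "g1")
  g2 <- toy_genes()
  g2$start[2] <- 2.7e6        # now shares exactly the last base of the span
  loci2 <- assign_genes(group_loci(toy_hits()), g2)
  expect_setequal(loci2$genes[[1]], c("g1", "g2"))
  # other chromosome never assigned
  expect_false("g4" %in% unlist(loci$genes))
})

test_that("top-locus gene selection walks the ranking and power-matches", {
  loci <- data.table::data.table(
    locus = c("L1", "L2", "L3"),
    chrom = "chr1", start = c(1, 100, 200), end = c(50, 150, 250),
    min_pval = c(1e-20, 1e-15, 1e-10),
    genes = list(c("a", "b"), c("g5", "g6"), c("c"))
  )
  burden <- data.frame(
    gene = c("a", "b", "c", "g5", "g6"),
    pval = c(1e-8, 1e-7, 1e-9, 1e-4, 0.5)
  )
  sel <- select_top_locus_genes(loci, burden, burden_threshold = 1e-6)
  expect_identical(sel$target, 3L)
  expect_setequal(sel$selected_genes, c("a", "b", "g5"))
  expect_identical(sel$top_loci, c("L1", "L2"))
  # a locus with no genes consumes a rank slot but contributes nothing
  loci_gap <- data.table::copy(loci)
  loci_gap$genes[[2]] <- character(0)
  sel2 <- select_top_locus_genes(loci_gap, burden, burden_threshold = 1e-6)
  expect_identical(sel2$top_loci, c("L1", "L2", "L3"))
  expect_setequal(sel2$selected_genes, c("a", "b", "c"))
  # empty significant set warns and selects nothing
  expect_warning(
    sel3 <- select_top_locus_genes(loci, burden, burden_threshold = 1e-30),
    "no burden-significant"
  )
  expect_identical(sel3$n_selected, 0L)
})

test_that("overlap fraction counts contained significant genes", {
  loci <- data.table::data.table(
    locus = c("L1", "L2"), genes = list(c("a", "b"), "c")
  )
  expect_identical(overlap_fraction(c("a", "b", "c"), loci), 1)
  expect_identical(overlap_fraction(c("x", "y"), loci), 0)
  expect_equal(overlap_fraction(c("a", "x"), loci, locus_ids = "L1"), 0.5)
  expect_error(overlap_fraction(character(0), loci), "undefined")
})

test_that("locus concordance reproduces hand-computed rank correlations", {
  make_loci <- function(burden_ps) {
    data.table::data.table(
      locus = paste0("L", seq_along(burden_ps)),
      min_pval = 10^-(seq_along(burden_ps) * 3),
      genes = as.list(paste0("g", seq_along(burden_ps)))
    )
  }
  burden_same <- data.frame(gene = paste0("g", 1:5), pval = 10^-(1:5 * 2))
  expect_equal(locus_concordance(make_loci(1:5), burden_same)$rho, 1)
  burden_rev <- data.frame(gene = paste0("g", 1:5), pval = 10^-(5:1 * 2))
  expect_equal(locus_concordance(make_loci(1:5), burden_rev)$rho, -1)
  # hand-computed: burden -log10 p ranks (1,3,2,5,4) against gwas ranks
  # (1,2,3,4,5): Spearman rho = 1 - 6*sum(d^2)/(n(n^2-1)) = 1 - 24/120 = 0.8
  burden_hand <- data.frame(gene = paste0("g", 1:5),
                            pval = 10^-c(2, 6, 4, 10, 8))
  expect_equal(locus_concordance(make_loci(1:5), burden_hand)$rho, 0.8)
  # fewer than 3 loci with genes: flagged undefined
  two <- make_loci(1:2)
  expect_false(locus_concordance(two, burden_same)$defined)
})

test_that("block comparison drops runs sharing one spanning gene", {
  blocks <- data.frame(
    chrom = "chr1",
    start = c(1, 1001, 2001, 3001),
    end = c(1000, 2000, 3000, 4000)
  )
  variants <- data.frame(
    chrom = "chr1", pos = c(500, 1500, 2500, 3500),
    pval = c(1e-12, 1e-4, 1e-6, 1e-9)
  )
  genes <- data.frame(
    gene = c("span", "u1", "u2"),
    chrom = "chr1",
    start = c(900, 2500, 3500), end = c(1200, 2600, 3600)
  )
  burden <- data.frame(gene = c("span", "u1", "u2"),
                       pval = c(1e-10, 1e-3, 1e-5))
  cmp <- ld_block_compare(blocks, variants, burden, genes)
  # blocks 1-2 share gene "span" as their minimum and are both dropped
  expect_identical(nrow(cmp), 2L)
  expect_setequal(cmp$min_burden_gene, c("u1", "u2"))
  expect_identical(attr(cmp, "n_dropped_duplicates"), 2L)
  expect_equal(cmp$min_gwas_p, c(1e-6, 1e-9))
  # a block without variants is excluded
  cmp2 <- ld_block_compare(blocks, variants[-3, ], burden, genes)
  expect_false(any(cmp2$start == 2001))
  # overlapping blocks are an input error
  bad <- blocks
  bad$start[2] <- 900
  expect_error(ld_block_compare(bad, variants, burden, genes), "overlap")
})

test_that("nearest-gene assignment respects midpoints, ties, and conservation", {
  genes <- data.frame(
    gene = c("gA", "gB"), chrom = "chr1",
    start = c(100, 1100), end = c(300, 1300)     # midpoints 200, 1200
  )
  hits <- data.frame(
    chrom = "chr1",
    pos = c(200, 1190, 700, 650),   # exact midpoint; near gB; tie at 700
    pval = 1e-9
  )
  counts <- nearest_gene_hit_counts(hits, genes)
  # 700 is equidistant (500) from both midpoints: lower start wins
  expect_identical(counts$n_hits[counts$gene == "gA"], 3L)
  expect_identical(counts$n_hits[counts$gene == "gB"], 1L)
  expect_identical(sum(counts$n_hits), nrow(hits))
  # hits on a chromosome without genes are warned and unassigned
  hits2 <- rbind(hits, data.frame(chrom = "chrX", pos = 1, pval = 1e-9))
  expect_warning(counts2 <- nearest_gene_hit_counts(hits2, genes),
                 "unassigned")
  expect_identical(sum(counts2$n_hits), nrow(hits))
})
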