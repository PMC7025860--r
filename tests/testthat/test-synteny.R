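test_that("identical gene orders form a single covering block", {
  genes <- paste0("g", 1:10)
  pairs <- pairs_from_orders(list(chrA = genes), list(chrB = genes))
  res <- build_blocks(pairs)
  expect_equal(nrow(res$blocks), 1)
  expect_equal(res$blocks$n_anchors, 10)
  expect_setequal(res$anchors$block_id, 1)
})

test_that("a reciprocal translocation yields four blocks", {
  # genome A: chr1 = g1..g10, chr2 = g11..g20
  # genome B: chr1 = g1..g5 + g16..g20, chr2 = g11..g15 + g6..g10
  a <- list(chr1 = paste0("g", 1:10), chr2 = paste0("g", 11:20))
  b <- list(chr1 = paste0("g", c(1:5, 16:20)),
            chr2 = paste0("g", c(11:15, 6:10)))
  res <- build_blocks(pairs_from_orders(a, b))
  expect_equal(nrow(res$blocks), 4)
  expect_setequal(res$blocks$n_anchors, c(5, 5, 5, 5))
})

test_that("an inversion yields three blocks with the middle one inverted", {
  genes <- paste0("g", 1:20)
  inv <- genes
  inv[8:12] <- rev(genes[8:12])
  res <- build_blocks(pairs_from_orders(list(chr1 = genes),
                                        list(chr1 = inv)))
  expect_equal(nrow(res$blocks), 3)
  expect_equal(res$blocks$orientation, c("+", "-", "+"))
  expect_equal(res$blocks$n_anchors, c(7, 5, 8))
})

test_that("blocks partition the anchors and reject duplicate genes", {
  withr::with_seed(41, {
    genes <- paste0("g", 1:30)
    scrambled <- split(sample(genes), rep(1:3, each = 10))
    names(scrambled) <- paste0("chrB", 1:3)
    pairs <- pairs_from_orders(list(chrA = genes), scrambled)
    res <- build_blocks(pairs)
    expect_equal(sort(res$anchors$gene_a), sort(genes))
    expect_equal(sum(res$blocks$n_anchors), 30)
  })
  bad <- pairs_from_orders(list(chrA = c("g1", "g2")),
                           list(chrB = c("g1", "g2")))
  bad <- rbind(bad, bad[1, ])
  expect_error(build_blocks(bad), "duplicate")
})

test_that("self-comparison classifies every centromere as conserved", {
  g <- generate_genome(small_spec(), seed = 43)
  pairs <- truth_ortholog_pairs(g$truth, g$truth)
  syn <- build_blocks(pairs)
  fates <- classify_all_fates(g$truth$cores, g$truth$genes, syn,
                              g$truth$cores)
  expect_equal(fates$status, rep("conserved", 3))
})

test_that("flanks that land on two target chromosomes mark a breakpoint", {
  # B splits A's chr1 at the centromere gap between g10 and g11
  a <- list(chr1 = paste0("g", 1:20))
  b <- list(chrB1 = paste0("g", 1:10), chrB2 = paste0("g", 11:20))
  pairs <- pairs_from_orders(a, b)
  syn <- build_blocks(pairs)
  cen <- intervals("chr1", 1495, 1505)  # between gene 10 and gene 11
  genes_a <- intervals(pairs$chrom_a, pairs$start_a, pairs$end_a,
                       name = pairs$gene_a)
  fate <- classify_fate(cen, genes_a, syn, target_cens = intervals(
    "chrB9", 0, 100))
  expect_equal(fate$status, "breakpoint")
  expect_match(fate$evidence, "chrB1")
  expect_match(fate$evidence, "chrB2")
})

test_that("contiguous flanks without a target centromere mark inactivation", {
  genes <- paste0("g", 1:20)
  pairs <- pairs_from_orders(list(chr1 = genes), list(chrB1 = genes))
  syn <- build_blocks(pairs)
  genes_a <- intervals(pairs$chrom_a, pairs$start_a, pairs$end_a,
                       name = pairs$gene_a)
  cen <- intervals("chr1", 1495, 1505)
  # no centromere called anywhere near the corresponding B interval
  fate <- classify_fate(cen, genes_a, syn,
                        target_cens = intervals("chrB9", 0, 100),
                        adjacency_tol = 200)
  expect_equal(fate$status, "inactivated")
  # with a called centromere in the intervening interval: conserved
  fate <- classify_fate(cen, genes_a, syn,
                        target_cens = intervals("chrB1", 1495, 1505),
                        adjacency_tol = 200)
  expect_equal(fate$status, "conserved")
})

test_that("sparse flanks produce an insufficient-evidence status", {
  genes <- paste0("g", 1:6)
  pairs <- pairs_from_orders(list(chr1 = genes), list(chrB1 = genes))
  syn <- build_blocks(pairs)
  genes_a <- intervals(pairs$chrom_a, pairs$start_a, pairs$end_a,
                       name = pairs$gene_a)
  cen <- intervals("chr1", 295, 305)  # only 2 genes to the left
  expect_warning(
    fate <- classify_fate(cen, genes_a, syn,
                          target_cens = intervals("chrB1", 295, 305)),
    "flanking")
  expect_equal(fate$status, "insufficient_evidence")
})

test_that("Fitch parsimony has its closed-form small cases", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  res <- ancestral_chromosome_number(tr, c(a = 9, b = 9, c = 9, d = 9))
  expect_equal(res$root_states, 9L)
  expect_equal(res$changes, 0L)

  res <- ancestral_chromosome_number(tr, c(a = 7, b = 9, c = 9, d = 9))
  expect_equal(res$root_states, 9L)
  expect_equal(res$changes, 1L)

  expect_error(ancestral_chromosome_number(tr, c(a = 7, b = 9, c = 9)),
               "unlabeled leaf")
})

test_that("the packaged karyotype tree resolves to a nine-chromosome root", {
  k <- malassezia_karyotype()
  expect_setequal(k$tree$tip.label, names(k$counts))
  res <- ancestral_chromosome_number(k$tree, k$counts)
  expect_equal(res$root_states, 9L)
  expect_equal(res$changes, 2L)  # one origin of 8, one origin of 7
})

test_that("Fitch equals exhaustive enumeration on random labelled trees", {
  withr::with_seed(47, {
    for (i in 1:25) {
      n <- sample(3:8, 1)
      tr <- ape::rtree(n, rooted = TRUE)
      counts <- setNames(sample(c(7L, 8L, 9L), n, replace = TRUE),
                         tr$tip.label)
      got <- ancestral_chromosome_number(tr, counts)
      want <- oracle_fitch(tr, counts)
      expect_equal(got$changes, want$changes)
      expect_equal(got$root_states, want$root_states)
    }
  })
})
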