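test_that("genome generation is seed-deterministic with a valid truth table", {
  spec <- small_spec()
  g1 <- generate_genome(spec, seed = 5)
  g2 <- generate_genome(spec, seed = 5)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$cores, g2$truth$cores)

  expect_equal(length(g1$genome), 3)
  expect_equal(nrow(g1$truth$cores), 3)

  lens <- chrom_lengths <- setNames(Biostrings::width(g1$genome),
                                    names(g1$genome))
  validate_intervals(g1$truth$cores, lens)
  validate_intervals(g1$truth$genes, lens)

  # planted site instances are really in the emitted sequence
  for (i in seq_len(nrow(g1$truth$sites))) {
    s <- g1$truth$sites[i, ]
    found <- substr(as.character(g1$genome[[s$chrom]]), s$pos + 1, s$pos + 12)
    want <- if (s$strand == "+") s$instance else revcomp_chr(s$instance)
    expect_identical(found, want)
  }

  # per-core site count within the configured range
  per_core <- table(g1$truth$sites$chrom)
  expect_true(all(per_core >= 7 & per_core <= 13))

  # genes do not overlap each other or the core
  for (ch in names(g1$genome)) {
    gg <- g1$truth$genes[g1$truth$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
    core <- g1$truth$cores[g1$truth$cores$chrom == ch, ]
    expect_true(all(gg$end <= core$start | gg$start >= core$end))
  }
})

test_that("generated composition matches the specification", {
  spec <- small_spec()
  bg_err <- core_err <- numeric(0)
  for (seed in 1:5) {
    g <- generate_genome(spec, seed = seed)
    for (ch in names(g$genome)) {
      seq <- as.character(g$genome[[ch]])
      core <- g$truth$cores[g$truth$cores$chrom == ch, ]
      core_seq <- substr(seq, core$start + 1, core$end)
      flank <- paste0(substr(seq, 1, core$start),
                      substr(seq, core$end + 1, nchar(seq)))
      bg_err <- c(bg_err, gc_fraction(flank) - spec$background_gc)
      core_err <- c(core_err, (1 - gc_fraction(core_seq)) - spec$core_at)
    }
  }
  # law-of-large-numbers check: aggregate composition matches the spec
  # (individual cores carry planted motif instances and 800-bp sampling
  # noise, so the bound applies to the mean over chromosomes and seeds)
  expect_lt(abs(mean(bg_err)), 0.01)
  expect_lt(abs(mean(core_err)), 0.03)
  expect_lt(max(abs(core_err)), 0.08)
})

test_that("simulated ChIP behaves like its Poisson model", {
  spec <- small_spec()
  g <- generate_genome(spec, seed = 7)
  # fold 1: IP and input identically distributed; profile ~ 0 everywhere
  sim <- simulate_chip(g$genome, g$truth, fold = 1, depth = 30, seed = 8)
  prof <- subtract_input(sim$ip$chr1, sim$input$chr1)
  expect_lt(mean(prof$values), 5)
  expect_lt(max(prof$values), 30)

  # total IP reads scale linearly with depth
  tot <- vapply(c(30, 60, 90), function(d) {
    s <- simulate_chip(g$genome, g$truth, fold = 1, depth = d, seed = 9)
    sum(vapply(s$ip, function(tr) sum(tr$values), numeric(1)))
  }, numeric(1))
  expect_lt(abs(tot[2] / tot[1] - 2), 0.05 * 2)
  expect_lt(abs(tot[3] / tot[1] - 3), 0.05 * 3)

  # fold 20: the called region recovers the truth window centre
  sim <- simulate_chip(g$genome, g$truth, fold = 20, depth = 30, seed = 10)
  for (ch in names(sim$ip)) {
    call <- call_full_region(subtract_input(sim$ip[[ch]], sim$input[[ch]]))
    truth_reg <- sim$full_regions[sim$full_regions$chrom == ch, ]
    centre_got <- (call$interval$start + call$interval$end) / 2
    centre_want <- (truth_reg$start + truth_reg$end) / 2
    expect_lte(abs(centre_got - centre_want), 250)
  }
})

test_that("breakage deletes the core, conserving all other sequence", {
  spec <- small_spec(n_chrom = 4L)
  g <- generate_genome(spec, seed = 11)
  br <- apply_breakage(g$genome, g$truth, "chr3", "chr1", "chr2")
  expect_equal(length(br$genome), 3)

  core <- g$truth$cores[g$truth$cores$chrom == "chr3", ]
  expect_equal(sum(Biostrings::width(br$genome)),
               sum(Biostrings::width(g$genome)) - (core$end - core$start))
  expect_equal(nrow(br$truth$cores), 3)
  expect_false("chr3" %in% br$truth$cores$chrom)
  expect_equal(br$truth$events[[1]]$type, "breakage")

  # genes kept their sequence context: spot-check a donor left-arm gene
  donor_genes <- g$truth$genes[g$truth$genes$chrom == "chr3" &
                                 g$truth$genes$end <= core$start, ]
  gene <- donor_genes[nrow(donor_genes), ]
  moved <- br$truth$genes[br$truth$genes$name == gene$name, ]
  expect_equal(moved$chrom, "chr1")
  old_seq <- substr(as.character(g$genome[["chr3"]]), gene$start + 1,
                    gene$end)
  new_seq <- substr(as.character(br$genome[["chr1"]]), moved$start + 1,
                    moved$end)
  expect_identical(new_seq, old_seq)

  expect_error(apply_breakage(g$genome, g$truth, "chr1", "chr1", "chr2"),
               "distinct")
})

test_that("fusion erodes one core and shifts the survivor by the prefix", {
  spec <- small_spec(n_chrom = 4L)
  g <- generate_genome(spec, seed = 13)
  len1 <- Biostrings::width(g$genome)[1]
  fu <- apply_fusion_inactivation(g$genome, g$truth, "chr1", "chr2",
                                  inactivate = "i", seed = 14)
  expect_equal(length(fu$genome), 3)
  expect_true("chr1-chr2" %in% names(fu$genome))
  expect_equal(sum(Biostrings::width(fu$genome)),
               sum(Biostrings::width(g$genome)))

  # surviving core (chr2's) shifted by exactly the prepended chr1 length
  old <- g$truth$cores[g$truth$cores$chrom == "chr2", ]
  new <- fu$truth$cores[fu$truth$cores$chrom == "chr1-chr2", ]
  expect_equal(nrow(new), 1)
  expect_equal(new$start, old$start + len1)
  expect_equal(new$end, old$end + len1)

  # eroded locus no longer carries the AT-rich island
  dead <- g$truth$cores[g$truth$cores$chrom == "chr1", ]
  eroded_seq <- substr(as.character(fu$genome[["chr1-chr2"]]),
                       dead$start + 1, dead$end)
  expect_gt(gc_fraction(eroded_seq), 0.4)

  # two fusions: 4 -> 2 chromosomes
  fu2 <- apply_fusion_inactivation(fu$genome, fu$truth, "chr3", "chr4",
                                   inactivate = "j", seed = 15)
  expect_equal(length(fu2$genome), 2)
  expect_error(apply_fusion_inactivation(g$genome, g$truth, "chr1", "chr1"),
               "itself")
})

test_that("ortholog pairs from truth tables are one-to-one and complete", {
  g <- generate_genome(small_spec(), seed = 17)
  br <- apply_breakage(g$genome, g$truth, "chr2", "chr1", "chr3")
  pairs <- truth_ortholog_pairs(g$truth, br$truth)
  expect_false(anyDuplicated(pairs$gene_a) > 0)
  expect_false(anyDuplicated(pairs$gene_b) > 0)
  expect_equal(sort(pairs$gene_b), sort(br$truth$genes$name))
})
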