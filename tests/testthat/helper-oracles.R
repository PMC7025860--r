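# Independent oracles and small fixture builders. Every oracle here takes a
# deliberately naive path (per-position loops, substring extraction,
# exhaustive enumeration) so that it shares no code with the implementation
# it checks.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n, probs = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = probs), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# GC fraction of each window by explicit substring recount.
oracle_gc_windows <- function(seq, window, step) {
  L <- nchar(seq)
  starts <- seq(0, L - window, by = step)
  vapply(starts, function(s) {
    chars <- strsplit(substr(seq, s + 1, s + window), "")[[1]]
    chars <- chars[chars %in% BASES]
    sum(chars %in% c("G", "C")) / length(chars)
  }, numeric(1))
}

# Term-by-term LLR of one k-mer.
oracle_llr <- function(pwm, kmer) {
  chars <- strsplit(kmer, "")[[1]]
  total <- 0
  for (i in seq_along(chars)) {
    b <- match(chars[i], BASES)
    total <- total + log(pwm$probs[b, i] / pwm$background[[b]])
  }
  unname(total)
}

# Naive window-count oracle: for every window, loop over every in-window
# k-mer start on each strand and score it independently.
oracle_count_windows <- function(seq, pwm, thr = 7.5, window = 500,
                                 step = 100, strands = "both") {
  L <- nchar(seq)
  width <- pwm$width
  # score every position once (still by the naive per-k-mer path)
  pos_scores <- function(s) {
    n <- nchar(s) - width + 1
    vapply(seq_len(n), function(p) {
      oracle_llr(pwm, substr(s, p, p + width - 1))
    }, numeric(1))
  }
  fwd <- pos_scores(seq)
  hits_fwd <- which(fwd > thr)                   # 1-based k-mer starts
  hits <- hits_fwd
  if (strands == "both") {
    rts <- pos_scores(revcomp_chr(seq))
    # position p (1-based) on the reverse complement corresponds to
    # forward-strand k-mer start L - width - p + 2
    hits_rev <- L - width - which(rts > thr) + 2
    hits <- c(hits, hits_rev)
  }
  starts <- seq(0, L - window, by = step)
  vapply(starts, function(ws) {
    sum(hits - 1 >= ws & (hits - 1 + width) <= ws + window)
  }, integer(1))
}

# Exhaustive-minimisation parsimony oracle: tries every assignment of
# states to internal nodes and reports the minimal change count and the
# root states achieving it.
oracle_fitch <- function(tree, counts, states = c(7L, 8L, 9L)) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  tip_states <- as.integer(counts[tree$tip.label])
  grid <- as.matrix(expand.grid(rep(list(states), n_node)))
  edge <- tree$edge
  cost <- apply(grid, 1, function(assign) {
    full <- c(tip_states, assign)
    sum(full[edge[, 1]] != full[edge[, 2]])
  })
  best <- min(cost)
  root_idx <- 1L  # internal nodes are numbered n_tip+1 .. ; root is first
  list(changes = best,
       root_states = sort(unique(grid[cost == best, root_idx])))
}

# A GC-rich chromosome with one planted AT-rich island, plus abutting gene
# annotations, for delineation tests.
make_island_chrom <- function(len = 10000, island_start = 5000,
                              island_len = 520, gc_bg = 0.6, seed = 42) {
  withr::with_seed(seed, {
    bg_probs <- c((1 - gc_bg) / 2, gc_bg / 2, gc_bg / 2, (1 - gc_bg) / 2)
    seq <- random_seq(len, bg_probs)
    island <- paste(rep(c("A", "T"), length.out = island_len), collapse = "")
    substr(seq, island_start + 1, island_start + island_len) <- island
    seq
  })
}

# Ortholog pair table from explicit gene orders: `order_b` gives, for each
# genome-B chromosome, the genome-A gene names in B order ("-" prefix for
# inverted genes, ignored for coordinates).
pairs_from_orders <- function(order_a, order_b, gene_len = 100,
                              gap = 50) {
  mk <- function(orders) {
    rows <- list()
    for (ch in names(orders)) {
      genes <- sub("^-", "", orders[[ch]])
      starts <- (seq_along(genes) - 1) * (gene_len + gap)
      rows[[ch]] <- data.frame(gene = genes, chrom = ch, start = starts,
                               end = starts + gene_len,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  a <- mk(order_a)
  b <- mk(order_b)
  common <- intersect(a$gene, b$gene)
  ia <- match(common, a$gene)
  ib <- match(common, b$gene)
  data.frame(gene_a = common, chrom_a = a$chrom[ia], start_a = a$start[ia],
             end_a = a$end[ia], gene_b = common, chrom_b = b$chrom[ib],
             start_b = b$start[ib], end_b = b$end[ib], identity = 100,
             stringsAsFactors = FALSE)
}

# Small synthetic spec for fast unit tests (acceptance tests use defaults).
small_spec <- function(n_chrom = 3L, chrom_len = 60000L, ...) {
  synthetic_spec(n_chrom = n_chrom, chrom_len = chrom_len, ...)
}
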