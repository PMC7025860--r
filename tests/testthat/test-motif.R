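test_that("build_pwm estimates column probabilities with pseudocounts", {
  # near-zero pseudocount limit: observed base takes all the mass
  p <- build_pwm(c("AA", "AA"), pseudocount = 1e-12)
  expect_equal(unname(p$probs[, 1]), c(1, 0, 0, 0), tolerance = 1e-9)

  p <- build_pwm(c("AT", "AT"), pseudocount = 1)
  expect_equal(unname(p$probs["A", 1]), (2 + 1) / (2 + 4))

  expect_error(build_pwm(character(0)), "at least one")
  expect_error(build_pwm(c("AT", "ATT")), "same length")
  expect_error(build_pwm("ANT"), "A/C/G/T")
  expect_error(build_pwm("AT", pseudocount = 0), "pseudocount")

  # random instance sets match a hand-counting oracle; columns sum to 1
  withr::with_seed(13, {
    for (i in 1:10) {
      n <- sample(2:20, 1)
      w <- sample(4:12, 1)
      inst <- vapply(seq_len(n), function(j) random_seq(w), character(1))
      pc <- runif(1, 0.1, 2)
      p <- build_pwm(inst, pseudocount = pc)
      expect_equal(unname(colSums(p$probs)), rep(1, w))
      chars <- do.call(rbind, strsplit(inst, ""))
      for (pos in seq_len(w)) {
        counts <- vapply(BASES, function(b) sum(chars[, pos] == b),
                         numeric(1))
        expect_equal(unname(p$probs[, pos]),
                     unname((counts + pc) / (n + 4 * pc)))
      }
    }
  })
})

test_that("llr has its closed forms and matches term-by-term summation", {
  # every column uniform == background: LLR 0 for any k-mer
  uniform <- build_pwm(c("ACGT", "CGTA", "GTAC", "TACG"), pseudocount = 0.5)
  expect_equal(llr(uniform, "AAAA"), 0)
  expect_equal(llr(uniform, "GATC"), 0)

  # probability ~1 on the query base everywhere: 12 * log(4)
  sharp <- build_pwm(strrep("A", 12), pseudocount = 1e-12)
  expect_equal(llr(sharp, strrep("A", 12)), 12 * log(4), tolerance = 1e-6)

  expect_error(llr(sharp, "AAA"), "length")
  expect_true(is.na(llr(sharp, paste0(strrep("A", 11), "N"))))

  withr::with_seed(17, {
    for (i in 1:20) {
      inst <- vapply(1:5, function(j) random_seq(8), character(1))
      bg <- runif(4, 0.5, 2)
      bg <- bg / sum(bg)
      p <- build_pwm(inst, pseudocount = 0.3, background = bg)
      kmer <- random_seq(8)
      expect_equal(llr(p, kmer), oracle_llr(p, kmer), tolerance = 1e-12)
    }
  })
})

test_that("count_windows agrees with the naive double-loop oracle", {
  pwm <- default_motif_pwm()
  withr::with_seed(19, {
    for (i in 1:3) {
      seq <- random_seq(2000, probs = c(0.35, 0.15, 0.15, 0.35))
      for (strands in c("both", "forward")) {
        got <- count_windows(seq, pwm, llr_threshold = 5, window = 500,
                             step = 100, strands = strands)
        expect_equal(got$counts,
                     oracle_count_windows(seq, pwm, thr = 5,
                                          strands = strands))
      }
    }
  })
})

test_that("count_windows finds planted sites and nothing in hostile sequence", {
  pwm <- default_motif_pwm()
  # all-G chromosome with an AT-rich PWM: zero everywhere
  got <- count_windows(strrep("G", 3000), pwm)
  expect_true(all(got$counts == 0))

  # five consensus sites inside one 500-bp span: every window fully
  # containing the span counts at least 5
  consensus <- "ATTAATTTTAAT"
  seq <- strrep("G", 3000)
  offs <- 1000 + c(0, 100, 200, 300, 400)
  for (o in offs) substr(seq, o + 1, o + 12) <- consensus
  got <- count_windows(seq, pwm)
  span <- c(1000, 1412)
  containing <- got$starts <= span[1] & got$starts + 500 >= span[2]
  expect_true(any(containing))
  expect_true(all(got$counts[containing] >= 5))

  # monotonicity: adding one more consensus site never decreases counts
  seq2 <- seq
  substr(seq2, 1051, 1062) <- consensus
  got2 <- count_windows(seq2, pwm)
  expect_true(all(got2$counts >= got$counts))
})

test_that("both strands of a self-reverse-complementary PWM double counts", {
  # columns chosen so the PWM equals its reverse complement
  half <- c("ATTAAT")
  inst <- paste0(half, revcomp_chr(half))
  pwm <- build_pwm(c(inst, inst, inst), pseudocount = 0.5)
  withr::with_seed(23, seq <- random_seq(3000, c(0.4, 0.1, 0.1, 0.4)))
  fwd <- count_windows(seq, pwm, llr_threshold = 3, strands = "forward")
  both <- count_windows(seq, pwm, llr_threshold = 3, strands = "both")
  expect_equal(both$counts, 2L * fwd$counts)
})

test_that("shuffle_pwm permutes columns deterministically, preserving them", {
  pwm <- default_motif_pwm()
  s1 <- shuffle_pwm(pwm, seed = 4)
  s2 <- shuffle_pwm(pwm, seed = 4)
  expect_identical(s1$probs, s2$probs)

  # all columns identical: shuffling is a no-op on the matrix
  flat <- build_pwm(c(strrep("A", 6), strrep("T", 6)), pseudocount = 0.5)
  expect_equal(shuffle_pwm(flat, seed = 1)$probs, flat$probs)

  # the multiset of columns is preserved exactly, and the permutation is
  # never the identity
  for (seed in 1:100) {
    sh <- shuffle_pwm(pwm, seed = seed)
    key <- function(m) sort(apply(m, 2, paste, collapse = ","))
    expect_identical(key(sh$probs), key(pwm$probs))
    expect_identical(sort(attr(sh, "permutation")), 1:12)
  }
})

test_that("motif enrichment report contrasts centromere and background", {
  counts <- structure(list(chrom_id = "c1", window = 500L, step = 100L,
                           starts = c(0L, 100L, 200L),
                           counts = c(0L, 0L, 0L),
                           sites = data.frame()),
                      class = "window_counts")
  cen <- intervals("c1", 120, 180)
  rep0 <- motif_enrichment_report(counts, cen)
  expect_equal(rep0$cen_max, 0)
  expect_equal(rep0$other_max, 0)
  expect_true(rep0$undefined_ratio)

  counts$counts <- c(2L, 9L, 8L)
  cen <- intervals("c1", 550, 650)  # overlaps the 100- and 200-start windows
  rep1 <- motif_enrichment_report(counts, cen)
  expect_equal(rep1$cen_max, 9)
  expect_equal(rep1$other_max, 2)
  expect_equal(rep1$ratio, 4.5)
  expect_error(motif_enrichment_report(counts, intervals("c9", 0, 10)),
               "c9")
})

test_that("train_pwm seeds from AT-rich words and returns a valid PWM", {
  withr::with_seed(29, {
    cores <- vapply(1:6, function(i) {
      s <- random_seq(400, c(0.3, 0.2, 0.2, 0.3))
      substr(s, 100, 111) <- "ATTAATTTTAAT"
      s
    }, character(1))
  })
  p <- train_pwm(cores)
  expect_s3_class(p, "pwm")
  expect_equal(p$width, 12L)
  expect_equal(unname(colSums(p$probs)), rep(1, 12))
  # the trained motif is AT-dominated, as its seeds are
  expect_gt(mean(p$probs["A", ] + p$probs["T", ]), 0.8)
  expect_error(train_pwm("ACGT"), "at least 12")
})
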