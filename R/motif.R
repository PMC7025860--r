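# PWM motif scanning: build a position weight matrix from aligned instances,
# score every k-mer by natural-log likelihood ratio against a background
# composition model, count above-threshold sites in sliding windows, and run
# the column-shuffled control.
#
# The control matters because centromere cores are AT-rich: a shuffled PWM
# keeps every column's composition (so it matches AT-rich sequence about as
# often by chance) but destroys the positional arrangement, so genuinely
# motif-bearing sequence scores higher under the real PWM than the shuffled
# one.

#' Build a position weight matrix from aligned instances
#'
#' `probs[b, i] = (count of base b at position i + pseudocount) /
#' (n + 4 * pseudocount)`.
#'
#' @param instances character vector of equal-length DNA strings over
#'   A/C/G/T.
#' @param pseudocount added per base per column (default 0.5); keeps every
#'   probability positive with few training instances.
#' @param background base frequencies (A, C, G, T) summing to 1; default
#'   uniform. Use [genome_background()] for genome-wide frequencies.
#' @return object of class `pwm`: list with `width`, `probs` (4 x width
#'   matrix, rows A/C/G/T), `pseudocount`, `background`.
#' @export
#' @examples
#' build_pwm(c("AT", "AT"), pseudocount = 1)$probs
build_pwm <- function(instances, pseudocount = 0.5,
                      background = rep(0.25, 4)) {
  if (length(instances) < 1) stop("need at least one motif instance")
  if (length(unique(nchar(instances))) != 1) {
    stop("motif instances must all have the same length")
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  width <- nchar(instances[1])
  codes <- vapply(instances, dna_codes, integer(width))
  if (anyNA(codes)) stop("motif instances must contain only A/C/G/T")
  codes <- matrix(codes, nrow = width)
  n <- length(instances)
  probs <- vapply(seq_len(width), function(i) {
    (tabulate(codes[i, ], nbins = 4L) + pseudocount) / (n + 4 * pseudocount)
  }, numeric(4))
  new_pwm(probs, pseudocount, background)
}

new_pwm <- function(probs, pseudocount, background) {
  probs <- matrix(as.numeric(probs), nrow = 4,
                  dimnames = list(DNA_BASES, NULL))
  background <- as.numeric(background)
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("PWM columns must each sum to 1")
  }
  if (any(probs <= 0)) stop("PWM probabilities must all be positive")
  structure(list(width = ncol(probs), probs = probs,
                 pseudocount = pseudocount,
                 background = setNames(background, DNA_BASES)),
            class = "pwm")
}

#' Genome-wide mononucleotide background frequencies
#'
#' @param genome DNAStringSet, named character vector, or FASTA path.
#' @return numeric vector of A, C, G, T frequencies summing to 1 (N bases
#'   ignored).
#' @export
genome_background <- function(genome) {
  codes <- dna_codes(paste(as_genome_chars(genome), collapse = ""))
  counts <- tabulate(codes[!is.na(codes)], nbins = 4L)
  setNames(counts / sum(counts), DNA_BASES)
}

# log(probs/background) lookup matrix, 4 x width
pwm_weights <- function(pwm) log(pwm$probs / pwm$background)

# The PWM that scores the reverse strand in forward coordinates: positions
# reversed, bases complemented, background complemented likewise.
pwm_revcomp <- function(pwm) {
  probs <- pwm$probs[4:1, pwm$width:1, drop = FALSE]
  rownames(probs) <- DNA_BASES
  new_pwm(probs, pwm$pseudocount, pwm$background[4:1])
}

#' Log-likelihood ratio of a k-mer under a PWM
#'
#' Natural log of the ratio of the k-mer's likelihood as a sample from the
#' PWM to its likelihood under the background composition:
#' `sum_i log(probs[kmer_i, i] / background[kmer_i])`.
#'
#' @param pwm a [build_pwm()] object.
#' @param kmer DNA string of length `pwm$width`.
#' @return the LLR; `NA` if the k-mer contains N (such sites are skipped
#'   during scanning).
#' @export
llr <- function(pwm, kmer) {
  stopifnot(inherits(pwm, "pwm"))
  if (nchar(kmer) != pwm$width) {
    stop("k-mer length ", nchar(kmer), " does not match PWM width ",
         pwm$width)
  }
  codes <- dna_codes(kmer)
  if (anyNA(codes)) return(NA_real_)
  w <- pwm_weights(pwm)
  sum(w[cbind(codes, seq_len(pwm$width))])
}

# Per-position LLR along a coded sequence for one strand's weight matrix.
# Returns scores for 0-based positions 0..L-width; NA where the k-mer
# contains N.
scan_scores <- function(codes, weights) {
  width <- ncol(weights)
  L <- length(codes)
  if (L < width) return(numeric(0))
  n <- L - width + 1L
  s <- numeric(n)
  for (i in seq_len(width)) {
    wi <- weights[, i]
    v <- wi[codes[i:(i + n - 1L)]]
    s <- s + v
  }
  s
}

#' Count above-threshold motif sites in sliding windows
#'
#' Scores every k-mer position (both strands by default) and counts, for
#' each window start `0, step, 2*step, ...`, the sites whose LLR exceeds
#' `llr_threshold` and whose k-mer lies entirely within the window.
#' Overlapping sites each count, and a site contributes to every window that
#' contains it.
#'
#' @param seq chromosome sequence (character or [Biostrings::DNAString]).
#' @param pwm a [build_pwm()] object.
#' @param chrom_id chromosome identifier carried into the result.
#' @param llr_threshold sites must score strictly above this (default 7.5).
#' @param window window size in bases (default 500).
#' @param step window step in bases (default 100).
#' @param strands `"both"` (default) or `"forward"`.
#' @return object of class `window_counts`: list with `chrom_id`, `window`,
#'   `step`, `starts`, `counts`, and `sites` (data frame of 0-based site
#'   positions, strands and scores).
#' @export
count_windows <- function(seq, pwm, chrom_id = "chr", llr_threshold = 7.5,
                          window = 500L, step = 100L,
                          strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(inherits(pwm, "pwm"), step <= window)
  codes <- dna_codes(seq)
  L <- length(codes)
  if (L < window) {
    stop("sequence (", L, " bp) shorter than the window (", window, " bp)")
  }
  fwd <- scan_scores(codes, pwm_weights(pwm))
  fpos <- which(!is.na(fwd) & fwd > llr_threshold) - 1L
  hits <- data.frame(pos = fpos, strand = rep("+", length(fpos)),
                     score = fwd[fpos + 1L])
  if (strands == "both") {
    rev <- scan_scores(codes, pwm_weights(pwm_revcomp(pwm)))
    rpos <- which(!is.na(rev) & rev > llr_threshold) - 1L
    hits <- rbind(hits, data.frame(pos = rpos,
                                   strand = rep("-", length(rpos)),
                                   score = rev[rpos + 1L]))
  }
  starts <- seq.int(0L, L - window, by = step)
  counts <- integer(length(starts))
  if (nrow(hits)) {
    # window index range containing k-mer [pos, pos + width)
    i_lo <- ceiling((hits$pos + pwm$width - window) / step)
    i_hi <- floor(hits$pos / step)
    i_lo <- pmax(i_lo, 0L)
    i_hi <- pmin(i_hi, length(starts) - 1L)
    for (k in seq_len(nrow(hits))) {
      if (i_lo[k] <= i_hi[k]) {
        idx <- (i_lo[k]:i_hi[k]) + 1L
        counts[idx] <- counts[idx] + 1L
      }
    }
  }
  structure(list(chrom_id = as.character(chrom_id),
                 window = as.integer(window), step = as.integer(step),
                 starts = as.integer(starts), counts = counts,
                 sites = hits[order(hits$pos), , drop = FALSE]),
            class = "window_counts")
}

#' Shuffle the columns of a PWM
#'
#' Draws a seeded uniform-random permutation of the columns; each column's
#' content (its weight vector) is unchanged. If the identity permutation is
#' drawn it is redrawn once and the second draw is accepted whatever it is.
#'
#' @param pwm a [build_pwm()] object with `width >= 2`.
#' @param seed integer seed for the permutation.
#' @return a `pwm` with permuted columns; the permutation is stored in
#'   attribute `"permutation"`.
#' @export
shuffle_pwm <- function(pwm, seed) {
  stopifnot(inherits(pwm, "pwm"), pwm$width >= 2)
  perm <- with_seed(seed, {
    p <- sample.int(pwm$width)
    if (all(p == seq_len(pwm$width))) p <- sample.int(pwm$width)
    p
  })
  out <- new_pwm(pwm$probs[, perm, drop = FALSE], pwm$pseudocount,
                 pwm$background)
  attr(out, "permutation") <- perm
  out
}

#' Summarise motif enrichment at a centromere call
#'
#' Compares the maximum window count over centromere-overlapping windows
#' with the maximum over all other windows.
#'
#' @param counts a [count_windows()] result.
#' @param cen one-row interval data frame for the centromere (same
#'   chromosome).
#' @return list with `cen_max`, `other_max`, `ratio` (`NA` with
#'   `undefined_ratio = TRUE` when `other_max` is 0).
#' @export
motif_enrichment_report <- function(counts, cen) {
  stopifnot(inherits(counts, "window_counts"), nrow(cen) == 1)
  if (!identical(as.character(cen$chrom), counts$chrom_id)) {
    stop("window counts are for ", counts$chrom_id,
         " but the centromere call is on ", cen$chrom)
  }
  w_end <- counts$starts + counts$window
  overlaps <- counts$starts < cen$end & w_end > cen$start
  cen_max <- if (any(overlaps)) max(counts$counts[overlaps]) else 0L
  other_max <- if (any(!overlaps)) max(counts$counts[!overlaps]) else 0L
  list(cen_max = cen_max, other_max = other_max,
       ratio = if (other_max > 0) cen_max / other_max else NA_real_,
       undefined_ratio = other_max == 0)
}

#' Train a motif PWM from called centromere cores
#'
#' Seeds one instance per core with its most AT-rich `width`-mer (leftmost on
#' ties), builds a PWM, then runs one refinement pass in which each core
#' contributes its best-LLR `width`-mer (either strand) under the current
#' PWM, and rebuilds. This replaces de novo motif discovery: the motif is
#' assumed to be the most AT-rich recurring word in the cores.
#'
#' @param cores character vector of core centromere sequences.
#' @param width motif width (default 12).
#' @param pseudocount,background passed to [build_pwm()].
#' @return a `pwm`.
#' @export
train_pwm <- function(cores, width = 12L, pseudocount = 0.5,
                      background = rep(0.25, 4)) {
  cores <- as.character(cores)
  if (any(nchar(cores) < width)) {
    stop("every core must be at least ", width, " bp")
  }
  seed_kmer <- function(seq) {
    codes <- dna_codes(seq)
    at <- is.na(codes) | codes == 1L | codes == 4L  # N never best: see below
    at[is.na(codes)] <- FALSE
    cat_ <- c(0, cumsum(at))
    n <- length(codes) - width + 1L
    scores <- cat_[(1:n) + width] - cat_[1:n]
    best <- which.max(scores)  # leftmost maximum
    substr(seq, best, best + width - 1L)
  }
  best_kmer <- function(seq, pwm) {
    codes <- dna_codes(seq)
    f <- scan_scores(codes, pwm_weights(pwm))
    r <- scan_scores(codes, pwm_weights(pwm_revcomp(pwm)))
    fm <- suppressWarnings(max(f, na.rm = TRUE))
    rm_ <- suppressWarnings(max(r, na.rm = TRUE))
    if (fm >= rm_) {
      i <- which(f == fm)[1]
      substr(seq, i, i + width - 1L)
    } else {
      i <- which(r == rm_)[1]
      revcomp_string(substr(seq, i, i + width - 1L))
    }
  }
  seeds <- vapply(cores, seed_kmer, character(1), USE.NAMES = FALSE)
  pwm0 <- build_pwm(seeds, pseudocount, background)
  refined <- vapply(cores, best_kmer, character(1), pwm = pwm0,
                    USE.NAMES = FALSE)
  build_pwm(refined, pseudocount, background)
}
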