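# GC landscape: windowed GC profiles, the per-chromosome global GC trough,
# and delineation of the AT-rich core centromere around it.
#
# Short regional centromeres in compact fungal genomes sit at the global GC
# minimum of each chromosome: an AT-rich core of under a kilobase inside a
# GC-rich background. N bases are excluded from both the numerator and
# denominator of every GC fraction, and windows dominated by N (assembly
# gaps) are masked so they cannot produce spurious troughs.

#' GC fraction of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; N bases are ignored entirely.
#'
#' @param seq DNA as a character string, [Biostrings::DNAString], or a
#'   [Biostrings::DNAStringSet]/named character vector (pooled over records).
#' @return GC fraction in `[0, 1]`.
#' @export
#' @examples
#' gc_fraction("ATGC")  # 0.5
gc_fraction <- function(seq) {
  if (methods::is(seq, "DNAStringSet") ||
      (is.character(seq) && length(seq) > 1L)) {
    seq <- paste(as.character(seq), collapse = "")
  }
  codes <- dna_codes(seq)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) {
    stop("GC fraction undefined: no A/C/G/T bases in sequence")
  }
  sum(codes == 2L | codes == 3L) / length(codes)
}

#' Windowed GC profile of a chromosome
#'
#' Computes the GC fraction in windows starting at 0, `step`, `2*step`, ...;
#' a trailing partial window is dropped. Windows whose N fraction exceeds
#' `mask_n_fraction` are masked (GC reported as `NA`).
#'
#' @param seq chromosome sequence (character or [Biostrings::DNAString]).
#' @param chrom_id chromosome identifier carried into the profile.
#' @param window window size in bases (default 250).
#' @param step step between window starts; defaults to `window`
#'   (non-overlapping); set to less for a sliding profile.
#' @param mask_n_fraction windows with more than this fraction of N are
#'   masked (default 0.5).
#' @return object of class `gc_profile` with fields `chrom_id`, `window`,
#'   `step`, `starts` (0-based), `gc` (fractions, `NA` when masked).
#' @export
gc_profile <- function(seq, chrom_id = "chr", window = 250L,
                       step = window, mask_n_fraction = 0.5) {
  stopifnot(window >= 1, step >= 1, step <= window)
  codes <- dna_codes(seq)
  L <- length(codes)
  if (L < window) {
    stop("chromosome ", chrom_id, " (", L,
         " bp) is shorter than the window (", window, " bp)")
  }
  is_gc <- !is.na(codes) & (codes == 2L | codes == 3L)
  is_n <- is.na(codes)
  cgc <- c(0, cumsum(is_gc))
  cn <- c(0, cumsum(is_n))
  starts <- seq.int(0L, L - window, by = step)
  n_gc <- cgc[starts + window + 1] - cgc[starts + 1]
  n_n <- cn[starts + window + 1] - cn[starts + 1]
  denom <- window - n_n
  gc <- ifelse(denom > 0, n_gc / denom, NA_real_)
  gc[n_n / window > mask_n_fraction] <- NA_real_
  structure(list(chrom_id = as.character(chrom_id),
                 window = as.integer(window), step = as.integer(step),
                 starts = as.integer(starts), gc = as.numeric(gc)),
            class = "gc_profile")
}

#' Find the global GC trough of a profile
#'
#' Returns the window with minimal GC; ties are broken leftmost so the call
#' is deterministic. Masked windows are ignored.
#'
#' @param profile a [gc_profile()].
#' @return a one-row interval data frame (`name = "gc_trough"`, `score` = GC
#'   fraction of the trough window).
#' @export
find_gc_trough <- function(profile) {
  stopifnot(inherits(profile, "gc_profile"))
  ok <- !is.na(profile$gc)
  if (!any(ok)) stop("all windows masked on ", profile$chrom_id)
  i <- which(profile$gc == min(profile$gc[ok]) & ok)[1]
  intervals(profile$chrom_id, profile$starts[i],
            profile$starts[i] + profile$window,
            name = "gc_trough", score = profile$gc[i])
}

#' Delineate the AT-rich core centromere around a GC trough
#'
#' With a gene annotation, the core is the intergenic interval that contains
#' the trough (`method = "intergenic"`), the rule that produced published
#' core coordinates where annotations were available. Without one, the trough
#' window is extended symmetrically in step-sized increments for as long as
#' each added window stays at or below `gc_ceiling`
#' (`method = "trough_extension"`). Either way the core is capped at
#' `max_core_len`, trimming symmetrically around the trough.
#'
#' @param seq chromosome sequence.
#' @param trough one-row interval from [find_gc_trough()].
#' @param genes optional interval data frame of gene bodies on the same
#'   chromosome. If the trough falls inside a gene, a warning is issued and
#'   the extension method is used instead.
#' @param max_core_len maximum core length in bases (default 1500).
#' @param gc_ceiling highest window GC admitted into the core; defaults to
#'   the genome (or chromosome) mean GC minus 15 percentage points, which
#'   separates AT-rich cores from GC-rich background in compact fungal
#'   genomes.
#' @param genome_gc mean GC fraction used for the default ceiling; defaults
#'   to `gc_fraction(seq)`.
#' @param step extension increment in bases (default: trough width).
#' @return object of class `core_call`: list with `interval` (one-row
#'   interval data frame), `gc_percent`, and `method`.
#' @export
delineate_core <- function(seq, trough, genes = NULL, max_core_len = 1500L,
                           gc_ceiling = NULL, genome_gc = NULL,
                           step = NULL) {
  seq <- as.character(seq)
  L <- nchar(seq)
  stopifnot(nrow(trough) == 1, trough$start >= 0, trough$end <= L)
  window <- trough$end - trough$start
  if (is.null(step)) step <- window
  if (is.null(genome_gc)) genome_gc <- gc_fraction(seq)
  if (is.null(gc_ceiling)) gc_ceiling <- genome_gc - 0.15

  method <- "trough_extension"
  core <- NULL
  if (!is.null(genes) && nrow(genes) > 0) {
    g <- genes[genes$chrom == trough$chrom, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    mid <- (trough$start + trough$end) / 2
    inside <- any(g$start <= mid & g$end > mid)
    if (inside) {
      warning("GC trough on ", trough$chrom,
              " lies inside an annotated gene; falling back to ",
              "trough-extension delineation")
    } else {
      left <- suppressWarnings(max(c(0, g$end[g$end <= mid])))
      right <- suppressWarnings(min(c(L, g$start[g$start >= mid])))
      core <- c(left, right)
      method <- "intergenic"
    }
  }
  if (is.null(core)) {
    win_gc <- function(s, e) {
      gc_fraction(substr(seq, s + 1, e))
    }
    left <- trough$start
    right <- trough$end
    repeat {
      grew <- FALSE
      nl <- max(0, left - step)
      if (nl < left && win_gc(nl, left) <= gc_ceiling &&
          (right - nl) <= max_core_len) {
        left <- nl; grew <- TRUE
      }
      nr <- min(L, right + step)
      if (nr > right && win_gc(right, nr) <= gc_ceiling &&
          (nr - left) <= max_core_len) {
        right <- nr; grew <- TRUE
      }
      if (!grew) break
    }
    core <- c(left, right)
  }
  # cap, trimming around the trough midpoint
  if (core[2] - core[1] > max_core_len) {
    mid <- (trough$start + trough$end) / 2
    half <- max_core_len / 2
    lo <- max(core[1], round(mid - half))
    hi <- lo + max_core_len
    if (hi > core[2]) { hi <- core[2]; lo <- hi - max_core_len }
    core <- c(lo, hi)
  }
  core_seq <- substr(seq, core[1] + 1, core[2])
  structure(list(
    interval = intervals(trough$chrom, core[1], core[2], name = "core"),
    gc_percent = 100 * gc_fraction(core_seq),
    method = method), class = "core_call")
}

#' Predict one centromere per chromosome from the GC landscape
#'
#' Runs [gc_profile()], [find_gc_trough()] and [delineate_core()] on every
#' chromosome and returns one core call per chromosome. Chromosomes are
#' assumed monocentric; `runners_up` lists the next lowest windows per
#' chromosome for QC.
#'
#' @param genome DNAStringSet, named character vector, or FASTA path.
#' @param genes optional interval data frame of gene bodies (all
#'   chromosomes).
#' @param window,step,mask_n_fraction see [gc_profile()].
#' @param max_core_len,gc_ceiling see [delineate_core()].
#' @param runners_up report the `k` next-lowest windows per chromosome
#'   (default 0).
#' @return data frame with one row per chromosome: `chrom`, `core_start`,
#'   `core_end` (0-based half-open), `core_len`, `core_gc_percent`,
#'   `trough_start`, `trough_gc_percent`, `method`. Attributes:
#'   `genome_gc_percent`, and `runners_up` when requested.
#' @export
predict_centromeres <- function(genome, genes = NULL, window = 250L,
                                step = window, mask_n_fraction = 0.5,
                                max_core_len = 1500L, gc_ceiling = NULL,
                                runners_up = 0L) {
  chars <- as_genome_chars(genome)
  genome_gc <- gc_fraction(chars)
  if (is.null(gc_ceiling)) gc_ceiling <- genome_gc - 0.15
  rows <- list()
  extra <- list()
  for (ch in names(chars)) {
    prof <- gc_profile(chars[[ch]], ch, window = window, step = step,
                       mask_n_fraction = mask_n_fraction)
    trough <- find_gc_trough(prof)
    call <- delineate_core(chars[[ch]], trough, genes = genes,
                           max_core_len = max_core_len,
                           gc_ceiling = gc_ceiling, genome_gc = genome_gc)
    rows[[ch]] <- data.frame(
      chrom = ch,
      core_start = call$interval$start,
      core_end = call$interval$end,
      core_len = call$interval$end - call$interval$start,
      core_gc_percent = call$gc_percent,
      trough_start = trough$start,
      trough_gc_percent = 100 * trough$score,
      method = call$method,
      stringsAsFactors = FALSE)
    if (runners_up > 0) {
      ord <- order(prof$gc, prof$starts, na.last = NA)
      k <- ord[seq_len(min(runners_up + 1, length(ord)))][-1]
      if (length(k)) {
        extra[[ch]] <- data.frame(chrom = ch, window_start = prof$starts[k],
                                  gc_percent = 100 * prof$gc[k])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "genome_gc_percent") <- 100 * genome_gc
  if (runners_up > 0) attr(out, "runners_up") <- do.call(rbind, extra)
  out
}
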