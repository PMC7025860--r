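# Synteny blocks between two genomes and classification of centromere
# fates. A centromere of genome A is looked up in genome B through the
# orthologs of its flanking genes: if both flanks land around a called
# centromere of B the centromere is conserved; flanks split across two B
# chromosomes mark a breakpoint (centromere loss by breakage); flanks
# contiguous on one B chromosome with no called centromere between them mark
# an inactivated centromere (sequence divergence eroded the AT-rich core).

#' Build collinear synteny blocks from ortholog pairs
#'
#' Chains ortholog anchors that are collinear in both genomes, in the same
#' or inverted orientation, allowing up to `max_gap_genes` skipped genes
#' between consecutive anchors on either genome. Gene order is taken from
#' the anchor coordinates themselves.
#'
#' @param pairs data frame of one-to-one ortholog pairs with columns
#'   `gene_a`, `chrom_a`, `start_a`, `end_a`, `gene_b`, `chrom_b`,
#'   `start_b`, `end_b`, `identity` (see [read_ortholog_pairs()]).
#' @param max_gap_genes maximum number of unmatched genes tolerated between
#'   consecutive anchors (default 3).
#' @return list with `blocks` (data frame: `block_id`, `chrom_a`,
#'   `a_start`, `a_end`, `chrom_b`, `b_start`, `b_end`, `n_anchors`,
#'   `orientation`) and `anchors` (`pairs` with a `block_id` column).
#' @export
build_blocks <- function(pairs, max_gap_genes = 3L) {
  need <- c("gene_a", "chrom_a", "start_a", "end_a",
            "gene_b", "chrom_b", "start_b", "end_b")
  stopifnot(all(need %in% names(pairs)))
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b)) {
    stop("duplicate gene IDs: ortholog pairs must be one-to-one")
  }
  if (nrow(pairs) == 0) {
    return(list(blocks = data.frame(), anchors = pairs))
  }
  # gene rank along each chromosome of each genome
  ord_a <- order(pairs$chrom_a, pairs$start_a)
  pairs$rank_a <- NA_integer_
  pairs$rank_a[ord_a] <- stats::ave(seq_along(ord_a),
                                    pairs$chrom_a[ord_a],
                                    FUN = seq_along)
  ord_b <- order(pairs$chrom_b, pairs$start_b)
  pairs$rank_b <- NA_integer_
  pairs$rank_b[ord_b] <- stats::ave(seq_along(ord_b),
                                    pairs$chrom_b[ord_b],
                                    FUN = seq_along)

  p <- pairs[order(pairs$chrom_a, pairs$start_a), , drop = FALSE]
  n <- nrow(p)
  block_id <- integer(n)
  current <- 1L
  block_id[1] <- 1L
  orient <- 0L  # orientation of current block: 0 unset, +1, -1
  orientations <- list()
  for (i in seq_len(n)[-1]) {
    same_chroms <- p$chrom_a[i] == p$chrom_a[i - 1] &&
      p$chrom_b[i] == p$chrom_b[i - 1]
    new_block <- TRUE
    if (same_chroms) {
      da <- p$rank_a[i] - p$rank_a[i - 1]       # always >= 1
      db <- p$rank_b[i] - p$rank_b[i - 1]
      ok_gap <- (da - 1L) <= max_gap_genes && (abs(db) - 1L) <= max_gap_genes
      ok_dir <- db != 0 && (orient == 0L || sign(db) == orient)
      if (ok_gap && ok_dir) {
        new_block <- FALSE
        orient <- sign(db)
      }
    }
    if (new_block) {
      orientations[[current]] <- orient
      current <- current + 1L
      orient <- 0L
    }
    block_id[i] <- current
  }
  orientations[[current]] <- orient
  p$block_id <- block_id
  blocks <- do.call(rbind, lapply(split(p, p$block_id), function(b) {
    o <- orientations[[b$block_id[1]]]
    data.frame(block_id = b$block_id[1],
               chrom_a = b$chrom_a[1],
               a_start = min(b$start_a), a_end = max(b$end_a),
               chrom_b = b$chrom_b[1],
               b_start = min(b$start_b), b_end = max(b$end_b),
               n_anchors = nrow(b),
               orientation = if (o == 0L) "+" else c("-", "+", "+")[o + 2L],
               stringsAsFactors = FALSE)
  }))
  rownames(blocks) <- NULL
  p$rank_a <- NULL
  p$rank_b <- NULL
  list(blocks = blocks, anchors = p)
}

# Summarise one flank's landing site in genome B: majority chromosome and
# the span of the flank genes' orthologs on it.
flank_landing <- function(anchors, flank_genes) {
  hit <- anchors[anchors$gene_a %in% flank_genes, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  tab <- sort(table(hit$chrom_b), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return(NULL)  # ambiguous
  ch <- names(tab)[1]
  on <- hit[hit$chrom_b == ch, , drop = FALSE]
  list(chrom = ch, start = min(on$start_b), end = max(on$end_b),
       n = nrow(on), blocks = sort(unique(on$block_id)))
}

#' Classify the fate of a centromere in a second genome
#'
#' Takes the `k_flank` annotated genes on each side of the centromere core
#' in genome A, locates their orthologs in genome B via the synteny anchors,
#' and applies the decision tree:
#'
#' * both flanks on one B chromosome and a called B centromere inside (or
#'   within `adjacency_tol` of) the intervening interval -> `"conserved"`;
#' * exactly one flank syntenic, within `adjacency_tol` of a called B
#'   centromere -> `"partial"`;
#' * flanks on two different B chromosomes -> `"breakpoint"` (the centromere
#'   DNA has no homologous region: loss by breakage);
#' * both flanks contiguous on one B chromosome but no called centromere in
#'   the intervening interval -> `"inactivated"` (the core diverged and lost
#'   its AT-richness, so it no longer draws a GC-trough call).
#'
#' @param cen one-row interval data frame for the genome-A centromere core.
#' @param genes_a interval data frame of genome-A genes (`name` column must
#'   match `gene_a` in the anchors).
#' @param synteny result of [build_blocks()].
#' @param target_cens interval data frame of called centromere cores in
#'   genome B.
#' @param k_flank genes taken on each side of the core (default 5).
#' @param adjacency_tol distance in bases within which B-spans are treated
#'   as one syntenic context (default 50000).
#' @return data frame row: `status` (one of conserved, partial, breakpoint,
#'   inactivated, insufficient_evidence) and `evidence` (text naming the
#'   landing chromosomes/spans and any matched centromere).
#' @export
classify_fate <- function(cen, genes_a, synteny, target_cens,
                          k_flank = 5L, adjacency_tol = 50000L) {
  stopifnot(nrow(cen) == 1)
  anchors <- synteny$anchors
  g <- genes_a[genes_a$chrom == cen$chrom, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  left_genes <- utils::tail(g$name[g$end <= cen$start], k_flank)
  right_genes <- utils::head(g$name[g$start >= cen$end], k_flank)
  if (length(left_genes) < k_flank || length(right_genes) < k_flank) {
    warning("fewer than ", k_flank, " annotated genes flanking ",
            cen$chrom, ":", cen$start, "-", cen$end)
    return(data.frame(status = "insufficient_evidence",
                      evidence = "unannotated flanks",
                      stringsAsFactors = FALSE))
  }
  left <- flank_landing(anchors, left_genes)
  right <- flank_landing(anchors, right_genes)

  near_cen <- function(chrom, lo, hi) {
    tc <- target_cens[target_cens$chrom == chrom, , drop = FALSE]
    if (nrow(tc) == 0) return(NA_character_)
    ok <- tc$start <= hi + adjacency_tol & tc$end >= lo - adjacency_tol
    if (!any(ok)) return(NA_character_)
    tc <- tc[ok, , drop = FALSE]
    sprintf("%s:%d-%d", tc$chrom[1], tc$start[1], tc$end[1])
  }
  span_txt <- function(s) sprintf("%s[%d-%d]", s$chrom, s$start, s$end)

  if (is.null(left) && is.null(right)) {
    return(data.frame(status = "insufficient_evidence",
                      evidence = "no syntenic flank in target genome",
                      stringsAsFactors = FALSE))
  }
  if (is.null(left) || is.null(right)) {
    s <- if (is.null(left)) right else left
    hit <- near_cen(s$chrom, s$start, s$end)
    if (!is.na(hit)) {
      return(data.frame(status = "partial",
                        evidence = paste0("one flank at ", span_txt(s),
                                          " near ", hit),
                        stringsAsFactors = FALSE))
    }
    return(data.frame(status = "insufficient_evidence",
                      evidence = paste0("single syntenic flank at ",
                                        span_txt(s), ", no centromere near"),
                      stringsAsFactors = FALSE))
  }
  ev <- paste0("left:", span_txt(left), " right:", span_txt(right))
  if (!identical(left$chrom, right$chrom)) {
    return(data.frame(status = "breakpoint", evidence = ev,
                      stringsAsFactors = FALSE))
  }
  # both flanks on one B chromosome: inspect the intervening interval
  lo <- min(left$end, right$end)
  hi <- max(left$start, right$start)
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  hit <- near_cen(left$chrom, lo, hi)
  if (!is.na(hit)) {
    return(data.frame(status = "conserved",
                      evidence = paste0(ev, " centromere ", hit),
                      stringsAsFactors = FALSE))
  }
  data.frame(status = "inactivated",
             evidence = paste0(ev, " no centromere in ",
                               sprintf("%s:%d-%d", left$chrom, lo, hi)),
             stringsAsFactors = FALSE)
}

#' Classify every genome-A centromere against genome B
#'
#' @param cens_a interval data frame of genome-A centromere cores (one row
#'   per chromosome).
#' @inheritParams classify_fate
#' @return data frame with `query_chrom`, `status`, `evidence` per
#'   centromere.
#' @export
classify_all_fates <- function(cens_a, genes_a, synteny, target_cens,
                               k_flank = 5L, adjacency_tol = 50000L) {
  rows <- lapply(seq_len(nrow(cens_a)), function(i) {
    fate <- classify_fate(cens_a[i, , drop = FALSE], genes_a, synteny,
                          target_cens, k_flank, adjacency_tol)
    cbind(data.frame(query_chrom = cens_a$chrom[i],
                     stringsAsFactors = FALSE), fate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
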