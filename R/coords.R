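# Interval plumbing and the package-wide coordinate contract.
#
# Everything public in this package uses 0-based half-open intervals
# [start, end), the BED convention. Published centromere tables use 1-based
# coordinates; the two converters below are total and mutually inverse, and
# are the only place the conventions meet.

#' Build a validated interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `name`, `score`, in 0-based half-open coordinates.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param start,end integer-like vectors, `0 <= start < end`.
#' @param name optional feature names (default `"."`).
#' @param score optional numeric scores (default `NA`).
#' @return a `data.frame` with one row per interval.
#' @export
#' @examples
#' intervals("chr1", 0, 10)
intervals <- function(chrom, start, end, name = ".", score = NA_real_) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = as.character(name),
                   score = as.numeric(score),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the 0-based half-open invariants (`0 <= start < end`) and, when
#' chromosome lengths are supplied, that every interval fits its chromosome.
#'
#' @param x data frame with `chrom`, `start`, `end` columns.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return `x`, invisibly; errors describe the first offending interval.
#' @export
validate_intervals <- function(x, chrom_lengths = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop(sprintf("invalid interval %s:%d-%d (need 0 <= start < end)",
                 x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_lengths))
    if (length(unknown)) stop("unknown chromosome: ", unknown[1])
    over <- which(x$end > chrom_lengths[x$chrom])
    if (length(over)) {
      stop(sprintf("interval %s:%d-%d exceeds chromosome length %d",
                   x$chrom[over[1]], x$start[over[1]], x$end[over[1]],
                   chrom_lengths[[x$chrom[over[1]]]]))
    }
  }
  invisible(x)
}

#' Convert published 1-based coordinates to internal 0-based half-open
#'
#' Published centromere tables print 1-based start coordinates whose lengths
#' satisfy `length = end - start`; the printed length is treated as
#' authoritative, so the conversion is `start - 1` with `end` unchanged.
#'
#' @param start,end 1-based published coordinates.
#' @return data frame with 0-based half-open `start`, `end`.
#' @seealso [internal_to_paper()] for the inverse.
#' @export
#' @examples
#' paper_to_internal(786541, 787061)  # -> 786540, 787061
paper_to_internal <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  data.frame(start = as.numeric(start) - 1, end = as.numeric(end))
}

#' Convert internal 0-based half-open coordinates to the published convention
#'
#' @param start,end 0-based half-open coordinates.
#' @return data frame with 1-based `start`, `end` as printed in centromere
#'   tables.
#' @export
internal_to_paper <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  data.frame(start = as.numeric(start) + 1, end = as.numeric(end))
}

intervals_to_granges <- function(x) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
  if ("name" %in% names(x)) gr$name <- x$name
  if ("score" %in% names(x)) gr$score <- x$score
  gr
}

granges_to_intervals <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  df$name <- if ("name" %in% names(mc)) as.character(mc$name) else "."
  df$score <- if ("score" %in% names(mc)) as.numeric(mc$score) else NA_real_
  df
}
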