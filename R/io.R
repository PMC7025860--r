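# Readers and writers for the standard formats the pipeline touches.
# Sequence I/O goes through Biostrings, track/interval I/O through
# rtracklayer; this file only enforces the package's coordinate and
# validation contracts on top of them.

#' Read a genome from FASTA
#'
#' Loads every record, uppercases the sequence, and checks the headers are
#' usable as unique chromosome identifiers. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) {
                  stop("malformed FASTA in ", path, ": ",
                       conditionMessage(e), call. = FALSE)
                })
  if (length(x) == 0) stop("no FASTA records in ", path)
  # keep only the first whitespace-delimited token of each header
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop("duplicated FASTA record name: ", names(x)[duplicated(names(x))][1])
  }
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write a genome to FASTA
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  chars <- as_genome_chars(genome)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(chars), filepath = path)
  invisible(path)
}

#' Construct a coverage track
#'
#' A coverage track holds one non-negative read-depth value per fixed-size
#' bin along a chromosome.
#'
#' @param chrom_id chromosome identifier.
#' @param bin_size bin width in bases.
#' @param values numeric vector, one value per bin, all `>= 0`.
#' @param chrom_length optional chromosome length; when given, checks
#'   `length(values) == ceiling(chrom_length / bin_size)`.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(chrom_id, bin_size, values, chrom_length = NULL) {
  stopifnot(length(chrom_id) == 1L, bin_size >= 1, is.numeric(values))
  if (any(values < 0)) stop("coverage values must be non-negative")
  if (!is.null(chrom_length) &&
      length(values) != ceiling(chrom_length / bin_size)) {
    stop("coverage track for ", chrom_id, " has ", length(values),
         " bins; expected ", ceiling(chrom_length / bin_size))
  }
  structure(list(chrom_id = as.character(chrom_id),
                 bin_size = as.integer(bin_size),
                 values = as.numeric(values)),
            class = "coverage_track")
}

#' Read per-base coverage tracks from a bedGraph file
#'
#' Expands a 4-column bedGraph into one per-base (`bin_size = 1`) track per
#' chromosome in `chrom_lengths`; positions not covered by any interval get
#' zero. Intervals must be non-overlapping and fit their chromosome.
#'
#' @param path path to a bedGraph file.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return named list of [coverage_track()] objects, one per chromosome.
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)))
  empty <- file.size(path) == 0
  gr <- if (empty) {
    GenomicRanges::GRanges()
  } else {
    tryCatch(rtracklayer::import(path, format = "bedGraph"),
             error = function(e) {
               stop("malformed bedGraph in ", path, ": ",
                    conditionMessage(e), call. = FALSE)
             })
  }
  if (length(gr)) {
    df <- granges_to_intervals(gr)
    unknown <- setdiff(unique(df$chrom), names(chrom_lengths))
    if (length(unknown)) {
      stop("bedGraph interval on unknown chromosome: ", unknown[1])
    }
    over <- which(df$end > chrom_lengths[df$chrom])
    if (length(over)) {
      i <- over[1]
      stop(sprintf("bedGraph interval %s:%d-%d exceeds chromosome length %d",
                   df$chrom[i], df$start[i], df$end[i],
                   chrom_lengths[[df$chrom[i]]]))
    }
    for (ch in unique(df$chrom)) {
      sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
      if (!IRanges::isDisjoint(GenomicRanges::ranges(sub))) {
        stop("overlapping bedGraph intervals on ", ch)
      }
    }
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    if (length(gr)) {
      sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
      if (length(sub)) {
        s <- GenomicRanges::start(sub)  # 1-based
        e <- GenomicRanges::end(sub)
        for (i in seq_along(sub)) v[s[i]:e[i]] <- sub$score[i]
      }
    }
    coverage_track(ch, 1L, v, chrom_length = chrom_lengths[[ch]])
  })
  names(out) <- names(chrom_lengths)
  out
}

#' Write coverage tracks to a bedGraph file
#'
#' Runs of equal values are collapsed; zero runs are omitted.
#'
#' @param tracks a [coverage_track()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    r <- rle(tr$values)
    ends <- cumsum(r$lengths)            # in bins
    starts <- ends - r$lengths           # 0-based
    keep <- r$values != 0
    data.frame(chrom = tr$chrom_id,
               start = starts[keep] * tr$bin_size,
               end = ends[keep] * tr$bin_size,
               score = r$values[keep])
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end),
                               score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a BED file into an interval table
#'
#' @param path path to a BED file.
#' @return interval data frame (0-based half-open), see [intervals()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) {
                   stop("malformed BED in ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  granges_to_intervals(gr)
}

#' Write an interval table to BED
#'
#' Output is standard BED: 0-based half-open, tab-separated, one line per
#' interval, with name and score columns when present.
#'
#' @param x interval data frame, see [intervals()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' write_bed(intervals("c1", 0, 10, name = "cen"), tf)
#' readLines(tf)
write_bed <- function(x, path) {
  validate_intervals(x)
  gr <- intervals_to_granges(x)
  if (!"name" %in% names(S4Vectors::mcols(gr))) gr$name <- "."
  gr$name[is.na(gr$name)] <- "."
  if ("score" %in% names(S4Vectors::mcols(gr)) && all(is.na(gr$score))) {
    gr$score <- NULL
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read an ortholog pair table
#'
#' Tab-separated with one header line and columns `gene_a`, `chrom_a`,
#' `start_a`, `end_a`, `gene_b`, `chrom_b`, `start_b`, `end_b`, `identity`.
#' Coordinates are 0-based half-open.
#'
#' @param path path to the TSV.
#' @return data frame of ortholog pairs.
#' @export
read_ortholog_pairs <- function(path) {
  need <- c("gene_a", "chrom_a", "start_a", "end_a",
            "gene_b", "chrom_b", "start_b", "end_b", "identity")
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("ortholog table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df[need]
}
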