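# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Map a DNA string to integer codes 1..4 (A,C,G,T); anything else (N, gap)
# becomes NA. Works on plain characters; Biostrings objects are converted.
dna_codes <- function(seq) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L)
  raw <- utf8ToInt(toupper(seq))
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut[raw]
}

codes_to_dna <- function(codes) {
  chars <- c(utf8ToInt("A"), utf8ToInt("C"), utf8ToInt("G"), utf8ToInt("T"),
             utf8ToInt("N"))
  codes[is.na(codes)] <- 5L
  intToUtf8(chars[codes])
}

# Complement in code space: A<->T, C<->G.
complement_codes <- function(codes) 5L - codes

revcomp_string <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Draw an i.i.d. DNA string of length n at the given GC fraction (A=T, C=G).
random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes_to_dna(sample.int(4L, n, replace = TRUE, prob = p))
}

# Run expr under a fixed RNG seed without disturbing the caller's RNG state.
# A NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Coerce a genome argument (DNAStringSet, named character vector, or FASTA
# path) to a named uppercase character vector of chromosome sequences.
as_genome_chars <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTN]+$", genome)) {
    genome <- read_genome_fasta(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else {
    stop("genome must be a DNAStringSet, a named character vector, ",
         "or a FASTA path")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("every chromosome must be named")
  }
  if (anyDuplicated(names(out))) stop("duplicated chromosome names")
  out
}

chrom_lengths <- function(genome) {
  vapply(as_genome_chars(genome), nchar, integer(1))
}
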