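# Seeded generators that emulate the statistical structure the analysis
# assumes: GC-rich background chromosomes, one AT-rich sub-kilobase core per
# chromosome carrying planted 12-bp motif instances, gene annotations tiling
# the chromosome arms, simulated IP/input ChIP coverage over each core, and
# the two rearrangement mechanisms (centromere loss by breakage; chromosome
# fusion followed by centromere inactivation). Every generator is
# seed-deterministic and emits a truth table for the planted features.

#' The default 12-bp AT-rich centromere motif PWM
#'
#' A fixed position probability matrix used by the synthetic-genome
#' generator. The consensus `ATTAATTTTAAT` alternates A- and T-dominated
#' columns (consensus probability 0.88, the complementary AT base 0.02,
#' 0.05 per G/C). The columns are individually sharp but compositionally
#' alike, so planted instances score well above the scanning threshold
#' against a GC-rich background, generic AT-rich sequence mostly does not,
#' and the column-shuffled matrix -- which keeps the composition but
#' scrambles which position wants A versus T -- loses the planted sites.
#'
#' @return a `pwm` object of width 12.
#' @export
default_motif_pwm <- function() {
  consensus <- c("A", "T", "T", "A", "A", "T", "T", "T", "T", "A", "A", "T")
  probs <- vapply(consensus, function(b) {
    p <- c(A = 0.05, C = 0.05, G = 0.05, T = 0.05)
    p[b] <- 0.88
    p[if (b == "A") "T" else "A"] <- 0.02
    p[DNA_BASES]
  }, numeric(4))
  new_pwm(probs, pseudocount = 0.5, background = rep(0.25, 4))
}

#' Specification of a synthetic genome
#'
#' Defaults emulate the study system: nine 300-kb chromosomes of background
#' GC 58.5% each carrying one 800-bp core at AT 80% with 7-13 planted motif
#' instances, flanked by genes with lognormal lengths.
#'
#' @param n_chrom number of chromosomes (default 9, `>= 2`).
#' @param chrom_len chromosome length in bases (default 300000).
#' @param background_gc background GC fraction (default 0.585).
#' @param core_len AT-rich core length in bases (default 800).
#' @param core_at core AT fraction (default 0.80; must exceed the
#'   background AT fraction).
#' @param n_motif_range integer range of planted motif instances per core
#'   (default `c(7, 13)`).
#' @param motif_pwm PWM the planted instances are sampled from (default
#'   [default_motif_pwm()]); sampling rather than planting the consensus
#'   makes LLR score variation realistic.
#' @param core_margin_frac cores are placed at least this fraction of the
#'   chromosome length away from either end (default 0.1).
#' @param gene_len_meanlog,gene_len_sdlog lognormal gene length parameters
#'   (default `log(1400)`, 0.25: compact, gene-dense genomes).
#' @param intergenic_meanlog,intergenic_sdlog lognormal intergenic length
#'   parameters (default `log(350)`, 0.4).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chrom = 9L, chrom_len = 300000L,
                           background_gc = 0.585, core_len = 800L,
                           core_at = 0.80, n_motif_range = c(7L, 13L),
                           motif_pwm = default_motif_pwm(),
                           core_margin_frac = 0.1,
                           gene_len_meanlog = log(1400),
                           gene_len_sdlog = 0.25,
                           intergenic_meanlog = log(350),
                           intergenic_sdlog = 0.4) {
  stopifnot(n_chrom >= 2, chrom_len > 0, background_gc > 0,
            background_gc < 1, core_at > 1 - background_gc,
            length(n_motif_range) == 2, n_motif_range[1] >= 1,
            n_motif_range[2] >= n_motif_range[1],
            inherits(motif_pwm, "pwm"))
  if (core_len + n_motif_range[2] * motif_pwm$width > chrom_len) {
    stop("core and planted sites do not fit in the chromosome")
  }
  if (n_motif_range[2] * motif_pwm$width > core_len) {
    stop("planted sites do not fit in the core")
  }
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_len = as.integer(chrom_len),
                 background_gc = background_gc, core_len = as.integer(core_len),
                 core_at = core_at,
                 n_motif_range = as.integer(n_motif_range),
                 motif_pwm = motif_pwm,
                 core_margin_frac = core_margin_frac,
                 gene_len_meanlog = gene_len_meanlog,
                 gene_len_sdlog = gene_len_sdlog,
                 intergenic_meanlog = intergenic_meanlog,
                 intergenic_sdlog = intergenic_sdlog),
            class = "synthetic_spec")
}

sample_pwm_instance <- function(pwm) {
  codes <- vapply(seq_len(pwm$width), function(i) {
    sample.int(4L, 1L, prob = pwm$probs[, i])
  }, integer(1))
  codes_to_dna(codes)
}

# Tile genes outward from the core on both sides; returns an interval df.
tile_genes <- function(spec, chrom, core_start, core_end, chrom_len) {
  draw_len <- function() max(150, round(rlnorm(1, spec$gene_len_meanlog,
                                               spec$gene_len_sdlog)))
  draw_gap <- function() max(50, round(rlnorm(1, spec$intergenic_meanlog,
                                              spec$intergenic_sdlog)))
  left <- list(); pos <- core_start
  repeat {
    gap <- draw_gap(); len <- draw_len()
    e <- pos - gap; s <- e - len
    if (s < 0) break
    left[[length(left) + 1L]] <- c(s, e)
    pos <- s
  }
  right <- list(); pos <- core_end
  repeat {
    gap <- draw_gap(); len <- draw_len()
    s <- pos + gap; e <- s + len
    if (e > chrom_len) break
    right[[length(right) + 1L]] <- c(s, e)
    pos <- e
  }
  coords <- c(rev(left), right)
  if (!length(coords)) {
    return(intervals(character(0), numeric(0), numeric(0) + 1))
  }
  m <- do.call(rbind, coords)
  n <- nrow(m)
  intervals(rep(chrom, n), m[, 1], m[, 2],
            name = sprintf("%s_g%03d", chrom, seq_len(n)),
            score = NA_real_)
}

#' Generate a synthetic genome with planted centromeres
#'
#' Background sequence is drawn i.i.d. at `background_gc`; each chromosome
#' gets one core drawn i.i.d. at `core_at` at a uniform-random interior
#' position, with `n ~ uniform(n_motif_range)` motif instances sampled from
#' `motif_pwm` planted at non-overlapping positions on random strands; genes
#' tile both flanks up to the chromosome ends.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; the same seed reproduces the genome
#'   byte-identically.
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `truth`:
#'   `cores` (interval df), `sites` (df with `chrom`, `pos`, `strand`,
#'   `instance`), `genes` (interval df), `events` (empty list, appended to
#'   by the rearrangement operators).
#' @export
generate_genome <- function(spec = synthetic_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    chroms <- sprintf("chr%d", seq_len(spec$n_chrom))
    seqs <- character(spec$n_chrom)
    cores <- list(); sites <- list(); genes <- list()
    margin <- ceiling(spec$core_margin_frac * spec$chrom_len)
    width <- spec$motif_pwm$width
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      seq <- random_dna(spec$chrom_len, spec$background_gc)
      core_start <- sample.int(spec$chrom_len - 2L * margin -
                                 spec$core_len + 1L, 1L) + margin - 1L
      core_end <- core_start + spec$core_len
      core_seq <- random_dna(spec$core_len, 1 - spec$core_at)
      n_sites <- sample(spec$n_motif_range[1]:spec$n_motif_range[2], 1L)
      # non-overlapping 0-based offsets within the core
      repeat {
        offs <- sort(sample.int(spec$core_len - width + 1L, n_sites) - 1L)
        if (all(diff(offs) >= width)) break
      }
      strands <- sample(c("+", "-"), n_sites, replace = TRUE)
      for (k in seq_len(n_sites)) {
        inst <- sample_pwm_instance(spec$motif_pwm)
        planted <- if (strands[k] == "+") inst else revcomp_string(inst)
        substr(core_seq, offs[k] + 1L, offs[k] + width) <- planted
        sites[[length(sites) + 1L]] <- data.frame(
          chrom = ch, pos = core_start + offs[k], strand = strands[k],
          instance = inst, stringsAsFactors = FALSE)
      }
      substr(seq, core_start + 1L, core_end) <- core_seq
      seqs[ci] <- seq
      cores[[ci]] <- intervals(ch, core_start, core_end, name = "core")
      genes[[ci]] <- tile_genes(spec, ch, core_start, core_end,
                                spec$chrom_len)
    }
    genome <- Biostrings::DNAStringSet(setNames(seqs, chroms))
    truth <- list(cores = do.call(rbind, cores),
                  sites = do.call(rbind, sites),
                  genes = do.call(rbind, genes),
                  events = list())
    list(genome = genome, truth = truth)
  })
}

#' Simulate IP and input ChIP coverage over planted centromeres
#'
#' Input bins are `Poisson(depth)`; IP bins are `Poisson(depth * f)` where
#' `f = fold` across a `full_width` window centred on each truth core
#' (proportional at partially covered bins) and 1 elsewhere. The simulated
#' kinetochore-bound region is recorded in the returned truth intervals.
#'
#' @param genome genome the tracks are simulated for (chromosome names and
#'   lengths are taken from it).
#' @param truth truth table from [generate_genome()] (uses `cores`).
#' @param fold enrichment fold over the bound region (default 20, `>= 1`).
#' @param depth expected input reads per bin (default 30).
#' @param full_width width in bases of the bound region (default 4000).
#' @param bin_size track bin size in bases (default 100).
#' @param seed integer seed.
#' @return list with `ip` and `input` (named lists of [coverage_track()])
#'   and `full_regions` (interval df of the simulated bound regions).
#' @export
simulate_chip <- function(genome, truth, fold = 20, depth = 30,
                          full_width = 4000L, bin_size = 100L, seed = 1L) {
  stopifnot(fold >= 1, depth > 0)
  lens <- chrom_lengths(genome)
  with_seed(seed, {
    ip <- list(); input <- list(); regions <- list()
    for (ch in names(lens)) {
      L <- lens[[ch]]
      nbins <- ceiling(L / bin_size)
      mult <- rep(1, nbins)
      core <- truth$cores[truth$cores$chrom == ch, , drop = FALSE]
      if (nrow(core) == 1) {
        centre <- (core$start + core$end) / 2
        lo <- max(0, centre - full_width / 2)
        hi <- min(L, centre + full_width / 2)
        regions[[ch]] <- intervals(ch, lo, hi, name = "full_region")
        bin_lo <- pmax((seq_len(nbins) - 1) * bin_size, lo)
        bin_hi <- pmin(seq_len(nbins) * bin_size, hi)
        frac <- pmax(0, bin_hi - bin_lo) / bin_size
        mult <- 1 + (fold - 1) * frac
      }
      input[[ch]] <- coverage_track(ch, bin_size, rpois(nbins, depth),
                                    chrom_length = L)
      ip[[ch]] <- coverage_track(ch, bin_size, rpois(nbins, depth * mult),
                                 chrom_length = L)
    }
    list(ip = ip, input = input,
         full_regions = do.call(rbind, regions))
  })
}

shift_features <- function(df, chrom_from, chrom_to, offset,
                           keep = NULL, cols = c("start", "end")) {
  sel <- df$chrom == chrom_from
  if (!is.null(keep)) sel <- sel & keep
  out <- df[sel, , drop = FALSE]
  out$chrom <- chrom_to
  for (cl in intersect(cols, names(out))) out[[cl]] <- out[[cl]] + offset
  out
}

#' Reduce the chromosome number by centromere breakage
#'
#' Splits the donor chromosome at its centromere core, deletes the core
#' sequence (the centromere DNA is lost), and fuses the two acentric arms to
#' the ends of two other chromosomes: the left arm to the right end of
#' `acceptor_left`, the right arm to the left end of `acceptor_right`. No
#' scar sequence is inserted at the junctions. The chromosome count drops by
#' exactly one and the event is logged in the truth table.
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector.
#' @param truth truth table from [generate_genome()].
#' @param donor,acceptor_left,acceptor_right chromosome names; all three
#'   must be distinct.
#' @return list with updated `genome` and `truth`.
#' @export
apply_breakage <- function(genome, truth, donor, acceptor_left,
                           acceptor_right) {
  chars <- as_genome_chars(genome)
  stopifnot(donor %in% names(chars), acceptor_left %in% names(chars),
            acceptor_right %in% names(chars))
  if (donor == acceptor_left || donor == acceptor_right ||
      acceptor_left == acceptor_right) {
    stop("donor and the two acceptors must be distinct chromosomes")
  }
  core <- truth$cores[truth$cores$chrom == donor, , drop = FALSE]
  if (nrow(core) != 1) stop("donor ", donor, " has no truth core")
  left_arm <- substr(chars[[donor]], 1, core$start)
  right_arm <- substr(chars[[donor]], core$end + 1, nchar(chars[[donor]]))
  len_al <- nchar(chars[[acceptor_left]])
  len_ra <- nchar(right_arm)

  out <- chars[setdiff(names(chars), donor)]
  out[[acceptor_left]] <- paste0(chars[[acceptor_left]], left_arm)
  out[[acceptor_right]] <- paste0(right_arm, chars[[acceptor_right]])

  move <- function(df) {
    keep <- df[!(df$chrom %in% c(donor, acceptor_right)), , drop = FALSE]
    from_left <- shift_features(df, donor, acceptor_left, len_al,
                                keep = df$end <= core$start)
    from_right <- shift_features(df, donor, acceptor_right, -core$end,
                                 keep = df$start >= core$end)
    shifted_ar <- shift_features(df, acceptor_right, acceptor_right, len_ra)
    rbind(keep, from_left, from_right, shifted_ar)
  }
  truth$genes <- move(truth$genes)
  cores2 <- truth$cores[!(truth$cores$chrom %in%
                            c(donor, acceptor_right)), , drop = FALSE]
  cores2 <- rbind(cores2, shift_features(truth$cores, acceptor_right,
                                         acceptor_right, len_ra))
  truth$cores <- cores2[order(match(cores2$chrom, names(out))), ,
                        drop = FALSE]
  sites <- truth$sites
  keep_sites <- sites[!(sites$chrom %in% c(donor, acceptor_right)), ,
                      drop = FALSE]
  moved_sites <- shift_features(sites, acceptor_right, acceptor_right,
                                len_ra, cols = "pos")
  truth$sites <- rbind(keep_sites, moved_sites)
  truth$events <- c(truth$events, list(list(
    type = "breakage", donor = donor, acceptor_left = acceptor_left,
    acceptor_right = acceptor_right,
    lost_core = core)))
  list(genome = Biostrings::DNAStringSet(unlist(out)), truth = truth)
}

#' Reduce the chromosome number by fusion and centromere inactivation
#'
#' Joins two chromosomes end to end (`chrom_i` then `chrom_j`, no scar
#' sequence at the junction) and inactivates the designated core by
#' replacing its sequence with a same-length i.i.d. draw at `background_gc`,
#' modelling the erosion of AT-richness and motif content that accompanies
#' centromere inactivation. The surviving core is untouched. The chromosome
#' count drops by exactly one.
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector.
#' @param truth truth table from [generate_genome()].
#' @param chrom_i,chrom_j chromosomes to fuse (`chrom_i != chrom_j`).
#' @param inactivate which core to erode: `"i"` or `"j"`.
#' @param background_gc GC fraction of the replacement sequence
#'   (default 0.585).
#' @param seed integer seed for the replacement draw.
#' @return list with updated `genome` and `truth`; the fused chromosome is
#'   named `"<chrom_i>-<chrom_j>"`.
#' @export
apply_fusion_inactivation <- function(genome, truth, chrom_i, chrom_j,
                                      inactivate = c("j", "i"),
                                      background_gc = 0.585, seed = 1L) {
  inactivate <- match.arg(inactivate)
  chars <- as_genome_chars(genome)
  stopifnot(chrom_i %in% names(chars), chrom_j %in% names(chars))
  if (chrom_i == chrom_j) stop("cannot fuse a chromosome with itself")
  len_i <- nchar(chars[[chrom_i]])
  fused_name <- paste0(chrom_i, "-", chrom_j)
  fused <- paste0(chars[[chrom_i]], chars[[chrom_j]])

  dead_chrom <- if (inactivate == "i") chrom_i else chrom_j
  core <- truth$cores[truth$cores$chrom == dead_chrom, , drop = FALSE]
  if (nrow(core) != 1) stop(dead_chrom, " has no truth core")
  off <- if (inactivate == "i") 0 else len_i
  dead <- c(core$start, core$end) + off
  replacement <- with_seed(seed,
                           random_dna(core$end - core$start, background_gc))
  substr(fused, dead[1] + 1, dead[2]) <- replacement

  out <- chars[setdiff(names(chars), c(chrom_i, chrom_j))]
  out[[fused_name]] <- fused

  remap <- function(df, cols = c("start", "end")) {
    keep <- df[!(df$chrom %in% c(chrom_i, chrom_j)), , drop = FALSE]
    from_i <- shift_features(df, chrom_i, fused_name, 0, cols = cols)
    from_j <- shift_features(df, chrom_j, fused_name, len_i, cols = cols)
    rbind(keep, from_i, from_j)
  }
  truth$genes <- remap(truth$genes)
  cores2 <- remap(truth$cores)
  surv <- !(cores2$chrom == fused_name &
              cores2$start == dead[1] & cores2$end == dead[2])
  truth$cores <- cores2[surv, , drop = FALSE]
  sites2 <- remap(truth$sites, cols = "pos")
  in_dead <- sites2$chrom == fused_name & sites2$pos >= dead[1] &
    sites2$pos < dead[2]
  truth$sites <- sites2[!in_dead, , drop = FALSE]
  truth$events <- c(truth$events, list(list(
    type = "fusion_inactivation", chrom_i = chrom_i, chrom_j = chrom_j,
    fused = fused_name, inactivated = dead_chrom,
    eroded_interval = intervals(fused_name, dead[1], dead[2],
                                name = "eroded_core"))))
  list(genome = Biostrings::DNAStringSet(unlist(out)), truth = truth)
}

#' Ortholog pairs between a genome and a rearranged derivative
#'
#' The rearrangement operators track gene coordinates through every event,
#' so orthologs between the ancestral and derived genome are simply the
#' genes present in both truth tables, matched by name.
#'
#' @param truth_a,truth_b truth tables (use `genes`).
#' @param identity percent identity to assign (default 100).
#' @return ortholog pair data frame, see [read_ortholog_pairs()].
#' @export
truth_ortholog_pairs <- function(truth_a, truth_b, identity = 100) {
  a <- truth_a$genes
  b <- truth_b$genes
  common <- intersect(a$name, b$name)
  ia <- match(common, a$name)
  ib <- match(common, b$name)
  data.frame(gene_a = common,
             chrom_a = a$chrom[ia], start_a = a$start[ia], end_a = a$end[ia],
             gene_b = common,
             chrom_b = b$chrom[ib], start_b = b$start[ib], end_b = b$end[ib],
             identity = identity, stringsAsFactors = FALSE)
}

#' Simulate qPCR threshold cycles for a locus
#'
#' Generates IP and input Ct values whose noiseless [percent_input()] equals
#' `true_percent`, with Gaussian noise of `noise_sd` cycles added to each
#' measured Ct.
#'
#' @param true_percent true percent of input immunoprecipitated.
#' @param input_fraction input aliquot fraction (default 0.01).
#' @param ct_input mean input Ct (default 20 cycles).
#' @param noise_sd Ct noise standard deviation in cycles (default 0.2).
#' @param n technical replicates (default 3).
#' @param seed integer seed (optional).
#' @return data frame with `ct_ip`, `ct_input`, `input_fraction`.
#' @export
simulate_qpcr <- function(true_percent, input_fraction = 0.01,
                          ct_input = 20, noise_sd = 0.2, n = 3,
                          seed = NULL) {
  stopifnot(true_percent > 0)
  with_seed(seed, {
    delta <- log2(true_percent / (100 * input_fraction))
    data.frame(ct_ip = ct_input - delta + rnorm(n, 0, noise_sd),
               ct_input = ct_input + rnorm(n, 0, noise_sd),
               input_fraction = input_fraction)
  })
}
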