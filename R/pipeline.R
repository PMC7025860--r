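# Orchestration: the prediction report in the published-table convention,
# the full multi-stage run, YAML configuration, and the packaged worked
# example (the M. sympodialis centromere table).

#' Predict centromeres and report them in the published-table convention
#'
#' Runs [predict_centromeres()] and reports 1-based coordinates (the
#' convention of published centromere tables; BED output stays 0-based
#' half-open). One row per chromosome; the genome GC footer is carried as an
#' attribute.
#'
#' @inheritParams predict_centromeres
#' @param out optional path; when given, the report is written as TSV with
#'   a header comment naming the coordinate convention.
#' @return data frame of class `centromere_report` with columns `chrom`,
#'   `core_start`, `core_end` (1-based), `core_len`, `core_gc_percent`,
#'   `method`; attribute `genome_gc_percent`.
#' @export
run_predict <- function(genome, genes = NULL, window = 250L, step = window,
                        max_core_len = 1500L, gc_ceiling = NULL,
                        out = NULL) {
  calls <- predict_centromeres(genome, genes = genes, window = window,
                               step = step, max_core_len = max_core_len,
                               gc_ceiling = gc_ceiling)
  paper <- internal_to_paper(calls$core_start, calls$core_end)
  report <- data.frame(chrom = calls$chrom,
                       core_start = paper$start,
                       core_end = paper$end,
                       core_len = calls$core_len,
                       core_gc_percent = round(calls$core_gc_percent, 1),
                       method = calls$method,
                       stringsAsFactors = FALSE)
  attr(report, "genome_gc_percent") <- attr(calls, "genome_gc_percent")
  attr(report, "calls") <- calls
  class(report) <- c("centromere_report", "data.frame")
  if (!is.null(out)) {
    con <- file(out, "w")
    writeLines(paste0("# coordinates are 1-based; genome GC% = ",
                      round(attr(report, "genome_gc_percent"), 2)), con)
    write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  report
}

#' Mean, minimum and maximum centromere length
#'
#' @param lengths numeric vector of centromere lengths in bases.
#' @return list with `mean`, `min`, `max`.
#' @export
centromere_length_stats <- function(lengths) {
  stopifnot(is.numeric(lengths), length(lengths) > 0)
  list(mean = mean(lengths), min = min(lengths), max = max(lengths))
}

#' The packaged M. sympodialis centromere coordinate table
#'
#' Published coordinates (1-based) of the eight core centromeres and
#' Mtw1-bound full-length centromeres of *M. sympodialis*, with the printed
#' lengths and core GC percentages. Core printed lengths satisfy
#' `length = end - start`; the printed lengths are authoritative where the
#' conventions conflict (see [paper_to_internal()]).
#'
#' @return data frame with columns `chrom`, `core_start`, `core_end`,
#'   `core_len`, `core_gc_percent`, `full_start`, `full_end`, `full_len`;
#'   attribute `genome_gc_percent` (58.5).
#' @export
msy_centromere_table <- function() {
  path <- system.file("extdata", "msy_centromeres_table1.tsv",
                      package = "censcape", mustWork = TRUE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "genome_gc_percent") <- 58.5
  df
}

#' Read a run configuration from YAML
#'
#' Recognised keys: `fasta`, `genes`, `ip_bedgraph`, `input_bedgraph`,
#' `target_fasta`, `target_genes`, `ortholog_pairs`, `pwm_instances`,
#' `seed`, `out_dir`, and parameter blocks `gc` (window, step,
#' max_core_len), `scan` (llr_threshold, window, step), `chip`
#' (min_fraction_of_peak, merge_gap), `fate` (k_flank, adjacency_tol).
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("fasta", "genes", "ip_bedgraph", "input_bedgraph",
             "target_fasta", "target_genes", "ortholog_pairs",
             "pwm_instances", "seed", "out_dir", "gc", "scan", "chip",
             "fate")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Run the full centromere analysis
#'
#' Composes the stages: centromere prediction, PWM training from the called
#' cores, genome-wide motif window scanning with a shuffled-PWM control,
#' optional ChIP full-region calling, and optional fate classification
#' against a second genome. Stages whose inputs are absent are skipped and
#' noted in the summary.
#'
#' @param config list (or YAML path, see [read_run_config()]) with at least
#'   `fasta` (or `genome`: a DNAStringSet / named character vector).
#'   Optional: `genes` (interval df or GFF-like TSV path with chrom, start,
#'   end, name columns), `ip_bedgraph`/`input_bedgraph` (paths or track
#'   lists under `ip_tracks`/`input_tracks`), `target_genome` /
#'   `target_genes` / `ortholog_pairs` for fate classification, `seed`,
#'   `out_dir`, and the parameter blocks described in [read_run_config()].
#' @return list with `report`, `pwm`, `scan` (per-chromosome window counts
#'   and enrichment summaries, plus the shuffled control), `chip` (full
#'   region calls, when coverage given), `fates` (when a target genome
#'   given), and `summary` (plain list, also written as JSON when `out_dir`
#'   is set).
#' @export
run_full <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  stage <- "predict"
  result <- tryCatch({
    genome <- if (!is.null(config$genome)) as_genome_chars(config$genome)
              else as_genome_chars(read_genome_fasta(config$fasta))
    genes <- config$genes
    if (is.character(genes)) genes <- read.delim(genes,
                                                 stringsAsFactors = FALSE)
    gc_par <- config$gc
    report <- run_predict(genome, genes = genes,
                          window = gc_par$window %||% 250L,
                          step = gc_par$step %||% gc_par$window %||% 250L,
                          max_core_len = gc_par$max_core_len %||% 1500L)
    calls <- attr(report, "calls")

    stage <- "scan-motif"
    background <- genome_background(genome)
    core_seqs <- vapply(seq_len(nrow(calls)), function(i) {
      substr(genome[[calls$chrom[i]]], calls$core_start[i] + 1,
             calls$core_end[i])
    }, character(1))
    pwm <- if (!is.null(config$pwm_instances)) {
      build_pwm(config$pwm_instances, background = background)
    } else {
      train_pwm(core_seqs, background = background)
    }
    scan_par <- config$scan
    thr <- scan_par$llr_threshold %||% 7.5
    win <- scan_par$window %||% 500L
    stp <- scan_par$step %||% 100L
    shuffled <- shuffle_pwm(pwm, seed = seed)
    scan <- lapply(seq_len(nrow(calls)), function(i) {
      ch <- calls$chrom[i]
      cen <- intervals(ch, calls$core_start[i], calls$core_end[i])
      counts <- count_windows(genome[[ch]], pwm, ch, llr_threshold = thr,
                              window = win, step = stp)
      ctrl <- count_windows(genome[[ch]], shuffled, ch,
                            llr_threshold = thr, window = win, step = stp)
      list(chrom = ch, counts = counts,
           enrichment = motif_enrichment_report(counts, cen),
           control = motif_enrichment_report(ctrl, cen))
    })
    names(scan) <- calls$chrom

    stage <- "chip-call"
    chip <- NULL
    ip <- config$ip_tracks
    input <- config$input_tracks
    if (!is.null(config$ip_bedgraph) && !is.null(config$input_bedgraph)) {
      lens <- chrom_lengths(genome)
      ip <- read_bedgraph(config$ip_bedgraph, lens)
      input <- read_bedgraph(config$input_bedgraph, lens)
    }
    if (!is.null(ip) && !is.null(input)) {
      chip_par <- config$chip
      chip <- lapply(names(ip), function(ch) {
        prof <- subtract_input(ip[[ch]], input[[ch]])
        call_full_region(prof,
                         min_fraction_of_peak =
                           chip_par$min_fraction_of_peak %||% 0.1,
                         merge_gap = chip_par$merge_gap %||% 500L)
      })
      names(chip) <- names(ip)
    }

    stage <- "fate"
    fates <- NULL
    if (!is.null(config$target_genome) || !is.null(config$target_fasta)) {
      target <- if (!is.null(config$target_genome)) {
        as_genome_chars(config$target_genome)
      } else as_genome_chars(read_genome_fasta(config$target_fasta))
      pairs <- config$ortholog_pairs
      if (is.character(pairs)) pairs <- read_ortholog_pairs(pairs)
      if (is.null(pairs)) stop("fate stage needs ortholog_pairs")
      target_report <- run_predict(target,
                                   genes = config$target_genes,
                                   window = config$gc$window %||% 250L)
      target_calls <- attr(target_report, "calls")
      target_cens <- intervals(target_calls$chrom,
                               target_calls$core_start,
                               target_calls$core_end, name = "core")
      fate_par <- config$fate
      synteny <- build_blocks(pairs,
                              max_gap_genes = fate_par$max_gap_genes %||% 3L)
      cens_a <- intervals(calls$chrom, calls$core_start, calls$core_end,
                          name = "core")
      fates <- classify_all_fates(cens_a, genes, synteny, target_cens,
                                  k_flank = fate_par$k_flank %||% 5L,
                                  adjacency_tol =
                                    fate_par$adjacency_tol %||% 50000L)
    }

    summary <- list(
      n_chromosomes = nrow(report),
      genome_gc_percent = attr(report, "genome_gc_percent"),
      core_lengths = report$core_len,
      motif_cen_max = vapply(scan, function(s) s$enrichment$cen_max,
                             numeric(1)),
      motif_other_max = vapply(scan, function(s) s$enrichment$other_max,
                               numeric(1)),
      shuffled_cen_max = vapply(scan, function(s) s$control$cen_max,
                                numeric(1)),
      full_region_widths = if (is.null(chip)) NULL else
        vapply(chip, function(x) x$interval$end - x$interval$start,
               numeric(1)),
      fates = if (is.null(fates)) NULL else
        setNames(fates$status, fates$query_chrom),
      skipped = c(if (is.null(chip)) "chip-call",
                  if (is.null(fates)) "fate"),
      seed = seed)

    out <- list(report = report, pwm = pwm, scan = scan, chip = chip,
                fates = fates, summary = summary)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write.table(as.data.frame(report),
                  file.path(config$out_dir, "centromeres.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_bed(intervals(calls$chrom, calls$core_start, calls$core_end,
                          name = paste0("CEN_", calls$chrom)),
                file.path(config$out_dir, "centromeres.bed"))
      jsonlite::write_json(summary,
                           file.path(config$out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
    out
  }, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a
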