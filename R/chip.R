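# ChIP quantification: the kinetochore-bound region called from IP minus
# library-size-scaled input coverage, and the qPCR arithmetic used to report
# percent-of-input enrichment, fold difference over a control locus, and the
# histone H3:H4 depletion ratio at centromere cores.

#' Subtract scaled input coverage from IP coverage
#'
#' The input track is scaled to the IP library size
#' (`total IP / total input`) and subtracted bin by bin; negative bins are
#' floored at zero, since read counts cannot be negative evidence of
#' binding.
#'
#' @param ip,input [coverage_track()] objects on the same chromosome with
#'   the same binning; both must have positive totals.
#' @return object of class `enrichment_profile` with the same binning.
#' @export
subtract_input <- function(ip, input) {
  stopifnot(inherits(ip, "coverage_track"), inherits(input, "coverage_track"))
  if (!identical(ip$chrom_id, input$chrom_id)) {
    stop("IP is on ", ip$chrom_id, " but input is on ", input$chrom_id)
  }
  if (ip$bin_size != input$bin_size ||
      length(ip$values) != length(input$values)) {
    stop("IP and input tracks have mismatched binning")
  }
  tot_ip <- sum(ip$values)
  tot_in <- sum(input$values)
  if (tot_ip <= 0 || tot_in <= 0) stop("both tracks need positive totals")
  values <- pmax(0, ip$values - (tot_ip / tot_in) * input$values)
  structure(list(chrom_id = ip$chrom_id, bin_size = ip$bin_size,
                 values = values), class = "enrichment_profile")
}

#' Call the single enriched region of a chromosome
#'
#' Bins at or above `min_fraction_of_peak` times the chromosome's peak value
#' are thresholded, runs separated by at most `merge_gap` bases are merged,
#' and the run containing the summit (the maximal bin, leftmost on ties) is
#' returned. One call per chromosome: monocentric chromosomes carry a single
#' kinetochore-bound region.
#'
#' @param profile an [subtract_input()] enrichment profile with a positive
#'   maximum.
#' @param min_fraction_of_peak threshold as a fraction of the peak
#'   (default 0.1).
#' @param merge_gap maximum gap, in bases, bridged when merging runs
#'   (default 500).
#' @return object of class `full_region_call`: list with `interval`
#'   (one-row interval data frame in bases), `peak_height`, `summit`
#'   (0-based offset of the summit bin's midpoint).
#' @export
call_full_region <- function(profile, min_fraction_of_peak = 0.1,
                             merge_gap = 500L) {
  stopifnot(inherits(profile, "enrichment_profile"))
  v <- profile$values
  peak <- max(v)
  if (peak <= 0) {
    stop("no enrichment on ", profile$chrom_id, ": profile is all zero")
  }
  summit_bin <- which.max(v)
  above <- v >= min_fraction_of_peak * peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  gap_bins <- ceiling(merge_gap / profile$bin_size)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L <= gap_bins) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  hit <- which(merged$start <= summit_bin & merged$end >= summit_bin)
  run <- merged[hit[1], ]
  bs <- profile$bin_size
  interval <- intervals(profile$chrom_id, (run$start - 1) * bs,
                        min(run$end * bs, length(v) * bs),
                        name = "full_region", score = peak)
  structure(list(interval = interval, peak_height = peak,
                 summit = (summit_bin - 1) * bs + bs / 2),
            class = "full_region_call")
}

#' qPCR percent of input
#'
#' Standard delta-Ct arithmetic with amplification efficiency 2:
#' `100 * input_fraction * 2^(ct_input - ct_ip)`, where `input_fraction` is
#' the fraction of the sample kept aside as input.
#'
#' @param ct_ip,ct_input threshold cycles for the IP and input reactions.
#' @param input_fraction fraction of material in the input aliquot, in
#'   `(0, 1]`.
#' @return percent of input immunoprecipitated (vectorised).
#' @export
#' @examples
#' percent_input(20, 20, 1)    # 100
#' percent_input(19, 20, 1)    # 200: one cycle earlier = twice the DNA
percent_input <- function(ct_ip, ct_input, input_fraction) {
  stopifnot(all(input_fraction > 0), all(input_fraction <= 1),
            all(ct_ip > 0), all(ct_input > 0))
  100 * input_fraction * 2^(ct_input - ct_ip)
}

#' Ratio of two percent-of-input enrichments
#'
#' Used for the histone H3 : histone H4 depletion ratio at centromere cores
#' (values below 1 indicate H3 depletion, i.e. replacement by the
#' centromeric histone H3 variant).
#'
#' @param a,b percent-of-input values; `b` must be positive.
#' @return `a / b` (vectorised).
#' @export
relative_ratio <- function(a, b) {
  if (any(b == 0)) stop("relative ratio undefined: denominator is zero")
  a / b
}

#' Fold difference versus a control locus
#'
#' @param test,control percent-of-input values; `control` must be positive.
#' @return `test / control` (vectorised).
#' @export
fold_vs_control <- function(test, control) {
  if (any(control == 0)) stop("fold difference undefined: control is zero")
  test / control
}
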