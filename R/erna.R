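#' Detect per-condition candidate eRNA regions
#'
#' Runs the global-background Poisson peak caller (p = 1e-4, duplicates
#' kept) on the pooled, filtered RNA-seq reads of each condition. Regions
#' of intergenic read enrichment are the per-condition candidate
#' transcribed enhancers.
#'
#' @param reads_by_condition Named list (e.g. `WT`, `HD`) of filtered
#'   stranded read `GRanges` (each the pool of that condition's replicates).
#' @param peak_params A [peak_call_params()] object; if its `shift` is
#'   `NA`, the shift is estimated per condition with [estimate_shift()].
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return Named list of candidate-peak `GRanges`.
#' @export
detect_candidates <- function(reads_by_condition, peak_params, chrom_sizes) {
  stopifnot(length(reads_by_condition) >= 1, !is.null(names(reads_by_condition)))
  lapply(reads_by_condition, function(rd) {
    pp <- peak_params
    if (is.na(pp$shift)) pp$shift <- as.integer(estimate_shift(rd))
    call_peaks(rd, pp, chrom_sizes)
  })
}

#' Merge per-condition candidates into one unique region set
#'
#' Takes the union of all candidate intervals; candidates overlapping by at
#' least one base are merged into their spanning interval (adjacent but
#' non-overlapping intervals stay separate). Each merged region records
#' which conditions contributed.
#'
#' @param condition_sets Named list of candidate `GRanges`.
#' @return Unstranded `GRanges` with a `detected_in` character metadata
#'   column (comma-separated condition names).
#' @export
merge_candidates <- function(condition_sets) {
  stopifnot(length(condition_sets) >= 1, !is.null(names(condition_sets)))
  pooled <- do.call(c, unname(lapply(condition_sets, function(g) {
    g <- GenomicRanges::granges(g)
    GenomicRanges::strand(g) <- "*"
    S4Vectors::mcols(g) <- NULL
    g
  })))
  merged <- GenomicRanges::reduce(pooled, min.gapwidth = 0L,
                                  ignore.strand = TRUE)
  det <- matrix(FALSE, length(merged), length(condition_sets),
                dimnames = list(NULL, names(condition_sets)))
  for (cond in names(condition_sets))
    det[, cond] <- overlaps_any(merged, condition_sets[[cond]])
  merged$detected_in <- apply(det, 1, function(r)
    paste(colnames(det)[r], collapse = ","))
  sort(merged)
}

#' Vet candidate eRNA regions against H3K27ac islands
#'
#' Keeps candidates that overlap (>= 1 bp, strand ignored) an H3K27ac
#' island in either condition — the enhancer-mark filter that turns
#' transcribed intergenic regions into the eRNA catalogue. Support is
#' recorded per condition so stricter policies remain recoverable.
#'
#' @param candidates Merged candidate `GRanges` (from [merge_candidates()]).
#' @param islands_wt,islands_hd `GRanges` H3K27ac islands per condition.
#' @return `GRanges` catalogue with `erna_id` and `h3k27ac_support`
#'   metadata; attribute `"discarded"` holds the rejected candidates with
#'   a `reason` column.
#' @export
filter_by_h3k27ac <- function(candidates, islands_wt, islands_hd) {
  in_wt <- overlaps_any(candidates, islands_wt)
  in_hd <- overlaps_any(candidates, islands_hd)
  keep <- in_wt | in_hd
  out <- candidates[keep]
  out$h3k27ac_support <- paste0(ifelse(in_wt[keep], "WT", ""),
                                ifelse(in_wt[keep] & in_hd[keep], ",", ""),
                                ifelse(in_hd[keep], "HD", ""))
  out$erna_id <- sprintf("eRNA%05d", seq_along(out))
  disc <- candidates[!keep]
  if (length(disc)) disc$reason <- "no_h3k27ac_island"
  attr(out, "discarded") <- disc
  out
}
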