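#' Construct a set of genomic intervals
#'
#' Thin constructor around [GenomicRanges::GRanges] used throughout the
#' package. Intervals are 1-based, closed (the native GRanges convention);
#' BED input/output converts to and from the 0-based half-open convention
#' at the file boundary.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based closed coordinates,
#'   `start <= end` and width `end - start + 1 >= 1`.
#' @param strand Strand per interval: `"+"`, `"-"` or `"*"` (unstranded;
#'   `"."` is accepted and mapped to `"*"`).
#' @param ... Further metadata columns passed to `GRanges()`.
#' @return A `GRanges` object.
#' @export
intervals <- function(chrom, start, end, strand = "*", ...) {
  strand <- ifelse(strand == ".", "*", strand)
  if (any(end < start))
    stop("zero- or negative-width interval (end < start) at entry ",
         which(end < start)[1])
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, ...)
}

#' Sort intervals into canonical (chrom, start, end) order
#'
#' Normalisation sorts by chromosome name, then start, then end, ignoring
#' strand. It is idempotent and duplicates are retained.
#'
#' @param gr A `GRanges` object.
#' @return The same ranges in canonical order.
#' @export
normalize_intervals <- function(gr) {
  o <- order(as.character(GenomeInfoDb::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr[o]
}

#' Overlapping interval pairs with a minimum-overlap and strand rule
#'
#' Returns every pair `(i, j)` with `a[i]` overlapping `b[j]` by at least
#' `min_overlap` bases whose strand combination satisfies `strand_mode`:
#' `"ignore"` accepts any pair, `"same"` requires identical `+`/`-` strands,
#' `"opposite"` requires one `+` and one `-`. Unstranded (`*`) intervals
#' never satisfy `"same"` or `"opposite"`.
#'
#' @param a,b `GRanges` objects.
#' @param min_overlap Minimum overlap in bases (>= 1).
#' @param strand_mode One of `"ignore"`, `"same"`, `"opposite"`.
#' @return A data.frame with columns `a_idx`, `b_idx`, `overlap`.
#' @export
interval_pairs <- function(a, b, min_overlap = 1L,
                           strand_mode = c("ignore", "same", "opposite")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(min_overlap >= 1L)
  h <- GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap,
                                   ignore.strand = TRUE)
  ai <- S4Vectors::queryHits(h)
  bi <- S4Vectors::subjectHits(h)
  sa <- as.character(GenomicRanges::strand(a))[ai]
  sb <- as.character(GenomicRanges::strand(b))[bi]
  keep <- switch(strand_mode,
    ignore   = rep(TRUE, length(ai)),
    same     = sa == sb & sa %in% c("+", "-"),
    opposite = (sa == "+" & sb == "-") | (sa == "-" & sb == "+"))
  ai <- ai[keep]; bi <- bi[keep]
  ov <- pmin(GenomicRanges::end(a)[ai], GenomicRanges::end(b)[bi]) -
    pmax(GenomicRanges::start(a)[ai], GenomicRanges::start(b)[bi]) + 1L
  data.frame(a_idx = ai, b_idx = bi, overlap = ov)
}

# internal: does each interval of `a` overlap any interval of `b` by >= 1 bp,
# strand ignored
overlaps_any <- function(a, b) {
  GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE) > 0L
}

# internal: named integer chrom sizes -> Seqinfo
as_seqinfo <- function(chrom_sizes) {
  GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                        seqlengths = unname(as.integer(chrom_sizes)))
}
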