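#' Parameters for window/gap island calling
#'
#' Defaults follow standard broad-mark (H3K27ac) practice: 200 bp windows,
#' 600 bp gaps, a candidate-island E-value of 1000, a false discovery rate
#' of 1e-2 when a control library is supplied, and an effective genome
#' fraction of 0.77.
#'
#' @param window Window size in bases (default 200).
#' @param gap Maximum run of ineligible bases bridged between eligible
#'   windows (default 600; must be a multiple of `window`).
#' @param e_value Expected number of background islands tolerated at the
#'   island-score threshold (default 1000).
#' @param fdr BH-adjusted significance cutoff for chip-vs-control island
#'   tests (default 1e-2; used only when a control is supplied).
#' @param effective_genome_fraction Mappable fraction of the genome
#'   (default 0.77).
#' @param redundancy_threshold Maximum reads kept per (5' position, strand)
#'   (default 1).
#' @param window_p Poisson upper-tail p-value below which a single window
#'   is eligible (default 0.2).
#' @param mc_reps Null-genome simulations used to locate the E-value score
#'   threshold (default 5).
#' @param mc_seed Seed for those simulations (default 1; the caller's RNG
#'   state is preserved).
#' @return A list of class `island_call_params`.
#' @export
island_call_params <- function(window = 200L, gap = 600L, e_value = 1000,
                               fdr = 1e-2, effective_genome_fraction = 0.77,
                               redundancy_threshold = 1L, window_p = 0.2,
                               mc_reps = 5L, mc_seed = 1L) {
  if (window <= 0 || gap < 0) stop("window and gap must be positive")
  if (gap %% window != 0) stop("gap must be a multiple of window")
  stopifnot(effective_genome_fraction > 0, effective_genome_fraction <= 1)
  structure(list(window = as.integer(window), gap = as.integer(gap),
                 e_value = e_value, fdr = fdr,
                 effective_genome_fraction = effective_genome_fraction,
                 redundancy_threshold = as.integer(redundancy_threshold),
                 window_p = window_p, mc_reps = as.integer(mc_reps),
                 mc_seed = as.integer(mc_seed)),
            class = "island_call_params")
}

# internal: cap reads at `thr` per (chrom, 5' position, strand)
deduplicate_reads <- function(reads, thr) {
  s <- as.character(GenomicRanges::strand(reads))
  five <- ifelse(s == "+", GenomicRanges::start(reads),
                 GenomicRanges::end(reads))
  key <- paste(as.character(GenomeInfoDb::seqnames(reads)), five, s)
  o <- order(key)
  k <- key[o]
  rank_in_group <- sequence(rle(k)$lengths)
  keep <- o[rank_in_group <= thr]
  reads[sort(keep)]
}

# internal: merge eligible window indices (0-based) separated by <= gap_w
# ineligible windows; returns a data.frame of first/last window index
merge_eligible_windows <- function(idx, gap_w) {
  if (length(idx) == 0)
    return(data.frame(first = integer(), last = integer()))
  idx <- sort(idx)
  new_island <- c(TRUE, diff(idx) > gap_w + 1L)
  grp <- cumsum(new_island)
  data.frame(first = tapply(idx, grp, min), last = tapply(idx, grp, max))
}

# internal: island scores for one chromosome's window counts
island_scores_for_counts <- function(counts, k0, lambda_w, gap_w) {
  idx <- which(counts >= k0) - 1L
  isl <- merge_eligible_windows(idx, gap_w)
  if (nrow(isl) == 0) return(cbind(isl, score = numeric()))
  sc <- vapply(seq_len(nrow(isl)), function(i) {
    cts <- counts[(isl$first[i] + 1L):(isl$last[i] + 1L)]
    cts <- cts[cts >= k0]
    sum(-stats::dpois(cts, lambda_w, log = TRUE))
  }, 0)
  cbind(isl, score = sc)
}

# internal: score threshold such that the expected number of same-or-higher
# scoring islands under the Poisson background model is <= e_value
island_score_threshold <- function(n_windows, k0, lambda_w, gap_w, e_value,
                                   mc_reps, mc_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(mc_seed)
  sim_scores <- unlist(lapply(seq_len(mc_reps), function(r) {
    counts <- stats::rpois(n_windows, lambda_w)
    island_scores_for_counts(counts, k0, lambda_w, gap_w)[, "score"]
  }))
  k <- floor(e_value * mc_reps)
  if (length(sim_scores) <= k) return(0)
  sort(sim_scores, decreasing = TRUE)[k + 1L]
}

#' Call broad enrichment islands from windowed read counts
#'
#' Reads are deduplicated per (position, strand), assigned to fixed
#' non-overlapping windows by their midpoint, and windows with
#' significantly many reads under the genome-wide Poisson rate are merged
#' across gaps of up to `gap` bases into islands. An island's score is the
#' sum of `-ln P(count; lambda)` over its eligible windows; islands are
#' kept while the expected number of equal-or-higher-scoring background
#' islands (estimated by simulating the null window-count process) stays
#' within `e_value`. With a control library, per-island chip-vs-control
#' Poisson tests are BH-adjusted and islands kept at `fdr`.
#'
#' @param chip_reads `GRanges` ChIP alignments.
#' @param control_reads Optional `GRanges` control (input) alignments.
#' @param params An [island_call_params()] object.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return `GRanges` islands with metadata `score`, `read_count`,
#'   `n_eligible`, and `p`/`padj` when a control is supplied.
#' @export
call_islands <- function(chip_reads, control_reads = NULL, params,
                         chrom_sizes) {
  stopifnot(inherits(params, "island_call_params"))
  w <- params$window
  gap_w <- params$gap %/% w
  chip <- deduplicate_reads(chip_reads, params$redundancy_threshold)
  genome_size <- sum(chrom_sizes)
  lambda_w <- length(chip) * w /
    (genome_size * params$effective_genome_fraction)
  if (length(chip) == 0 || lambda_w <= 0)
    return(GenomicRanges::GRanges(score = numeric(), read_count = integer(),
                                  n_eligible = integer()))
  k0 <- min_significant_count(params$window_p, lambda_w)
  mid <- (GenomicRanges::start(chip) + GenomicRanges::end(chip)) %/% 2L
  chrom <- as.character(GenomeInfoDb::seqnames(chip))
  out <- list()
  for (ch in names(chrom_sizes)) {
    n_win <- as.integer(ceiling(chrom_sizes[[ch]] / w))
    m <- mid[chrom == ch]
    m <- m[m >= 1 & m <= chrom_sizes[[ch]]]
    counts <- tabulate((m - 1L) %/% w + 1L, nbins = n_win)
    isl <- island_scores_for_counts(counts, k0, lambda_w, gap_w)
    if (nrow(isl) == 0) next
    gr <- GenomicRanges::GRanges(
      ch,
      IRanges::IRanges(isl$first * w + 1L,
                       pmin((isl$last + 1L) * w, chrom_sizes[[ch]])),
      seqinfo = as_seqinfo(chrom_sizes),
      score = isl$score,
      n_eligible = vapply(seq_len(nrow(isl)), function(i)
        sum(counts[(isl$first[i] + 1L):(isl$last[i] + 1L)] >= k0), 0L))
    out[[ch]] <- gr
  }
  if (length(out) == 0)
    return(GenomicRanges::GRanges(score = numeric(), read_count = integer(),
                                  n_eligible = integer()))
  islands <- do.call(c, unname(out))
  n_windows_total <- sum(ceiling(chrom_sizes / w))
  thr <- island_score_threshold(n_windows_total, k0, lambda_w, gap_w,
                                params$e_value, params$mc_reps,
                                params$mc_seed)
  islands <- islands[islands$score >= thr]
  mid_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(mid, width = 1L))
  islands$read_count <- GenomicRanges::countOverlaps(islands, mid_gr)
  if (!is.null(control_reads)) {
    ctrl <- deduplicate_reads(control_reads, params$redundancy_threshold)
    cmid <- (GenomicRanges::start(ctrl) + GenomicRanges::end(ctrl)) %/% 2L
    cmid_gr <- GenomicRanges::GRanges(
      as.character(GenomeInfoDb::seqnames(ctrl)),
      IRanges::IRanges(cmid, width = 1L))
    cc <- GenomicRanges::countOverlaps(islands, cmid_gr)
    scale <- length(chip) / max(length(ctrl), 1L)
    lam <- pmax(cc, 1) * scale
    p <- stats::ppois(islands$read_count - 1, lam, lower.tail = FALSE)
    islands$p <- p
    islands$padj <- stats::p.adjust(p, method = "BH")
    islands <- islands[islands$padj < params$fdr]
  }
  sort(islands)
}
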