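#' Run the full eRNA identification and dysregulation analysis
#'
#' Orchestrates the complete flow on in-memory objects: genic-mask
#' construction and read filtering, per-condition candidate detection and
#' merging, H3K27ac vetting, counting, normalisation and differential
#' testing, gene association, super-enhancer enrichment, RNAPII
#' accounting, island size profiles and (optionally) motif enrichment.
#' Every stage's output is returned so downstream steps can be re-run
#' individually, and every parameter is echoed into the report.
#'
#' @param rna_reads Named list (`WT`, `HD`) of per-replicate read
#'   `GRanges` lists.
#' @param genes Gene `GRanges` (from [read_gtf()] or the simulator).
#' @param islands Named list (`WT`, `HD`) of H3K27ac island `GRanges`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param rnapii Optional named list (`WT`, `HD`) of RNAPII peak `GRanges`.
#' @param super_enhancers Optional super-enhancer `GRanges` (an input
#'   list, produced externally).
#' @param genome Optional named `DNAStringSet` (enables motif/GC stages).
#' @param motifs Optional list of [pwm_motif()] objects.
#' @param up_ext,down_ext Genic mask extensions (defaults 3000, 10000).
#' @param p_threshold Candidate-detection Poisson cutoff (default 1e-4).
#' @param shift Read shift; `NA` (default) estimates it per condition.
#' @param alpha Differential significance level (default 0.05).
#' @param de_results Optional externally computed differential table (a
#'   data.frame with columns `id`, `log2fc`, `pvalue`, `padj`, matched to
#'   catalogue `erna_id`s) used in place of the built-in NB Wald test —
#'   the seam for plugging in another DE engine.
#' @param n_resamples Motif resamples (default 100).
#' @param seed Seed for the motif resampling (default 1).
#' @return List of class `erna_report`: `params`, `mask`, `filter_stats`,
#'   `candidates`, `catalogue` (GRanges with status and annotation),
#'   `counts`, `diff`, `funnel`, `se_enrichment`, `rnapii_summary`,
#'   `size_profile`, `motif_table`, `timings`.
#' @export
run_erna_pipeline <- function(rna_reads, genes, islands, chrom_sizes,
                              rnapii = NULL, super_enhancers = NULL,
                              genome = NULL, motifs = NULL,
                              up_ext = 3000, down_ext = 10000,
                              p_threshold = 1e-4, shift = NA,
                              alpha = 0.05, de_results = NULL,
                              n_resamples = 100L, seed = 1L) {
  stopifnot(all(c("WT", "HD") %in% names(rna_reads)),
            all(c("WT", "HD") %in% names(islands)))
  t0 <- proc.time()[["elapsed"]]
  timings <- numeric()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[stage] <<- t1 - t0
    t0 <<- t1
  }

  mask <- build_genic_mask(genes, up_ext, down_ext, chrom_sizes)
  filtered <- lapply(rna_reads, function(reps) {
    per <- lapply(reps, filter_reads, mask = mask)
    pooled <- do.call(c, lapply(per, GenomicRanges::granges))
    list(per_replicate = per, pooled = pooled)
  })
  filter_stats <- lapply(filtered, function(f)
    lapply(f$per_replicate, attr, "filter_stats"))
  tick("filter")

  pooled <- lapply(filtered, `[[`, "pooled")
  pp <- peak_call_params(p_threshold = p_threshold,
                         shift = if (is.na(shift)) NA_integer_
                                 else as.integer(shift),
                         mode = "global_background",
                         effective_genome_size = sum(chrom_sizes))
  candidates <- detect_candidates(pooled, pp, chrom_sizes)
  merged <- merge_candidates(candidates)
  catalogue <- filter_by_h3k27ac(merged, islands$WT, islands$HD)
  tick("detect")

  samples <- c(lapply(filtered$WT$per_replicate, identity),
               lapply(filtered$HD$per_replicate, identity))
  names(samples) <- c(paste0("WT_", seq_along(filtered$WT$per_replicate)),
                      paste0("HD_", seq_along(filtered$HD$per_replicate)))
  condition <- sub("_.*", "", names(samples))
  counts <- count_reads(catalogue, samples)
  if (is.null(de_results)) {
    diff <- differential_test(counts, condition, alpha = alpha,
                              ref_level = "WT")
  } else {
    need <- c("id", "log2fc", "pvalue", "padj")
    if (!all(need %in% names(de_results)))
      stop("de_results must carry columns: ", paste(need, collapse = ", "))
    i <- match(catalogue$erna_id, de_results$id)
    if (anyNA(i))
      stop("de_results is missing catalogue ids (first: ",
           catalogue$erna_id[which(is.na(i))[1]], ")")
    diff <- de_results[i, , drop = FALSE]
    diff$status <- classify_status(diff, alpha)
  }
  catalogue$status <- diff$status
  catalogue$log2fc <- diff$log2fc
  catalogue$padj <- diff$padj
  catalogue$base_mean <- diff$base_mean
  tick("quantify")

  catalogue$gene_id <- assign_nearest_gene(catalogue, genes)
  funnel <- list(
    candidates = vapply(candidates, length, 0L),
    merged = length(merged),
    catalogue = length(catalogue),
    down = sum(catalogue$status == "down"),
    up = sum(catalogue$status == "up"),
    unchanged = sum(catalogue$status == "unchanged"))

  se_enrichment <- NULL
  if (!is.null(super_enhancers)) {
    in_se <- overlaps_any(catalogue, super_enhancers)
    se_enrichment <- lapply(c(down = "down", up = "up"), function(st) {
      i <- catalogue$status == st
      if (!any(i)) return(NULL)
      overlap_enrichment(sum(in_se & i), sum(i), sum(in_se),
                         length(catalogue))
    })
    catalogue$is_super_enhancer <- in_se
  }
  rnapii_summary <- NULL
  if (!is.null(rnapii)) {
    rnapii_summary <- rnapii_accounting(catalogue, rnapii$WT, rnapii$HD)
    catalogue$rnapii_wt <- overlaps_any(catalogue, rnapii$WT)
    catalogue$rnapii_hd <- overlaps_any(catalogue, rnapii$HD)
  }
  size_prof <- size_profile(catalogue, islands$WT, islands$HD)
  tick("integrate")

  motif_table <- NULL
  if (!is.null(genome) && !is.null(motifs) &&
      sum(catalogue$status == "down") >= 2) {
    motif_table <- enrich_motifs(catalogue[catalogue$status == "down"],
                                 catalogue, motifs, genome,
                                 n = n_resamples, seed = seed)
    tick("motifs")
  }

  structure(list(
    params = list(up_ext = up_ext, down_ext = down_ext,
                  p_threshold = p_threshold, shift = shift, alpha = alpha,
                  n_resamples = n_resamples, seed = seed,
                  window = NA, gap = NA),
    mask = mask, filter_stats = filter_stats, candidates = candidates,
    catalogue = catalogue, counts = counts, diff = diff, funnel = funnel,
    se_enrichment = se_enrichment, rnapii_summary = rnapii_summary,
    size_profile = size_prof, motif_table = motif_table,
    timings = timings), class = "erna_report")
}

#' @export
print.erna_report <- function(x, ...) {
  cat("eRNA analysis report\n")
  cat("  candidates per condition:",
      paste(names(x$funnel$candidates), x$funnel$candidates,
            collapse = ", "), "\n")
  cat("  merged candidate regions:", x$funnel$merged, "\n")
  cat("  H3K27ac-supported eRNAs: ", x$funnel$catalogue, "\n")
  cat("  down / up / unchanged:   ", x$funnel$down, "/", x$funnel$up, "/",
      x$funnel$unchanged, "\n")
  if (!is.null(x$rnapii_summary))
    cat("  RNAPII+ eRNAs WT/HD:     ", x$rnapii_summary$n_with_peak_wt, "/",
        x$rnapii_summary$n_with_peak_hd, "\n")
  invisible(x)
}
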