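#' Assign each eRNA to its nearest gene by TSS distance
#'
#' Associates each eRNA with the gene whose transcription start site is
#' closest to the eRNA midpoint (absolute distance, either strand). Ties
#' resolve to the lexicographically smaller `gene_id`; eRNAs farther than
#' `max_distance` from every TSS (or on a gene-less chromosome) get `NA`.
#'
#' @param ernas `GRanges` of eRNA regions.
#' @param genes `GRanges` gene spans with `gene_id` and strand `+`/`-`
#'   (TSS = start for `+`, end for `-`).
#' @param max_distance Optional cap in bases.
#' @return Character vector of gene ids, one per eRNA.
#' @export
assign_nearest_gene <- function(ernas, genes, max_distance = NULL) {
  if (length(ernas) == 0) return(character())
  if (length(genes) == 0) return(rep(NA_character_, length(ernas)))
  gs <- as.character(GenomicRanges::strand(genes))
  tss <- ifelse(gs == "+", GenomicRanges::start(genes),
                GenomicRanges::end(genes))
  gchr <- as.character(GenomeInfoDb::seqnames(genes))
  gid <- S4Vectors::mcols(genes)$gene_id
  mid <- (GenomicRanges::start(ernas) + GenomicRanges::end(ernas)) %/% 2L
  echr <- as.character(GenomeInfoDb::seqnames(ernas))
  out <- rep(NA_character_, length(ernas))
  for (ch in unique(echr)) {
    gi <- which(gchr == ch)
    if (length(gi) == 0) next
    ei <- which(echr == ch)
    # order candidate genes so ties pick the smaller gene_id
    d <- abs(outer(mid[ei], tss[gi], "-"))
    for (k in seq_along(ei)) {
      dk <- d[k, ]
      best <- which(dk == min(dk))
      pick <- best[order(gid[gi][best])][1]
      if (is.null(max_distance) || dk[pick] <= max_distance)
        out[ei[k]] <- gid[gi][pick]
    }
  }
  out
}

#' Observed-vs-expected enrichment of a gene subset (chi-square, 1 df)
#'
#' Tests whether "hits" are over-represented in a subset relative to the
#' universe rate: `expected = subset_size * hits_in_universe /
#' universe_size`, and the statistic sums `(O - E)^2 / E` over the hit and
#' non-hit cells of the subset. Enrichment requires both `p < p_cut` and
#' `observed > expected`.
#'
#' @param hits_in_subset,subset_size,hits_in_universe,universe_size Counts.
#' @param p_cut Significance cutoff (default 1e-2).
#' @param form `"goodness_of_fit"` (default) treats the universe rate as
#'   fixed and tests the subset's two cells; `"independence"` runs the
#'   full 2x2 chi-square (no continuity correction) of subset membership
#'   against hit status.
#' @return List with `observed`, `expected`, `chi2`, `p`, `enriched`.
#' @export
overlap_enrichment <- function(hits_in_subset, subset_size,
                               hits_in_universe, universe_size,
                               p_cut = 1e-2,
                               form = c("goodness_of_fit", "independence")) {
  form <- match.arg(form)
  stopifnot(hits_in_subset <= subset_size,
            hits_in_universe <= universe_size,
            subset_size <= universe_size)
  expected <- subset_size * hits_in_universe / universe_size
  expected_miss <- subset_size - expected
  if (expected == 0 || expected_miss == 0)
    stop("degenerate contingency: an expected cell is zero")
  if (form == "goodness_of_fit") {
    chi2 <- (hits_in_subset - expected)^2 / expected +
      ((subset_size - hits_in_subset) - expected_miss)^2 / expected_miss
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    tab <- rbind(c(hits_in_subset, subset_size - hits_in_subset),
                 c(hits_in_universe - hits_in_subset,
                   (universe_size - subset_size) -
                     (hits_in_universe - hits_in_subset)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic)
    p <- ct$p.value
  }
  list(observed = hits_in_subset, expected = expected, chi2 = chi2, p = p,
       enriched = p < p_cut && hits_in_subset > expected)
}

#' RNAPII percentage accounting from plain counts
#'
#' Reporting arithmetic for RNAPII peak dynamics at eRNAs, rounded to
#' integer percent: the share of the down class's WT-peak-positive eRNAs
#' that lose their peak in HD, the share of the up class that gains one,
#' and the overall drop in peak-positive eRNAs between conditions.
#'
#' @param n_lost Down-class eRNAs with a WT peak but no HD peak.
#' @param n_with_wt_peak Down-class eRNAs with a WT peak.
#' @param n_gained Up-class eRNAs with an HD peak but no WT peak.
#' @param class_size Size of the up class.
#' @param n_wt_total,n_hd_total Catalogue-wide peak-positive counts.
#' @return List `pct_lost`, `pct_gained`, `pct_overall_decrease`.
#' @export
rnapii_rates <- function(n_lost, n_with_wt_peak, n_gained, class_size,
                         n_wt_total, n_hd_total) {
  list(pct_lost = round(100 * n_lost / n_with_wt_peak),
       pct_gained = round(100 * n_gained / class_size),
       pct_overall_decrease = round(100 * (n_wt_total - n_hd_total) /
                                      n_wt_total))
}

#' RNAPII peak presence / loss / gain accounting over the eRNA catalogue
#'
#' An eRNA "has" an RNAPII peak in a condition iff it overlaps one by at
#' least one base. Per status class this reports how many eRNAs carry a WT
#' peak, how many of those lose it in HD, and how many gain an HD peak
#' without a WT one, with report-level integer-percent rounding.
#'
#' @param ernas `GRanges` catalogue with a `status` metadata column
#'   (`down`/`up`/`unchanged`).
#' @param rnapii_wt,rnapii_hd `GRanges` RNAPII peak sets.
#' @return List with catalogue-wide `n_with_peak_wt`, `n_with_peak_hd`,
#'   `pct_overall_decrease`, and a `per_status` data.frame with columns
#'   `status`, `n`, `n_with_wt_peak`, `n_lost`, `n_gained`, `pct_lost`,
#'   `pct_gained`.
#' @export
rnapii_accounting <- function(ernas, rnapii_wt, rnapii_hd) {
  status <- S4Vectors::mcols(ernas)$status
  stopifnot(!is.null(status))
  has_wt <- overlaps_any(ernas, rnapii_wt)
  has_hd <- overlaps_any(ernas, rnapii_hd)
  lost <- has_wt & !has_hd
  gained <- !has_wt & has_hd
  per <- do.call(rbind, lapply(unique(status), function(st) {
    i <- status == st
    nw <- sum(has_wt & i)
    data.frame(status = st, n = sum(i), n_with_wt_peak = nw,
               n_lost = sum(lost & i), n_gained = sum(gained & i),
               pct_lost = if (nw > 0) round(100 * sum(lost & i) / nw)
                          else NA_real_,
               pct_gained = round(100 * sum(gained & i) / sum(i)))
  }))
  nwt <- sum(has_wt); nhd <- sum(has_hd)
  list(n_with_peak_wt = nwt, n_with_peak_hd = nhd,
       pct_overall_decrease = if (nwt > 0)
         round(100 * (nwt - nhd) / nwt) else NA_real_,
       per_status = per)
}

#' Intersect two gene (or id) sets
#'
#' @param a,b Character vectors.
#' @return List with `intersection`, `n_a`, `n_b`, `n_intersection`.
#' @export
crosslist <- function(a, b) {
  a <- unique(a); b <- unique(b)
  i <- intersect(a, b)
  list(intersection = i, n_a = length(a), n_b = length(b),
       n_intersection = length(i))
}

#' Associated H3K27ac island widths per eRNA, by condition and status
#'
#' For each eRNA, the summed width of the islands it overlaps, per
#' condition; the summary gives median widths per status class and a
#' Wilcoxon rank-sum p-value comparing the down and up classes within each
#' condition (broad, super-enhancer-like islands at down eRNAs show up as
#' a larger down-class median).
#'
#' @param ernas `GRanges` catalogue with a `status` metadata column.
#' @param islands_wt,islands_hd `GRanges` island sets.
#' @return List: `widths` (data.frame `erna`, `status`, `width_wt`,
#'   `width_hd`), `medians` (status x condition), `wilcoxon_p` (per
#'   condition, down vs up).
#' @export
size_profile <- function(ernas, islands_wt, islands_hd) {
  sum_widths <- function(isl) {
    p <- interval_pairs(ernas, isl, min_overlap = 1L, strand_mode = "ignore")
    w <- GenomicRanges::width(isl)[p$b_idx]
    out <- numeric(length(ernas))
    if (nrow(p)) {
      agg <- tapply(w, p$a_idx, sum)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  status <- S4Vectors::mcols(ernas)$status
  stopifnot(!is.null(status))
  ids <- S4Vectors::mcols(ernas)$erna_id
  if (is.null(ids)) ids <- as.character(seq_along(ernas))
  df <- data.frame(erna = ids, status = status,
                   width_wt = sum_widths(islands_wt),
                   width_hd = sum_widths(islands_hd))
  med <- stats::aggregate(cbind(width_wt, width_hd) ~ status, df, stats::median)
  wp <- vapply(c(width_wt = "width_wt", width_hd = "width_hd"), function(col) {
    d <- df[[col]][status == "down"]; u <- df[[col]][status == "up"]
    if (length(d) == 0 || length(u) == 0) return(NA_real_)
    suppressWarnings(stats::wilcox.test(d, u)$p.value)
  }, 0)
  list(widths = df, medians = med, wilcoxon_p = wp)
}
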