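#' Count reads per region into a count matrix
#'
#' A read is counted for a region it overlaps by at least one base, strand
#' ignored. A read overlapping several regions is assigned to the region
#' with the largest overlap (the leftmost region on ties), so each read is
#' counted at most once. Regions must be non-overlapping (a merged
#' catalogue).
#'
#' @param regions `GRanges` of non-overlapping regions; row names come from
#'   an `erna_id` metadata column when present.
#' @param reads_by_sample Named list of read `GRanges`, one per sample.
#' @return Integer matrix, regions x samples.
#' @export
count_reads <- function(regions, reads_by_sample) {
  stopifnot(is.list(reads_by_sample), !is.null(names(reads_by_sample)))
  self <- GenomicRanges::countOverlaps(regions, regions, ignore.strand = TRUE)
  if (any(self > 1L))
    stop("regions overlap each other; merge them first (see merge_candidates)")
  ids <- S4Vectors::mcols(regions)$erna_id
  if (is.null(ids)) ids <- sprintf("region%05d", seq_along(regions))
  reg_start <- GenomicRanges::start(regions)
  m <- vapply(reads_by_sample, function(reads) {
    p <- interval_pairs(reads, regions, min_overlap = 1L,
                        strand_mode = "ignore")
    if (nrow(p) == 0) return(integer(length(regions)))
    # larger overlap wins; leftmost region start breaks ties
    o <- order(p$a_idx, -p$overlap, reg_start[p$b_idx], p$b_idx)
    p <- p[o, ]
    p <- p[!duplicated(p$a_idx), ]
    tabulate(p$b_idx, nbins = length(regions))
  }, integer(length(regions)))
  m <- matrix(as.integer(m), nrow = length(regions),
              dimnames = list(ids, names(reads_by_sample)))
  m
}

#' Median-of-ratios library size factors
#'
#' For each sample `j`, the factor is the median over features of
#' `k_ij / (prod_v k_iv)^(1/m)`, computed on features with all-positive
#' counts.
#'
#' @param counts Integer matrix, features x samples.
#' @return Numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  if (is.null(dim(counts)) || ncol(counts) < 1) stop("need a count matrix")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has positive counts in every sample; ",
         "median-of-ratios is undefined (consider a pseudo-reference ",
         "computed on non-zero samples)")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)                       # log geometric mean
  apply(lg, 2, function(col) exp(stats::median(col - ref)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s propagate).
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# internal: method-of-moments NB dispersion per row, pooled within condition
mom_dispersion <- function(norm_counts, condition) {
  conds <- unique(condition)
  n <- ncol(norm_counts)
  ss <- 0; df <- 0
  for (cc in conds) {
    x <- norm_counts[, condition == cc, drop = FALSE]
    mu_c <- rowMeans(x)
    ss <- ss + rowSums((x - mu_c)^2)
    df <- df + (ncol(x) - 1)
  }
  v <- ss / df
  mu <- rowMeans(norm_counts)
  pmax((v - mu) / mu^2, 1e-8)
}

#' Negative binomial Wald test for two-condition differential expression
#'
#' Counts are normalised with median-of-ratios size factors; per-feature NB
#' dispersions are estimated by method of moments within condition, floored
#' at 1e-8 and shrunk 50/50 toward a fitted mean-dispersion trend (refitted
#' under constraints when a coefficient leaves its admissible range)
#' `a0 / mu + a1`; a negative binomial GLM with log link and size-factor
#' offsets is fitted per feature and the condition coefficient tested with
#' a two-sided Wald statistic referred to a Student-t distribution with
#' `4 * (n_samples - 2)` effective degrees of freedom (a Satterthwaite-style
#' account of the estimated dispersion; a plain normal reference is visibly
#' anticonservative at replicate-level sample sizes); p-values are
#' BH-adjusted.
#'
#' Features with zero counts in every sample are reported with `NA`
#' statistics and excluded from the adjustment.
#'
#' @param counts Integer matrix, features x samples.
#' @param condition Factor/character of sample conditions (2 levels,
#'   >= 2 samples each); the *first* level (default `"WT"` if present) is
#'   the reference, so `log2fc` is second-vs-reference.
#' @param alpha Significance level used by [classify_status()]
#'   (default 0.05).
#' @param ref_level Reference condition label.
#' @return data.frame with columns `id`, `base_mean`, `log2fc`, `se_log2fc`,
#'   `wald_stat`, `pvalue`, `padj`, `status`.
#' @export
differential_test <- function(counts, condition, alpha = 0.05,
                              ref_level = "WT") {
  condition <- as.character(condition)
  stopifnot(ncol(counts) == length(condition))
  lv <- unique(condition)
  if (length(lv) != 2) stop("exactly two conditions required")
  if (min(table(condition)) < 2)
    stop("each condition needs at least two samples")
  if (ref_level %in% lv) lv <- c(ref_level, setdiff(lv, ref_level))
  cond <- factor(condition, levels = lv)
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  nonzero <- rowSums(counts) > 0
  alpha_mom <- mom_dispersion(norm[nonzero, , drop = FALSE],
                              as.character(cond))
  mu <- rowMeans(norm[nonzero, , drop = FALSE])
  # trend a0/mu + a1; when a coefficient leaves its admissible range the
  # trend is refitted under the constraint (clipping one coefficient of a
  # near-collinear fit while keeping the other would bias every row)
  tr <- stats::lm.fit(cbind(1, 1 / mu), alpha_mom)$coefficients
  a1 <- tr[1]; a0 <- tr[2]
  if (a0 < 0) {
    a0 <- 0
    a1 <- max(mean(alpha_mom), 1e-8)
  }
  if (a1 < 1e-8) {
    a1 <- 1e-8
    a0 <- max(sum((alpha_mom - a1) / mu) / sum(1 / mu^2), 0)
  }
  alpha_trend <- a0 / mu + a1
  disp <- pmax(0.5 * alpha_mom + 0.5 * alpha_trend, 1e-8)
  off <- log(sf)
  fit_row <- function(y, d) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ cond + offset(off),
                                  family = MASS::negative.binomial(1 / d))),
      error = function(e) NULL)
    if (is.null(fit)) return(c(NA_real_, NA_real_))
    # the NB variance is fully specified by the plug-in dispersion, so do
    # not let summary.glm re-estimate a residual scale from few df
    cf <- summary(fit, dispersion = 1)$coefficients
    if (nrow(cf) < 2) return(c(NA_real_, NA_real_))
    cf[2, 1:2]
  }
  nz_idx <- which(nonzero)
  est <- vapply(seq_along(nz_idx), function(i)
    fit_row(counts[nz_idx[i], ], disp[i]), c(0, 0))
  beta <- est[1, ]; se <- est[2, ]
  wald <- beta / se
  # Student-t reference with Satterthwaite-style effective df: the plug-in
  # dispersion mixes a (n-2)-df within-condition estimate at weight 1/2
  # with the low-variance trend, so its variance is ~1/4 of the raw
  # estimate's and the effective df ~4 * (n - 2); a plain normal reference
  # is visibly anticonservative at replicate-level sample sizes
  t_df <- 4 * (ncol(counts) - 2)
  pv <- 2 * stats::pt(-abs(wald), df = t_df)
  res <- data.frame(
    id = if (!is.null(rownames(counts))) rownames(counts)
         else sprintf("row%05d", seq_len(nrow(counts))),
    base_mean = rowMeans(norm),
    log2fc = NA_real_, se_log2fc = NA_real_, wald_stat = NA_real_,
    pvalue = NA_real_, padj = NA_real_, row.names = NULL)
  res$log2fc[nz_idx] <- beta / log(2)
  res$se_log2fc[nz_idx] <- se / log(2)
  res$wald_stat[nz_idx] <- wald
  res$pvalue[nz_idx] <- pv
  res$padj[nz_idx] <- bh_adjust(pv)
  res$status <- classify_status(res, alpha)
  attr(res, "size_factors") <- sf
  attr(res, "dispersion") <- disp
  res
}

#' Classify differential results as down / up / unchanged
#'
#' `down` iff `padj < alpha` and `log2fc < 0`; `up` iff `padj < alpha` and
#' `log2fc > 0`; everything else (including untestable features) is
#' `unchanged`.
#'
#' @param results data.frame with `padj` and `log2fc` columns.
#' @param alpha Adjusted-significance cutoff (default 0.05).
#' @return Character vector of statuses.
#' @export
classify_status <- function(results, alpha = 0.05) {
  st <- rep("unchanged", nrow(results))
  sig <- !is.na(results$padj) & results$padj < alpha
  st[sig & results$log2fc < 0] <- "down"
  st[sig & results$log2fc > 0] <- "up"
  st
}
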