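#' Construct a position weight matrix motif
#'
#' @param motif_id Identifier.
#' @param matrix Numeric matrix with rows `A`, `C`, `G`, `T` and one column
#'   per motif position; columns must each sum to 1 (within 1e-9). Count
#'   matrices are accepted and column-normalised.
#' @param background Length-4 0-order background probabilities
#'   (default uniform).
#' @return A list of class `pwm_motif`.
#' @export
pwm_motif <- function(motif_id, matrix, background = rep(0.25, 4)) {
  stopifnot(nrow(matrix) == 4, ncol(matrix) >= 1, all(matrix >= 0))
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-9)) {
    if (any(cs <= 0)) stop("PWM column with zero mass")
    matrix <- sweep(matrix, 2, cs, "/")
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  structure(list(motif_id = motif_id, matrix = matrix,
                 background = background), class = "pwm_motif")
}

#' Read motifs from JASPAR PFM text
#'
#' Accepts the JASPAR 2014 flat format: a `>ID name` header followed by
#' four lines of counts, either bare numbers or `A [ 4 19 0 ... ]` rows.
#'
#' @param path File path.
#' @return List of [pwm_motif()] objects.
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no JASPAR motif headers ('>') in ", path)
  lapply(seq_along(heads), function(i) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    body <- lines[(heads[i] + 1):to]
    if (length(body) < 4) stop("motif ", id, ": expected 4 count rows")
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[?|\\]$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    m <- do.call(rbind, rows)
    pwm_motif(id, m)
  })
}

#' Read motifs from MEME minimal motif format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections
#' and the optional `Background letter frequencies` line.
#'
#' @param path File path.
#' @return List of [pwm_motif()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(tok[seq(2, 8, by = 2)])
  }
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0) stop("no MOTIF blocks in ", path)
  lapply(starts, function(s) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    m <- t(vapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:4]), numeric(4)))
    pwm_motif(id, t(m), background = bg)
  })
}

# internal: integer-discretised log-odds score model with an exact
# score-to-p map computed by dynamic programming under the background
pwm_score_model <- function(motif, background, pseudocount = 1e-3,
                            n_bins = 1000L) {
  pm <- (motif$matrix + pseudocount) / (1 + 4 * pseudocount)
  if (any(pm <= 0)) stop("zero probability in PWM and no pseudocount")
  lom <- log2(pm / background)
  w <- ncol(lom)
  smin <- sum(apply(lom, 2, min)); smax <- sum(apply(lom, 2, max))
  eps <- max((smax - smin) / n_bins, 1e-12)
  ilom <- round(lom / eps)
  # reverse-complement scoring matrix for the minus strand
  ilom_rc <- ilom[4:1, w:1, drop = FALSE]
  # DP over positions: distribution of the integer score under background
  vals <- 0L; pr <- 1
  for (j in seq_len(w)) {
    nv <- as.vector(outer(vals, ilom[, j], "+"))
    np <- as.vector(outer(pr, background, "*"))
    agg <- tapply(np, nv, sum)
    vals <- as.integer(names(agg)); pr <- as.numeric(agg)
  }
  o <- order(vals, decreasing = TRUE)
  vals <- vals[o]; pr <- pr[o]
  pval <- cumsum(pr)  # P(score >= vals[k])
  list(ilom = ilom, ilom_rc = ilom_rc, w = w, eps = eps,
       score_vals = vals, score_pvals = pval)
}

# internal: p-value for integer scores under the model (P(S >= s))
pwm_score_p <- function(model, s) {
  idx <- findInterval(-s, -model$score_vals)
  p <- ifelse(idx == 0, model$score_pvals[1], model$score_pvals[pmax(idx, 1)])
  ifelse(s > model$score_vals[1], 0, p)
}

# internal: integer code vector for a sequence (A/C/G/T -> 1:4, other -> 0)
encode_seq <- function(seq) {
  x <- match(strsplit(toupper(as.character(seq)), "")[[1]],
             c("A", "C", "G", "T"))
  x[is.na(x)] <- 0L
  x
}

# internal: integer window scores for one encoded sequence and scoring
# matrix; windows containing non-ACGT bases get -Inf
window_scores <- function(codes, imat) {
  w <- ncol(imat)
  L <- length(codes)
  if (L < w) return(numeric(0))
  n_off <- L - w + 1L
  sc <- numeric(n_off)
  ok <- rep(TRUE, n_off)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n_off - 1L)]
    bad <- cj == 0L
    ok <- ok & !bad
    cj[bad] <- 1L
    sc <- sc + imat[cbind(cj, j)]
  }
  sc[!ok] <- -Inf
  sc
}

#' Scan sequences with a PWM at an exact p-value threshold
#'
#' Computes the log-odds score `log2(p_motif / p_background)` at every
#' offset of every sequence on both strands; the score-to-p-value map is
#' built by exact dynamic programming over the discretised score
#' distribution under the 0-order background (1/1000 of the score range
#' per bin). Hits are windows with `P(score >= s) < p_threshold`; windows
#' containing `N` never match.
#'
#' @param sequences `DNAStringSet` or character vector.
#' @param motif A [pwm_motif()].
#' @param p_threshold Per-window p-value cutoff (default 1e-4).
#' @param background Length-4 background probabilities; by default
#'   estimated from the scanned sequences (falling back to the motif's).
#' @param pseudocount Probability added to each PWM entry (default 1e-3).
#' @return Integer total hit count with attribute `"hits"`: a data.frame
#'   of `seq`, `pos`, `strand`, `score`, `p`, and attribute
#'   `"per_sequence"`: hit counts per sequence.
#' @export
scan_pwm <- function(sequences, motif, p_threshold = 1e-4,
                     background = NULL, pseudocount = 1e-3) {
  stopifnot(inherits(motif, "pwm_motif"))
  seqs <- as.character(sequences)
  if (is.null(background)) background <- estimate_background(seqs)
  model <- pwm_score_model(motif, background, pseudocount)
  hits <- list()
  per_seq <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    codes <- encode_seq(seqs[i])
    for (st in c("+", "-")) {
      imat <- if (st == "+") model$ilom else model$ilom_rc
      sc <- window_scores(codes, imat)
      if (!length(sc)) next
      p <- pwm_score_p(model, sc)
      p[!is.finite(sc)] <- 1
      hit <- which(p < p_threshold)
      if (length(hit)) {
        per_seq[i] <- per_seq[i] + length(hit)
        hits[[length(hits) + 1L]] <- data.frame(
          seq = i, pos = hit, strand = st,
          score = sc[hit] * model$eps, p = p[hit])
      }
    }
  }
  count <- sum(per_seq)
  attr(count, "hits") <- if (length(hits)) do.call(rbind, hits) else
    data.frame(seq = integer(), pos = integer(), strand = character(),
               score = numeric(), p = numeric())
  attr(count, "per_sequence") <- per_seq
  count
}

# internal: 0-order ACGT background from sequences (uniform fallback)
estimate_background <- function(seqs) {
  tab <- table(factor(unlist(strsplit(toupper(seqs), "")),
                      levels = c("A", "C", "G", "T")))
  if (sum(tab) == 0) return(rep(0.25, 4))
  bg <- (as.numeric(tab) + 1) / (sum(tab) + 4)   # add-one smoothing
  bg / sum(bg)
}

#' Draw size-matched random region sets from the eRNA catalogue
#'
#' Each of the `n` resamples draws `length(target_sizes)` catalogue
#' regions without replacement so that the drawn size distribution matches
#' the targets': a target of size `s` is matched by a uniform draw among
#' the available regions within `size_tolerance` relative size difference
#' (a window that always contains any exact-size match), falling back to
#' the nearest-size available region when the window is empty. A strict
#' closest-size rule would return near-identical sets every resample and
#' collapse the null spread the Z statistic needs.
#'
#' @param target_sizes Integer vector of target region sizes.
#' @param universe_sizes Integer vector of catalogue region sizes
#'   (`length >= length(target_sizes)`).
#' @param n Number of resamples (default 100).
#' @param seed RNG seed making the draw deterministic.
#' @param size_tolerance Relative size window for the random draw
#'   (default 0.2).
#' @return List of `n` integer index vectors into the universe.
#' @export
sample_matched_regions <- function(target_sizes, universe_sizes, n = 100L,
                                   seed = 1L, size_tolerance = 0.2) {
  nt <- length(target_sizes); nu <- length(universe_sizes)
  if (nu < nt) stop("universe smaller than target set")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(r) {
    avail <- rep(TRUE, nu)
    picked <- integer(nt)
    for (k in seq_len(nt)) {
      s <- target_sizes[k]
      cand <- which(avail & abs(universe_sizes - s) <= size_tolerance * s)
      if (length(cand) == 0) {
        a <- which(avail)
        cand <- a[which.min(abs(universe_sizes[a] - s))]
      }
      pick <- if (length(cand) == 1) cand else sample(cand, 1L)
      picked[k] <- pick
      avail[pick] <- FALSE
    }
    picked
  })
}

#' Resampling Z-score for a motif occurrence count
#'
#' `z = (x - mean(resamples)) / sd(resamples)` (sd with denominator
#' `n - 1`), with a one-sided upper-tail normal p-value. When the resample
#' spread is zero the result is flagged degenerate: `z = 0, p = 1` if
#' `x <= mean`, else `z = Inf` with a near-zero sentinel p.
#'
#' @param x Observed occurrence count in the target regions.
#' @param resample_counts Numeric vector (length >= 2) of occurrence
#'   counts in the matched random region sets.
#' @param alternative `"greater"` (default, enrichment) or `"two.sided"`
#'   (`|z|`, reporting depletion as well).
#' @return List `x`, `mu`, `sigma`, `z`, `p`, `degenerate`.
#' @export
motif_zscore <- function(x, resample_counts,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(resample_counts)
  if (n < 2) stop("need at least two resample counts")
  mu <- mean(resample_counts)
  sigma <- stats::sd(resample_counts)
  if (sigma == 0) {
    if (x == mu || (alternative == "greater" && x < mu))
      return(list(x = x, mu = mu, sigma = 0, z = 0, p = 1, degenerate = TRUE))
    return(list(x = x, mu = mu, sigma = 0,
                z = if (x > mu) Inf else -Inf,
                p = .Machine$double.xmin, degenerate = TRUE))
  }
  z <- (x - mu) / sigma
  p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(-abs(z))
  list(x = x, mu = mu, sigma = sigma, z = z, p = p, degenerate = FALSE)
}

# internal: extract region sequences from a genome DNAStringSet with
# bounds checking
region_sequences <- function(genome, regions) {
  chrom <- as.character(GenomeInfoDb::seqnames(regions))
  bad <- !(chrom %in% names(genome))
  if (any(bad)) stop("region on unknown contig ", chrom[which(bad)[1]])
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(GenomicRanges::end(regions) > lens) ||
      any(GenomicRanges::start(regions) < 1))
    stop("region beyond contig end")
  Biostrings::subseq(genome[chrom], start = GenomicRanges::start(regions),
                     end = GenomicRanges::end(regions))
}

#' Motif enrichment in target eRNA regions by catalogue resampling
#'
#' For each motif, counts occurrences in the target regions
#' ([scan_pwm()]), draws `n` size-matched random region sets from the eRNA
#' catalogue ([sample_matched_regions()]) as the occurrence null — the
#' catalogue itself serves as background so eRNA-specific nucleotide
#' composition cancels — and reports the resampling Z-score with BH
#' adjustment across motifs. Per-region hit counts are computed once per
#' motif over the union of catalogue and target regions, so each resample
#' is a sum of cached counts; the scan background is estimated from the
#' catalogue sequence.
#'
#' @param targets `GRanges` target regions (e.g. down eRNAs).
#' @param universe `GRanges` eRNA catalogue to resample from.
#' @param motifs List of [pwm_motif()] objects.
#' @param genome Named `DNAStringSet`.
#' @param n Number of resamples (default 100).
#' @param seed RNG seed (default 1).
#' @param p_threshold Per-window scan cutoff (default 1e-4).
#' @param alternative Passed to [motif_zscore()].
#' @return data.frame: `motif`, `x`, `mu`, `sigma`, `z`, `p`, `padj`,
#'   `degenerate`.
#' @export
enrich_motifs <- function(targets, universe, motifs, genome, n = 100L,
                          seed = 1L, p_threshold = 1e-4,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  useq <- region_sequences(genome, universe)
  tseq <- region_sequences(genome, targets)
  bg <- estimate_background(as.character(useq))
  draws <- sample_matched_regions(GenomicRanges::width(targets),
                                  GenomicRanges::width(universe),
                                  n = n, seed = seed)
  res <- lapply(motifs, function(mo) {
    ucnt <- attr(scan_pwm(useq, mo, p_threshold, background = bg),
                 "per_sequence")
    x <- as.integer(scan_pwm(tseq, mo, p_threshold, background = bg))
    rs <- vapply(draws, function(idx) sum(ucnt[idx]), 0)
    zs <- motif_zscore(x, rs, alternative = alternative)
    data.frame(motif = mo$motif_id, x = zs$x, mu = zs$mu, sigma = zs$sigma,
               z = zs$z, p = zs$p, degenerate = zs$degenerate)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out[, c("motif", "x", "mu", "sigma", "z", "p", "padj", "degenerate")]
}

#' G+C fraction of regions
#'
#' `(G + C) / (A + C + G + T)` per region; `N` bases are excluded from the
#' denominator and all-`N` regions report `NA`.
#'
#' @param regions `GRanges`.
#' @param genome Named `DNAStringSet` covering the regions.
#' @return Numeric vector of per-region GC fractions.
#' @export
gc_content <- function(regions, genome) {
  seqs <- region_sequences(genome, regions)
  f <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(f[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- rowSums(f[, c("G", "C"), drop = FALSE])
  ifelse(acgt > 0, gc / acgt, NA_real_)
}

#' Build a near-consensus PWM from a consensus string
#'
#' Each position gives probability `p` to the consensus base and
#' `(1 - p) / 3` to the rest — convenient for planting and recovering
#' known motifs in synthetic data.
#'
#' @param consensus Character string over `ACGT`.
#' @param p Consensus-base probability per position (default 0.97).
#' @param motif_id Identifier (defaults to the consensus).
#' @return A [pwm_motif()].
#' @export
consensus_pwm <- function(consensus, p = 0.97, motif_id = consensus) {
  b <- match(strsplit(toupper(consensus), "")[[1]], c("A", "C", "G", "T"))
  if (any(is.na(b))) stop("consensus must be over ACGT")
  m <- matrix((1 - p) / 3, nrow = 4, ncol = length(b))
  m[cbind(b, seq_along(b))] <- p
  pwm_motif(motif_id, m)
}

#' Draw size-matched random genomic regions
#'
#' Uniform random regions of the given widths, anywhere on the genome —
#' the appropriate control for sequence-composition comparisons such as
#' GC content, where the question is "eRNAs vs the genome" rather than
#' "this eRNA class vs the catalogue".
#'
#' @param genome Named `DNAStringSet` (or a named vector of contig
#'   lengths).
#' @param widths Integer vector of region widths.
#' @param seed RNG seed (caller RNG preserved).
#' @return `GRanges` with one region per requested width.
#' @export
random_genomic_regions <- function(genome, widths, seed = 1L) {
  lens <- if (is.numeric(genome)) genome
          else stats::setNames(Biostrings::width(genome), names(genome))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ok <- vapply(widths, function(w) any(lens >= w), TRUE)
  if (!all(ok)) stop("a requested width exceeds every contig")
  chrom <- vapply(widths, function(w) {
    eligible <- names(lens)[lens >= w]
    if (length(eligible) == 1) eligible
    else sample(eligible, 1, prob = lens[eligible])
  }, "")
  start <- vapply(seq_along(widths), function(i)
    sample.int(lens[[chrom[i]]] - widths[i] + 1L, 1L), 0L)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = widths))
}

#' GC content of target regions vs catalogue and random genomic controls
#'
#' @param targets,universe `GRanges` region sets.
#' @param genome Named `DNAStringSet`.
#' @param seed Seed for the random genomic size-matched draw.
#' @return List with per-group mean GC (`target`, `universe`,
#'   `random_genomic`) and the per-region vectors.
#' @export
gc_summary <- function(targets, universe, genome, seed = 1L) {
  rnd <- random_genomic_regions(genome, GenomicRanges::width(targets),
                                seed = seed)
  gt <- gc_content(targets, genome)
  gu <- gc_content(universe, genome)
  gr <- gc_content(rnd, genome)
  list(target = mean(gt, na.rm = TRUE),
       universe = mean(gu, na.rm = TRUE),
       random_genomic = mean(gr, na.rm = TRUE),
       per_region = list(target = gt, universe = gu, random_genomic = gr))
}
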