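# Brute-force reference implementations and fixture builders used across
# the suite. Oracles deliberately avoid the package code paths they check.

library(GenomicRanges)

# all-vs-all interval pairs with min-overlap and strand rule
bf_pairs <- function(a, b, min_overlap = 1L,
                     strand_mode = c("ignore", "same", "opposite")) {
  strand_mode <- match.arg(strand_mode)
  out <- NULL
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(seqnames(a)[i]) != as.character(seqnames(b)[j])) next
    ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1L
    if (ov < min_overlap) next
    sa <- as.character(strand(a)[i]); sb <- as.character(strand(b)[j])
    ok <- switch(strand_mode,
                 ignore = TRUE,
                 same = sa == sb && sa %in% c("+", "-"),
                 opposite = (sa == "+" && sb == "-") ||
                   (sa == "-" && sb == "+"))
    if (ok) out <- rbind(out, data.frame(a_idx = i, b_idx = j, overlap = ov))
  }
  if (is.null(out))
    data.frame(a_idx = integer(), b_idx = integer(), overlap = integer())
  else out
}

# textbook step-up BH
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive nearest-TSS scan with lexicographic tie rule
bf_nearest <- function(ernas, genes, max_distance = NULL) {
  tss <- ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
  vapply(seq_along(ernas), function(i) {
    mid <- (start(ernas)[i] + end(ernas)[i]) %/% 2L
    same <- which(as.character(seqnames(genes)) ==
                    as.character(seqnames(ernas)[i]))
    if (length(same) == 0) return(NA_character_)
    d <- abs(tss[same] - mid)
    best <- same[d == min(d)]
    pick <- best[order(genes$gene_id[best])][1]
    if (!is.null(max_distance) && min(d) > max_distance) return(NA_character_)
    genes$gene_id[pick]
  }, "")
}

# quadratic union-find merge of >=1 bp-overlapping intervals (one chrom)
bf_merge <- function(starts, ends) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && starts[i] <= ends[j] && starts[j] <= ends[i]) {
      parent[find(i)] <- find(j)
    }
  }
  grp <- vapply(seq_len(n), find, 0L)
  t(vapply(unique(grp), function(g)
    c(min(starts[grp == g]), max(ends[grp == g])), c(0, 0)))
}

# SICER-style eligible-window merge (window indices, bp gap)
bf_merge_windows <- function(idx, window, gap) {
  if (length(idx) == 0) return(data.frame(first = integer(), last = integer()))
  idx <- sort(idx)
  out <- list(); cur <- c(idx[1], idx[1])
  for (k in idx[-1]) {
    if ((k - cur[2] - 1) * window <= gap) cur[2] <- k
    else { out[[length(out) + 1]] <- cur; cur <- c(k, k) }
  }
  out[[length(out) + 1]] <- cur
  data.frame(first = vapply(out, `[`, 0, 1), last = vapply(out, `[`, 0, 2))
}

# full-enumeration PWM scan on the same 1/1000-of-range integer score grid
# the package discretises to; p-values come from summing exact word
# probabilities rather than the package's DP convolution
bf_pwm_hits <- function(seqs, motif, p_threshold, background,
                        pseudocount = 1e-3) {
  pm <- (motif$matrix + pseudocount) / (1 + 4 * pseudocount)
  lom <- log2(pm / background)
  w <- ncol(lom)
  smin <- sum(apply(lom, 2, min)); smax <- sum(apply(lom, 2, max))
  eps <- max((smax - smin) / 1000, 1e-12)
  ilom <- round(lom / eps)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  wsc <- vapply(seq_len(nrow(words)), function(r)
    sum(ilom[cbind(words[r, ], seq_len(w))]), 0)
  wpr <- vapply(seq_len(nrow(words)), function(r)
    prod(background[words[r, ]]), 0)
  pv <- function(s) sum(wpr[wsc >= s])
  rc <- function(codes) rev(5L - codes)
  total <- 0L
  for (sq in seqs) {
    codes <- match(strsplit(sq, "")[[1]], c("A", "C", "G", "T"))
    for (variant in list(codes, rc(codes))) {
      if (length(variant) < w) next
      for (o in 1:(length(variant) - w + 1)) {
        win <- variant[o:(o + w - 1)]
        if (anyNA(win)) next
        s <- sum(ilom[cbind(win, seq_len(w))])
        if (pv(s) < p_threshold) total <- total + 1L
      }
    }
  }
  total
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_granges <- function(n, chroms = c("c1", "c2"), max_pos = 1000,
                           max_width = 60, stranded = TRUE) {
  st <- sample(max_pos, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE),
          IRanges(st, width = sample(max_width, n, replace = TRUE)),
          strand = if (stranded) sample(c("+", "-"), n, replace = TRUE)
                   else "*")
}

# a compact simulation configuration used by fast unit tests
small_sim_config <- function(seed = 11, depth = 8e4, ...) {
  sim_config(genome_size = 8e5, n_genes = 10, n_enhancers = 12, n_super = 4,
             depth = depth, n_down = 4, n_up = 3, seed = seed, ...)
}

overlaps_any_test <- function(a, b) countOverlaps(a, b) > 0
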