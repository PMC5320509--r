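test_that("a planted width-7 consensus is found at its offset", {
  set.seed(19)
  mo <- consensus_pwm("TGACTCA")
  left <- random_dna_str(20)
  right <- random_dna_str(23)
  seqs <- c(paste0(left, "TGACTCA", right), random_dna_str(50))
  cnt <- scan_pwm(seqs, mo, p_threshold = 1e-4,
                  background = rep(0.25, 4))
  hits <- attr(cnt, "hits")
  expect_gte(as.integer(cnt), 1)
  expect_true(any(hits$seq == 1 & hits$pos == 21 & hits$strand == "+"))
})

test_that("scanning is strand-symmetric and void below the motif width", {
  set.seed(20)
  mo <- consensus_pwm("TGACTCA")
  sq <- paste0(random_dna_str(15), "TGACTCA", random_dna_str(15))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
  bg <- rep(0.25, 4)
  expect_equal(as.integer(scan_pwm(sq, mo, background = bg)),
               as.integer(scan_pwm(rc, mo, background = bg)))
  expect_equal(as.integer(scan_pwm("ACGT", mo, background = bg)), 0L)
})

test_that("windows containing N never match", {
  mo <- consensus_pwm("TGACTCA")
  expect_equal(as.integer(scan_pwm("TGANTCA", mo,
                                   background = rep(0.25, 4))), 0L)
})

test_that("PWM hit counts equal the full-enumeration oracle", {
  set.seed(27)
  for (case in 1:20) {
    w <- sample(4:6, 1)
    m <- matrix(stats::rgamma(4 * w, 0.6), 4, w)
    mo <- pwm_motif("rnd", m)
    bg <- as.numeric(stats::rgamma(4, 4)); bg <- bg / sum(bg)
    seqs <- vapply(1:3, function(i) random_dna_str(sample(30:120, 1)), "")
    thr <- 10^-sample(2:3, 1)
    got <- as.integer(scan_pwm(seqs, mo, p_threshold = thr, background = bg))
    want <- bf_pwm_hits(seqs, mo, thr, bg)
    expect_equal(got, want)
  }
})

test_that("the resampling Z-score satisfies its algebraic identity", {
  set.seed(33)
  rs <- rpois(100, 7)
  z <- motif_zscore(12, rs)
  expect_equal(z$z * z$sigma + z$mu, 12)
  expect_false(z$degenerate)
  # formula arithmetic: x = 12, mu = 5, sigma = 2 -> z = 3.5
  rs2 <- c(3, 7, 3, 7, 5)   # mean 5, sd exactly 2
  z2 <- motif_zscore(12, rs2)
  expect_equal(z2$mu, 5)
  expect_equal(z2$sigma, 2)
  expect_equal(z2$z, 3.5)
  z3 <- motif_zscore(mean(rs), rs)
  expect_equal(z3$p, pnorm(z3$z, lower.tail = FALSE))
  zx <- motif_zscore(5, rep(5, 10))
  expect_true(zx$degenerate && zx$z == 0 && zx$p == 1)
  zy <- motif_zscore(9, rep(5, 10))
  expect_true(zy$degenerate && is.infinite(zy$z) && zy$p > 0)
  expect_error(motif_zscore(3, 5), "two resample")
})

test_that("the Z-score null is approximately calibrated", {
  set.seed(71)
  nsim <- 4000
  x <- rpois(nsim, 20)
  rs <- matrix(rpois(nsim * 100, 20), nrow = nsim)
  mu <- rowMeans(rs)
  sg <- apply(rs, 1, sd)
  p <- pnorm((x - mu) / sg, lower.tail = FALSE)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("matched resampling preserves the target size multiset when possible", {
  d <- sample_matched_regions(c(200, 500), c(200, 500, 900), n = 20,
                              seed = 5)
  for (idx in d) expect_setequal(c(200, 500, 900)[idx], c(200, 500))
  # target = universe: every resample is the whole universe
  u <- c(100, 230, 560, 810)
  d2 <- sample_matched_regions(u, u, n = 10, seed = 1)
  for (idx in d2) expect_setequal(idx, 1:4)
  expect_error(sample_matched_regions(1:5, 1:3), "smaller")
})

test_that("matched resampling is seed-deterministic but varies across draws", {
  us <- sample(600:1500, 60, replace = TRUE)
  a <- sample_matched_regions(us[1:15], us, n = 25, seed = 9)
  b <- sample_matched_regions(us[1:15], us, n = 25, seed = 9)
  expect_identical(a, b)
  expect_gt(length(unique(vapply(a, paste, "", collapse = ","))), 1)
  # drawn sizes stay close to their targets
  for (idx in a[1:5])
    expect_true(all(abs(us[idx] - us[1:15]) <= 0.2 * us[1:15]))
})

test_that("planted motifs enrich and a self-universe yields z = 0", {
  set.seed(61)
  chrom <- random_dna_str(60000, gc = 0.5)
  genome <- Biostrings::DNAStringSet(c(cX = chrom))
  st <- seq(1000, 59000, by = 1500)[1:30]
  wd <- sample(300:500, 30, replace = TRUE)
  regions <- intervals("cX", st, st + wd)
  # plant the consensus in half of the first ten (target) regions
  for (i in c(1, 3, 5, 7, 9)) {
    s <- st[i] + 100
    Biostrings::subseq(genome[["cX"]], s, s + 6) <-
      Biostrings::DNAString("TGACTCA")
  }
  mo <- consensus_pwm("TGACTCA")
  decoy <- consensus_pwm("ACACACA", motif_id = "decoy")
  res <- enrich_motifs(regions[1:10], regions, list(mo, decoy), genome,
                       n = 60, seed = 2)
  expect_lt(res$padj[res$motif == "TGACTCA"], 0.05)
  expect_equal(res$x[1], res$z[1] * res$sigma[1] + res$mu[1])
  # target identical to universe: no enrichment is expressible
  self <- enrich_motifs(regions, regions, list(mo), genome, n = 20,
                        seed = 3)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
})

test_that("GC content excludes N from the denominator", {
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGTNNNNGGGG"))
  expect_equal(gc_content(intervals("c1", 1, 4), genome), 0.5)
  expect_true(is.na(gc_content(intervals("c1", 5, 8), genome)))
  expect_equal(gc_content(intervals("c1", 1, 12), genome), 6 / 8)
  expect_error(gc_content(intervals("c1", 5, 20), genome), "contig")
})

test_that("two-sided Z reporting exposes depletion", {
  rs <- c(10, 12, 14, 10, 12, 14)
  enr <- motif_zscore(20, rs, alternative = "two.sided")
  dep <- motif_zscore(4, rs, alternative = "two.sided")
  expect_lt(dep$z, 0)
  expect_equal(dep$p, 2 * pnorm(dep$z))
  expect_equal(enr$p, 2 * pnorm(-enr$z))
})

test_that("random genomic regions provide a size-matched GC control", {
  set.seed(2)
  genome <- Biostrings::DNAStringSet(c(cA = random_dna_str(40000, gc = 0.4),
                                       cB = random_dna_str(30000, gc = 0.4)))
  widths <- sample(200:800, 25, replace = TRUE)
  r1 <- random_genomic_regions(genome, widths, seed = 4)
  r2 <- random_genomic_regions(genome, widths, seed = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(GenomicRanges::width(r1), widths)
  expect_true(all(GenomicRanges::end(r1) <=
                    Biostrings::width(genome)[match(
                      as.character(GenomicRanges::seqnames(r1)),
                      names(genome))]))
  expect_error(random_genomic_regions(genome, 50000), "width exceeds")
  # GC-rich targets separate from genome-wide controls
  tg <- intervals("cA", 101, 700)
  Biostrings::subseq(genome[["cA"]], 101, 700) <-
    Biostrings::DNAString(random_dna_str(600, gc = 0.62))
  gs <- gc_summary(tg, intervals("cA", 1001, 1600), genome, seed = 1)
  expect_gt(gs$target - gs$random_genomic, 0.12)
})
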