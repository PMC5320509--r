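test_that("shift estimation recovers a planted strand offset", {
  set.seed(2)
  p <- sample(1000:8000, 400, replace = TRUE)
  reads <- c(intervals("c1", p, p + 49, "+"),
             intervals("c1", p + 97, p + 146, "-"))  # 5' ends 146 apart
  s <- estimate_shift(reads)
  expect_equal(as.integer(s), 73)
  expect_equal(attr(s, "fragment_length"), 146)
  # identical profiles: optimum at lag 0, smallest-lag tie rule
  r0 <- c(intervals("c1", p, p + 49, "+"), intervals("c1", p - 49, p, "-"))
  expect_equal(as.integer(estimate_shift(r0)), 0)
  expect_error(estimate_shift(intervals("c1", p, p + 49, "+")),
               "both strands")
})

test_that("shift estimation matches a brute-force correlation oracle", {
  set.seed(12)
  for (case in 1:5) {
    np <- 60
    fp <- sample(200:1500, np, replace = TRUE)
    fm <- sample(200:1500, np, replace = TRUE) + sample(20:80, 1)
    reads <- c(intervals("c1", fp, fp + 30, "+"),
               intervals("c1", fm - 30, fm, "-"))
    cc <- vapply(0:200, function(L) sum(outer(fp + L, fm, "==")), 0)
    want <- (which.max(cc) - 1L) %/% 2L
    expect_equal(as.integer(estimate_shift(reads, max_lag = 200)), want)
  }
})

test_that("a 200 bp fragment simulation estimates shift near 100", {
  set.seed(8)
  sites <- sample(2000:48000, 40)           # point sources
  site <- sample(sites, 2000, replace = TRUE)
  flen <- pmax(150, round(rnorm(2000, 200, 8)))
  f <- site - flen %/% 2 + sample(-20:20, 2000, replace = TRUE)
  strand <- sample(c("+", "-"), 2000, replace = TRUE)
  st <- ifelse(strand == "+", f, f + flen - 50)
  reads <- intervals("c1", st, st + 49, strand)
  s <- as.integer(estimate_shift(reads))
  expect_gte(s, 95)
  expect_lte(s, 105)
})

test_that("a stacked site on a quiet background yields exactly one peak", {
  set.seed(6)
  p <- sample(1:9950, 100, replace = TRUE)
  bg <- intervals("c1", p, p + 49,
                  sample(c("+", "-"), 100, replace = TRUE))
  sig <- intervals("c1", rep(5000, 30), rep(5049, 30), "+")
  pp <- peak_call_params(1e-4, shift = 25, mode = "global_background",
                         effective_genome_size = 1e4)
  pk <- call_peaks(c(bg, sig), pp, c(c1 = 10000))
  expect_equal(length(pk), 1)
  expect_true(start(pk) <= 5025 && end(pk) >= 5025)
  # oracle: the summit count's Poisson tail clears the threshold
  lambda <- 130 * 50 / 1e4
  expect_lt(ppois(pk$height - 1, lambda, lower.tail = FALSE), 1e-4)
  expect_length(call_peaks(GenomicRanges::GRanges(), pp, c(c1 = 10000)), 0)
})

test_that("peak regions match a brute-force pileup oracle on random cases", {
  set.seed(99)
  for (case in 1:25) {
    n <- sample(c(40, 80, 150), 1)
    shift <- sample(c(5L, 10L, 20L), 1)
    ext <- 2L * shift
    chrlen <- 3000L
    st <- sample(chrlen - 60L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    # plant one hotspot so most cases emit at least one peak
    st[1:15] <- sample(1400:1450, 15, replace = TRUE)
    reads <- intervals("c1", st, st + 49L, strand)
    pthr <- 10^-sample(3:5, 1)
    pp <- peak_call_params(pthr, shift = shift, mode = "global_background",
                           effective_genome_size = chrlen)
    pk <- call_peaks(reads, pp, c(c1 = chrlen))
    # brute-force pileup of shifted, 2*shift-extended tags
    five <- ifelse(strand == "+", st, st + 49L)
    center <- ifelse(strand == "+", five + shift, five - shift)
    cov <- integer(chrlen)
    for (ctr in center) {
      a <- max(ctr - shift + 1L, 1L); b <- min(a + ext - 1L, chrlen)
      cov[a:b] <- cov[a:b] + 1L
    }
    lambda <- n * ext / chrlen
    sig <- which(ppois(cov - 1, lambda, lower.tail = FALSE) < pthr)
    if (length(sig) == 0) {
      expect_length(pk, 0)
      next
    }
    grp <- cumsum(c(TRUE, diff(sig) > ext + 1L))  # gap <= ext merges
    want <- t(vapply(split(sig, grp), range, c(0, 0)))
    expect_equal(unname(cbind(start(pk), end(pk))), unname(want))
    expect_true(all(cov[pk$summit] == pk$height))
  }
})

test_that("local-lambda mode emits a subset of global-background peaks", {
  set.seed(14)
  st <- c(sample(1:19000, 400, replace = TRUE),
          sample(9000:11000, 400, replace = TRUE),  # broad local elevation
          rep(10000, 25))                           # sharp site inside it
  reads <- intervals("c1", st, st + 49,
                     sample(c("+", "-"), length(st), replace = TRUE))
  gs <- 20000
  glob <- call_peaks(reads, peak_call_params(1e-3, 20, "global_background",
                                             gs), c(c1 = gs))
  loc <- call_peaks(reads, peak_call_params(1e-3, 20, "local_lambda", gs),
                    c(c1 = gs))
  expect_lte(length(loc), length(glob))
  expect_true(all(overlaps_any_test(loc, glob)))
  # peak sets never overlap within themselves
  expect_true(all(countOverlaps(glob, glob) == 1))
})

test_that("duplicating every read never loses a planted peak", {
  set.seed(15)
  st <- c(sample(1:9000, 150, replace = TRUE), rep(4000, 20))
  reads <- intervals("c1", st, st + 49,
                     sample(c("+", "-"), length(st), replace = TRUE))
  pp <- peak_call_params(1e-4, 20, "global_background", 1e4)
  one <- call_peaks(reads, pp, c(c1 = 10000))
  two <- call_peaks(c(reads, reads), pp, c(c1 = 10000))
  planted_in <- function(pk) any(start(pk) <= 4020 & end(pk) >= 4020)
  expect_true(planted_in(one))
  expect_true(planted_in(two))
})
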