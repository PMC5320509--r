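test_that("nearest-gene assignment uses TSS distance with lexicographic ties", {
  genes <- c(intervals("c1", 10001, 12000, "+"),
             intervals("c1", 60001, 62000, "-"))
  genes$gene_id <- c("B", "A")
  # midpoint 15000: 5 kb from B's TSS (10001), 47 kb from A's TSS (62000)
  e1 <- intervals("c1", 14001, 16000)
  expect_equal(assign_nearest_gene(e1, genes), "B")
  # equidistant: A wins lexicographically; TSS at 10001 and 62000,
  # midpoint 36001 is 26000 from both
  e2 <- intervals("c1", 36001, 36001)
  expect_equal(assign_nearest_gene(e2, genes), "A")
  expect_true(is.na(assign_nearest_gene(e1, genes, max_distance = 1000)))
  e3 <- intervals("c9", 100, 200)
  expect_true(is.na(assign_nearest_gene(e3, genes)))
})

test_that("nearest-gene assignment matches the exhaustive scan", {
  set.seed(77)
  genes <- random_granges(40, max_pos = 100000, max_width = 3000)
  genes$gene_id <- sprintf("G%02d", sample(99, 40))
  ernas <- random_granges(500, max_pos = 100000, max_width = 1500,
                          stranded = FALSE)
  expect_equal(assign_nearest_gene(ernas, genes), bf_nearest(ernas, genes))
})

test_that("observed-vs-expected chi-square matches the worked example", {
  r <- overlap_enrichment(50, 100, 250, 1000)
  expect_equal(r$expected, 25)
  expect_equal(r$chi2, 25^2 / 25 + 25^2 / 75, tolerance = 1e-12)
  expect_equal(r$chi2, 33.33, tolerance = 1e-2)
  expect_true(r$p < 1e-2 && r$enriched)
  # exact agreement with expectation: statistic zero, not enriched
  r0 <- overlap_enrichment(25, 100, 250, 1000)
  expect_equal(r0$chi2, 0)
  expect_false(r0$enriched)
  # strong depletion is significant but not "enriched"
  rd <- overlap_enrichment(2, 100, 500, 1000)
  expect_lt(rd$p, 1e-4)
  expect_false(rd$enriched)
  expect_error(overlap_enrichment(0, 100, 0, 1000), "zero")
})

test_that("chi-square agrees with the independently coded textbook test", {
  set.seed(55)
  for (i in 1:100) {
    universe <- sample(200:2000, 1)
    hits_u <- sample(10:(universe - 10), 1)
    subset <- sample(20:(universe %/% 2), 1)
    hits_s <- sample(0:subset, 1)
    rate <- hits_u / universe
    if (subset * rate < 1 || subset * (1 - rate) < 1) next
    r <- overlap_enrichment(hits_s, subset, hits_u, universe)
    want <- suppressWarnings(
      stats::chisq.test(c(hits_s, subset - hits_s),
                        p = c(rate, 1 - rate)))
    expect_equal(r$chi2, unname(want$statistic), tolerance = 1e-9)
    expect_equal(r$p, want$p.value, tolerance = 1e-9)
  }
})

test_that("RNAPII percentage arithmetic reproduces report-style rounding", {
  expect_equal(rnapii_rates(1, 3, 0, 4, 10, 10)$pct_lost, 33)
  r <- rnapii_rates(127, 331, 18, 351, 3248, 2990)
  expect_equal(r$pct_lost, 38)
  expect_equal(r$pct_gained, 5)
  expect_equal(r$pct_overall_decrease, 8)
})

test_that("RNAPII accounting is partition-consistent on random catalogues", {
  set.seed(66)
  ernas <- random_granges(200, max_pos = 50000, max_width = 800,
                          stranded = FALSE)
  ernas$status <- sample(c("down", "up", "unchanged"), 200, replace = TRUE)
  pw <- random_granges(60, max_pos = 50000, max_width = 400)
  ph <- random_granges(60, max_pos = 50000, max_width = 400)
  acc <- rnapii_accounting(ernas, pw, ph)
  per <- acc$per_status
  expect_equal(sum(per$n), 200)
  expect_true(all(per$n_lost <= per$n_with_wt_peak))
  expect_equal(sum(per$n_with_wt_peak), acc$n_with_peak_wt)
  has_wt <- countOverlaps(ernas, pw) > 0
  has_hd <- countOverlaps(ernas, ph) > 0
  retained <- sum(has_wt & has_hd)
  expect_equal(acc$n_with_peak_wt, sum(per$n_lost) + retained)
})

test_that("gene-set intersection reports the expected sizes", {
  r <- crosslist(c("x", "y", "z"), c("y", "z", "w"))
  expect_setequal(r$intersection, c("y", "z"))
  expect_equal(c(r$n_a, r$n_b, r$n_intersection), c(3, 3, 2))
  expect_equal(crosslist(c("a"), c("b"))$n_intersection, 0)
  expect_setequal(crosslist(c("a", "b"), c("a", "b", "c"))$intersection,
                  c("a", "b"))
})

test_that("island size profiles sum overlapping island widths per condition", {
  ernas <- c(intervals("c1", 1000, 1500), intervals("c1", 9000, 9400))
  ernas$status <- c("down", "up")
  iw <- intervals("c1", 500, 5499)       # 5 kb island over eRNA 1
  ih <- c(intervals("c1", 800, 2799),    # 2 kb island over eRNA 1
          intervals("c1", 9100, 9300))
  sp <- size_profile(ernas, iw, ih)
  expect_equal(sp$widths$width_wt, c(5000, 0))
  expect_equal(sp$widths$width_hd, c(2000, 201))
  same <- size_profile(ernas, iw, iw)
  expect_equal(same$widths$width_wt, same$widths$width_hd)
})

test_that("the 2x2 independence form is available and close to the default", {
  g <- overlap_enrichment(50, 100, 250, 1000)
  i <- overlap_enrichment(50, 100, 250, 1000, form = "independence")
  expect_true(i$enriched)
  expect_gt(i$chi2, g$chi2 * 0.8)
  want <- suppressWarnings(stats::chisq.test(
    rbind(c(50, 50), c(200, 700)), correct = FALSE))
  expect_equal(i$chi2, unname(want$statistic), tolerance = 1e-9)
})
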