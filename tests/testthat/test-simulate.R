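test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_erna_dataset(small_sim_config(seed = 11))
  b <- simulate_erna_dataset(small_sim_config(seed = 11))
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.data.frame(a$rna_reads$WT[[1]]),
                   as.data.frame(b$rna_reads$WT[[1]]))
  c2 <- simulate_erna_dataset(small_sim_config(seed = 12))
  expect_false(identical(a$truth$start, c2$truth$start))
})

test_that("planted enhancers stay clear of all default genic masks", {
  sim <- simulate_erna_dataset(small_sim_config(seed = 21))
  mask <- build_genic_mask(sim$genes, 3000, 10000, sim$chrom_sizes)
  tg <- truth_granges(sim$truth)
  expect_equal(sum(countOverlaps(tg, mask, ignore.strand = TRUE)), 0)
  # islands of neighbouring enhancers do not reach into masks either
  expect_equal(sum(countOverlaps(sim$islands$WT, mask,
                                 ignore.strand = TRUE)), 0)
  # truth bookkeeping matches the config
  cfg <- sim$config
  expect_equal(nrow(sim$truth), cfg$n_enhancers)
  expect_equal(sum(sim$truth$class == "super"), cfg$n_super)
  expect_equal(sum(sim$truth$status == "down"), cfg$n_down)
  expect_equal(sum(sim$truth$status == "up"), cfg$n_up)
})

test_that("enhancer sequence GC matches the configured composition", {
  sim <- simulate_erna_dataset(small_sim_config(seed = 31))
  tg <- truth_granges(sim$truth)
  wide <- tg[GenomicRanges::width(tg) >= 1000]
  gc <- gc_content(wide, sim$genome)
  expect_true(all(abs(gc - sim$config$enhancer_gc) <= 0.05))
  expect_equal(mean(gc), sim$config$enhancer_gc, tolerance = 0.02)
  # background clearly lower
  bgr <- intervals(names(sim$chrom_sizes)[1], 1, 15000)
  expect_equal(gc_content(bgr, sim$genome), sim$config$background_gc,
               tolerance = 0.03)
})

test_that("genic reads map antisense to their source gene", {
  sim <- simulate_erna_dataset(small_sim_config(seed = 41))
  reads <- sim$rna_reads$WT[[1]]
  plus_genes <- sim$genes[strand(sim$genes) == "+"]
  inner <- GenomicRanges::resize(plus_genes,
                                 pmax(GenomicRanges::width(plus_genes) - 400, 1),
                                 fix = "center")
  hit <- reads[countOverlaps(reads, inner, ignore.strand = TRUE) > 0]
  # gene bodies dominate over background, so the antisense strand does too
  expect_gt(mean(as.character(strand(hit)) == "-"), 0.9)
})

test_that("doubling the depth doubles expected and realised eRNA counts", {
  cfg1 <- small_sim_config(seed = 51)
  cfg2 <- small_sim_config(seed = 51, depth = 2 * cfg1$depth)
  s1 <- simulate_erna_dataset(cfg1)
  s2 <- simulate_erna_dataset(cfg2)
  expect_equal(s2$truth$mu_wt, 2 * s1$truth$mu_wt)
  tg <- truth_granges(s1$truth)
  n1 <- sum(countOverlaps(tg, do.call(c, s1$rna_reads$WT)))
  n2 <- sum(countOverlaps(tg, do.call(c, s2$rna_reads$WT)))
  # realised counts carry NB noise; ratio sd here is about 0.05
  expect_gt(n2 / n1, 1.7)
  expect_lt(n2 / n1, 2.3)
})

test_that("infeasible placements are refused", {
  expect_error(simulate_erna_dataset(
    sim_config(genome_size = 1e5, n_genes = 30, n_enhancers = 40)),
    "infeasible")
})

test_that("recovery scoring handles identity and empty catalogues", {
  sim <- simulate_erna_dataset(small_sim_config(seed = 61))
  tg <- truth_granges(sim$truth)
  perfect <- score_recovery(sim$truth, tg)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$precision, 1)
  none <- score_recovery(sim$truth, GenomicRanges::GRanges())
  expect_equal(none$sensitivity, 0)
})

test_that("reads mode emits ChIP libraries the island caller recovers", {
  sim <- simulate_erna_dataset(small_sim_config(seed = 71,
                                                h3k27ac_mode = "reads"))
  ip <- island_call_params(mc_reps = 2)
  isl <- call_islands(sim$chip_reads$WT, sim$control_reads, ip,
                      sim$chrom_sizes)
  tg <- truth_granges(sim$truth)
  covered <- mean(countOverlaps(tg, isl) > 0)
  expect_gte(covered, 0.9)
})

test_that("a written dataset round-trips through the file readers", {
  sim <- simulate_erna_dataset(small_sim_config(seed = 81))
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  genes <- read_gtf(file.path(dir, "genes.gtf"))
  expect_equal(length(genes), length(sim$genes))
  expect_equal(start(genes), start(sort(sim$genes, ignore.strand = TRUE)))
  reads <- read_alignments(file.path(dir, "rna_WT_rep1.bed"), "bed")
  orig <- sim$rna_reads$WT[[1]]
  expect_equal(length(reads), length(orig))
  expect_equal(sum(reads$is_split), sum(orig$is_split))
  isl <- read_bed(file.path(dir, "h3k27ac_islands_HD.bed"))
  expect_equal(length(isl), length(sim$islands$HD))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(unname(Biostrings::width(genome)),
               unname(as.integer(sim$chrom_sizes)))
})
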