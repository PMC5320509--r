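#' Configuration for the synthetic two-condition eRNA dataset
#'
#' Defines a small two-contig genome carrying protein-coding genes and
#' intergenic transcribed enhancers (typical and broad/super), two
#' conditions (WT and HD) with planted eRNA fold changes, strand-specific
#' RNA-seq reads with genic read-through, H3K27ac islands, RNAPII peaks
#' and planted motif instances. Defaults describe the study conditions the
#' package is validated under.
#'
#' @param genome_size Total genome size in bases (default 2e6, split over
#'   `n_contigs`).
#' @param n_contigs Number of contigs (default 2).
#' @param n_genes Number of genes (default 40).
#' @param n_enhancers Number of enhancers (default 60).
#' @param n_super Broad (super-enhancer-like) enhancers among them
#'   (default 12).
#' @param background_gc,enhancer_gc Genome / enhancer GC fractions
#'   (defaults 0.42, 0.55).
#' @param read_length,fragment_length Read and fragment lengths in bases
#'   (defaults 50, 200).
#' @param depth RNA-seq reads per condition, summed over replicates
#'   (default 4e5).
#' @param n_replicates Replicates per condition (default 4).
#' @param readthrough_decay Exponential scale of post-TES read-through,
#'   bases (default 2000).
#' @param erna_enrichment Enhancer transcription rate as a fold over the
#'   intergenic background (default 10).
#' @param n_down,n_up Enhancers planted with decreased / increased eRNA in
#'   HD (defaults 15, 8).
#' @param fold_down,fold_up Planted HD/WT fold changes (defaults 0.25, 4).
#' @param nb_dispersion Negative binomial dispersion of replicate counts
#'   (default 0.05).
#' @param motif_consensus Consensus planted centrally in a fraction of
#'   down-enhancers (default `"TGACTCA"`).
#' @param motif_plant_fraction Fraction of down-enhancers carrying the
#'   consensus (default 0.5).
#' @param rnapii_loss_fraction Fraction of down-enhancers whose RNAPII
#'   peak is absent in HD (default 0.4).
#' @param rnapii_gain_fraction Fraction of up-enhancers with an HD-only
#'   RNAPII peak (default 0.25).
#' @param split_read_fraction Fraction of reads flagged split-mapped
#'   (default 0.02).
#' @param h3k27ac_mode `"islands"` emits per-condition island intervals
#'   directly; `"reads"` additionally emits ChIP and control reads to
#'   exercise the island caller.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_size = 2e6, n_contigs = 2L, n_genes = 40L,
                       n_enhancers = 60L, n_super = 12L,
                       background_gc = 0.42, enhancer_gc = 0.55,
                       read_length = 50L, fragment_length = 200L,
                       depth = 4e5, n_replicates = 4L,
                       readthrough_decay = 2000,
                       erna_enrichment = 10,
                       n_down = 15L, n_up = 8L,
                       fold_down = 0.25, fold_up = 4,
                       nb_dispersion = 0.05,
                       motif_consensus = "TGACTCA",
                       motif_plant_fraction = 0.5,
                       rnapii_loss_fraction = 0.4,
                       rnapii_gain_fraction = 0.25,
                       split_read_fraction = 0.02,
                       h3k27ac_mode = c("islands", "reads"),
                       seed = 17L) {
  cfg <- as.list(environment())
  cfg$h3k27ac_mode <- match.arg(h3k27ac_mode)
  stopifnot(n_super <= n_enhancers, n_down + n_up <= n_enhancers,
            n_replicates >= 2)
  structure(cfg, class = "sim_config")
}

# internal: random DNA of a given GC fraction
random_dna <- function(n, gc) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# internal: lay genes and enhancers along contigs with buffer zones so no
# enhancer falls inside any default extended genic mask and islands of
# neighbouring enhancers cannot touch
layout_elements <- function(cfg) {
  contig_len <- floor(cfg$genome_size / cfg$n_contigs)
  per_genes <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_contigs + 1)))
  per_enh <- diff(round(seq(0, cfg$n_enhancers,
                            length.out = cfg$n_contigs + 1)))
  genes <- list(); enh <- list()
  for (ci in seq_len(cfg$n_contigs)) {
    ch <- paste0("chrS", ci)
    ng <- per_genes[ci]; ne <- per_enh[ci]
    # two gene clusters per contig, enhancers in three surrounding zones
    gene_cluster_sizes <- diff(round(seq(0, ng, length.out = 3)))
    enh_zone_sizes <- diff(round(seq(0, ne, length.out = 4)))
    cursor <- 20000 + sample(0:2000, 1)
    e_done <- 0; g_done <- 0
    widths_e <- integer(0)
    plan <- c("E", "G", "E", "G", "E")
    zone_e <- 1; zone_g <- 1
    for (z in plan) {
      if (z == "E") {
        for (k in seq_len(enh_zone_sizes[zone_e])) {
          w <- sample(600:1500, 1)   # provisional; super widened later
          enh[[length(enh) + 1]] <- list(chrom = ch, start = cursor,
                                         width = w)
          cursor <- cursor + w + 16000 + sample(0:2000, 1)
        }
        zone_e <- zone_e + 1
      } else {
        cursor <- cursor + 18000
        for (k in seq_len(gene_cluster_sizes[zone_g])) {
          w <- sample(2000:6000, 1)
          genes[[length(genes) + 1]] <- list(chrom = ch, start = cursor,
                                             width = w)
          cursor <- cursor + w + 2000 + sample(0:1000, 1)
        }
        cursor <- cursor + 18000
        zone_g <- zone_g + 1
      }
      if (cursor > contig_len - 20000)
        stop("infeasible placement: too many elements for genome_size")
    }
  }
  list(genes = genes, enhancers = enh, contig_len = contig_len)
}

#' Generate a synthetic two-condition eRNA dataset with known truth
#'
#' See [sim_config()] for the generated structure. Genic reads map
#' antisense to their gene (first-strand chemistry) and continue past the
#' gene end with exponentially decaying read-through; enhancer reads are
#' bidirectional at `erna_enrichment` times the intergenic background,
#' scaled per condition by the planted fold change with NB replicate
#' noise; a fixed fraction of reads is flagged split-mapped. All outputs
#' are deterministic under the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (`DNAStringSet`), `chrom_sizes`, `genes`
#'   (`GRanges`), `rna_reads` (list `WT`/`HD` of per-replicate read
#'   `GRanges`), `islands` (list `WT`/`HD`), optional `chip_reads` /
#'   `control_reads`, `rnapii` (list `WT`/`HD` of peak `GRanges`),
#'   `super_enhancers` (`GRanges`), `truth` (data.frame) and `config`.
#' @export
simulate_erna_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  lay <- layout_elements(cfg)
  chrom_sizes <- stats::setNames(rep(lay$contig_len, cfg$n_contigs),
                                 paste0("chrS", seq_len(cfg$n_contigs)))

  ne <- length(lay$enhancers)
  class <- rep("typical", ne)
  class[sample(ne, cfg$n_super)] <- "super"
  status <- rep("null", ne)
  sup_idx <- which(class == "super")
  typ_idx <- which(class == "typical")
  n_down_super <- min(cfg$n_down, length(sup_idx))
  down_idx <- c(sup_idx[seq_len(n_down_super)],
                sample(typ_idx, cfg$n_down - n_down_super))
  status[down_idx] <- "down"
  up_idx <- sample(setdiff(typ_idx, down_idx), cfg$n_up)
  status[up_idx] <- "up"

  e_chrom <- vapply(lay$enhancers, `[[`, "", "chrom")
  e_start <- vapply(lay$enhancers, function(x) x$start, 0)
  e_width <- vapply(lay$enhancers, function(x) x$width, 0)
  e_end <- e_start + e_width - 1

  g_chrom <- vapply(lay$genes, `[[`, "", "chrom")
  g_start <- vapply(lay$genes, function(x) x$start, 0)
  g_width <- vapply(lay$genes, function(x) x$width, 0)
  g_strand <- sample(c("+", "-"), length(lay$genes), replace = TRUE)
  genes <- GenomicRanges::GRanges(
    g_chrom, IRanges::IRanges(g_start, width = g_width), strand = g_strand,
    gene_id = sprintf("SYNG%04d", seq_along(lay$genes)),
    biotype = "protein_coding")

  # genome sequence: background GC with enhancer-GC spans and planted motif
  motif_planted <- rep(FALSE, ne)
  plant <- sample(down_idx, round(cfg$motif_plant_fraction *
                                    length(down_idx)))
  motif_planted[plant] <- TRUE
  genome <- Biostrings::DNAStringSet(vapply(names(chrom_sizes), function(ch) {
    paste(random_dna(chrom_sizes[[ch]], cfg$background_gc), collapse = "")
  }, ""))
  names(genome) <- names(chrom_sizes)
  for (i in seq_len(ne)) {
    seq_i <- random_dna(e_width[i], cfg$enhancer_gc)
    if (motif_planted[i]) {
      mo <- strsplit(cfg$motif_consensus, "")[[1]]
      at <- floor((e_width[i] - length(mo)) / 2) + 1
      seq_i[at:(at + length(mo) - 1)] <- mo
    }
    Biostrings::subseq(genome[[e_chrom[i]]], e_start[i], e_end[i]) <-
      Biostrings::DNAString(paste(seq_i, collapse = ""))
  }

  # expected read budget per replicate
  d_rep <- cfg$depth / cfg$n_replicates
  n_bg <- round(0.35 * d_rep)
  r0 <- n_bg / sum(chrom_sizes)              # background reads per bp
  fold <- ifelse(status == "down", cfg$fold_down,
                 ifelse(status == "up", cfg$fold_up, 1))
  mu_wt <- cfg$erna_enrichment * r0 * e_width
  gw <- stats::rlnorm(length(genes), 0, 0.8)
  n_genic <- max(round(d_rep - n_bg - sum(mu_wt)), 1000)
  mu_gene <- n_genic * gw / sum(gw)

  rl <- cfg$read_length
  fl <- cfg$fragment_length
  # single-end fragment-end reads: a sequenced fragment [f, f+fl) yields a
  # 5'-anchored read at the left end when it maps "+" and at the right end
  # when it maps "-", so the +/- 5' profiles sit ~fl apart around a
  # transcribed locus and estimate_shift() can recover fl/2
  read_pos_from_fragment <- function(f, strand) {
    ifelse(strand == "+", f, f + fl - rl)
  }
  sample_gene_reads <- function() {
    cnt <- stats::rnbinom(length(genes), mu = mu_gene,
                          size = 1 / cfg$nb_dispersion)
    idx <- rep(seq_along(genes), cnt)
    rt <- stats::runif(length(idx)) < 0.15   # read-through fraction
    f <- floor(stats::runif(length(idx), g_start[idx],
                            pmax(g_start[idx] + 1,
                                 g_start[idx] + g_width[idx] - fl)))
    dist <- stats::rexp(sum(rt), 1 / cfg$readthrough_decay)
    plus <- g_strand[idx] == "+"
    gend <- g_start[idx] + g_width[idx] - 1
    f[rt] <- ifelse(plus[rt], gend[rt] + floor(dist),
                    g_start[idx[rt]] - floor(dist) - fl)
    strand <- ifelse(plus, "-", "+")         # antisense chemistry
    list(chrom = g_chrom[idx], pos = read_pos_from_fragment(f, strand),
         strand = strand)
  }
  sample_enhancer_reads <- function(cond_fold) {
    cnt <- stats::rnbinom(ne, mu = mu_wt * cond_fold,
                          size = 1 / cfg$nb_dispersion)
    idx <- rep(seq_len(ne), cnt)
    f <- floor(stats::runif(length(idx), e_start[idx] - fl / 2,
                            pmax(e_start[idx] - fl / 2 + 1,
                                 e_end[idx] - fl / 2)))
    strand <- sample(c("+", "-"), length(idx), replace = TRUE)
    list(chrom = e_chrom[idx], pos = read_pos_from_fragment(f, strand),
         strand = strand, idx = idx)
  }
  sample_background_reads <- function() {
    chrom <- sample(names(chrom_sizes), n_bg, replace = TRUE,
                    prob = chrom_sizes / sum(chrom_sizes))
    f <- floor(stats::runif(n_bg, 1, chrom_sizes[chrom] - fl))
    strand <- sample(c("+", "-"), n_bg, replace = TRUE)
    list(chrom = chrom, pos = read_pos_from_fragment(f, strand),
         strand = strand)
  }
  make_replicate <- function(cond) {
    g <- sample_gene_reads()
    e <- sample_enhancer_reads(if (cond == "HD") fold else rep(1, ne))
    b <- sample_background_reads()
    chrom <- c(g$chrom, e$chrom, b$chrom)
    pos <- pmax(c(g$pos, e$pos, b$pos), 1)
    lim <- chrom_sizes[chrom] - rl
    pos <- pmin(pos, lim)
    strand <- c(g$strand, e$strand, b$strand)
    n <- length(pos)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = rl),
                           strand = strand,
                           is_split = stats::runif(n) < cfg$split_read_fraction,
                           n_blocks = 1L)
  }
  rna_reads <- list(
    WT = lapply(seq_len(cfg$n_replicates), function(r) make_replicate("WT")),
    HD = lapply(seq_len(cfg$n_replicates), function(r) make_replicate("HD")))

  # H3K27ac islands: broad at super enhancers, shrunk in HD at down eRNAs
  isl_w_wt <- ifelse(class == "super",
                     sample(8000:15000, ne, replace = TRUE),
                     sample(800:2000, ne, replace = TRUE))
  isl_w_hd <- ifelse(status == "down", round(isl_w_wt * 0.6), isl_w_wt)
  center <- (e_start + e_end) %/% 2
  make_islands <- function(w) {
    st <- pmax(center - w %/% 2, 1)
    GenomicRanges::GRanges(e_chrom,
                           IRanges::IRanges(st, width = w),
                           enhancer_id = sprintf("SYNE%04d", seq_len(ne)))
  }
  islands <- list(WT = make_islands(isl_w_wt), HD = make_islands(isl_w_hd))

  # RNAPII peaks (400 bp, centred): all enhancers have a WT peak except
  # "gained" ups; a fraction of down enhancers lose the HD peak
  rnapii_wt_flag <- rep(TRUE, ne)
  gain <- sample(up_idx, round(cfg$rnapii_gain_fraction * length(up_idx)))
  rnapii_wt_flag[gain] <- FALSE
  rnapii_hd_flag <- rep(TRUE, ne)
  lose <- sample(down_idx, round(cfg$rnapii_loss_fraction * length(down_idx)))
  rnapii_hd_flag[lose] <- FALSE
  pii <- GenomicRanges::GRanges(e_chrom,
                                IRanges::IRanges(pmax(center - 200, 1),
                                                 width = 400))
  rnapii <- list(WT = pii[rnapii_wt_flag], HD = pii[rnapii_hd_flag])

  out <- list(
    genome = genome, chrom_sizes = chrom_sizes, genes = genes,
    rna_reads = rna_reads, islands = islands, rnapii = rnapii,
    super_enhancers = GenomicRanges::GRanges(
      e_chrom[class == "super"],
      IRanges::IRanges(GenomicRanges::start(islands$WT)[class == "super"],
                       GenomicRanges::end(islands$WT)[class == "super"])),
    truth = data.frame(
      enhancer_id = sprintf("SYNE%04d", seq_len(ne)),
      chrom = e_chrom, start = e_start, end = e_end, class = class,
      status = status, fold_change = fold, motif_planted = motif_planted,
      rnapii_wt = rnapii_wt_flag, rnapii_hd = rnapii_hd_flag,
      island_width_wt = isl_w_wt, island_width_hd = isl_w_hd,
      mu_wt = mu_wt),
    config = cfg)

  if (cfg$h3k27ac_mode == "reads") {
    chip_density <- 0.3
    make_chip <- function(isl) {
      w <- GenomicRanges::width(isl)
      cnt <- stats::rpois(length(isl), chip_density * w)
      idx <- rep(seq_along(isl), cnt)
      pos <- floor(stats::runif(length(idx), GenomicRanges::start(isl)[idx],
                                GenomicRanges::end(isl)[idx] - rl + 1))
      n_c_bg <- round(0.02 * sum(chrom_sizes))  # sparse uniform background
      bgc <- sample(names(chrom_sizes), n_c_bg, replace = TRUE)
      bgp <- floor(stats::runif(n_c_bg, 1, chrom_sizes[bgc] - rl))
      GenomicRanges::GRanges(
        c(as.character(GenomeInfoDb::seqnames(isl))[idx], bgc),
        IRanges::IRanges(pmax(c(pos, bgp), 1), width = rl),
        strand = sample(c("+", "-"), length(idx) + n_c_bg, replace = TRUE))
    }
    out$chip_reads <- list(WT = make_chip(islands$WT),
                           HD = make_chip(islands$HD))
    n_ctrl <- round(0.02 * sum(chrom_sizes))
    cbc <- sample(names(chrom_sizes), n_ctrl, replace = TRUE)
    out$control_reads <- GenomicRanges::GRanges(
      cbc, IRanges::IRanges(floor(stats::runif(n_ctrl, 1,
                                               chrom_sizes[cbc] - rl)),
                            width = rl),
      strand = sample(c("+", "-"), n_ctrl, replace = TRUE))
  }
  out
}

#' Truth enhancers as a GRanges
#'
#' @param truth The `truth` data.frame from [simulate_erna_dataset()].
#' @return `GRanges` with the truth metadata columns.
#' @export
truth_granges <- function(truth) {
  GenomicRanges::GRanges(truth$chrom,
                         IRanges::IRanges(truth$start, truth$end),
                         enhancer_id = truth$enhancer_id,
                         class = truth$class, status = truth$status,
                         motif_planted = truth$motif_planted)
}

#' Score catalogue recovery against planted truth
#'
#' A truth enhancer is recovered iff at least one catalogue record
#' overlaps it by >= 1 bp; a catalogue record is a true positive iff it
#' overlaps any truth element. The confusion matrix crosses planted
#' status with the called status of the overlapping record.
#'
#' @param truth Truth data.frame from [simulate_erna_dataset()].
#' @param catalogue `GRanges` eRNA records (optionally with a `status`
#'   metadata column).
#' @return List `sensitivity`, `precision`, `n_truth`, `n_catalogue`,
#'   `confusion` (table, possibly empty).
#' @export
score_recovery <- function(truth, catalogue) {
  tg <- truth_granges(truth)
  if (length(catalogue) == 0)
    return(list(sensitivity = 0, precision = NA_real_,
                n_truth = length(tg), n_catalogue = 0, confusion = table(NULL)))
  recovered <- overlaps_any(tg, catalogue)
  tp <- overlaps_any(catalogue, tg)
  conf <- table(NULL)
  if (!is.null(S4Vectors::mcols(catalogue)$status)) {
    h <- GenomicRanges::findOverlaps(tg, catalogue, ignore.strand = TRUE)
    planted <- truth$status[S4Vectors::queryHits(h)]
    called <- S4Vectors::mcols(catalogue)$status[S4Vectors::subjectHits(h)]
    conf <- table(planted = planted, called = called)
  }
  list(sensitivity = mean(recovered), precision = mean(tp),
       n_truth = length(tg), n_catalogue = length(catalogue),
       confusion = conf)
}

#' Write a simulated dataset to standard-format files
#'
#' Exports the generated study to a directory: `genome.fa` (FASTA),
#' `genes.gtf`, per-replicate read BEDs (`rna_<cond>_rep<i>.bed`),
#' H3K27ac islands, RNAPII peaks and super-enhancers as BED, and
#' `truth.tsv` — the on-disk face of the generator for use with the
#' file-based readers.
#'
#' @param sim Result of [simulate_erna_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  g <- sim$genes
  lines <- sprintf(
    "%s\ternakit_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
    as.character(GenomeInfoDb::seqnames(g)), GenomicRanges::start(g),
    GenomicRanges::end(g), as.character(GenomicRanges::strand(g)),
    g$gene_id, g$biotype)
  writeLines(lines, file.path(dir, "genes.gtf"))
  write_reads_bed <- function(reads, path) {
    df <- data.frame(as.character(GenomeInfoDb::seqnames(reads)),
                     GenomicRanges::start(reads) - 1L,
                     GenomicRanges::end(reads),
                     sprintf("read%07d", seq_along(reads)), 0L,
                     as.character(GenomicRanges::strand(reads)),
                     ifelse(S4Vectors::mcols(reads)$is_split, 2L, 1L))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  for (cond in names(sim$rna_reads))
    for (i in seq_along(sim$rna_reads[[cond]]))
      write_reads_bed(sim$rna_reads[[cond]][[i]],
                      file.path(dir, sprintf("rna_%s_rep%d.bed", cond, i)))
  for (cond in names(sim$islands))
    write_bed(sim$islands[[cond]],
              file.path(dir, sprintf("h3k27ac_islands_%s.bed", cond)))
  for (cond in names(sim$rnapii))
    write_bed(sim$rnapii[[cond]],
              file.path(dir, sprintf("rnapii_peaks_%s.bed", cond)))
  write_bed(sim$super_enhancers, file.path(dir, "super_enhancers.bed"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
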