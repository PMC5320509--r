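#' Gene biotypes masked during eRNA read filtering
#'
#' The default set of Ensembl gene biotypes whose (extended) gene bodies are
#' excluded when selecting putative eRNA reads: immunoglobulin and T-cell
#' receptor segments, mitochondrial and cytoplasmic rRNA/tRNA, pseudogenes
#' and protein-coding genes.
#'
#' @return Character vector of 13 biotype labels.
#' @export
default_mask_biotypes <- function() {
  c("IG_C_gene", "IGD_gene", "IG_J_gene", "IG_LV_gene", "IG_V_pseudogene",
    "Mt_rRNA", "Mt_tRNA", "polymorphic_pseudogene", "protein_coding",
    "pseudogene", "rRNA", "TR_V_gene", "TR_V_pseudogene")
}

#' Read gene models from a GTF file
#'
#' Imports gene records from an Ensembl-dialect GTF and keeps genes whose
#' biotype is in `biotype_filter`. When the file has no explicit `gene`
#' feature rows, per-gene spans are formed as the range of all features
#' sharing a `gene_id` (full gene span, not per transcript).
#'
#' @param path GTF file path.
#' @param biotype_filter Character vector of biotypes to keep;
#'   defaults to [default_mask_biotypes()].
#' @return `GRanges` with metadata columns `gene_id` and `biotype`,
#'   strand `+` or `-`.
#' @export
read_gtf <- function(path, biotype_filter = default_mask_biotypes()) {
  raw <- readLines(path)
  if (length(raw) == 0 || all(grepl("^#", raw) | !nzchar(raw)))
    return(GenomicRanges::GRanges(gene_id = character(),
                                  biotype = character()))
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in '", path,
                                          "': ", conditionMessage(e)))
  if (length(gr) == 0) {
    return(GenomicRanges::GRanges(gene_id = character(), biotype = character()))
  }
  mc <- S4Vectors::mcols(gr)
  bt_col <- intersect(c("gene_biotype", "biotype", "gene_type"), names(mc))[1]
  if (is.na(bt_col)) stop("GTF has no gene biotype attribute")
  if ("type" %in% names(mc) && any(mc$type == "gene")) {
    gr <- gr[mc$type == "gene"]
  } else {
    # fall back to per-gene span over all features
    sp <- split(gr, S4Vectors::mcols(gr)$gene_id)
    rng <- unlist(range(sp))
    ids <- names(rng)
    bt <- S4Vectors::mcols(gr)[[bt_col]][match(ids, S4Vectors::mcols(gr)$gene_id)]
    gr <- rng
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = ids, biotype = bt)
  }
  if (any(as.character(GenomicRanges::strand(gr)) == "*"))
    stop("gene record without strand in '", path, "'")
  mc <- S4Vectors::mcols(gr)
  bt <- if ("biotype" %in% names(mc)) mc$biotype else mc[[bt_col]]
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(gene_id = mc$gene_id,
                                                biotype = bt)
  out <- out[bt %in% biotype_filter]
  names(out) <- NULL
  normalize_intervals(out)
}

# internal: reference-consumed width and N-gap count from a CIGAR string
cigar_ref_stats <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  vapply(ops, function(x) {
    n <- as.integer(sub("[A-Z=]$", "", x))
    op <- sub("^[0-9]+", "", x)
    c(width = sum(n[op %in% c("M", "D", "N", "=", "X")]),
      n_gaps = sum(op == "N"))
  }, c(width = 0, n_gaps = 0))
}

#' Read strand-specific alignments from SAM text or BED
#'
#' Produces one record per primary mapped alignment. For SAM, strand comes
#' from FLAG bit 0x10 and a read is split-mapped iff its CIGAR contains an
#' `N` operation; secondary (0x100), supplementary (0x800) and unmapped
#' records are dropped. For BED (6 columns, optional 7th `blockCount`
#' column), a read is split iff `blockCount > 1`.
#'
#' @param path File path.
#' @param format `"sam"`, `"bed"`, or `"auto"` (by file extension).
#' @return `GRanges` with strand and metadata columns `is_split`, `n_blocks`.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  }
  if (format == "sam") read_alignments_sam(path) else read_alignments_bed(path)
}

read_alignments_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    warning("no alignment records in '", path, "'")
    return(empty_reads())
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11)) stop("malformed SAM line ", which(nf < 11)[1])
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  keep <- bitwAnd(flag, 0x4) == 0 & bitwAnd(flag, 0x100) == 0 &
    bitwAnd(flag, 0x800) == 0
  if (!any(keep)) {
    warning("no primary mapped records in '", path, "'")
    return(empty_reads())
  }
  f <- f[keep]; flag <- flag[keep]
  chrom <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cig <- cigar_ref_stats(vapply(f, `[[`, "", 6L))
  strand <- ifelse(bitwAnd(flag, 0x10) > 0, "-", "+")
  n_blocks <- as.integer(cig["n_gaps", ]) + 1L
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pos, width = as.integer(cig["width", ])),
    strand = strand, is_split = n_blocks > 1L, n_blocks = n_blocks)
}

read_alignments_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", fill = TRUE)
  if (ncol(tab) < 6) stop("BED alignment input needs >= 6 columns")
  strand <- tab[[6]]
  if (any(!strand %in% c("+", "-")))
    stop("missing or undefined strand in BED line ",
         which(!strand %in% c("+", "-"))[1])
  start0 <- as.integer(tab[[2]]); end0 <- as.integer(tab[[3]])
  if (any(end0 <= start0))
    stop("zero-length interval in BED line ", which(end0 <= start0)[1])
  n_blocks <- if (ncol(tab) >= 7) {
    nb <- suppressWarnings(as.integer(tab[[7]]))
    ifelse(is.na(nb), 1L, nb)
  } else rep(1L, nrow(tab))
  GenomicRanges::GRanges(
    tab[[1]], IRanges::IRanges(start0 + 1L, end0), strand = strand,
    is_split = n_blocks > 1L, n_blocks = n_blocks)
}

empty_reads <- function() {
  GenomicRanges::GRanges(is_split = logical(), n_blocks = integer())
}

#' Read / write interval sets as BED
#'
#' BED3/BED6 input and output; the chrom/start/end/strand round-trip is
#' lossless. BED coordinates are 0-based half-open on disk and 1-based
#' closed in memory.
#'
#' @param path File path.
#' @return `read_bed`: a `GRanges`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  w <- GenomicRanges::width(gr)
  if (any(w < 1))
    stop("zero-length BED interval at entry ", which(w < 1)[1])
  S4Vectors::mcols(gr) <- NULL
  names(gr) <- NULL
  gr
}

#' @rdname read_bed
#' @param gr `GRanges` to write.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(GenomicRanges::granges(gr), path, format = "bed")
  invisible(path)
}
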