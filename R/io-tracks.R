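#' Read ChIP-seq peaks from a BED file
#'
#' BED is 0-based half-open; coordinates are converted once, here, to the
#' 1-based closed convention of GRanges.  Containment of a 1-based SNP
#' position p in a BED interval \[start, end) is then exactly an overlap
#' with the imported range.
#'
#' @param path BED3+ file.
#' @param mark histone mark label attached to every peak; must be one of
#'   the five supported marks.
#' @return GRanges with a `mark` metadata column.
#' @export
readBedPeaks <- function(path, mark) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  mark <- match.arg(mark, ALL_MARKS)
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    gr <- GRanges()
    mcols(gr)$mark <- character()
    return(gr)
  }
  bad <- which(raw[[3]] <= raw[[2]])
  if (length(bad))
    stop("BED interval with end <= start at line ", bad[1], " of ", path)
  gr <- rtracklayer::import(path, format = "BED")
  mcols(gr)$mark <- mark
  gr
}

#' Write peaks as BED3
#'
#' @param peaks GRanges (1-based closed, as returned by [readBedPeaks()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedPeaks <- function(peaks, path) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromatin interactions from a BEDPE file
#'
#' Columns 1-6 are chrom1/start1/end1/chrom2/start2/end2 (0-based
#' half-open).  Interchromosomal lines are dropped with a `message()`
#' reporting the count; only intrachromosomal interactions are returned.
#'
#' @param path BEDPE file.
#' @param source dataset label attached to every interaction.
#' @return a [ChromatinInteractions-class]
#' @export
readBedpeInteractions <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("BEDPE file not found: ", path)
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L)
    return(ChromatinInteractions(GRanges(), GRanges(), character()))
  if (ncol(raw) < 6L) stop("malformed BEDPE (fewer than 6 columns): ", path)
  if (!is.numeric(raw[[2]]) || !is.numeric(raw[[3]]) ||
      !is.numeric(raw[[5]]) || !is.numeric(raw[[6]]))
    stop("malformed BEDPE (non-numeric coordinates): ", path)
  intra <- raw[[1]] == raw[[4]]
  if (any(!intra))
    message(sum(!intra), " interchromosomal interaction(s) dropped")
  raw <- raw[intra, , drop = FALSE]
  ChromatinInteractions(
    GRanges(raw[[1]], IRanges(raw[[2]] + 1L, raw[[3]])),
    GRanges(raw[[4]], IRanges(raw[[5]] + 1L, raw[[6]])),
    rep_len(source, nrow(raw)))
}

#' Write interactions as BEDPE
#'
#' @param x a [ChromatinInteractions-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedpe <- function(x, path) {
  a1 <- anchorOne(x); a2 <- anchorTwo(x)
  df <- data.frame(as.character(seqnames(a1)), start(a1) - 1L, end(a1),
                   as.character(seqnames(a2)), start(a2) - 1L, end(a2),
                   interactionSource(x))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-sample allelic depths
#'
#' Tab-separated table with header
#' `chrom, pos, ref, alt, sample, assay, study_id, ref_depth, alt_depth`;
#' `pos` is 1-based (VCF convention).  One row is one observation of one
#' SNP in one sample under one assay in one study.
#'
#' @param path TSV file.
#' @return data.frame of typed records.
#' @export
readAllelicCounts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "sample", "assay", "study_id",
            "ref_depth", "alt_depth")
  if (!all(need %in% names(df)))
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  bad_assay <- setdiff(unique(df$assay), ALL_ASSAYS)
  if (length(bad_assay))
    stop("unknown assay label(s): ", paste(bad_assay, collapse = ", "),
         "; allowed: ", paste(ALL_ASSAYS, collapse = ", "))
  if (any(df$ref_depth < 0 | df$alt_depth < 0))
    stop("negative allelic depths are not allowed")
  df$pos <- as.integer(df$pos)
  df$ref_depth <- as.integer(df$ref_depth)
  df$alt_depth <- as.integer(df$alt_depth)
  df
}

#' Write per-sample allelic depths
#'
#' @param counts data.frame as returned by [readAllelicCounts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAllelicCounts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Tab-separated table with header
#' `gene_id, chrom, start, end, tss, strand`; all coordinates 1-based,
#' start/end inclusive, `tss` inside (or at a boundary of) the gene body.
#'
#' @param path TSV file.
#' @return GRanges with metadata columns `gene_id` and `tss` and gene
#'   strand set.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be + or -")
  if (any(df$tss < df$start | df$tss > df$end))
    stop("tss must lie within the gene body")
  GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
          gene_id = df$gene_id, tss = as.integer(df$tss))
}

#' Write gene models
#'
#' @param genes GRanges as returned by [readGeneModels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  df <- data.frame(gene_id = mcols(genes)$gene_id,
                   chrom = as.character(seqnames(genes)),
                   start = start(genes), end = end(genes),
                   tss = mcols(genes)$tss,
                   strand = as.character(strand(genes)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read precomputed LD block definitions
#'
#' One row per block member: `population, chrom, block_id, snp_id`.  This
#' is the exchange format for externally constructed blocks (for example
#' Gabriel-confidence-interval blocks) and for the blocks produced by
#' [fourGameteBlocks()].
#'
#' @param path TSV file.
#' @return data.frame with the four columns above.
#' @export
readLdBlocks <- function(path) {
  if (!file.exists(path)) stop("block file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("population", "chrom", "block_id", "snp_id")
  if (!all(need %in% names(df)))
    stop("block table must have columns: ", paste(need, collapse = ", "))
  df[, need]
}

#' Write LD block definitions
#' @param blocks data.frame as returned by [readLdBlocks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLdBlocks <- function(blocks, path) {
  write.table(blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach panel SNP ids to a counts table
#'
#' Matches count rows to panel SNPs by chromosome and 1-based position and
#' adds a `snp_id` column; rows at positions absent from the panel get NA
#' (and are excluded from downstream testing, mirroring the exclusion of
#' SNPs without reference-panel genotypes).
#'
#' @param counts data.frame from [readAllelicCounts()].
#' @param panel a [HaplotypePanel-class].
#' @return `counts` with an added `snp_id` column.
#' @export
attachSnpIds <- function(counts, panel) {
  key <- paste(counts$chrom, counts$pos)
  pkey <- paste(as.character(seqnames(snpRanges(panel))),
                start(snpRanges(panel)))
  counts$snp_id <- snpIds(panel)[match(key, pkey)]
  counts
}
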