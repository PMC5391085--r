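#' Promoter window of a gene
#'
#' 1.5 kb upstream to 0.5 kb downstream of the TSS, reflected by gene
#' strand, 2000 bp in total before clamping at the chromosome start.
#'
#' @param genes gene GRanges with `tss` metadata and strand.
#' @return GRanges of promoter windows (same order as `genes`).
#' @export
promoterWindow <- function(genes) {
  tss <- mcols(genes)$tss
  minus <- as.character(strand(genes)) == "-"
  # 0-based half-open [tss-1500, tss+500) on +, [tss-500, tss+1500) on -;
  # converted to 1-based closed coordinates and clamped at 1
  s <- ifelse(minus, tss - 499L, tss - 1499L)
  e <- ifelse(minus, tss + 1500L, tss + 500L)
  s <- pmax(s, 1L)
  GRanges(seqnames(genes), IRanges(s, e), strand = strand(genes),
          gene_id = mcols(genes)$gene_id)
}

#' Distal peak overlap bit
#'
#' 1 iff any peak of the track covers the variant position.
#'
#' @param variant single-position GRanges (1-based), or a
#'   [HaplotypePanel-class] SNP via [snpRanges()].
#' @param track peak GRanges.
#' @return integer 0/1 (vectorised over `variant`).
#' @export
distalPeakBit <- function(variant, track) {
  as.integer(IRanges::overlapsAny(variant, track))
}

#' Promoter coverage bit
#'
#' 1 iff the union of the track's peaks covers at least half of the
#' gene's promoter window.
#'
#' @param gene single gene GRanges row.
#' @param track peak GRanges.
#' @return integer 0/1.
#' @export
promoterPeakBit <- function(gene, track) {
  prom <- promoterWindow(gene)
  if (length(track) == 0L) return(0L)
  cov <- GenomicRanges::intersect(reduce(track, ignore.strand = TRUE),
                                  prom, ignore.strand = TRUE)
  as.integer(sum(width(cov)) >= width(prom) / 2)
}

#' GO term membership bit
#'
#' @param gene_id gene identifier.
#' @param members character vector of member gene ids for the term.
#' @return integer 0/1.
#' @export
goBit <- function(gene_id, members) {
  as.integer(gene_id %in% members)
}

#' Unsigned TSS distance
#'
#' Absolute base-pair distance between a variant and the target gene's
#' TSS; errors when the two lie on different chromosomes (pairs are
#' intrachromosomal by construction).
#'
#' @param variant single-position GRanges.
#' @param gene single gene GRanges row with `tss`.
#' @return non-negative integer distance.
#' @export
tssDistance <- function(variant, gene) {
  if (as.character(seqnames(variant)) != as.character(seqnames(gene)))
    stop("variant and gene are on different chromosomes")
  abs(start(variant) - mcols(gene)$tss)
}

#' Build the per-pair feature matrix
#'
#' Assembles one row per pair from a feature specification.  Supported
#' kinds: `distal_peak` (track bit at the regulatory variant),
#' `promoter_peak` (half-coverage bit at the target gene promoter),
#' `go_term` (gene membership bit), `tss_distance` (unsigned bp), and
#' `tf_affinity` (looked up from a precomputed table; absent evidence is
#' 0).  Binary and continuous columns mix freely; there are no missing
#' values in the result.
#'
#' @param pairs pair data.frame with `pair_id, reg_snp, gene_id`.
#' @param specs data.frame `name, kind, source` (names unique; column
#'   order of the result follows `specs`).
#' @param panel a [HaplotypePanel-class] (for variant positions).
#' @param genes gene GRanges.
#' @param tracks named list of peak GRanges, keyed by `source`.
#' @param go_sets named list of gene-id vectors, keyed by `source`.
#' @param affinity optional data.frame `snp_id, score` (a stand-in for
#'   motif-scanner output); missing variants score 0.
#' @return numeric matrix, rownames = pair ids, colnames = spec names.
#' @export
buildFeatureMatrix <- function(pairs, specs, panel, genes, tracks = list(),
                               go_sets = list(), affinity = NULL) {
  if (anyDuplicated(pairs$pair_id))
    stop("duplicate pair ids in feature construction")
  if (anyDuplicated(specs$name)) stop("feature names must be unique")
  snp_gr <- snpRanges(panel)
  reg_idx <- match(pairs$reg_snp, snpIds(panel))
  gene_idx <- match(pairs$gene_id, mcols(genes)$gene_id)
  if (anyNA(reg_idx)) stop("regulatory SNP absent from panel")
  if (anyNA(gene_idx)) stop("gene absent from gene models")

  col <- function(spec) {
    kind <- spec$kind
    src <- spec$source
    switch(kind,
      distal_peak = {
        tr <- tracks[[src]]
        if (is.null(tr)) stop("unknown track: ", src)
        distalPeakBit(snp_gr[reg_idx], tr)
      },
      promoter_peak = {
        tr <- tracks[[src]]
        if (is.null(tr)) stop("unknown track: ", src)
        vapply(gene_idx, function(gi) promoterPeakBit(genes[gi], tr),
               integer(1))
      },
      go_term = {
        members <- go_sets[[src]]
        if (is.null(members)) stop("unknown GO set: ", src)
        vapply(pairs$gene_id, goBit, integer(1), members = members)
      },
      tss_distance =
        vapply(seq_len(nrow(pairs)), function(i)
          tssDistance(snp_gr[reg_idx[i]], genes[gene_idx[i]]), numeric(1)),
      tf_affinity = {
        if (is.null(affinity)) rep(0, nrow(pairs))
        else {
          sc <- affinity$score[match(pairs$reg_snp, affinity$snp_id)]
          ifelse(is.na(sc), 0, sc)
        }
      },
      stop("unknown feature kind: ", kind))
  }
  X <- vapply(seq_len(nrow(specs)),
              function(j) as.numeric(col(specs[j, ])),
              numeric(nrow(pairs)))
  X <- matrix(X, nrow = nrow(pairs),
              dimnames = list(pairs$pair_id, specs$name))
  X
}
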