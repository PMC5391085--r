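#' Regulatory polarity of a histone mark
#'
#' H3K27ac, H3K36me3, H3K4me1 and H3K4me3 are activating marks; H3K27me3
#' is repressive.  Polarity decides whether regulatory and transcript
#' imbalance must agree (activating) or oppose (repressive) to form an
#' allele-specific pair.
#'
#' @param mark histone mark name.
#' @return "activating" or "repressive".
#' @export
markPolarity <- function(mark) {
  mark <- match.arg(mark, ALL_MARKS)
  if (mark %in% REPRESSIVE_MARKS) "repressive" else "activating"
}

#' Map a peak to its interaction-linked target genes
#'
#' A gene is a target of the peak iff some intrachromosomal interaction
#' has one anchor overlapping the peak and the other anchor overlapping
#' the gene body or its promoter window; both anchor orders are
#' considered.  The contributing dataset labels are returned so
#' multi-source support can be reported.
#'
#' @param peak single-range GRanges.
#' @param interactions a [ChromatinInteractions-class].
#' @param genes gene GRanges from [readGeneModels()].
#' @param gene_side "body_or_promoter" (default) or "promoter_only".
#' @return data.frame `gene_id, source` (one row per supporting link).
#' @export
mapPeakToGenes <- function(peak, interactions, genes,
                           gene_side = c("body_or_promoter",
                                         "promoter_only")) {
  gene_side <- match.arg(gene_side)
  if (length(interactions) == 0L || length(genes) == 0L)
    return(data.frame(gene_id = character(), source = character()))
  prom <- promoterWindow(genes)
  gene_target <- if (gene_side == "promoter_only") prom else
    c(GRanges(seqnames(genes), IRanges(start(genes), end(genes))),
      GRanges(seqnames(prom), IRanges(start(prom), end(prom))))
  gene_ids <- rep(mcols(genes)$gene_id,
                  if (gene_side == "promoter_only") 1L else 2L)

  hitsFor <- function(peak_anchor, gene_anchor) {
    # seqlevel mismatches between anchors and peaks mean "no overlap"
    pk <- which(suppressWarnings(IRanges::overlapsAny(peak_anchor, peak)))
    if (!length(pk)) return(NULL)
    h <- suppressWarnings(findOverlaps(gene_anchor[pk], gene_target))
    if (!length(h)) return(NULL)
    data.frame(gene_id = gene_ids[S4Vectors::subjectHits(h)],
               source = interactionSource(interactions)[pk[S4Vectors::queryHits(h)]])
  }
  out <- rbind(hitsFor(anchorOne(interactions), anchorTwo(interactions)),
               hitsFor(anchorTwo(interactions), anchorOne(interactions)))
  if (is.null(out))
    return(data.frame(gene_id = character(), source = character()))
  unique(out)
}

#' Phase flip indicator for a SNP pair in one sample
#'
#' TRUE iff the alternative alleles of the two heterozygous SNPs reside on
#' different haplotypes of the sample, in which case the transcript allele
#' ratio must be flipped before comparing regulatory directions.
#'
#' @param panel a [HaplotypePanel-class].
#' @param reg_snp,tx_snp SNP identifiers.
#' @param sample sample identifier.
#' @return logical scalar; error when either genotype is homozygous (the
#'   pair is not testable in this sample).
#' @export
isFlipped <- function(panel, reg_snp, tx_snp, sample) {
  si <- match(sample, sampleIds(panel))
  if (is.na(si)) stop("unknown sample: ", sample)
  ri <- match(reg_snp, snpIds(panel))
  ti <- match(tx_snp, snpIds(panel))
  if (is.na(ri) || is.na(ti)) stop("SNP not in panel")
  r1 <- hapMatrix(panel, 1)[ri, si]; r2 <- hapMatrix(panel, 2)[ri, si]
  t1 <- hapMatrix(panel, 1)[ti, si]; t2 <- hapMatrix(panel, 2)[ti, si]
  if (r1 == r2 || t1 == t2)
    stop("phase flip undefined for a homozygous genotype")
  r1 != t1
}

#' Orient an allele ratio by a flip flag
#'
#' Flipped ratios are complemented (`1 - ratio`); applying the same flag
#' twice restores the input.  After flipping the transcript ratio of a
#' pair, both members measure the read fraction of the same physical
#' haplotype (the one carrying the regulatory reference allele), a frame
#' that is stable across samples.
#'
#' @param ratio allele ratio(s) in \[0, 1\].
#' @param flipped logical flag(s).
#' @return oriented ratio(s).
#' @export
orientRatio <- function(ratio, flipped) {
  ifelse(flipped, 1 - ratio, ratio)
}

#' Regulatory direction match
#'
#' For activating marks the major regulatory allele and major transcript
#' allele must lie on the same haplotype (both oriented ratios on the same
#' side of 0.5); for the repressive mark they must oppose.  A ratio of
#' exactly 0.5 has no major allele: the result is NA and the pair is
#' excluded from pairing.
#'
#' @param reg_ratio,tx_ratio oriented ratios (same haplotype frame).
#' @param polarity "activating" or "repressive".
#' @return logical (NA when either ratio is exactly 0.5).
#' @export
directionMatch <- function(reg_ratio, tx_ratio,
                           polarity = c("activating", "repressive")) {
  polarity <- match.arg(polarity)
  out <- ifelse(reg_ratio == 0.5 | tx_ratio == 0.5, NA,
                (reg_ratio > 0.5) == (tx_ratio > 0.5))
  if (polarity == "repressive") out <- !out
  out
}

#' Enumerate candidate regulatory-transcript pairs
#'
#' For each tag SNP: its LD set is intersected with the panel and with the
#' ChIP-seq peaks of each mark; every peak hosting a candidate regulatory
#' SNP is mapped to genes through the interaction (or eQTL) links; every
#' panel SNP inside a mapped gene body becomes a candidate transcript SNP.
#' Labels and testability are decided later by [labelPairs()].
#'
#' @param tags character vector of tag SNP ids (must be panel members for
#'   self-expansion; tags absent from all LD sets yield no pairs).
#' @param ld_sets named list (by tag) of LD-expanded SNP id vectors, e.g.
#'   from [ldExpand()].
#' @param peaks GRanges of peaks with a `mark` column ([readBedPeaks()]).
#' @param links a [ChromatinInteractions-class], or a data.frame
#'   `snp_id, gene_id` of eQTL edges replacing the interactions.
#' @param genes gene GRanges.
#' @param panel a [HaplotypePanel-class].
#' @param gene_side passed to [mapPeakToGenes()].
#' @return data.frame `pair_id, tag_snp, reg_snp, mark, gene_id, tx_snp,
#'   n_sources, sources`.
#' @export
enumerateCandidatePairs <- function(tags, ld_sets, peaks, links, genes,
                                    panel,
                                    gene_side = "body_or_promoter") {
  snp_gr <- snpRanges(panel)
  empty <- data.frame(pair_id = character(), tag_snp = character(),
                      reg_snp = character(), mark = character(),
                      gene_id = character(), tx_snp = character(),
                      n_sources = integer(), sources = character())
  rows <- list()
  use_eqtl <- is.data.frame(links)
  for (tag in tags) {
    ld <- intersect(ld_sets[[tag]], snpIds(panel))
    if (!length(ld)) next
    idx <- match(ld, snpIds(panel))
    in_peak <- findOverlaps(snp_gr[idx], peaks)
    if (!length(in_peak)) next
    for (h in seq_along(in_peak)) {
      reg <- ld[S4Vectors::queryHits(in_peak)[h]]
      pk <- S4Vectors::subjectHits(in_peak)[h]
      mk <- mcols(peaks)$mark[pk]
      gmap <- if (use_eqtl) {
        gl <- links[links$snp_id == reg, , drop = FALSE]
        data.frame(gene_id = gl$gene_id,
                   source = rep("eQTL", nrow(gl)))
      } else {
        mapPeakToGenes(peaks[pk], links, genes, gene_side)
      }
      if (!nrow(gmap)) next
      for (g in unique(gmap$gene_id)) {
        src <- sort(unique(gmap$source[gmap$gene_id == g]))
        gi <- genes[mcols(genes)$gene_id == g]
        tx_hit <- IRanges::overlapsAny(snp_gr, gi)
        tx_snps <- setdiff(snpIds(panel)[tx_hit], reg)
        for (tx in tx_snps) {
          rows[[length(rows) + 1L]] <- data.frame(
            pair_id = paste(reg, mk, g, tx, sep = "|"),
            tag_snp = tag, reg_snp = reg, mark = mk, gene_id = g,
            tx_snp = tx, n_sources = length(src),
            sources = paste(src, collapse = ","))
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- unique(do.call(rbind, rows))
  # the same physical pair can be reached from several tags; keep one row
  # per (tag, pair) but collapse duplicates within a tag
  out <- out[!duplicated(out[, c("pair_id", "tag_snp")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Cache of per-sample test tables keyed by snp/assay.
perSampleCache <- function(panel, counts, cfg) {
  env <- new.env(parent = emptyenv())
  function(snp_id, assay) {
    key <- paste(snp_id, assay)
    if (!is.null(env[[key]])) return(env[[key]]$value)
    val <- perSampleTests(snp_id, assay, panel, counts, cfg)
    env[[key]] <- list(value = val)
    val
  }
}

#' Label candidate pairs as true, control or untestable
#'
#' Runs the locus-level meta-analysed imbalance tests for the regulatory
#' SNP (its mark's ChIP assay) and the transcript SNP (RNA), determines
#' the jointly heterozygous filter-passing samples, orients the
#' transcript ratios into the regulatory SNP's haplotype frame by phase
#' flipping, and applies the polarity direction match.
#'
#' Labels: `true_pair` when both loci are imbalanced (Fisher combined
#' P < meta_alpha) and the direction matches; `untestable` when either
#' locus has no surviving heterozygous sample or no sample is
#' heterozygous-and-filtered at both loci (no orientation possible);
#' `control_pair` otherwise.
#'
#' @param candidates data.frame from [enumerateCandidatePairs()].
#' @param panel a [HaplotypePanel-class].
#' @param counts counts data.frame with `snp_id` attached.
#' @param cfg an [imbalanceConfig()].
#' @return `candidates` with added columns `flipped, n_joint, reg_p,
#'   reg_imbalanced, reg_ratio, tx_p, tx_imbalanced, tx_ratio_oriented,
#'   direction_ok, label`.
#' @export
labelPairs <- function(candidates, panel, counts, cfg = imbalanceConfig()) {
  get_tab <- perSampleCache(panel, counts, cfg)
  n <- nrow(candidates)
  out <- candidates
  out$flipped <- rep(NA, n)
  out$n_joint <- rep(0L, n)
  out$reg_p <- out$reg_ratio <- out$tx_p <- out$tx_ratio_oriented <-
    rep(NA_real_, n)
  out$reg_imbalanced <- out$tx_imbalanced <- rep(NA, n)
  out$direction_ok <- rep(NA, n)
  out$label <- rep("untestable", n)
  if (!n) return(out)
  for (i in seq_len(n)) {
    reg <- candidates$reg_snp[i]; tx <- candidates$tx_snp[i]
    mk <- candidates$mark[i]
    reg_tab <- get_tab(reg, mk)
    tx_tab <- get_tab(tx, "RNA")
    if (is.null(reg_tab) || is.null(tx_tab)) next
    joint <- intersect(reg_tab$sample, tx_tab$sample)
    if (!length(joint)) next
    flips <- vapply(joint, function(s) isFlipped(panel, reg, tx, s),
                    logical(1))
    reg_meta <- fisherCombine(reg_tab$p_value)
    tx_meta <- fisherCombine(tx_tab$p_value)
    reg_joint <- mean(reg_tab$ratio[match(joint, reg_tab$sample)])
    tx_joint <- mean(orientRatio(tx_tab$ratio[match(joint, tx_tab$sample)],
                                 flips))
    dir_ok <- directionMatch(reg_joint, tx_joint, markPolarity(mk))
    out$flipped[i] <- flips[1L]
    out$n_joint[i] <- length(joint)
    out$reg_p[i] <- reg_meta$combined_p
    out$tx_p[i] <- tx_meta$combined_p
    out$reg_imbalanced[i] <- reg_meta$combined_p < cfg$meta_alpha
    out$tx_imbalanced[i] <- tx_meta$combined_p < cfg$meta_alpha
    out$reg_ratio[i] <- reg_joint
    out$tx_ratio_oriented[i] <- tx_joint
    out$direction_ok[i] <- dir_ok
    out$label[i] <- if (isTRUE(out$reg_imbalanced[i]) &&
                        isTRUE(out$tx_imbalanced[i]) &&
                        isTRUE(dir_ok)) "true_pair" else "control_pair"
  }
  out
}

#' Build allele-specific pairs from tags to transcripts
#'
#' End-to-end pairing: LD candidates in peaks, interaction-mapped target
#' genes, transcript SNPs, phase-oriented direction matching and labels.
#' Emits a funnel summary (tags in, tags paired, genes paired) via
#' `message()`.
#'
#' @inheritParams enumerateCandidatePairs
#' @inheritParams labelPairs
#' @return labeled pair data.frame (see [labelPairs()]).
#' @export
buildPairs <- function(tags, ld_sets, peaks, links, genes, panel, counts,
                       cfg = imbalanceConfig(),
                       gene_side = "body_or_promoter") {
  cand <- enumerateCandidatePairs(tags, ld_sets, peaks, links, genes,
                                  panel, gene_side)
  pairs <- labelPairs(cand, panel, counts, cfg)
  paired <- pairs[pairs$label == "true_pair", , drop = FALSE]
  message(length(tags), " tag(s) in; ",
          length(unique(paired$tag_snp)), " tag(s) paired; ",
          length(unique(paired$gene_id)), " gene(s) paired")
  pairs
}

#' Per-sample oriented ratio observations for pairs
#'
#' One row per (pair, jointly testable sample) with the regulatory
#' reference-allele ratio and the transcript ratio, both in the regulatory
#' haplotype frame when `phased = TRUE`; with `phased = FALSE` the
#' transcript ratio stays on the reference-genome orientation (no flip),
#' which is the contrast used to show that phasing is what sustains
#' long-range concordance.
#'
#' @param pairs labeled pair data.frame from [labelPairs()].
#' @param panel a [HaplotypePanel-class].
#' @param counts counts data.frame with `snp_id`.
#' @param cfg an [imbalanceConfig()].
#' @param phased apply per-sample phase flips (default TRUE).
#' @return data.frame `pair_id, reg_snp, tx_snp, mark, sample, reg_ratio,
#'   tx_ratio`.
#' @export
pairRatioObservations <- function(pairs, panel, counts,
                                  cfg = imbalanceConfig(), phased = TRUE) {
  get_tab <- perSampleCache(panel, counts, cfg)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    reg <- pairs$reg_snp[i]; tx <- pairs$tx_snp[i]; mk <- pairs$mark[i]
    reg_tab <- get_tab(reg, mk)
    tx_tab <- get_tab(tx, "RNA")
    if (is.null(reg_tab) || is.null(tx_tab)) return(NULL)
    joint <- intersect(reg_tab$sample, tx_tab$sample)
    if (!length(joint)) return(NULL)
    txr <- tx_tab$ratio[match(joint, tx_tab$sample)]
    if (phased) {
      flips <- vapply(joint, function(s) isFlipped(panel, reg, tx, s),
                      logical(1))
      txr <- orientRatio(txr, flips)
    }
    data.frame(pair_id = pairs$pair_id[i], reg_snp = reg, tx_snp = tx,
               mark = mk, sample = joint,
               reg_ratio = reg_tab$ratio[match(joint, reg_tab$sample)],
               tx_ratio = txr)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pair_id = character(), reg_snp = character(),
                      tx_snp = character(), mark = character(),
                      sample = character(), reg_ratio = numeric(),
                      tx_ratio = numeric())
  rownames(out) <- NULL
  out
}
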