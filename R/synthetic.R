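#' Synthetic panel configuration
#'
#' Defines the study conditions the generator emulates: a reference panel
#' of lymphoblastoid-like samples (default 100, matching the scale of the
#' real panel) with phased genotypes, per-tag LD blocks of candidate
#' regulatory SNPs inside ChIP-seq peaks, interaction-linked target genes
#' with transcript SNPs, planted cis-regulatory effects of configurable
#' strength, allelic read counts, QTL trait matrices and per-pair feature
#' tables with planted class signal.
#'
#' Haplotypes follow a two-founder copy model: each chromosome copies a
#' founder indicator along the tag segment, redrawing the founder with
#' probability `ld_decay` at each SNP, so |r| between SNPs decays with
#' their separation and `ld_decay = 0` gives a perfectly correlated
#' block.  The alt-allele frequency equals `maf`.  A planted effect makes
#' the haplotype carrying the regulatory SNP's alt allele produce a
#' fraction `effect_fraction` of the ChIP reads (and of the RNA reads for
#' activating marks; the complement for the repressive mark), so read
#' counts are binomial around that fraction — the same binomial model the
#' imbalance test assumes under its null at 0.5.
#'
#' @param n_samples samples in the panel.
#' @param n_tags number of GWAS tag SNPs (one LD block and one target
#'   gene each).
#' @param prop_effect fraction of tags with a planted cis effect.
#' @param snps_per_block candidate regulatory SNPs per tag block.
#' @param n_tx_snps transcript SNPs per target gene.
#' @param ld_decay per-SNP founder redraw probability.
#' @param maf alt-allele (founder B) frequency.
#' @param effect_fraction planted read fraction of the effect haplotype.
#' @param depth sequencing depth per observation (0 emits nothing).
#' @param n_studies studies per sample/assay (for study averaging).
#' @param marks histone marks cycled over tags.
#' @param n_features binary features per pair.
#' @param feature_rate_true,feature_rate_false per-class bit rates of the
#'   planted feature signal.
#' @param qtl_beta planted per-dosage trait effect for effect tags.
#' @param trait_noise_sd Gaussian noise of the trait matrices.
#' @param n_decoys decoy interactions connecting random peak-gene pairs
#'   across tags.
#' @param seed mandatory integer seed.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(n_samples = 100L, n_tags = 10L, prop_effect = 0.5,
                      snps_per_block = 5L, n_tx_snps = 2L,
                      ld_decay = 0.05, maf = 0.15, effect_fraction = 0.8,
                      depth = 50L, n_studies = 1L,
                      marks = c("H3K27ac", "H3K4me1"),
                      n_features = 20L, feature_rate_true = 0.9,
                      feature_rate_false = 0.1, qtl_beta = 0.5,
                      trait_noise_sd = 1, n_decoys = 0L, seed) {
  if (missing(seed)) stop("a seed is mandatory for the generator")
  stopifnot(effect_fraction > 0, effect_fraction < 1, maf > 0, maf < 1,
            depth >= 0, all(marks %in% ALL_MARKS))
  structure(as.list(environment()), class = "SimConfig")
}

# Founder-copy haplotypes: n_snps x n_chrom matrix of 0/1 alleles.  Each
# chromosome draws founder B (allele 1) with probability maf at the first
# SNP and redraws with probability ld_decay at each subsequent SNP.
founderChain <- function(n_chrom, n_snps, ld_decay, maf) {
  H <- matrix(0L, n_snps, n_chrom)
  cur <- rbinom(n_chrom, 1L, maf)
  H[1L, ] <- cur
  if (n_snps > 1L) for (i in 2:n_snps) {
    redraw <- runif(n_chrom) < ld_decay
    cur[redraw] <- rbinom(sum(redraw), 1L, maf)
    H[i, ] <- cur
  }
  H
}

# Genomic layout of one tag region; positions are 1-based.
tagLayout <- function(t, cfg) {
  base <- t * 1e6
  block_pos <- base + 1000 + (seq_len(cfg$snps_per_block) - 1L) * 150
  tx_pos <- base + 6000 + (seq_len(cfg$n_tx_snps) - 1L) * 200
  list(tag_index = t,
       chrom = "chr1",
       block_pos = block_pos,
       tx_pos = tx_pos,
       peak = c(base + 900, base + 2000),
       gene = c(base + 5000, base + 9000),
       tss = base + 5000,
       anchor1 = c(base + 800, base + 2100),
       anchor2 = c(base + 4800, base + 9100),
       block_ids = paste0("t", t, "_b", seq_len(cfg$snps_per_block)),
       tx_ids = paste0("t", t, "_tx", seq_len(cfg$n_tx_snps)),
       gene_id = paste0("gene", t),
       peak_trait = paste0("peak", t),
       mark = cfg$marks[(t - 1L) %% length(cfg$marks) + 1L])
}

#' Simulate the phased haplotype panel
#'
#' @param cfg a [simConfig()].
#' @return a [HaplotypePanel-class] covering all tag regions.
#' @export
simulateHaplotypes <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_samples
  snps <- list(); h1 <- list(); h2 <- list()
  for (t in seq_len(cfg$n_tags)) {
    lay <- tagLayout(t, cfg)
    pos <- c(lay$block_pos, lay$tx_pos)
    ids <- c(lay$block_ids, lay$tx_ids)
    H <- founderChain(2L * n, length(pos), cfg$ld_decay, cfg$maf)
    snps[[t]] <- GRanges(lay$chrom, IRanges(pos, width = 1L),
                         snp_id = ids, ref = "A", alt = "G")
    h1[[t]] <- H[, seq_len(n) * 2L - 1L, drop = FALSE]
    h2[[t]] <- H[, seq_len(n) * 2L, drop = FALSE]
  }
  HaplotypePanel(do.call(c, snps), paste0("S", seq_len(n)),
                 do.call(rbind, h1), do.call(rbind, h2))
}

#' Ground-truth layout of the synthetic panel
#'
#' @param cfg a [simConfig()].
#' @return data.frame, one row per tag: ids, coordinates, mark, planted
#'   effect flag, causal regulatory SNP and QTL beta.
#' @export
simTruth <- function(cfg) {
  n_eff <- round(cfg$prop_effect * cfg$n_tags)
  do.call(rbind, lapply(seq_len(cfg$n_tags), function(t) {
    lay <- tagLayout(t, cfg)
    data.frame(tag_index = t,
               tag_snp = lay$block_ids[1L],
               causal_snp = lay$block_ids[ceiling(cfg$snps_per_block / 2)],
               gene_id = lay$gene_id,
               peak_trait = lay$peak_trait,
               mark = lay$mark,
               effect = t <= n_eff,
               effect_fraction = cfg$effect_fraction,
               qtl_beta = ifelse(t <= n_eff, cfg$qtl_beta, 0))
  }))
}

# Reference-allele read probability at `snp` for a het sample, given the
# causal regulatory SNP genotype and the planted fraction of reads coming
# from the haplotype that carries the causal alt allele.
refReadProb <- function(h1_snp, h2_snp, h1_causal, h2_causal, frac) {
  if (h1_causal == h2_causal) return(0.5)       # no causal het, no effect
  eff_is_h1 <- h1_causal == 1L
  eff_allele <- if (eff_is_h1) h1_snp else h2_snp
  if (eff_allele == 0L) frac else 1 - frac
}

#' Simulate allelic read counts
#'
#' For every heterozygous (sample, SNP): block SNPs yield ChIP counts
#' under the tag's mark, transcript SNPs yield RNA counts.  Reads are
#' binomial at the planted haplotype fraction for effect tags (when the
#' sample is also heterozygous at the causal SNP) and at 0.5 otherwise.
#'
#' @param cfg a [simConfig()].
#' @param panel panel from [simulateHaplotypes()].
#' @param truth data.frame from [simTruth()].
#' @return counts data.frame in the [readAllelicCounts()] schema.
#' @export
simulateAllelicCounts <- function(cfg, panel, truth) {
  if (cfg$depth == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample = character(), assay = character(),
                      study_id = character(), ref_depth = integer(),
                      alt_depth = integer()))
  H1 <- hapMatrix(panel, 1); H2 <- hapMatrix(panel, 2)
  rownames(H1) <- rownames(H2) <- snpIds(panel)
  pos_of <- setNames(start(snpRanges(panel)), snpIds(panel))
  samples <- sampleIds(panel)
  rows <- list()
  for (t in seq_len(cfg$n_tags)) {
    lay <- tagLayout(t, cfg)
    tr <- truth[truth$tag_index == t, ]
    causal <- tr$causal_snp
    polarity <- markPolarity(lay$mark)
    emit <- function(snp, assay, frac_chip) {
      het <- H1[snp, ] != H2[snp, ]
      for (s in which(het)) {
        p_ref <- if (tr$effect)
          refReadProb(H1[snp, s], H2[snp, s], H1[causal, s], H2[causal, s],
                      frac_chip)
        else 0.5
        for (st in seq_len(cfg$n_studies)) {
          ref_d <- rbinom(1L, cfg$depth, p_ref)
          rows[[length(rows) + 1L]] <<- data.frame(
            chrom = lay$chrom, pos = unname(pos_of[snp]), ref = "A",
            alt = "G", sample = samples[s], assay = assay,
            study_id = paste0("study", st), ref_depth = ref_d,
            alt_depth = cfg$depth - ref_d)
        }
      }
    }
    for (snp in lay$block_ids) emit(snp, lay$mark, cfg$effect_fraction)
    rna_frac <- if (polarity == "activating") cfg$effect_fraction
                else 1 - cfg$effect_fraction
    for (snp in lay$tx_ids) emit(snp, "RNA", rna_frac)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate peak-intensity and expression trait matrices
#'
#' `trait = baseline + beta x dosage(causal SNP) + N(0, noise_sd)`, with
#' beta taken from the ground truth (0 for non-effect tags).
#'
#' @param cfg a [simConfig()].
#' @param panel panel from [simulateHaplotypes()].
#' @param truth data.frame from [simTruth()].
#' @return list of two matrices `peaks` and `expression` (trait x
#'   sample).
#' @export
simulateTraitMatrices <- function(cfg, panel, truth) {
  dos <- genotypeDosage(panel)
  rownames(dos) <- snpIds(panel)
  n <- nSamples(panel)
  mk <- function(ids) {
    m <- matrix(0, nrow(truth), n,
                dimnames = list(ids, sampleIds(panel)))
    for (i in seq_len(nrow(truth))) {
      d <- dos[truth$causal_snp[i], ]
      m[i, ] <- 10 + truth$qtl_beta[i] * d + rnorm(n, 0, cfg$trait_noise_sd)
    }
    m
  }
  list(peaks = mk(truth$peak_trait), expression = mk(truth$gene_id))
}

#' Simulate per-pair feature tables with planted class signal
#'
#' Candidate pairs of effect tags draw each binary feature at
#' `feature_rate_true`, others at `feature_rate_false`; one continuous
#' affinity-like column separates the classes by a unit mean shift.
#'
#' @param cfg a [simConfig()].
#' @param candidates candidate pairs from [enumerateCandidatePairs()].
#' @param truth data.frame from [simTruth()].
#' @return numeric matrix (pair x feature), rownames = pair ids.
#' @export
simulateFeatures <- function(cfg, candidates, truth) {
  latent <- truth$effect[match(candidates$gene_id, truth$gene_id)]
  rate <- ifelse(latent, cfg$feature_rate_true, cfg$feature_rate_false)
  n <- nrow(candidates)
  X <- vapply(seq_len(cfg$n_features),
              function(j) rbinom(n, 1L, rate), numeric(n))
  X <- cbind(matrix(X, nrow = n), rnorm(n, ifelse(latent, 1, 0), 1))
  dimnames(X) <- list(candidates$pair_id,
                      c(paste0("epi", seq_len(cfg$n_features)), "affinity"))
  X
}

#' Simulate a complete panel with ground truth
#'
#' Runs every generator stage under one seed and assembles the bundle all
#' pipeline stages consume: panel, counts (snp ids attached), peaks,
#' interactions, gene models, LD block definitions and expansions,
#' candidate pairs, feature matrix, trait matrices and the truth table.
#'
#' @param cfg a [simConfig()].
#' @return named list with elements `cfg, truth, panel, counts, peaks,
#'   interactions, genes, blocks, ld_sets, tags, candidates, X, traits,
#'   links`.
#' @export
simulatePanel <- function(cfg) {
  panel <- simulateHaplotypes(cfg)     # seeds the RNG stream
  truth <- simTruth(cfg)
  lays <- lapply(seq_len(cfg$n_tags), tagLayout, cfg = cfg)

  peaks <- do.call(c, lapply(lays, function(l)
    GRanges(l$chrom, IRanges(l$peak[1], l$peak[2]), mark = l$mark)))
  genes <- do.call(c, lapply(lays, function(l)
    GRanges(l$chrom, IRanges(l$gene[1], l$gene[2]), strand = "+",
            gene_id = l$gene_id, tss = as.integer(l$tss))))
  a1 <- do.call(c, lapply(lays, function(l)
    GRanges(l$chrom, IRanges(l$anchor1[1], l$anchor1[2]))))
  a2 <- do.call(c, lapply(lays, function(l)
    GRanges(l$chrom, IRanges(l$anchor2[1], l$anchor2[2]))))
  src <- rep("simChIA", length(a1))
  if (cfg$n_decoys > 0L) {
    from <- sample(seq_len(cfg$n_tags), cfg$n_decoys, replace = TRUE)
    to <- vapply(from, function(f)
      sample(setdiff(seq_len(cfg$n_tags), f), 1L), integer(1))
    a1 <- c(a1, do.call(c, lapply(lays[from], function(l)
      GRanges(l$chrom, IRanges(l$anchor1[1], l$anchor1[2])))))
    a2 <- c(a2, do.call(c, lapply(lays[to], function(l)
      GRanges(l$chrom, IRanges(l$anchor2[1], l$anchor2[2])))))
    src <- c(src, rep("simDecoy", cfg$n_decoys))
  }
  interactions <- ChromatinInteractions(a1, a2, src)

  blocks <- do.call(rbind, lapply(lays, function(l)
    data.frame(population = "SIM", chrom = l$chrom,
               block_id = l$tag_index,
               snp_id = c(l$block_ids, l$tx_ids))))
  tags <- truth$tag_snp
  ld_sets <- setNames(lapply(seq_len(cfg$n_tags), function(t)
    lays[[t]]$block_ids), tags)

  counts <- simulateAllelicCounts(cfg, panel, truth)
  counts_id <- attachSnpIds(counts, panel)
  candidates <- enumerateCandidatePairs(tags, ld_sets, peaks,
                                        interactions, genes, panel)
  X <- simulateFeatures(cfg, candidates, truth)
  traits <- simulateTraitMatrices(cfg, panel, truth)
  links <- data.frame(trait_id = truth$peak_trait, gene_id = truth$gene_id)

  list(cfg = cfg, truth = truth, panel = panel, counts = counts_id,
       peaks = peaks, interactions = interactions, genes = genes,
       blocks = blocks, ld_sets = ld_sets, tags = tags,
       candidates = candidates, X = X, traits = traits, links = links)
}

#' Write a simulated panel to disk
#'
#' Emits the plain-text files every reader of the package consumes: a
#' phased VCF, the counts TSV, one BED per mark, a BEDPE, the gene and
#' block TSVs, the feature table and the ground truth as JSON.
#'
#' @param sim bundle from [simulatePanel()].
#' @param outdir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
emitPanel <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  writePhasedVcf(sim$panel, p("panel.vcf"))
  writeAllelicCounts(sim$counts[, setdiff(names(sim$counts), "snp_id")],
                     p("counts.tsv"))
  marks <- unique(mcols(sim$peaks)$mark)
  peak_files <- character()
  for (m in marks) {
    f <- p(paste0("peaks_", m, ".bed"))
    writeBedPeaks(sim$peaks[mcols(sim$peaks)$mark == m], f)
    peak_files[m] <- f
  }
  writeBedpe(sim$interactions, p("interactions.bedpe"))
  writeGeneModels(sim$genes, p("genes.tsv"))
  writeLdBlocks(sim$blocks, p("blocks.tsv"))
  write.table(data.frame(tag_snp = sim$tags), p("tags.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  feat <- data.frame(pair_id = rownames(sim$X), sim$X,
                     check.names = FALSE)
  write.table(feat, p("features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  wtr <- function(m, f) write.table(
    data.frame(trait_id = rownames(m), m, check.names = FALSE), f,
    sep = "\t", quote = FALSE, row.names = FALSE)
  wtr(sim$traits$peaks, p("traits_peaks.tsv"))
  wtr(sim$traits$expression, p("traits_expression.tsv"))
  write.table(sim$links, p("links.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(sim$truth, p("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(vcf = p("panel.vcf"), counts = p("counts.tsv"), peak_files,
              bedpe = p("interactions.bedpe"), genes = p("genes.tsv"),
              blocks = p("blocks.tsv"), features = p("features.tsv"),
              truth = p("truth.json")))
}

#' Simulate paired ratios with a planted explanatory power
#'
#' Regulatory ratios are uniform on \[0.1, 0.9\]; transcript ratios add
#' Gaussian noise scaled so that the population R^2 of the regression
#' equals `r2`.
#'
#' @param n number of pairs.
#' @param r2 planted coefficient of determination in (0, 1].
#' @param seed integer seed.
#' @return data.frame `reg_ratio, tx_ratio`.
#' @export
simulateRatioPairs <- function(n, r2, seed) {
  stopifnot(r2 > 0, r2 <= 1)
  set.seed(seed)
  reg <- runif(n, 0.1, 0.9)
  noise_sd <- sd(reg) * sqrt((1 - r2) / r2)
  data.frame(reg_ratio = reg, tx_ratio = reg + rnorm(n, 0, noise_sd))
}

#' Simulate pairs spanning the LD decay for the phasing contrast
#'
#' Independent two-locus systems at increasing map separations: each
#' replicate draws a founder-chain segment and plants an effect of
#' random strength on one haplotype (the one carrying the regulatory alt
#' or ref allele, at random per replicate, so pairs spread across the
#' ratio scale), then emits per-sample ratio observations for the pair
#' (regulatory SNP, SNP at lag L) in two orientations — phased
#' (transcript ratio flipped by the sample's phase) and unphased (raw
#' reference orientation) — together with the empirical genetic distance
#' 1 - |r| of each pair.
#'
#' @param n_chains independent segments per lag.
#' @param lags integer vector of SNP separations.
#' @param ld_decay per-SNP founder redraw probability.
#' @param maf alt-allele frequency.
#' @param frac_range range of planted effect-haplotype read fractions;
#'   each replicate draws its own fraction uniformly from it.
#' @param depth read depth per observation.
#' @param n_samples samples per segment.
#' @param seed integer seed.
#' @return list: `obs_phased`, `obs_unphased` (data.frames `pair_id,
#'   reg_ratio, tx_ratio`) and `distances` (named vector by pair id).
#' @export
simulateLdPairs <- function(n_chains = 50L, lags = c(1L, 4L, 10L, 20L),
                            ld_decay = 0.15, maf = 0.3,
                            frac_range = c(0.55, 0.95), depth = 50L,
                            n_samples = 120L, seed = 1L) {
  set.seed(seed)
  max_lag <- max(lags)
  ph <- list(); un <- list(); dist <- numeric()
  for (ch in seq_len(n_chains)) {
    H <- founderChain(2L * n_samples, max_lag + 1L, ld_decay, maf)
    h1 <- H[, seq_len(n_samples) * 2L - 1L, drop = FALSE]
    h2 <- H[, seq_len(n_samples) * 2L, drop = FALSE]
    frac <- runif(1L, frac_range[1], frac_range[2])
    boost_alt <- sample(c(TRUE, FALSE), 1L)   # which reg allele's hap gains reads
    for (L in lags) {
      i <- 1L; j <- L + 1L
      joint <- which(h1[i, ] != h2[i, ] & h1[j, ] != h2[j, ])
      if (length(joint) < 3L) next
      pid <- paste0("c", ch, "_L", L)
      x_all <- c(h1[i, ], h2[i, ]); y_all <- c(h1[j, ], h2[j, ])
      if (var(x_all) == 0 || var(y_all) == 0) next
      dist[pid] <- 1 - abs(cor(x_all, y_all))
      reg_ratio <- tx_ph <- tx_un <- numeric(length(joint))
      for (k in seq_along(joint)) {
        s <- joint[k]
        eff_is_h1 <- (h1[i, s] == 1L) == boost_alt
        p_ref_reg <- if (boost_alt) 1 - frac else frac
        tx_eff_allele <- if (eff_is_h1) h1[j, s] else h2[j, s]
        p_ref_tx <- if (tx_eff_allele == 0L) frac else 1 - frac
        reg_ratio[k] <- rbinom(1L, depth, p_ref_reg) / depth
        txr <- rbinom(1L, depth, p_ref_tx) / depth
        tx_un[k] <- txr
        flipped <- h1[i, s] != h1[j, s]
        tx_ph[k] <- orientRatio(txr, flipped)
      }
      ph[[length(ph) + 1L]] <- data.frame(pair_id = pid,
                                          reg_ratio = reg_ratio,
                                          tx_ratio = tx_ph)
      un[[length(un) + 1L]] <- data.frame(pair_id = pid,
                                          reg_ratio = reg_ratio,
                                          tx_ratio = tx_un)
    }
  }
  list(obs_phased = do.call(rbind, ph), obs_unphased = do.call(rbind, un),
       distances = dist)
}
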