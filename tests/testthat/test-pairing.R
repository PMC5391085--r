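test_that("mark polarity follows the activating/repressive split", {
  expect_equal(markPolarity("H3K27ac"), "activating")
  expect_equal(markPolarity("H3K36me3"), "activating")
  expect_equal(markPolarity("H3K4me1"), "activating")
  expect_equal(markPolarity("H3K4me3"), "activating")
  expect_equal(markPolarity("H3K27me3"), "repressive")
  expect_error(markPolarity("H3K9me3"))
})

test_that("peaks map to genes through overlapping anchors", {
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
                                 mark = "H3K27ac")
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5051, 8000),
                                  strand = "+", gene_id = "g1",
                                  tss = 5051L)
  ia <- ChromatinInteractions(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5100)),
    "d1")
  hit <- mapPeakToGenes(peak, ia, genes)
  expect_equal(hit$gene_id, "g1")
  expect_equal(nrow(hit), 1L)

  # anchors on another chromosome never map
  ia2 <- ChromatinInteractions(
    GenomicRanges::GRanges("chr2", IRanges::IRanges(151, 250)),
    GenomicRanges::GRanges("chr2", IRanges::IRanges(5001, 5100)),
    "d1")
  expect_equal(nrow(mapPeakToGenes(peak, ia2, genes)), 0L)

  # two datasets supporting the same link -> two sources
  both <- ChromatinInteractions(
    c(anchorOne(ia), anchorOne(ia)), c(anchorTwo(ia), anchorTwo(ia)),
    c("d1", "d2"))
  hit2 <- mapPeakToGenes(peak, both, genes)
  expect_setequal(hit2$source, c("d1", "d2"))
})

test_that("phase flip detects alt alleles on different haplotypes", {
  # two SNPs, one sample; rows are (reg, tx)
  gt <- function(reg, tx) makePanel(rbind(reg[1], tx[1]),
                                    rbind(reg[2], tx[2]))
  expect_false(isFlipped(gt(c(0L, 1L), c(0L, 1L)), "s1", "s2", "I1"))
  expect_true(isFlipped(gt(c(0L, 1L), c(1L, 0L)), "s1", "s2", "I1"))
  expect_false(isFlipped(gt(c(1L, 0L), c(1L, 0L)), "s1", "s2", "I1"))
  expect_true(isFlipped(gt(c(1L, 0L), c(0L, 1L)), "s1", "s2", "I1"))
  expect_error(isFlipped(gt(c(0L, 0L), c(0L, 1L)), "s1", "s2", "I1"),
               "homozygous")
})

test_that("ratio orientation is an involution", {
  expect_equal(orientRatio(0.8, TRUE), 0.2)
  expect_equal(orientRatio(0.8, FALSE), 0.8)
  x <- runif(20)
  f <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  expect_equal(orientRatio(orientRatio(x, f), f), x)
})

test_that("direction matching honours polarity and excludes ties", {
  expect_true(directionMatch(0.8, 0.7, "activating"))
  expect_true(directionMatch(0.8, 0.3, "repressive"))
  expect_false(directionMatch(0.8, 0.3, "activating"))
  expect_false(directionMatch(0.8, 0.7, "repressive"))
  expect_true(is.na(directionMatch(0.5, 0.7, "activating")))
  expect_true(is.na(directionMatch(0.8, 0.5, "repressive")))
})

test_that("pairing decisions equal a brute-force haplotype evaluator", {
  # all 4 het-het phase configurations x 2 polarities x ratio grid
  grid <- c(0.1, 0.3, 0.7, 0.9)
  for (reg_h1 in 0:1) for (tx_h1 in 0:1) {
    panel <- makePanel(rbind(reg_h1, tx_h1),
                       rbind(1L - reg_h1, 1L - tx_h1))
    for (pol in c("activating", "repressive"))
      for (reg_ref_ratio in grid) for (tx_ref_ratio in grid) {
        flipped <- isFlipped(panel, "s1", "s2", "I1")
        got <- directionMatch(reg_ref_ratio,
                              orientRatio(tx_ref_ratio, flipped), pol)

        # oracle: identify the haplotype carrying each major allele
        maj_reg_allele <- if (reg_ref_ratio > 0.5) 0L else 1L
        maj_tx_allele <- if (tx_ref_ratio > 0.5) 0L else 1L
        hap_of_reg <- if (reg_h1 == maj_reg_allele) 1L else 2L
        hap_of_tx <- if (tx_h1 == maj_tx_allele) 1L else 2L
        same_hap <- hap_of_reg == hap_of_tx
        want <- if (pol == "activating") same_hap else !same_hap
        expect_identical(got, want)
      }
  }
})

test_that("planted effects become true pairs, null tags controls", {
  sim <- simulatePanel(simConfig(n_samples = 25, n_tags = 4, seed = 9))
  pairs <- labelPairs(sim$candidates, sim$panel, sim$counts)
  latent <- sim$truth$effect[match(pairs$gene_id, sim$truth$gene_id)]
  expect_gt(mean(pairs$label[latent] == "true_pair"), 0.8)
  expect_gt(mean(pairs$label[!latent] == "control_pair"), 0.8)
  # label partition is exhaustive and exclusive
  expect_true(all(pairs$label %in% c("true_pair", "control_pair",
                                     "untestable")))
})

test_that("pairs with no usable heterozygote are untestable", {
  sim <- simulatePanel(simConfig(n_samples = 25, n_tags = 2, seed = 5))
  reg <- sim$candidates$reg_snp[1]
  hom <- sampleIds(sim$panel)[!isHet(sim$panel, reg)]
  # restrict the panel to samples homozygous at this regulatory SNP
  sub <- subsetPanel(sim$panel, hom)
  counts <- sim$counts[sim$counts$sample %in% hom, ]
  pairs <- labelPairs(sim$candidates[1, , drop = FALSE], sub, counts)
  expect_equal(pairs$label, "untestable")
})

test_that("oriented concordance survives mixed phase configurations", {
  # plant one effect; check per-sample oriented ratios recompute from
  # haplotype truth irrespective of each sample's phase orientation
  sim <- simulatePanel(simConfig(n_samples = 40, n_tags = 2,
                                 effect_fraction = 0.8, seed = 13))
  pairs <- labelPairs(sim$candidates, sim$panel, sim$counts)
  tr <- sim$truth[sim$truth$effect, ]
  own <- pairs[pairs$gene_id %in% tr$gene_id &
                 pairs$reg_snp == tr$causal_snp, ]
  obs <- pairRatioObservations(own, sim$panel, sim$counts)
  expect_gt(nrow(obs), 5L)
  # oracle: the effect haplotype is the one carrying the causal alt, so in
  # the reg-REF frame both ratios sit at 1 - 0.8 in every sample, whatever
  # that sample's hap1/hap2 phase configuration is (binomial noise at
  # depth 50 has sd ~ 0.06, and the site filter trims the low tail)
  expect_true(all(abs(obs$tx_ratio - 0.2) < 0.2))
  expect_true(all(abs(obs$reg_ratio - 0.2) < 0.2))
  expect_lt(sd(obs$tx_ratio), 0.12)
  # the unphased view of the same pairs is not phase-consistent whenever
  # flips occur
  un <- pairRatioObservations(own, sim$panel, sim$counts, phased = FALSE)
  flips <- mapply(function(r, t, s) isFlipped(sim$panel, r, t, s),
                  un$reg_snp, un$tx_snp, un$sample)
  if (any(flips) && any(!flips))
    expect_gt(sd(un$tx_ratio), sd(obs$tx_ratio))
})
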