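# Shared fixture builders: tiny panels and count tables constructed in code.

# Panel from explicit haplotype matrices (snps x samples).
makePanel <- function(h1, h2, pos = NULL, chrom = "chr1",
                      ids = NULL, samples = NULL) {
  n <- nrow(h1)
  m <- ncol(h1)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  if (is.null(samples)) samples <- paste0("I", seq_len(m))
  snps <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                                 snp_id = ids, ref = "A", alt = "G")
  HaplotypePanel(snps, samples, h1, h2)
}

# One count row in the readAllelicCounts() schema.
countRow <- function(pos, sample, assay, ref_depth, alt_depth,
                     chrom = "chr1", study_id = "study1") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
             sample = sample, assay = assay, study_id = study_id,
             ref_depth = as.integer(ref_depth),
             alt_depth = as.integer(alt_depth))
}

# Stub classifier that always votes the same class; mimics the pieces of a
# randomForest object that rescueUntestable() touches.
constantModel <- function(vote_true, feature_names) {
  structure(list(vote = vote_true,
                 importance = matrix(0, length(feature_names), 1,
                                     dimnames = list(feature_names,
                                                     "MeanDecreaseGini"))),
            class = "constantModel")
}

predict.constantModel <- function(object, newdata, type = "response", ...) {
  factor(rep(if (object$vote) "true" else "control", nrow(newdata)),
         levels = c("control", "true"))
}
registerS3method("predict", "constantModel", predict.constantModel)

# Ensemble of constant voters for vote-boundary tests.
constantEnsemble <- function(n_true, n_false, feature_names,
                             vote_threshold = 5L) {
  models <- c(lapply(seq_len(n_true), function(i)
    constantModel(TRUE, feature_names)),
    lapply(seq_len(n_false), function(i)
      constantModel(FALSE, feature_names)))
  structure(list(models = models, cfg = forestConfig(
    vote_threshold = vote_threshold, seed = 1L)),
    class = "EnsembleResult")
}
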