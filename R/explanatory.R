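#' Regress transcript allele ratios on regulatory allele ratios
#'
#' Ordinary least squares of the transcript (RNA-seq) oriented ratio on
#' the paired regulatory (ChIP-seq) oriented ratio; the coefficient of
#' determination R^2 is the "explanatory power" of cis-regulatory
#' imbalance over allele-specific expression.
#'
#' @param reg_ratio,tx_ratio numeric vectors of paired oriented ratios
#'   (>= 3 points).
#' @return list `n_pairs, slope, intercept, r_squared`.
#' @export
fitRatioRegression <- function(reg_ratio, tx_ratio) {
  keep <- complete.cases(reg_ratio, tx_ratio)
  reg_ratio <- reg_ratio[keep]; tx_ratio <- tx_ratio[keep]
  if (length(reg_ratio) < 3L)
    stop("at least 3 pairs are required for the ratio regression")
  if (var(reg_ratio) == 0)
    stop("regression undefined: regulatory ratios are constant")
  fit <- lm(tx_ratio ~ reg_ratio)
  # summary() warns on noiseless fits; a perfect fit is a legal input here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(n_pairs = length(reg_ratio),
       slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = r2)
}

#' Explanatory power against genetic distance
#'
#' For each threshold d of the grid, pools the ratio observations of all
#' pairs whose genetic distance 1 - |r| is at most d and reports the R^2
#' of [fitRatioRegression()] on the pooled points (cumulative curve).
#' Thresholds admitting fewer than 3 points yield NA.
#'
#' @param obs data.frame with `pair_id, reg_ratio, tx_ratio` (for example
#'   from [pairRatioObservations()]).
#' @param distances named numeric vector of genetic distances by pair id.
#' @param grid increasing distance thresholds in \[0, 1\].
#' @param per_pair average the observations of each pair into one point
#'   before fitting (default FALSE: points pool across samples).
#' @return data.frame `threshold, n_points, r_squared`.
#' @export
distanceCurve <- function(obs, distances, grid = seq(0, 1, by = 0.1),
                          per_pair = FALSE) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  if (per_pair) {
    agg <- aggregate(cbind(reg_ratio, tx_ratio) ~ pair_id, data = obs, mean)
    obs <- agg
  }
  d <- distances[obs$pair_id]
  out <- lapply(grid, function(th) {
    sel <- !is.na(d) & d <= th
    r2 <- if (sum(sel) >= 3L && var(obs$reg_ratio[sel]) > 0)
      fitRatioRegression(obs$reg_ratio[sel], obs$tx_ratio[sel])$r_squared
    else NA_real_
    data.frame(threshold = th, n_points = sum(sel), r_squared = r2)
  })
  do.call(rbind, out)
}

#' Permute chromatin interactions
#'
#' Randomly permutes the second anchors among interactions of the same
#' chromosome, preserving the interaction count, the per-chromosome
#' anchor multisets and intrachromosomality.  Used as the negative
#' control: pairing through permuted interactions connects imbalance
#' pairs at random.
#'
#' @param interactions a [ChromatinInteractions-class] (>= 2 links).
#' @param seed integer seed for reproducibility.
#' @return permuted [ChromatinInteractions-class].
#' @export
permuteInteractions <- function(interactions, seed = NULL) {
  if (length(interactions) < 2L)
    stop("need at least 2 interactions to permute")
  if (!is.null(seed)) set.seed(seed)
  chrom <- as.character(seqnames(anchorOne(interactions)))
  perm <- seq_along(chrom)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    perm[idx] <- idx[sample.int(length(idx))]
  }
  ChromatinInteractions(anchorOne(interactions),
                        anchorTwo(interactions)[perm],
                        interactionSource(interactions))
}

#' eQTL-based pairing alternative
#'
#' Replaces the chromatin-interaction edges by significant eQTL SNP-gene
#' links and reruns the same pairing pipeline, for comparing the two ways
#' of assigning target genes.
#'
#' @inheritParams buildPairs
#' @param eqtl_table data.frame `snp_id, gene_id` of significant
#'   eQTL-gene pairs.
#' @return labeled pair data.frame (see [labelPairs()]).
#' @export
eqtlPairing <- function(tags, ld_sets, peaks, eqtl_table, genes, panel,
                        counts, cfg = imbalanceConfig()) {
  stopifnot(is.data.frame(eqtl_table),
            all(c("snp_id", "gene_id") %in% names(eqtl_table)))
  buildPairs(tags, ld_sets, peaks, eqtl_table, genes, panel, counts, cfg)
}
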