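#' Configuration of the allelic-imbalance tests
#'
#' Defaults follow the standard allele-imbalance filtering and testing
#' recipe: a heterozygous site enters testing only when its total allelic
#' depth exceeds 8 reads and its reference-allele ratio lies in
#' \[0.15, 0.85\] (guarding against genotyping error and mapping
#' artefacts); per-sample imbalance is an exact two-sided binomial test at
#' null probability 0.5; evidence across samples is combined by Fisher's
#' method and called imbalanced at combined chi-square P < 0.05.
#'
#' @param min_total_depth total depth must be strictly greater than this.
#' @param ratio_low,ratio_high inclusive bounds on the reference ratio.
#' @param per_sample_alpha nominal per-sample significance level.
#' @param meta_alpha threshold on the Fisher combined P.
#' @param null_p binomial null probability.
#' @param adjust_bh apply Benjamini-Hochberg across sites (off by default;
#'   the method as published works on raw P values).
#' @return list of class `ImbalanceConfig`.
#' @export
imbalanceConfig <- function(min_total_depth = 8L, ratio_low = 0.15,
                            ratio_high = 0.85, per_sample_alpha = 0.05,
                            meta_alpha = 0.05, null_p = 0.5,
                            adjust_bh = FALSE) {
  stopifnot(ratio_low >= 0, ratio_low < ratio_high, ratio_high <= 1,
            min_total_depth >= 0, null_p > 0, null_p < 1)
  structure(list(min_total_depth = min_total_depth, ratio_low = ratio_low,
                 ratio_high = ratio_high,
                 per_sample_alpha = per_sample_alpha,
                 meta_alpha = meta_alpha, null_p = null_p,
                 adjust_bh = adjust_bh),
            class = "ImbalanceConfig")
}

#' Reference-allele ratio
#'
#' @param ref_depth,alt_depth non-negative read counts.
#' @return `ref_depth / (ref_depth + alt_depth)`; error on zero total.
#' @export
referenceRatio <- function(ref_depth, alt_depth) {
  total <- ref_depth + alt_depth
  if (any(total == 0)) stop("reference ratio undefined at zero total depth")
  ref_depth / total
}

#' Depth and ratio site filter
#'
#' A heterozygous observation is testable iff total depth > 8 (default)
#' and the reference ratio lies within \[0.15, 0.85\] inclusive.
#'
#' @param ref_depth,alt_depth read counts (vectorised).
#' @param cfg an [imbalanceConfig()].
#' @return logical vector.
#' @export
passesSiteFilter <- function(ref_depth, alt_depth, cfg = imbalanceConfig()) {
  total <- ref_depth + alt_depth
  ok_depth <- total > cfg$min_total_depth
  ratio <- ifelse(total > 0, ref_depth / total, NA_real_)
  ok_depth & !is.na(ratio) & ratio >= cfg$ratio_low & ratio <= cfg$ratio_high
}

#' Average allelic depths over studies
#'
#' When the same sample/assay/SNP combination was assayed by several
#' studies, reference and alternative depths are averaged component-wise
#' over the studies and rounded half-up to integers (the binomial test
#' needs integer counts); with a single study the record passes through
#' unchanged.
#'
#' @param ads data.frame of count rows sharing `chrom, pos, sample, assay`
#'   with distinct `study_id`s.
#' @return one-row data.frame with averaged integer depths.
#' @export
averageAcrossStudies <- function(ads) {
  key <- unique(ads[, c("chrom", "pos", "sample", "assay")])
  if (nrow(key) != 1L)
    stop("averageAcrossStudies needs rows for a single snp/sample/assay")
  out <- ads[1L, , drop = FALSE]
  out$study_id <- paste(sort(unique(ads$study_id)), collapse = "+")
  out$ref_depth <- roundHalfUp(mean(ads$ref_depth))
  out$alt_depth <- roundHalfUp(mean(ads$alt_depth))
  out
}

# round half away from zero is not needed; counts are non-negative,
# so floor(x + 0.5) is round-half-up
roundHalfUp <- function(x) as.integer(floor(x + 0.5))

#' Exact two-sided binomial test at p = 0.5
#'
#' Two-sided P as the doubled smaller tail, capped at 1:
#' `min(1, 2 * min(P(X <= k), P(X >= k)))`.  With the symmetric null this
#' equals the minimum-likelihood two-sided test and is symmetric in
#' `k <-> n - k`.
#'
#' @param k reference-allele count (vectorised).
#' @param n total count.
#' @param p null probability (default 0.5).
#' @return two-sided P value(s) in (0, 1].
#' @export
binomialTwoSided <- function(k, n, p = 0.5) {
  if (any(n < 1)) stop("total count must be at least 1")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  lower <- pbinom(k, n, p)
  upper <- pbinom(k - 1, n, p, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Fisher's method for combining P values
#'
#' `chi_sq = -2 * sum(log(p_i))` referred to a chi-square distribution
#' with `2k` degrees of freedom (upper tail).  Zero P values are clamped
#' to the smallest positive double with a warning.
#'
#' @param ps numeric vector of P values in (0, 1].
#' @return list `chi_sq`, `dof`, `combined_p`.
#' @export
fisherCombine <- function(ps) {
  if (!length(ps)) stop("no P values to combine")
  if (any(ps < 0 | ps > 1)) stop("P values must lie in [0, 1]")
  if (any(ps == 0)) {
    warning("zero P value(s) clamped to smallest positive double")
    ps[ps == 0] <- .Machine$double.xmin
  }
  chi_sq <- -2 * sum(log(ps))
  dof <- 2L * length(ps)
  list(chi_sq = chi_sq, dof = dof,
       combined_p = pchisq(chi_sq, dof, lower.tail = FALSE))
}

# Per-sample study-averaged, filtered observations for one snp/assay.
# Returns a data.frame (possibly 0 rows): sample, ref_depth, alt_depth,
# ratio, p_value -- restricted to samples heterozygous in `panel`.
perSampleTests <- function(snp_id, assay, panel, counts,
                           cfg = imbalanceConfig()) {
  rows <- counts[!is.na(counts$snp_id) & counts$snp_id == snp_id &
                   counts$assay == assay, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  het <- isHet(panel, snp_id)
  rows <- rows[rows$sample %in% sampleIds(panel)[het], , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  avg <- do.call(rbind, lapply(split(rows, rows$sample), averageAcrossStudies))
  keep <- passesSiteFilter(avg$ref_depth, avg$alt_depth, cfg)
  avg <- avg[keep, , drop = FALSE]
  if (!nrow(avg)) return(NULL)
  avg$ratio <- referenceRatio(avg$ref_depth, avg$alt_depth)
  avg$p_value <- binomialTwoSided(avg$ref_depth,
                                  avg$ref_depth + avg$alt_depth, cfg$null_p)
  rownames(avg) <- NULL
  avg
}

#' Meta-analysed imbalance test at one site
#'
#' Restricts the counts to samples heterozygous for the SNP, averages
#' depths over studies within each sample, applies the depth/ratio filter,
#' runs the per-sample exact binomial test and combines the surviving
#' samples' P values by Fisher's method.  Ratios can be re-oriented per
#' sample (see [buildPairs()]) via `flip`, which only affects the reported
#' mean ratio, never the P values.
#'
#' @param snp_id SNP identifier.
#' @param assay assay label (histone mark or "RNA").
#' @param panel a [HaplotypePanel-class].
#' @param counts counts data.frame carrying a `snp_id` column (see
#'   [attachSnpIds()]).
#' @param cfg an [imbalanceConfig()].
#' @param flip optional named logical vector (by sample): TRUE means the
#'   sample's ratio is reported as `1 - ratio`.
#' @return one-row data.frame `snp_id, assay, n_samples, chi_sq, dof,
#'   combined_p, mean_ratio, is_imbalanced`, or NULL when no sample
#'   survives the het/depth/ratio filters (the site is untestable).
#' @export
testSite <- function(snp_id, assay, panel, counts, cfg = imbalanceConfig(),
                     flip = NULL) {
  per <- perSampleTests(snp_id, assay, panel, counts, cfg)
  if (is.null(per)) return(NULL)
  meta <- fisherCombine(per$p_value)
  ratio <- per$ratio
  if (!is.null(flip)) {
    f <- flip[per$sample]
    f[is.na(f)] <- FALSE
    ratio <- ifelse(f, 1 - ratio, ratio)
  }
  data.frame(snp_id = snp_id, assay = assay, n_samples = nrow(per),
             chi_sq = meta$chi_sq, dof = meta$dof,
             combined_p = meta$combined_p, mean_ratio = mean(ratio),
             is_imbalanced = meta$combined_p < cfg$meta_alpha)
}

#' Imbalance tests across all sites of an assay
#'
#' @param panel a [HaplotypePanel-class].
#' @param counts counts data.frame with `snp_id` attached.
#' @param assay assay label.
#' @param cfg an [imbalanceConfig()].
#' @return data.frame with one [testSite()] row per testable site; an
#'   optional BH-adjusted column when `cfg$adjust_bh`.
#' @export
testAllSites <- function(panel, counts, assay, cfg = imbalanceConfig()) {
  ids <- unique(counts$snp_id[!is.na(counts$snp_id) &
                                counts$assay == assay])
  res <- do.call(rbind, lapply(ids, testSite, assay = assay, panel = panel,
                               counts = counts, cfg = cfg))
  if (is.null(res))
    return(data.frame(snp_id = character(), assay = character(),
                      n_samples = integer(), chi_sq = numeric(),
                      dof = integer(), combined_p = numeric(),
                      mean_ratio = numeric(), is_imbalanced = logical()))
  if (isTRUE(cfg$adjust_bh)) {
    res$combined_p_bh <- stats::p.adjust(res$combined_p, "BH")
    res$is_imbalanced <- res$combined_p_bh < cfg$meta_alpha
  }
  rownames(res) <- NULL
  res
}
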