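#' Simple-regression QTL fit
#'
#' Ordinary least squares of a quantitative trait (peak intensity or gene
#' expression) on the additive genotype dosage, with the two-sided t-test
#' on the slope.
#'
#' @param dosage integer vector of alt-allele dosages (0/1/2) per sample.
#' @param trait numeric trait values per sample.
#' @return list `beta, se, t, p_value, n`.
#' @export
fitQtl <- function(dosage, trait) {
  keep <- complete.cases(dosage, trait)
  dosage <- dosage[keep]; trait <- trait[keep]
  if (length(dosage) < 3L) stop("QTL fit needs at least 3 samples")
  if (var(dosage) == 0)
    stop("QTL fit undefined: monomorphic dosage")
  # summary() warns on noiseless fits; those are legitimate here
  fit <- suppressWarnings(summary(lm(trait ~ dosage)))
  co <- fit$coefficients
  list(beta = unname(co["dosage", "Estimate"]),
       se = unname(co["dosage", "Std. Error"]),
       t = unname(co["dosage", "t value"]),
       p_value = unname(co["dosage", "Pr(>|t|)"]),
       n = length(dosage))
}

#' QTL scan over candidate SNP-trait pairs
#'
#' @param panel a [HaplotypePanel-class].
#' @param traits numeric matrix, one row per trait (rownames = trait ids),
#'   one column per sample (colnames = sample ids).
#' @param candidates data.frame `snp_id, trait_id` of associations to
#'   test; monomorphic SNPs are skipped.
#' @return data.frame `snp_id, trait_id, beta, p_value, n`.
#' @export
hqtlScan <- function(panel, traits, candidates) {
  dos <- genotypeDosage(panel)
  colnames(dos) <- sampleIds(panel)
  rownames(dos) <- snpIds(panel)
  common <- intersect(colnames(dos), colnames(traits))
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    s <- candidates$snp_id[i]; tr <- candidates$trait_id[i]
    if (!s %in% rownames(dos) || !tr %in% rownames(traits)) return(NULL)
    d <- dos[s, common]
    if (var(d) == 0) return(NULL)
    f <- fitQtl(d, traits[tr, common])
    data.frame(snp_id = s, trait_id = tr, beta = f$beta,
               p_value = f$p_value, n = f$n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(snp_id = character(), trait_id = character(),
                      beta = numeric(), p_value = numeric(), n = integer())
  rownames(out) <- NULL
  out
}

#' hQTL-eQTL pairs with same-direction filtering
#'
#' A pair (SNP, peak, gene) is kept iff the SNP is an hQTL for the peak
#' (P < alpha), an eQTL for an interaction-linked gene (P < alpha), and
#' the two effect signs agree for activating marks (oppose for the
#' repressive mark).
#'
#' @param hqtl data.frame from [hqtlScan()] over peak traits.
#' @param eqtl data.frame from [hqtlScan()] over expression traits.
#' @param links data.frame `trait_id, gene_id` connecting peak traits to
#'   genes via chromatin interactions.
#' @param alpha unadjusted significance threshold (default 0.05).
#' @param polarity "activating" (default) or "repressive".
#' @return data.frame `snp_id, trait_id, gene_id, beta_h, p_h, beta_e,
#'   p_e` of retained pairs.
#' @export
hqtlEqtlPairs <- function(hqtl, eqtl, links, alpha = 0.05,
                          polarity = c("activating", "repressive")) {
  polarity <- match.arg(polarity)
  sig_h <- hqtl[hqtl$p_value < alpha, , drop = FALSE]
  sig_e <- eqtl[eqtl$p_value < alpha, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(sig_h))) {
    gene_ids <- links$gene_id[links$trait_id == sig_h$trait_id[i]]
    hit <- sig_e[sig_e$snp_id == sig_h$snp_id[i] &
                   sig_e$trait_id %in% gene_ids, , drop = FALSE]
    if (!nrow(hit)) next
    same <- sign(hit$beta) == sign(sig_h$beta[i])
    ok <- if (polarity == "activating") same else !same
    hit <- hit[ok, , drop = FALSE]
    if (!nrow(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      snp_id = sig_h$snp_id[i], trait_id = sig_h$trait_id[i],
      gene_id = hit$trait_id, beta_h = sig_h$beta[i],
      p_h = sig_h$p_value[i], beta_e = hit$beta, p_e = hit$p_value)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp_id = character(), trait_id = character(),
                      gene_id = character(), beta_h = numeric(),
                      p_h = numeric(), beta_e = numeric(), p_e = numeric())
  rownames(res) <- NULL
  res
}

#' Sensitivity comparison between the allelic and QTL arms
#'
#' Counts, over an identical candidate tag set, how many tags each arm
#' detects and their overlap.
#'
#' @param allelic_detected character vector of tag ids detected by
#'   allelic mapping.
#' @param qtl_detected character vector of tag ids detected by QTL
#'   mapping.
#' @param common_start_set the identical candidate set both arms started
#'   from.
#' @return list `n_candidates, n_allelic, n_qtl, n_overlap, ratio`
#'   (allelic / QTL; NA when the QTL arm detects nothing).
#' @export
sensitivityReport <- function(allelic_detected, qtl_detected,
                              common_start_set) {
  a <- intersect(unique(allelic_detected), common_start_set)
  q <- intersect(unique(qtl_detected), common_start_set)
  list(n_candidates = length(unique(common_start_set)),
       n_allelic = length(a), n_qtl = length(q),
       n_overlap = length(intersect(a, q)),
       ratio = if (length(q)) length(a) / length(q) else NA_real_)
}
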