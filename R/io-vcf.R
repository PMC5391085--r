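#' Read phased genotypes from a VCF file
#'
#' Loads a VCF (v4.1+) and returns a [HaplotypePanel-class] containing only
#' biallelic SNVs whose GT field is phased (`|` separator) in every sample.
#' Multiallelic records and records with an unphased or missing genotype in
#' any sample are skipped; the number skipped is reported via `message()`.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param region optional GRanges; only records overlapping it are kept.
#' @return a [HaplotypePanel-class]; a warning is issued when no phased
#'   biallelic record survives.
#' @export
readPhasedVcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)

  biallelic <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf)) == 1L &
    width(rr) == 1L
  phased <- apply(gt, 1L, function(g)
    all(grepl("|", g, fixed = TRUE) & !grepl(".", g, fixed = TRUE)))
  keep <- which(biallelic & phased)
  n_skip <- length(rr) - length(keep)
  if (n_skip > 0)
    message(n_skip,
            " VCF record(s) skipped (multiallelic, unphased or missing GT)")
  if (!is.null(region))
    keep <- keep[IRanges::overlapsAny(rr[keep], region)]

  samples <- colnames(gt)
  if (length(keep) == 0L) {
    warning("no phased biallelic SNVs in ", path)
    snps <- GRanges(snp_id = character(), ref = character(),
                    alt = character())
    return(HaplotypePanel(snps, samples,
                          matrix(integer(), 0, length(samples)),
                          matrix(integer(), 0, length(samples))))
  }

  rr <- rr[keep]
  gt <- gt[keep, , drop = FALSE]
  ids <- names(rr)
  fallback <- paste0(as.character(seqnames(rr)), ":", start(rr))
  bad_id <- is.na(ids) | ids == "." | ids == ""
  ids[bad_id] <- fallback[bad_id]
  snps <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L),
                  snp_id = unname(ids),
                  ref = as.character(VariantAnnotation::ref(vcf)[keep]),
                  alt = as.character(unlist(VariantAnnotation::alt(vcf)[keep])))
  # GT strings are "a|b": haplotype 1 is character 1, haplotype 2 character 3
  hap <- function(k) matrix(as.integer(substr(gt, k, k)), nrow = nrow(gt))
  HaplotypePanel(snps, samples, hap(1L), hap(3L))
}

#' Write a HaplotypePanel as a phased VCF
#'
#' Emits a minimal VCF v4.2 file with phased GT fields, the inverse of
#' [readPhasedVcf()] for round-trip testing and for the synthetic panel
#' generator.
#'
#' @param panel a [HaplotypePanel-class]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
writePhasedVcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIds(panel)), collapse = "\t")),
             con)
  if (nSnps(panel)) {
    gt <- matrix(paste(hapMatrix(panel, 1), hapMatrix(panel, 2), sep = "|"),
                 nrow = nSnps(panel))
    rows <- cbind(as.character(seqnames(snpRanges(panel))),
                  start(snpRanges(panel)),
                  snpIds(panel),
                  mcols(snpRanges(panel))$ref,
                  mcols(snpRanges(panel))$alt,
                  ".", "PASS", ".", "GT", gt)
    writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}
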