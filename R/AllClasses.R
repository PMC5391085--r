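#' Phased haplotype panel
#'
#' Phased biallelic genotypes over a set of samples.  SNP metadata lives in
#' a [GenomicRanges::GRanges] of width-1 positions (1-based, VCF
#' convention) with metadata columns `snp_id`, `ref` and `alt`; the two
#' haplotype matrices hold allele indicators (0 = reference, 1 =
#' alternative) with one row per SNP and one column per sample.  Phase is
#' meaningful only within a sample: `hap1`/`hap2` labels are arbitrary but
#' consistent across SNPs of that sample.
#'
#' @slot snps GRanges of SNP positions with `snp_id`, `ref`, `alt`.
#' @slot samples character vector of sample identifiers.
#' @slot hap1,hap2 integer matrices (SNP x sample) of 0/1 allele codes.
#'
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  representation(
    snps = "GRanges",
    samples = "character",
    hap1 = "matrix",
    hap2 = "matrix"
  )
)

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  n <- length(object@snps)
  m <- length(object@samples)
  need <- c("snp_id", "ref", "alt")
  if (!all(need %in% names(mcols(object@snps))))
    msg <- c(msg, "snps must carry mcols snp_id, ref, alt")
  if (!identical(dim(object@hap1), c(n, m)) ||
      !identical(dim(object@hap2), c(n, m)))
    msg <- c(msg, "haplotype matrices must be n_snps x n_samples")
  if (length(object@hap1) && !all(object@hap1 %in% 0:1 & object@hap2 %in% 0:1))
    msg <- c(msg, "haplotype alleles must be 0 or 1")
  if (anyDuplicated(mcols(object@snps)$snp_id))
    msg <- c(msg, "snp_id values must be unique")
  if (n && any(mcols(object@snps)$ref == mcols(object@snps)$alt))
    msg <- c(msg, "ref and alt alleles must differ")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param snps GRanges of width-1 SNP positions with metadata columns
#'   `snp_id`, `ref`, `alt`.
#' @param samples character vector of sample ids.
#' @param hap1,hap2 integer matrices (SNP x sample) of 0/1 allele codes.
#' @return A [HaplotypePanel-class] object.
#' @examples
#' snps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1),
#'   snp_id = c("rs1", "rs2"), ref = "A", alt = "G")
#' HaplotypePanel(snps, "NA1", matrix(0L, 2, 1), matrix(1L, 2, 1))
#' @export
HaplotypePanel <- function(snps, samples, hap1, hap2) {
  dn <- list(mcols(snps)$snp_id, samples)
  hap1 <- matrix(as.integer(hap1), nrow = length(snps),
                 ncol = length(samples), dimnames = dn)
  hap2 <- matrix(as.integer(hap2), nrow = length(snps),
                 ncol = length(samples), dimnames = dn)
  new("HaplotypePanel", snps = snps, samples = as.character(samples),
      hap1 = hap1, hap2 = hap2)
}

#' @describeIn HaplotypePanel-class number of SNPs
#' @param x,object a `HaplotypePanel`
#' @export
nSnps <- function(x) length(x@snps)

#' @describeIn HaplotypePanel-class number of samples
#' @export
nSamples <- function(x) length(x@samples)

#' @describeIn HaplotypePanel-class SNP identifiers
#' @export
snpIds <- function(x) mcols(x@snps)$snp_id

#' @describeIn HaplotypePanel-class sample identifiers
#' @export
sampleIds <- function(x) x@samples

#' @describeIn HaplotypePanel-class GRanges of SNP positions with metadata
#' @export
snpRanges <- function(x) x@snps

#' Haplotype allele matrix
#'
#' @param x a [HaplotypePanel-class]
#' @param hap which haplotype, 1 or 2
#' @return integer matrix (SNP x sample) of 0/1 allele codes.
#' @export
hapMatrix <- function(x, hap = 1) {
  stopifnot(hap %in% 1:2)
  if (hap == 1) x@hap1 else x@hap2
}

#' Additive genotype dosage matrix
#'
#' Counts of the alternative allele per sample (0, 1 or 2), the standard
#' additive coding used in the QTL regressions.
#'
#' @param x a [HaplotypePanel-class]
#' @return integer matrix (SNP x sample) with values in 0:2.
#' @export
genotypeDosage <- function(x) x@hap1 + x@hap2

#' Heterozygosity indicator
#'
#' @param x a [HaplotypePanel-class]
#' @param snp_id single SNP identifier
#' @return named logical vector over samples.
#' @export
isHet <- function(x, snp_id) {
  i <- match(snp_id, snpIds(x))
  if (is.na(i)) stop("SNP not in panel: ", snp_id)
  x@hap1[i, ] != x@hap2[i, ]
}

#' Subset a panel by samples and/or SNPs
#'
#' @param x a [HaplotypePanel-class]
#' @param samples sample ids to keep (default all)
#' @param snps SNP ids to keep (default all)
#' @return a [HaplotypePanel-class]
#' @export
subsetPanel <- function(x, samples = sampleIds(x), snps = snpIds(x)) {
  si <- match(samples, sampleIds(x))
  vi <- match(snps, snpIds(x))
  if (anyNA(si)) stop("unknown sample id(s)")
  if (anyNA(vi)) stop("unknown SNP id(s)")
  HaplotypePanel(x@snps[vi], samples,
                 x@hap1[vi, si, drop = FALSE], x@hap2[vi, si, drop = FALSE])
}

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nSnps(object), "SNPs x", nSamples(object),
      "samples\n")
  if (nSnps(object)) {
    chr <- unique(as.character(seqnames(object@snps)))
    cat("  seqnames:", paste(head(chr, 5), collapse = ", "),
        if (length(chr) > 5) "..." else "", "\n")
    het <- mean(object@hap1 != object@hap2)
    cat(sprintf("  heterozygosity: %.3f\n", het))
  }
})

#' Chromatin interactions
#'
#' Paired genomic anchors linking regulatory regions to genes.  Only
#' intrachromosomal interactions are admitted: the two anchors of every
#' interaction share a chromosome.
#'
#' @slot anchor1,anchor2 GRanges of equal length (1-based, closed, as
#'   converted from BEDPE half-open input).
#' @slot source character vector of dataset labels, one per interaction.
#'
#' @exportClass ChromatinInteractions
setClass("ChromatinInteractions",
  representation(anchor1 = "GRanges", anchor2 = "GRanges",
                 source = "character")
)

setValidity("ChromatinInteractions", function(object) {
  msg <- character()
  if (length(object@anchor1) != length(object@anchor2))
    msg <- c(msg, "anchors must have equal length")
  if (length(object@source) != length(object@anchor1))
    msg <- c(msg, "one source label per interaction")
  if (length(object@anchor1) &&
      !all(as.character(seqnames(object@anchor1)) ==
           as.character(seqnames(object@anchor2))))
    msg <- c(msg, "interactions must be intrachromosomal")
  if (length(msg)) msg else TRUE
})

#' Construct a ChromatinInteractions object
#'
#' @param anchor1,anchor2 GRanges of equal length on matching chromosomes.
#' @param source dataset label(s), recycled to the interaction count.
#' @return a [ChromatinInteractions-class]
#' @export
ChromatinInteractions <- function(anchor1, anchor2, source = "interactome") {
  source <- rep_len(as.character(source), length(anchor1))
  new("ChromatinInteractions", anchor1 = anchor1, anchor2 = anchor2,
      source = source)
}

#' @describeIn ChromatinInteractions-class first anchors
#' @param x,object a `ChromatinInteractions`
#' @export
anchorOne <- function(x) x@anchor1

#' @describeIn ChromatinInteractions-class second anchors
#' @export
anchorTwo <- function(x) x@anchor2

#' @describeIn ChromatinInteractions-class dataset labels
#' @export
interactionSource <- function(x) x@source

setMethod("length", "ChromatinInteractions", function(x) length(x@anchor1))

setMethod("show", "ChromatinInteractions", function(object) {
  cat("ChromatinInteractions:", length(object), "intrachromosomal links from",
      length(unique(object@source)), "source(s)\n")
})

#' Subset interactions
#' @param x a [ChromatinInteractions-class]
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "ChromatinInteractions", function(x, i, j, ..., drop = TRUE) {
  ChromatinInteractions(x@anchor1[i], x@anchor2[i], x@source[i])
})
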