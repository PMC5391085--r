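writeVcfText <- function(lines, samples = "NA1") {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               lines), f)
  f
}

test_that("phased VCF records parse into a het panel", {
  f <- writeVcfText("chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1")
  panel <- readPhasedVcf(f)
  expect_equal(nSnps(panel), 1L)
  expect_equal(snpIds(panel), "rs1")
  expect_true(isHet(panel, "rs1"))
  expect_equal(unname(hapMatrix(panel, 1)[1, 1]), 0L)
  expect_equal(unname(hapMatrix(panel, 2)[1, 1]), 1L)
})

test_that("unphased and multiallelic records are skipped with a count", {
  f <- writeVcfText(c("chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1",
                      "chr1\t200\trs2\tA\tG,T\t.\tPASS\t.\tGT\t0|1"))
  expect_message(expect_warning(panel <- readPhasedVcf(f), "no phased"),
                 "2 VCF record")
  expect_equal(nSnps(panel), 0L)
})

test_that("panel round-trips through VCF exactly", {
  set.seed(7)
  h1 <- matrix(rbinom(15, 1, 0.5), 5, 3)
  h2 <- matrix(rbinom(15, 1, 0.5), 5, 3)
  panel <- makePanel(h1, h2)
  f <- tempfile(fileext = ".vcf")
  writePhasedVcf(panel, f)
  back <- readPhasedVcf(f)
  expect_equal(nSnps(back), 5L)
  expect_equal(nSamples(back), 3L)
  expect_equal(snpIds(back), snpIds(panel))
  expect_equal(unname(hapMatrix(back, 1)), unname(h1))
  expect_equal(unname(hapMatrix(back, 2)), unname(h2))
})

test_that("BED peaks parse with coordinates preserved", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", f)
  pk <- readBedPeaks(f, "H3K27ac")
  # BED [100,200) half-open -> 1-based closed 101..200
  expect_equal(start(pk), 101L)
  expect_equal(end(pk), 200L)
  expect_equal(S4Vectors::mcols(pk)$mark, "H3K27ac")

  writeLines(character(), f)
  expect_length(readBedPeaks(f, "H3K27ac"), 0L)
})

test_that("BED coordinate sums match an independent line scan", {
  set.seed(11)
  starts <- sample.int(10000, 10)
  ends <- starts + sample.int(500, 10)
  f <- tempfile(fileext = ".bed")
  writeLines(paste("chr2", starts, ends, sep = "\t"), f)
  pk <- readBedPeaks(f, "H3K4me1")
  expect_length(pk, 10L)
  raw <- strsplit(readLines(f), "\t")
  expect_equal(sum(start(pk) - 1L) + sum(end(pk)),
               sum(vapply(raw, function(x)
                 as.integer(x[2]) + as.integer(x[3]), integer(1))))
})

test_that("malformed BED intervals are rejected with the line number", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t300\t300"), f)
  expect_error(readBedPeaks(f, "H3K27ac"), "line 2")
})

test_that("BEDPE keeps intrachromosomal interactions only", {
  f <- tempfile(fileext = ".bedpe")
  writeLines("chr1\t0\t100\tchr1\t5000\t5100", f)
  x <- readBedpeInteractions(f, "d1")
  expect_length(x, 1L)
  expect_equal(start(anchorOne(x)), 1L)
  expect_equal(end(anchorTwo(x)), 5100L)

  writeLines("chr1\t0\t100\tchr2\t0\t100", f)
  expect_message(x <- readBedpeInteractions(f, "d1"), "1 interchromosomal")
  expect_length(x, 0L)

  writeLines(c("chr1\t0\t100\tchr1\t5000\t5100",
               "chr2\t0\t100\tchr2\t900\t1000",
               "chr1\t0\t100\tchr2\t0\t100",
               "chr3\t10\t20\tchr3\t50\t60"), f)
  expect_message(x <- readBedpeInteractions(f, "d1"), "1 interchromosomal")
  expect_length(x, 3L)
})

test_that("allelic count tables are validated on read", {
  f <- tempfile(fileext = ".tsv")
  writeAllelicCounts(countRow(100, "I1", "H3K27ac", 10, 5), f)
  df <- readAllelicCounts(f)
  expect_equal(nrow(df), 1L)
  expect_equal(df$ref_depth, 10L)

  writeAllelicCounts(countRow(100, "I1", "H3K27ac", -1, 5), f)
  expect_error(readAllelicCounts(f), "negative")

  writeAllelicCounts(countRow(100, "I1", "H3K9ac", 3, 5), f)
  expect_error(readAllelicCounts(f), "H3K27ac")   # error lists allowed assays
})

test_that("generator count tables round-trip exactly", {
  sim <- simulatePanel(simConfig(n_samples = 5, n_tags = 2, seed = 3))
  f <- tempfile(fileext = ".tsv")
  counts <- sim$counts[, setdiff(names(sim$counts), "snp_id")]
  writeAllelicCounts(counts, f)
  back <- readAllelicCounts(f)
  rownames(counts) <- NULL
  expect_equal(back, counts)
  expect_equal(table(back$assay), table(counts$assay))
})

test_that("containment convention matches a brute-force half-open scan", {
  set.seed(23)
  for (rep_i in 1:20) {
    bed_start <- sample.int(1000, 1)
    bed_end <- bed_start + sample.int(200, 1)
    pos <- sample.int(1300, 50)   # 1-based SNP positions
    f <- tempfile(fileext = ".bed")
    writeLines(paste("chr1", bed_start, bed_end, sep = "\t"), f)
    pk <- readBedPeaks(f, "H3K27ac")
    got <- as.logical(distalPeakBit(
      GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1)), pk))
    want <- bed_start <= (pos - 1) & (pos - 1) < bed_end
    expect_identical(got, want)
  }
})

test_that("gene models validate TSS and strand", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = "g1", chrom = "chr1", start = 100L,
                   end = 500L, tss = 100L, strand = "+")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- readGeneModels(f)
  expect_equal(S4Vectors::mcols(g)$tss, 100L)

  df$tss <- 600L
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readGeneModels(f), "tss")
})
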