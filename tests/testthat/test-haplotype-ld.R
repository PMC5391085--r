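# Haplotype vectors below are written chromosome-wise: with one sample the
# two columns are its two haplotypes; with two samples, columns are
# (I1.h1, I2.h1 | I1.h2, I2.h2).

test_that("ldPearson matches hand-computed correlations", {
  # 4 chromosomes: a = 0,0,1,1 ; identical column -> r = 1
  h1 <- rbind(c(0L, 0L), c(0L, 0L))
  h2 <- rbind(c(1L, 1L), c(1L, 1L))
  p <- makePanel(h1, h2)
  st <- ldPearson(p, "s1", "s2")
  expect_equal(st$r, 1)
  expect_equal(st$distance, 0)

  # a = [0,0,1,1], b = [0,1,0,1] -> covariance 0.25 - 0.5*0.5 = 0, r = 0
  h1 <- rbind(c(0L, 0L), c(0L, 1L))
  h2 <- rbind(c(1L, 1L), c(0L, 1L))
  st <- ldPearson(makePanel(h1, h2), "s1", "s2")
  expect_equal(st$r, 0)
  expect_equal(st$distance, 1)

  # perfect anti-correlation: distance still 0
  h1 <- rbind(c(0L, 0L), c(1L, 1L))
  h2 <- rbind(c(1L, 1L), c(0L, 0L))
  st <- ldPearson(makePanel(h1, h2), "s1", "s2")
  expect_equal(st$r, -1)
  expect_equal(st$distance, 0)
})

test_that("monomorphic SNPs yield a flagged undefined stat", {
  h1 <- rbind(c(0L, 0L), c(0L, 1L))
  h2 <- rbind(c(0L, 0L), c(1L, 0L))
  st <- ldPearson(makePanel(h1, h2), "s1", "s2")
  expect_false(st$defined)
  expect_true(is.na(st$r))
  expect_error(ldPearson(makePanel(h1, h2), "s1", "nope"), "not in panel")
})

test_that("ldPearson agrees with the covariance formula oracle", {
  set.seed(31)
  for (i in 1:100) {
    m <- sample(3:8, 1)
    h1 <- matrix(rbinom(2 * m, 1, 0.5), 2, m)
    h2 <- matrix(rbinom(2 * m, 1, 0.5), 2, m)
    p <- makePanel(h1, h2)
    x <- c(h1[1, ], h2[1, ]); y <- c(h1[2, ], h2[2, ])
    if (var(x) == 0 || var(y) == 0) next
    oracle <- mean(x * y) - mean(x) * mean(y)
    oracle <- oracle / sqrt((mean(x^2) - mean(x)^2) *
                              (mean(y^2) - mean(y)^2))
    expect_equal(ldPearson(p, "s1", "s2")$r, oracle, tolerance = 1e-12)
  }
})

test_that("four-gamete blocks split exactly at four-gamete pairs", {
  # gametes {00,11} only -> one block
  h1 <- rbind(c(0L, 1L), c(0L, 1L))
  h2 <- rbind(c(1L, 0L), c(1L, 0L))
  b <- fourGameteBlocks(makePanel(h1, h2), "chr1")
  expect_equal(unique(b$block_id), 1L)

  # all four gametes -> two blocks (chromosomes 00,01,10,11)
  h1 <- rbind(c(0L, 1L), c(0L, 0L))
  h2 <- rbind(c(0L, 1L), c(1L, 1L))
  b <- fourGameteBlocks(makePanel(h1, h2), "chr1")
  expect_equal(b$block_id, c(1L, 2L))

  # single SNP -> singleton block
  b <- fourGameteBlocks(makePanel(matrix(0L, 1, 2), matrix(1L, 1, 2)),
                        "chr1")
  expect_equal(nrow(b), 1L)
  expect_equal(b$block_id, 1L)
})

test_that("four-gamete partition matches a brute-force checker", {
  set.seed(41)
  for (rep_i in 1:15) {
    n_snp <- 20; n_samp <- sample(4:10, 1)
    h1 <- matrix(rbinom(n_snp * n_samp, 1, 0.4), n_snp, n_samp)
    h2 <- matrix(rbinom(n_snp * n_samp, 1, 0.4), n_snp, n_samp)
    p <- makePanel(h1, h2)
    b <- fourGameteBlocks(p, "chr1")

    # partition: every SNP exactly once, in position order
    expect_equal(b$snp_id, paste0("s", 1:n_snp))
    expect_true(all(diff(b$block_id) %in% 0:1))

    H <- cbind(h1, h2)
    gam <- function(i, j)
      length(unique(paste(H[i, ], H[j, ])))
    # within every block all pairs show <= 3 gametes
    for (bl in unique(b$block_id)) {
      idx <- match(b$snp_id[b$block_id == bl], paste0("s", 1:n_snp))
      if (length(idx) > 1)
        for (a in seq_along(idx)[-1]) for (c in seq_len(a - 1))
          expect_lte(gam(idx[a], idx[c]), 3L)
    }
    # greedy: the first SNP of each later block conflicts with some
    # member of the preceding block
    blocks <- split(match(b$snp_id, paste0("s", 1:n_snp)), b$block_id)
    for (k in seq_along(blocks)[-1]) {
      first <- blocks[[k]][1]
      prev <- blocks[[k - 1]]
      expect_true(any(vapply(prev, function(j) gam(first, j) == 4L,
                             logical(1))))
    }
  }
})

test_that("block merging is the transitive closure of co-occurrence", {
  gab <- data.frame(population = "CEU", chrom = "chr1", block_id = 1L,
                    snp_id = c("s1", "s2"))
  gam <- data.frame(population = "CEU", chrom = "chr1", block_id = 1L,
                    snp_id = c("s2", "s3"))
  m <- mergeBlocks(gab, gam)
  expect_equal(sort(m$snp_id[m$block_id == m$block_id[m$snp_id == "s1"]]),
               c("s1", "s2", "s3"))

  # empty GAM -> identity
  m2 <- mergeBlocks(gab, gam[0, ])
  expect_equal(sort(m2$snp_id), c("s1", "s2"))
  expect_equal(unique(m2$block_id), 1L)

  # disjoint blocks stay separate
  gam3 <- data.frame(population = "CEU", chrom = "chr1", block_id = 1L,
                     snp_id = c("s3", "s4"))
  m3 <- mergeBlocks(gab, gam3)
  expect_equal(length(unique(m3$block_id)), 2L)

  expect_error(mergeBlocks(gab, transform(gam, population = "YRI")),
               "population")
})

test_that("LD expansion intersects block membership over populations", {
  mk <- function(pop, members)
    data.frame(population = pop, chrom = "chr1", block_id = 1L,
               snp_id = members)
  blocks <- list(CEU = mk("CEU", c("t", "s1", "s2", "s3")),
                 YRI = mk("YRI", c("t", "s2", "s3", "s4")),
                 CHB = mk("CHB", c("t", "s2", "s3")),
                 JPT = mk("JPT", c("t", "s2", "s3")))
  expect_setequal(ldExpand("t", blocks), c("t", "s2", "s3"))

  # blockless in one population -> degenerate singleton
  blocks$JPT <- mk("JPT", c("s9", "s10"))
  expect_equal(ldExpand("t", blocks), "t")

  # identical blocks -> that block
  same <- list(CEU = mk("CEU", c("t", "a")), YRI = mk("YRI", c("t", "a")))
  expect_setequal(ldExpand("t", same), c("t", "a"))

  expect_error(ldExpand("t", list()), "no populations")
})
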