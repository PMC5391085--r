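#' Pairwise linkage disequilibrium as a haplotype correlation
#'
#' Pearson correlation r between the 0/1 allele indicators of two SNPs over
#' all 2N phased chromosomes of the panel, together with the genetic
#' distance 1 - |r| used throughout the explanatory-power analysis.  If
#' either SNP is monomorphic in the panel, r is undefined and the stat is
#' flagged (`defined = FALSE`, r and distance NA).
#'
#' @param panel a [HaplotypePanel-class]
#' @param snp_a,snp_b SNP identifiers present in the panel.
#' @return one-row data.frame: `snp_a, snp_b, r, distance, defined`.
#' @examples
#' # identical allele columns give r = 1 and distance 0
#' @export
ldPearson <- function(panel, snp_a, snp_b) {
  ia <- match(snp_a, snpIds(panel))
  ib <- match(snp_b, snpIds(panel))
  if (is.na(ia) || is.na(ib))
    stop("SNP not in panel: ", if (is.na(ia)) snp_a else snp_b)
  x <- c(hapMatrix(panel, 1)[ia, ], hapMatrix(panel, 2)[ia, ])
  y <- c(hapMatrix(panel, 1)[ib, ], hapMatrix(panel, 2)[ib, ])
  if (var(x) == 0 || var(y) == 0)
    return(data.frame(snp_a = snp_a, snp_b = snp_b, r = NA_real_,
                      distance = NA_real_, defined = FALSE))
  r <- cor(x, y)
  data.frame(snp_a = snp_a, snp_b = snp_b, r = r, distance = 1 - abs(r),
             defined = TRUE)
}

# Number of distinct gametes (haplotype configurations in {00,01,10,11})
# observed for a pair of allele vectors over the 2N chromosomes.
gameteCount <- function(x, y) length(unique(x * 2L + y))

#' Haplotype blocks by the four-gamete rule
#'
#' Greedy left-to-right partition of the chromosome's SNPs (in position
#' order): a SNP joins the current block iff, for every SNP already in the
#' block, the pair shows at most 3 of the 4 possible gametes among the
#' observed haplotypes; otherwise it starts a new block.  Observing all
#' four gametes implies historical recombination between the loci, so a
#' block never spans such a pair.  Monomorphic SNPs always join (at most 2
#' gametes).
#'
#' @param panel a phased [HaplotypePanel-class]
#' @param chrom chromosome to partition.
#' @param population label recorded with the blocks (default "PANEL").
#' @return data.frame `population, chrom, block_id, snp_id`, one row per
#'   member, blocks numbered left to right.
#' @export
fourGameteBlocks <- function(panel, chrom, population = "PANEL") {
  on_chr <- which(as.character(seqnames(snpRanges(panel))) == chrom)
  if (!length(on_chr))
    return(data.frame(population = character(), chrom = character(),
                      block_id = integer(), snp_id = character()))
  on_chr <- on_chr[order(start(snpRanges(panel))[on_chr])]
  H <- cbind(hapMatrix(panel, 1)[on_chr, , drop = FALSE],
             hapMatrix(panel, 2)[on_chr, , drop = FALSE])
  ids <- snpIds(panel)[on_chr]
  block_id <- integer(length(on_chr))
  current <- 1L
  members <- 1L
  block_id[1L] <- 1L
  for (i in seq_along(on_chr)[-1L]) {
    ok <- all(vapply(members, function(j)
      gameteCount(H[i, ], H[j, ]) <= 3L, logical(1)))
    if (ok) {
      members <- c(members, i)
    } else {
      current <- current + 1L
      members <- i
    }
    block_id[i] <- current
  }
  data.frame(population = population, chrom = chrom,
             block_id = block_id, snp_id = ids)
}

#' Merge two block partitions of the same population
#'
#' Two SNPs end up in one merged block iff they co-occur in any block of
#' either input (transitive closure of the union relation), the rule used
#' to combine confidence-interval (GAB) and four-gamete (GAM) blocks of
#' one ethnicity.
#'
#' @param gab,gam block data.frames (`population, chrom, block_id, snp_id`)
#'   from the same population and chromosome set.
#' @return merged block data.frame in the same format; merged blocks are
#'   renumbered per chromosome.
#' @export
mergeBlocks <- function(gab, gam) {
  pops <- unique(c(gab$population, gam$population))
  if (length(pops) > 1L)
    stop("cannot merge blocks from different populations: ",
         paste(pops, collapse = ", "))
  both <- rbind(gab, gam)
  if (nrow(both) == 0L) return(both)
  # connect consecutive members of each (source, block) group; connected
  # components of the resulting graph are the transitive closure
  both$grp <- paste(rep(c("gab", "gam"), c(nrow(gab), nrow(gam))),
                    both$chrom, both$block_id)
  verts <- unique(both[, c("chrom", "snp_id")])
  verts$key <- paste(verts$chrom, verts$snp_id)
  edges <- do.call(rbind, lapply(split(both, both$grp), function(b) {
    if (nrow(b) < 2L) return(NULL)
    k <- paste(b$chrom, b$snp_id)
    cbind(k[-length(k)], k[-1L])
  }))
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(), to = character())
    else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = verts$key)
  comp <- igraph::components(g)$membership[verts$key]
  out <- data.frame(population = pops, chrom = verts$chrom,
                    block_id = NA_integer_, snp_id = verts$snp_id)
  for (ch in unique(out$chrom)) {
    sel <- out$chrom == ch
    out$block_id[sel] <- match(comp[sel], unique(comp[sel]))
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$block_id), ]
}

#' Cross-population LD expansion of a tag SNP
#'
#' Returns the SNPs residing in the same merged block as the tag commonly
#' in all populations: the intersection over populations of the member set
#' of the block containing the tag.  The tag itself is always included; if
#' the tag belongs to no block in some population the expansion degenerates
#' to the tag alone.
#'
#' @param tag_id tag SNP identifier.
#' @param blocks_by_population named list of block data.frames, one per
#'   population.
#' @return character vector of SNP ids (tag first).
#' @export
ldExpand <- function(tag_id, blocks_by_population) {
  if (!length(blocks_by_population))
    stop("no populations supplied for LD expansion")
  sets <- lapply(blocks_by_population, function(b) {
    hit <- b[b$snp_id == tag_id, , drop = FALSE]
    if (nrow(hit) == 0L) return(tag_id)
    members <- b$snp_id[b$chrom == hit$chrom[1] &
                          b$block_id == hit$block_id[1]]
    union(tag_id, members)
  })
  out <- Reduce(intersect, sets)
  union(tag_id, out)
}
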