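#' Pairing funnel summary
#'
#' The three-level funnel reported per histone mark: applicable
#' (heterozygous with an interaction-linked candidate), imbalanced
#' (regulatory imbalance detected) and paired (allele-specific pair
#' formed), for tag SNPs and for target genes.
#'
#' @param pairs labeled pair data.frame from [labelPairs()].
#' @return data.frame `mark, level, n_tags, n_genes` with levels
#'   applicable >= imbalanced >= paired.
#' @export
reportFunnel <- function(pairs) {
  out <- lapply(unique(pairs$mark), function(m) {
    pm <- pairs[pairs$mark == m, , drop = FALSE]
    imb <- pm[!is.na(pm$reg_imbalanced) & pm$reg_imbalanced, , drop = FALSE]
    par <- pm[pm$label == "true_pair", , drop = FALSE]
    data.frame(mark = m,
               level = c("applicable", "imbalanced", "paired"),
               n_tags = c(length(unique(pm$tag_snp)),
                          length(unique(imb$tag_snp)),
                          length(unique(par$tag_snp))),
               n_genes = c(length(unique(pm$gene_id)),
                           length(unique(imb$gene_id)),
                           length(unique(par$gene_id))))
  })
  do.call(rbind, out)
}

#' Run the full pipeline on an emitted panel directory
#'
#' Orchestrates the stages in order — LD expansion, imbalance testing,
#' pairing, explanatory power, QTL comparison, prediction and (when
#' `subpanel_k` is given) subpanel rescue with full-panel validation —
#' reading every input through the package's file readers and writing
#' result TSVs plus a JSON manifest with stage counts and file hashes.
#'
#' @param indir directory written by [emitPanel()] (panel.vcf,
#'   counts.tsv, peaks_*.bed, interactions.bedpe, genes.tsv, blocks.tsv,
#'   tags.tsv, features.tsv).
#' @param outdir output directory.
#' @param imb_cfg an [imbalanceConfig()].
#' @param forest_cfg a [forestConfig()]; its seed drives all training
#'   randomness.
#' @param subpanel_k optional subpanel size for the rescue experiment.
#' @param n_reps subpanel resamplings (default 10).
#' @param run_qtl,run_forest stage switches.
#' @return invisible list with the stage results (`pairs`, `funnel`,
#'   `curve`, `qtl`, `ensemble`, `rescue_validation`, `manifest`).
#' @export
runPipeline <- function(indir, outdir, imb_cfg = imbalanceConfig(),
                        forest_cfg = forestConfig(), subpanel_k = NULL,
                        n_reps = 10L, run_qtl = FALSE, run_forest = TRUE) {
  req <- c("panel.vcf", "counts.tsv", "interactions.bedpe", "genes.tsv",
           "blocks.tsv", "tags.tsv", "features.tsv")
  missing_f <- req[!file.exists(file.path(indir, req))]
  if (length(missing_f))
    stop("missing input file(s): ", paste(missing_f, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  o <- function(f) file.path(outdir, f)

  panel <- readPhasedVcf(file.path(indir, "panel.vcf"))
  counts <- attachSnpIds(readAllelicCounts(file.path(indir, "counts.tsv")),
                         panel)
  peak_files <- list.files(indir, "^peaks_.*\\.bed$", full.names = TRUE)
  peaks <- do.call(c, lapply(peak_files, function(f)
    readBedPeaks(f, sub("^peaks_(.*)\\.bed$", "\\1", basename(f)))))
  interactions <- readBedpeInteractions(file.path(indir,
                                                  "interactions.bedpe"))
  genes <- readGeneModels(file.path(indir, "genes.tsv"))
  blocks <- readLdBlocks(file.path(indir, "blocks.tsv"))
  tags <- read.table(file.path(indir, "tags.tsv"), header = TRUE,
                     stringsAsFactors = FALSE)$tag_snp
  feat <- read.table(file.path(indir, "features.tsv"), header = TRUE,
                     sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
  X <- as.matrix(feat[, -1, drop = FALSE])
  rownames(X) <- feat$pair_id

  ld_sets <- setNames(lapply(tags, ldExpand,
                             blocks_by_population = split(blocks,
                                                          blocks$population)),
                      tags)
  pairs <- buildPairs(tags, ld_sets, peaks, interactions, genes, panel,
                      counts, imb_cfg)
  write.table(pairs, o("pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  funnel <- reportFunnel(pairs)
  write.table(funnel, o("funnel.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  obs <- pairRatioObservations(pairs, panel, counts, imb_cfg)
  distances <- vapply(unique(obs$pair_id), function(pid) {
    i <- match(pid, pairs$pair_id)
    ldPearson(panel, pairs$reg_snp[i], pairs$tx_snp[i])$distance
  }, numeric(1))
  curve <- distanceCurve(obs, distances)
  write.table(curve, o("explanatory_curve.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  qtl_res <- NULL
  if (run_qtl && file.exists(file.path(indir, "traits_peaks.tsv"))) {
    rdm <- function(f) {
      d <- read.table(file.path(indir, f), header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
      m <- as.matrix(d[, -1, drop = FALSE])
      rownames(m) <- d$trait_id
      m
    }
    tp <- rdm("traits_peaks.tsv")
    te <- rdm("traits_expression.tsv")
    links <- read.table(file.path(indir, "links.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
    peak_of <- setNames(links$trait_id, links$gene_id)
    cand_h <- unique(data.frame(snp_id = pairs$reg_snp,
                                trait_id = unname(peak_of[pairs$gene_id])))
    cand_e <- unique(data.frame(snp_id = pairs$reg_snp,
                                trait_id = pairs$gene_id))
    hq <- hqtlScan(panel, tp, cand_h)
    eq <- hqtlScan(panel, te, cand_e)
    qtl_res <- hqtlEqtlPairs(hq, eq, links)
    write.table(qtl_res, o("qtl_pairs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  ensemble <- NULL
  rescue_validation <- NULL
  if (run_forest) {
    parts <- partitionCases(pairs)
    testable <- rbind(parts$true, parts$control)
    if (nrow(parts$true) >= 2L && nrow(parts$control) >= 2L) {
      ensemble <- trainEnsemble(X[testable$pair_id, , drop = FALSE],
                                testable$label == "true_pair", forest_cfg)
      write.table(data.frame(classifier = seq_along(ensemble$cv_auc),
                             auc = ensemble$cv_auc),
                  o("ensemble_auc.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    if (!is.null(subpanel_k)) {
      sim_like <- list(panel = panel, counts = counts,
                       candidates = pairs[, c("pair_id", "tag_snp",
                                              "reg_snp", "mark",
                                              "gene_id", "tx_snp",
                                              "n_sources", "sources")],
                       X = X)
      reps <- subsampleExperiment(sim_like, subpanel_k, n_reps,
                                  forest_cfg, imb_cfg)
      val <- lapply(reps, function(r) {
        pos <- if (is.null(r$rescue)) character()
               else r$rescue$pair_id[r$rescue$positive]
        validateRescue(pos, pairs)
      })
      rescue_validation <- data.frame(
        sampling_number = seq_along(val),
        n_predicted = vapply(val, `[[`, numeric(1), "n_predicted"),
        n_tested = vapply(val, `[[`, numeric(1), "n_tested"),
        n_confirmed = vapply(val, `[[`, numeric(1), "n_confirmed"),
        percentage = vapply(val, `[[`, numeric(1), "percentage"))
      write.table(rescue_validation, o("rescue_validation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  out_files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    inputs = file.path(indir, req),
    outputs = setNames(as.list(unname(tools::md5sum(out_files))),
                       basename(out_files)),
    seed = forest_cfg$seed,
    counts = list(n_tags = length(tags), n_pairs = nrow(pairs),
                  n_true = sum(pairs$label == "true_pair"),
                  n_control = sum(pairs$label == "control_pair"),
                  n_untestable = sum(pairs$label == "untestable")))
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE)
  invisible(list(pairs = pairs, funnel = funnel, curve = curve,
                 qtl = qtl_res, ensemble = ensemble,
                 rescue_validation = rescue_validation,
                 manifest = manifest))
}
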