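#' Random Forest ensemble configuration
#'
#' The published configuration: 1,000 trees per classifier, default mtry
#' (floor of the square root of the feature count), minimum terminal-node
#' size 1, 5-fold cross validation with two repetitions (10 classifiers),
#' and a strict majority vote (more than 5 of 10) for positive rescue
#' calls.
#'
#' @param n_trees trees per forest.
#' @param folds cross-validation folds.
#' @param repetitions CV repetitions; ensemble size = folds x repetitions.
#' @param vote_threshold strict lower bound on positive votes.
#' @param seed integer seed controlling fold assignment and forests.
#' @return list of class `ForestConfig`.
#' @export
forestConfig <- function(n_trees = 1000L, folds = 5L, repetitions = 2L,
                         vote_threshold = 5L, seed = 1L) {
  stopifnot(folds >= 2L, repetitions >= 1L, n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 vote_threshold = as.integer(vote_threshold),
                 seed = as.integer(seed)),
            class = "ForestConfig")
}

#' Area under the ROC curve by the rank statistic
#'
#' Wilcoxon/Mann-Whitney AUC from scores: ties handled by midranks.
#'
#' @param scores numeric prediction scores.
#' @param positive logical vector, TRUE for the positive class.
#' @return AUC in \[0, 1\]; NA when either class is empty.
#' @export
aucMidrank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Partition labeled pairs into true, control and untestable sets
#'
#' True cases passed both imbalance tests with matching direction;
#' control cases were testable but failed; untestable cases lacked
#' jointly heterozygous filter-passing observations (either because no
#' heterozygote exists among the given samples or because the depth/ratio
#' filter removed them all).
#'
#' @param pairs labeled pair data.frame from [labelPairs()].
#' @return list of three data.frames: `true`, `control`, `untestable`.
#' @export
partitionCases <- function(pairs) {
  list(true = pairs[pairs$label == "true_pair", , drop = FALSE],
       control = pairs[pairs$label == "control_pair", , drop = FALSE],
       untestable = pairs[pairs$label == "untestable", , drop = FALSE])
}

# Stratified fold assignment: within each class, samples are dealt into
# folds as evenly as possible.
stratifiedFolds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Train the cross-validated Random Forest ensemble
#'
#' Stratified 5-fold cross validation repeated twice: each repetition
#' deals the pairs into 5 folds and trains one forest per fold on its
#' complement, giving 10 classifiers in total; every pair is held out
#' exactly once per repetition, hence exactly twice overall.  Held-out
#' AUC is computed per fold from the forest's class probabilities by the
#' rank statistic.
#'
#' @param X numeric feature matrix (rownames = pair ids).
#' @param y logical vector (TRUE = true pair) or two-level factor aligned
#'   with the rows of `X`.
#' @param cfg a [forestConfig()].
#' @return list of class `EnsembleResult`: `models` (10 forests), `folds`
#'   (data.frame pair_id, repetition, fold), `cv_auc` (one AUC per
#'   classifier), `scores` (held-out probabilities), `cfg`.
#' @export
trainEnsemble <- function(X, y, cfg = forestConfig()) {
  if (is.logical(y)) y <- factor(ifelse(y, "true", "control"),
                                 levels = c("control", "true"))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop("training labels contain a single class")
  stopifnot(nrow(X) == length(y))
  set.seed(cfg$seed)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  models <- list()
  fold_rows <- list()
  score_rows <- list()
  cv_auc <- numeric(0)
  for (rep_i in seq_len(cfg$repetitions)) {
    fold <- stratifiedFolds(y, cfg$folds)
    fold_rows[[rep_i]] <- data.frame(pair_id = rownames(X),
                                     repetition = rep_i, fold = fold)
    for (f in seq_len(cfg$folds)) {
      train <- fold != f
      m <- randomForest::randomForest(
        x = X[train, , drop = FALSE], y = y[train],
        ntree = cfg$n_trees, mtry = mtry, nodesize = 1)
      models[[length(models) + 1L]] <- m
      held <- which(!train)
      prob <- predict(m, X[held, , drop = FALSE], type = "prob")[, "true"]
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        pair_id = rownames(X)[held], repetition = rep_i, fold = f,
        score = unname(prob), label = y[held])
      cv_auc <- c(cv_auc, aucMidrank(prob, y[held] == "true"))
    }
  }
  structure(list(models = models,
                 folds = do.call(rbind, fold_rows),
                 cv_auc = cv_auc,
                 scores = do.call(rbind, score_rows),
                 cfg = cfg),
            class = "EnsembleResult")
}

#' Vote-based rescue of untestable pairs
#'
#' All 10 classifiers vote on every untestable pair; a pair is called
#' positive iff strictly more than `vote_threshold` (default 5) of the 10
#' call it a true pair.
#'
#' @param ensemble an `EnsembleResult` from [trainEnsemble()].
#' @param X_untestable feature matrix with the training feature columns.
#' @return data.frame `pair_id, votes, positive`.
#' @export
rescueUntestable <- function(ensemble, X_untestable) {
  m1 <- ensemble$models[[1L]]
  train_cols <- rownames(m1$importance)
  if (!identical(colnames(X_untestable), train_cols))
    stop("feature columns do not match the training matrix")
  if (nrow(X_untestable) == 0L)
    return(data.frame(pair_id = character(), votes = integer(),
                      positive = logical()))
  calls <- vapply(ensemble$models, function(m)
    predict(m, X_untestable, type = "response") == "true",
    logical(nrow(X_untestable)))
  calls <- matrix(calls, nrow = nrow(X_untestable))
  votes <- rowSums(calls)
  data.frame(pair_id = rownames(X_untestable), votes = as.integer(votes),
             positive = votes > ensemble$cfg$vote_threshold)
}

#' Subpanel training and rescue experiment
#'
#' Draws `n_reps` random subpanels of `k` samples, relabels the candidate
#' pairs on each subpanel's counts, trains the ensemble on its testable
#' (true vs control) pairs and votes on its untestable pairs.  Mirrors
#' the small-sample design: k in 2, 5, 10, 20 with 10 resamplings.
#'
#' @param sim synthetic panel bundle from [simulatePanel()] (any list
#'   with `panel`, `counts`, `candidates` and feature matrix `X`).
#' @param k samples per subpanel (k <= panel size).
#' @param n_reps number of resampled subpanels (default 10).
#' @param cfg a [forestConfig()]; per-replicate seeds are derived from
#'   `cfg$seed`.
#' @param imb_cfg an [imbalanceConfig()].
#' @return list of per-replicate results: `samples`, labeled `pairs`,
#'   `mean_auc`, `rescue` (votes data.frame), `n_true`, `n_control`,
#'   `n_untestable`; `NA` AUC when a subpanel yields a single class.
#' @export
subsampleExperiment <- function(sim, k, n_reps = 10L, cfg = forestConfig(),
                                imb_cfg = imbalanceConfig()) {
  panel <- sim$panel
  if (k > nSamples(panel)) stop("k exceeds panel size")
  set.seed(cfg$seed)
  sub_samples <- lapply(seq_len(n_reps), function(i)
    sample(sampleIds(panel), k))
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    smp <- sub_samples[[i]]
    sub_panel <- subsetPanel(panel, smp)
    sub_counts <- sim$counts[sim$counts$sample %in% smp, , drop = FALSE]
    pairs <- labelPairs(sim$candidates, sub_panel, sub_counts, imb_cfg)
    parts <- partitionCases(pairs)
    testable <- rbind(parts$true, parts$control)
    res <- list(samples = smp, pairs = pairs,
                n_true = nrow(parts$true), n_control = nrow(parts$control),
                n_untestable = nrow(parts$untestable),
                mean_auc = NA_real_, rescue = NULL)
    if (nrow(parts$true) >= 2L && nrow(parts$control) >= 2L) {
      Xt <- sim$X[testable$pair_id, , drop = FALSE]
      rep_cfg <- cfg
      rep_cfg$seed <- cfg$seed + i
      ens <- trainEnsemble(Xt, testable$label == "true_pair", rep_cfg)
      res$mean_auc <- mean(ens$cv_auc, na.rm = TRUE)
      if (nrow(parts$untestable)) {
        Xu <- sim$X[parts$untestable$pair_id, , drop = FALSE]
        res$rescue <- rescueUntestable(ens, Xu)
      }
    }
    out[[i]] <- res
  }
  out
}

#' Validate rescued pairs against the full panel
#'
#' Of the positive rescue calls made on a subpanel, counts how many
#' become testable when the whole panel is used and how many of those are
#' confirmed allele-specific (true pairs) on the full panel.
#'
#' @param positive_ids pair ids called positive by [rescueUntestable()].
#' @param full_pairs labeled pair data.frame computed on the full panel.
#' @return list `n_predicted, n_tested, n_confirmed, percentage`
#'   (percentage NA when nothing becomes testable).
#' @export
validateRescue <- function(positive_ids, full_pairs) {
  lab <- full_pairs$label[match(positive_ids, full_pairs$pair_id)]
  tested <- !is.na(lab) & lab != "untestable"
  confirmed <- tested & lab == "true_pair"
  list(n_predicted = length(positive_ids),
       n_tested = sum(tested),
       n_confirmed = sum(confirmed),
       percentage = if (sum(tested)) 100 * sum(confirmed) / sum(tested)
                    else NA_real_)
}
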