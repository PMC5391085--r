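# Separable two-class feature matrix with planted bit rates.
plantedFeatures <- function(n, p_true = 0.5, rate_true = 0.9,
                            rate_false = 0.1, n_feat = 15, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, p_true) == 1
  X <- vapply(seq_len(n_feat), function(j)
    rbinom(n, 1, ifelse(y, rate_true, rate_false)), numeric(n))
  X <- matrix(X, nrow = n,
              dimnames = list(paste0("p", seq_len(n)),
                              paste0("f", seq_len(n_feat))))
  list(X = X, y = y)
}

test_that("AUC by midrank agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(61)
  for (i in 1:10) {
    sc <- round(runif(60), 2)   # rounding forces ties
    lab <- rbinom(60, 1, 0.4) == 1
    if (!any(lab) || all(lab)) next
    expect_equal(aucMidrank(sc, lab),
                 as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  expect_true(is.na(aucMidrank(runif(5), rep(TRUE, 5))))
})

test_that("case partition splits by label", {
  pairs <- data.frame(pair_id = paste0("p", 1:6),
                      label = c("true_pair", "control_pair", "untestable",
                                "true_pair", "control_pair",
                                "control_pair"))
  parts <- partitionCases(pairs)
  expect_equal(nrow(parts$true), 2L)
  expect_equal(nrow(parts$control), 3L)
  expect_equal(nrow(parts$untestable), 1L)
  empty <- partitionCases(pairs[0, ])
  expect_equal(vapply(empty, nrow, integer(1)),
               c(true = 0L, control = 0L, untestable = 0L))
})

test_that("cross-validation holds each pair out exactly twice", {
  pf <- plantedFeatures(80, seed = 2)
  cfg <- forestConfig(n_trees = 60, seed = 7)
  ens <- trainEnsemble(pf$X, pf$y, cfg)
  expect_length(ens$models, 10L)
  held <- table(ens$scores$pair_id)
  expect_true(all(held == 2L))
  # every (repetition, fold) trains on the complement of its held-out set
  expect_equal(sort(unique(ens$folds$fold)), 1:5)
  expect_equal(sort(unique(ens$folds$repetition)), 1:2)
  # stratification keeps both classes in each fold
  by_fold <- split(pf$y[match(ens$folds$pair_id, rownames(pf$X))],
                   paste(ens$folds$repetition, ens$folds$fold))
  expect_true(all(vapply(by_fold, function(v) any(v) && any(!v),
                         logical(1))))
  expect_error(trainEnsemble(pf$X, rep(TRUE, 80), cfg), "single class")
})

test_that("training is deterministic under the seed", {
  pf <- plantedFeatures(60, seed = 3)
  cfg <- forestConfig(n_trees = 40, seed = 11)
  a <- trainEnsemble(pf$X, pf$y, cfg)
  b <- trainEnsemble(pf$X, pf$y, cfg)
  expect_equal(a$cv_auc, b$cv_auc)
  expect_equal(a$scores$score, b$scores$score)
})

test_that("planted signal is separable and permuted labels are not", {
  pf <- plantedFeatures(150, seed = 5)
  cfg <- forestConfig(n_trees = 150, seed = 13)
  ens <- trainEnsemble(pf$X, pf$y, cfg)
  expect_gt(mean(ens$cv_auc), 0.9)

  set.seed(17)
  y_perm <- sample(pf$y)
  null_ens <- trainEnsemble(pf$X, y_perm, cfg)
  expect_gt(mean(null_ens$cv_auc), 0.3)
  expect_lt(mean(null_ens$cv_auc), 0.7)
})

test_that("rescue votes use the strict more-than-5-of-10 rule", {
  feats <- paste0("f", 1:4)
  X <- matrix(0, 3, 4, dimnames = list(paste0("u", 1:3), feats))
  six <- constantEnsemble(6, 4, feats)
  five <- constantEnsemble(5, 5, feats)
  ten <- constantEnsemble(10, 0, feats)
  expect_true(all(rescueUntestable(six, X)$positive))    # 6 votes
  expect_equal(rescueUntestable(six, X)$votes, rep(6L, 3))
  expect_false(any(rescueUntestable(five, X)$positive))  # exactly 5
  expect_true(all(rescueUntestable(ten, X)$positive))    # 10 votes

  # vote monotonicity: adding a positive voter never drops a positive
  seven <- constantEnsemble(7, 3, feats)
  expect_true(all(rescueUntestable(seven, X)$positive >=
                    rescueUntestable(six, X)$positive))

  bad <- X; colnames(bad) <- paste0("g", 1:4)
  expect_error(rescueUntestable(six, bad), "columns")
})

test_that("real-ensemble votes on class-pure rows are unanimous", {
  pf <- plantedFeatures(100, seed = 23)
  ens <- trainEnsemble(pf$X, pf$y, forestConfig(n_trees = 80, seed = 3))
  proto_true <- matrix(1, 2, ncol(pf$X),
                       dimnames = list(c("a", "b"), colnames(pf$X)))
  proto_false <- matrix(0, 2, ncol(pf$X),
                        dimnames = list(c("c", "d"), colnames(pf$X)))
  expect_true(all(rescueUntestable(ens, proto_true)$positive))
  expect_false(any(rescueUntestable(ens, proto_false)$positive))
})

test_that("subpanel experiments are reproducible and validated", {
  sim <- simulatePanel(simConfig(n_samples = 30, n_tags = 6, seed = 67))
  cfg <- forestConfig(n_trees = 60, seed = 29)
  reps <- subsampleExperiment(sim, k = 10, n_reps = 3, cfg = cfg)
  reps2 <- subsampleExperiment(sim, k = 10, n_reps = 3, cfg = cfg)
  expect_equal(lapply(reps, `[[`, "samples"),
               lapply(reps2, `[[`, "samples"))
  expect_equal(vapply(reps, `[[`, numeric(1), "mean_auc"),
               vapply(reps2, `[[`, numeric(1), "mean_auc"))
  expect_error(subsampleExperiment(sim, k = 31), "exceeds")

  full <- labelPairs(sim$candidates, sim$panel, sim$counts)
  val <- validateRescue(character(), full)
  expect_equal(val$n_predicted, 0L)
  expect_true(is.na(val$percentage))

  # constructed upper bound: validating known true pairs confirms 100%
  true_ids <- full$pair_id[full$label == "true_pair"]
  val2 <- validateRescue(true_ids, full)
  expect_equal(val2$percentage, 100)
  expect_equal(val2$n_tested, length(true_ids))
})
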