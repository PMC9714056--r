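test_that("confusion counting matches hand tallies", {
  truth <- rep(c("amyloid", "non-amyloid"), c(6, 4))
  cm <- confusion(truth, truth)
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]),
               c(TP = 6L, TN = 4L, FP = 0L, FN = 0L))
  inv <- ifelse(truth == "amyloid", "non-amyloid", "amyloid")
  cm2 <- confusion(truth, inv)
  expect_equal(cm2$TP + cm2$TN, 0L)
  withr::with_seed(55, {
    yt <- sample(c("amyloid", "non-amyloid"), 50, replace = TRUE)
    yp <- sample(c("amyloid", "non-amyloid"), 50, replace = TRUE)
  })
  cm3 <- confusion(yt, yp)
  expect_equal(cm3$TP, sum(yt == "amyloid" & yp == "amyloid"))
  expect_equal(cm3$FP, sum(yt == "non-amyloid" & yp == "amyloid"))
  expect_error(confusion(yt, yp[-1]), "equal length")
  expect_error(confusion(c("a", "b"), c("a", "b")), "classes")
})

test_that("metric identities hold over random confusion matrices", {
  withr::with_seed(91, {
    for (i in 1:50) {
      counts <- rmultinom(1, size = sample(10:500, 1), prob = runif(4))[, 1]
      if (sum(counts) == 0) next
      cm <- confusion_counts(TP = counts[1], TN = counts[2],
                             FP = counts[3], FN = counts[4])
      r <- metrics(cm)
      expect_equal(r$ACC + r$error_rate, 1, tolerance = 1e-12)
      expect_equal(r$Q, (r$SN + r$SP) / 2, tolerance = 1e-12)
      expect_gte(r$MCC, -1)
      expect_lte(r$MCC, 1)
      # symmetry under simultaneous swap TP<->TN, FP<->FN
      r_swap <- metrics(confusion_counts(TP = counts[2], TN = counts[1],
                                         FP = counts[4], FN = counts[3]))
      expect_equal(r$MCC, r_swap$MCC, tolerance = 1e-12)
      # negation under prediction inversion (when defined)
      r_inv <- metrics(confusion_counts(TP = counts[4], TN = counts[3],
                                        FP = counts[2], FN = counts[1]))
      cn <- as.numeric(counts)
      denom <- (cn[1] + cn[3]) * (cn[1] + cn[4]) *
        (cn[2] + cn[3]) * (cn[2] + cn[4])
      if (denom > 0) expect_equal(r$MCC, -r_inv$MCC, tolerance = 1e-12)
    }
  })
})

test_that("zero-denominator conventions keep reports total", {
  r <- metrics(confusion_counts(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_equal(r$SN, 0)  # no positives in truth
  expect_equal(r$MCC, 0)
  expect_equal(r$ACC, 1)
  expect_equal(metrics(confusion_counts(0, 0, 3, 4))$SP, 0)
  expect_error(metrics(confusion_counts(0, 0, 0, 0)), "empty")
})

test_that("a perfect matrix scores perfectly", {
  r <- metrics(confusion_counts(TP = 7, TN = 9, FP = 0, FN = 0))
  expect_equal(r$ACC, 1)
  expect_equal(r$MCC, 1)
  expect_equal(r$error_rate, 0)
})

test_that("ROC/AUC matches trivial cases and brute-force pair counting", {
  lab <- rep(c("amyloid", "non-amyloid"), each = 5)
  perfect <- c(6:10, 1:5)
  expect_equal(roc_auc(perfect, lab)$auc, 1)
  expect_equal(roc_auc(rep(1, 10), lab)$auc, 0.5)
  for (seed in 1:8) {
    withr::with_seed(seed, {
      y <- sample(c("amyloid", "non-amyloid"), 20, replace = TRUE,
                  prob = c(0.5, 0.5))
      if (length(unique(y)) < 2) y[1:2] <- c("amyloid", "non-amyloid")
      s <- sample(round(rnorm(20), 1))  # includes ties
    })
    got <- roc_auc(s, y)
    expect_equal(got$auc, oracle_auc_pairs(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(-s, y)$auc, 1 - got$auc, tolerance = 1e-12)
    expect_true(all(got$roc$fpr >= 0 & got$roc$fpr <= 1))
  }
  expect_error(roc_auc(1:5, rep("amyloid", 5)), "one class")
})

test_that("AUC agrees with an established ROC implementation", {
  withr::with_seed(123, {
    y <- rep(c("amyloid", "non-amyloid"), each = 25)
    s <- c(rnorm(25, 1), rnorm(25, 0))
  })
  ours <- roc_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(y, levels = c("non-amyloid", "amyloid")),
    predictor = s, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("stratified k-fold validates every record once and pools counts", {
  fm <- fixture_train_fm()
  sub <- feature_matrix(fm$x[c(1:40, 101:140), ],
                        fm$ids[c(1:40, 101:140)],
                        fm$labels[c(1:40, 101:140)])
  cfg <- train_config(algorithm = "gentleboost", k = 5, max_split = 2,
                      num_learners = 10, learning_rate = 1, seed = 2)
  cv <- kfold_cv(sub, config = cfg)
  expect_equal(cv$k, 5L)
  expect_equal(as.integer(table(cv$assignment)), rep(16L, 5))
  # stratification: per-fold class ratio within one record of global
  for (f in 1:5) {
    in_fold <- sub$labels[cv$assignment == f]
    expect_lte(abs(sum(in_fold == "amyloid") - 8), 1)
  }
  # conservation: pooled counts equal summed per-fold counts
  summed <- Reduce(`+`, lapply(cv$fold_reports, function(r) {
    unlist(r$counts[c("TP", "TN", "FP", "FN")])
  }))
  expect_equal(unlist(cv$pooled$counts[c("TP", "TN", "FP", "FN")]), summed)
  # separable planted rule: near-perfect pooled CV accuracy
  expect_gte(cv$pooled$ACC, 0.85)
  expect_error(kfold_cv(sub, k = 50, config = cfg), "at least k")
})

test_that("robustness averages are arithmetic means of per-pair metrics", {
  ds <- gen_labelled_fixture(fixture_spec(16, seed = 41))
  sp <- split_spec(train_per_class = 10, test_per_class = 3, seed = 1)
  pair <- make_robustness_pairs(ds, n_pairs = 1, spec = sp, seed = 5)[[1]]
  pairs3 <- list(pair, pair, pair)
  pairs3[[2]]$index <- 2L
  pairs3[[3]]$index <- 3L
  cfg <- train_config(algorithm = "gentleboost", k = 2, max_split = 2,
                      num_learners = 5, learning_rate = 1)
  res <- robustness_run(pairs3, train = cfg)
  expect_equal(nrow(res$per_pair), 3L)
  # identical pairs: averages equal the single-pair values
  expect_equal(unname(res$averages["test_ACC"]),
               100 * res$per_pair$test_ACC[1], tolerance = 1e-12)
  expect_equal(unname(res$averages),
               unname(100 * colMeans(res$per_pair[, -1])), tolerance = 1e-12)
  # fixed seed end-to-end reproduces the result
  pairs_b <- make_robustness_pairs(ds, n_pairs = 2, spec = sp, seed = 5)
  res1 <- robustness_run(pairs_b, train = cfg)
  res2 <- robustness_run(make_robustness_pairs(ds, 2, sp, seed = 5),
                         train = cfg)
  expect_identical(res1$per_pair, res2$per_pair)
})

test_that("metric reports serialize with the documented keys", {
  r <- metrics(confusion_counts(TP = 33, TN = 21, FP = 12, FN = 0),
               auc = 0.83)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(r, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$ACC, r$ACC, tolerance = 1e-12)
  expect_equal(back$counts$FP, 12)
  expect_equal(back$AUC, 0.83)
})
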