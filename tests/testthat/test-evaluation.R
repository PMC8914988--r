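test_that("min-max normalization fits on train only, clips and guards constants", {
  tr <- matrix(c(0, 5, 10), 3, 1, dimnames = list(NULL, "f"))
  nm <- minmaxNormalize(tr)
  expect_equal(as.numeric(nm$train), c(0, 0.5, 1))

  const <- matrix(4, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(minmaxNormalize(const)$train), matrix(0, 3, 2))

  te <- matrix(c(-5, 20), 2, 1, dimnames = list(NULL, "f"))
  out <- minmaxNormalize(tr, te)$other
  # direct formula with clipping oracle
  expect_equal(as.numeric(out), pmin(pmax((c(-5, 20) - 0) / 10, 0), 1))

  bad <- matrix(0, 2, 1, dimnames = list(NULL, "g"))
  expect_error(minmaxNormalize(tr, bad), "columns")
})

test_that("macro metrics reproduce hand-computed values", {
  perfect <- diag(c(3, 4, 5))
  expect_equal(unname(macroMetrics(perfect)), rep(1, 4))

  cm <- matrix(c(2, 0, 1, 3), 2, 2)   # rows true: (2,1) / (0,3)
  m <- macroMetrics(cm)
  expect_equal(unname(m["accuracy"]), 5 / 6)
  expect_equal(unname(m["macroP"]), (1 + 0.75) / 2)
  expect_equal(unname(m["macroR"]), (2 / 3 + 1) / 2)
  expect_equal(unname(m["macroF1"]),
               2 * 0.875 * (5 / 6) / (0.875 + 5 / 6))

  expect_error(macroMetrics(matrix(0, 2, 2)), "empty")
  expect_error(macroMetrics(matrix(1, 2, 3)), "square")
})

test_that("uniform random predictions land at chance accuracy", {
  set.seed(99)
  m <- 6; n <- 30000
  truth <- sample(m, n, replace = TRUE)
  pred <- sample(m, n, replace = TRUE)
  cm <- table(truth, pred)
  expect_equal(unname(macroMetrics(cm)["accuracy"]), 1 / m, tolerance = 0.05)
})

test_that("k-fold folds are stratified, exhaustive and seed-stable", {
  ds <- generateDataset(syntheticConfig(nSubjects = 2, nRounds = 5, seed = 41))
  ss <- preprocessDataset(ds$frames, ds$anthropometrics)
  se <- extractFeatures(ss)
  ev <- runKFold(se, k = 5, seed = 7)
  expect_s4_class(ev, "SleeveEval")
  # every sample tested exactly once
  expect_equal(sum(confusionMatrix(ev)), length(ss))
  expect_equal(sum(perFoldMetrics(ev)$n), length(ss))
  # stratification: 10 instances per class over 5 folds = 2 per fold
  expect_true(all(perFoldMetrics(ev)$n == length(ss) / 5))
  # determinism
  ev2 <- runKFold(se, k = 5, seed = 7)
  expect_equal(evalMetrics(ev), evalMetrics(ev2))
  expect_equal(confusionMatrix(ev), confusionMatrix(ev2))
  expect_error(runKFold(se, k = 1), "k must be")
})

test_that("the macro-F1 identity holds exactly on every emitted result", {
  ds <- generateDataset(syntheticConfig(nSubjects = 3, nRounds = 2, seed = 43,
                                        activities = paste0("act0", 1:6)))
  ss <- preprocessDataset(ds$frames, ds$anthropometrics)
  se <- extractFeatures(ss)
  for (cl in c("svm", "knn", "dt")) {
    for (scheme in c("kfold", "loso")) {
      ev <- if (scheme == "kfold")
        runKFold(se, config = classifierConfig(cl), k = 3, seed = 2)
      else runLOSO(se, config = classifierConfig(cl))
      m <- evalMetrics(ev)
      expect_identical(unname(m["macroF1"]),
                       2 * m[["macroP"]] * m[["macroR"]] /
                         (m[["macroP"]] + m[["macroR"]]))
      expect_true(all(m >= 0 & m <= 1))
    }
  }
})

test_that("leave-one-subject-out builds one fold per subject", {
  ds <- generateDataset(syntheticConfig(nSubjects = 2, nRounds = 3, seed = 44,
                                        activities = paste0("act0", 1:5)))
  ss <- preprocessDataset(ds$frames, ds$anthropometrics)
  se <- extractFeatures(ss)
  ev <- runLOSO(se)
  expect_equal(nrow(perFoldMetrics(ev)), 2L)
  expect_equal(sum(confusionMatrix(ev)), length(ss))

  one <- se[, as.data.frame(SummarizedExperiment::colData(se))$subject_id == "S01"]
  expect_error(runLOSO(one), "2 subjects")
})

test_that("all six classifier configurations train and predict", {
  ds <- generateDataset(syntheticConfig(nSubjects = 2, nRounds = 3, seed = 45,
                                        activities = paste0("act0", 1:4)))
  ss <- preprocessDataset(ds$frames, ds$anthropometrics)
  se <- extractFeatures(ss)
  for (cl in c("svm", "knn", "lr", "rf", "dt", "nb")) {
    ev <- runKFold(se, config = classifierConfig(cl), k = 3, seed = 1)
    expect_true(is.finite(evalMetrics(ev)["accuracy"]))
  }
  expect_error(classifierConfig("boost"), "arg")
})

test_that("the ablation grid reports eight accuracies per classifier", {
  ds <- generateDataset(syntheticConfig(nSubjects = 3, nRounds = 2, seed = 46,
                                        activities = paste0("act0", 1:5)))
  tab <- runAblation(ds$frames, ds$anthropometrics,
                     classifiers = c("svm", "dt"), k = 3, seed = 1)
  expect_equal(nrow(tab), 2L)
  accCols <- setdiff(colnames(tab), "classifier")
  expect_length(accCols, 8L)
  expect_true(all(grepl("^(kfold|loso)\\.", accCols)))
  expect_true(all(unlist(tab[accCols]) >= 0 & unlist(tab[accCols]) <= 1))
})
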