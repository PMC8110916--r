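# small labeled FeatureSet with an informative block of features
makeToyFS <- function(n = 20, seed = 1, leak = FALSE) {
  set.seed(seed)
  reg <- featureRegistry()
  y <- rep(c("AD", "non-AD"), each = n / 2)
  mat <- matrix(rnorm(509 * n, sd = 0.5), 509, n,
                dimnames = list(reg$name, sprintf("T%02d", 1:n)))
  mat[1:5, y == "AD"] <- mat[1:5, y == "AD"] + 2
  if (leak) mat[6, ] <- ifelse(y == "AD", 1, 0)
  FeatureSet(mat, data.frame(subject_id = sprintf("T%02d", 1:n), age = 70,
                             sex = "F", label = y,
                             mmse = ifelse(y == "AD", 18, 28) +
                               round(rnorm(n))))
}

test_that("LOSO plans give one singleton test fold per subject", {
  ids <- sprintf("T%02d", 1:10)
  plan <- cvPlan(ids, "loso")
  expect_length(plan$folds, 10)
  expect_true(all(lengths(plan$folds) == 1))
  expect_setequal(unlist(plan$folds), ids)
})

test_that("stratified k-fold plans partition subjects with both classes
           in every training part", {
  ids <- sprintf("T%02d", 1:20)
  labels <- rep(c("AD", "non-AD"), each = 10)
  plan <- cvPlan(ids, "kfold", k = 5, seed = 3, labels = labels)
  expect_setequal(unlist(plan$folds), ids)
  expect_equal(sum(lengths(plan$folds)), 20)
  for (f in plan$folds) {
    trainLabels <- labels[!ids %in% f]
    expect_equal(length(unique(trainLabels)), 2)
  }
  expect_error(cvPlan(ids, "kfold", k = 25), "more folds")
})

test_that("an oracle predictor reaches perfect pooled metrics", {
  fs <- makeToyFS(leak = TRUE)
  plan <- cvPlan(sprintf("T%02d", 1:20), "loso")
  rep_ <- runCv(plan, modelSpec("svm_rbf", k = 3), fs, seeds = 1)
  expect_equal(unname(rep_$mean["accuracy"]), 1)
  expect_equal(unname(rep_$mean["auroc"]), 1)
})

test_that("k-fold with k = n reproduces LOSO exactly for deterministic
           models", {
  fs <- makeToyFS()
  ids <- sprintf("T%02d", 1:20)
  loso <- runCv(cvPlan(ids, "loso"), modelSpec("svm_rbf", k = 5), fs,
                seeds = 1)
  kn <- runCv(cvPlan(ids, "kfold", k = 20, seed = 9,
                     labels = as.character(featureLabels(fs))),
              modelSpec("svm_rbf", k = 5), fs, seeds = 1)
  expect_equal(loso$mean, kn$mean, tolerance = 1e-12)
  # seed-averaged metrics of a deterministic model equal one run
  three <- runCv(cvPlan(ids, "loso"), modelSpec("svm_rbf", k = 5), fs,
                 seeds = 1:3)
  expect_equal(three$mean, loso$mean, tolerance = 1e-12)
})

test_that("poisoning held-out rows does not change per-fold selection", {
  fs <- makeToyFS()
  X <- featureMatrix(fs)
  y <- as.character(featureLabels(fs))
  testIds <- rownames(X)[1:4]
  trainIdx <- !rownames(X) %in% testIds
  selClean <- selectTopKAnova(X[trainIdx, ], y[trainIdx], 10)
  Xpois <- X
  Xpois[!trainIdx, ] <- 1e6
  selPois <- selectTopKAnova(Xpois[trainIdx, ], y[trainIdx], 10)
  expect_identical(as.integer(selClean), as.integer(selPois))

  mClean <- fitClassifier(modelSpec("svm_rbf", k = 10), X[trainIdx, ],
                          y[trainIdx])
  mPois <- fitClassifier(modelSpec("svm_rbf", k = 10), Xpois[trainIdx, ],
                         y[trainIdx])
  expect_identical(mClean@selection$indices, mPois@selection$indices)
  expect_identical(predict(mClean, X[!trainIdx, ]),
                   predict(mPois, X[!trainIdx, ]))
})

test_that("majority vote follows the modal label and the odd-count rule", {
  fs <- makeToyFS()
  X <- featureMatrix(fs)
  y <- as.character(featureLabels(fs))
  models <- lapply(1:3, function(s)
    fitClassifier(modelSpec("rf", k = 5, seed = s), X, y))
  mv <- majorityVotePredict(models, X)
  votes <- vapply(models, function(m) predict(m, X)$label,
                  character(nrow(X)))
  manual <- apply(votes, 1, function(v) names(which.max(table(v))))
  expect_equal(mv, manual)
  expect_error(majorityVotePredict(models[1:2], X), "odd")

  # identical models -> vote equals the single model's prediction
  same <- lapply(1:3, function(s)
    fitClassifier(modelSpec("svm_rbf", k = 5), X, y))
  expect_equal(majorityVotePredict(same, X), predict(same[[1]], X)$label)
})

test_that("classification metrics match the confusion-table arithmetic", {
  perfect <- classificationMetrics(c("AD", "non-AD"), c("AD", "non-AD"))
  expect_true(all(perfect[c("accuracy", "precision", "recall",
                            "specificity", "f1")] == 1))

  allAD <- classificationMetrics(rep(c("AD", "non-AD"), each = 10),
                                 rep("AD", 20))
  expect_equal(unname(allAD["accuracy"]), 0.5)
  expect_equal(unname(allAD["recall"]), 1)
  expect_equal(unname(allAD["specificity"]), 0)

  # TP=20 FP=4 TN=20 FN=4
  yt <- rep(c("AD", "non-AD"), each = 24)
  yp <- c(rep("AD", 20), rep("non-AD", 4), rep("AD", 4), rep("non-AD", 20))
  m <- classificationMetrics(yt, yp)
  expect_equal(unname(m["accuracy"]), 40 / 48)
  p <- 20 / 24
  expect_equal(unname(m["f1"]), 2 * p * p / (p + p))

  # AUROC rank statistic against pROC
  set.seed(8)
  yt2 <- sample(rep(c("AD", "non-AD"), each = 30))
  sc <- rnorm(60) + (yt2 == "AD")
  m2 <- classificationMetrics(yt2, ifelse(sc > 0.5, "AD", "non-AD"), sc)
  ref <- as.numeric(pROC::auc(pROC::roc(response = yt2, predictor = sc,
                                        levels = c("non-AD", "AD"),
                                        quiet = TRUE)))
  expect_equal(unname(m2["auroc"]), ref, tolerance = 1e-12)

  one <- classificationMetrics(rep("AD", 5), rep("AD", 5))
  expect_true(is.na(one["specificity"]))
})

test_that("regression metrics follow their formulas", {
  expect_equal(unname(regressionMetrics(1:5, 1:5)), c(0, 0))
  expect_equal(unname(regressionMetrics(1:5, 1:5 + 2)), c(2, 2))
  set.seed(9)
  a <- rnorm(50); b <- rnorm(50)
  m <- regressionMetrics(a, b)
  expect_equal(unname(m["rmse"]), sqrt(mean((a - b)^2)))
  expect_equal(unname(m["mae"]), mean(abs(a - b)))
})

test_that("Kruskal-Wallis comparison matches the rank-sum oracle", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  r <- compareModelsKW(g)
  expect_equal(r$H, oracleKW(g), tolerance = 1e-12)

  same <- compareModelsKW(list(a = c(0.8, 0.8, 0.8), b = c(0.8, 0.8, 0.8)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  set.seed(14)
  for (i in 1:20) {
    gs <- lapply(1:sample(2:4, 1), function(j)
      round(runif(sample(3:8, 1)), 2))
    names(gs) <- paste0("m", seq_along(gs))
    expect_equal(compareModelsKW(gs)$H, oracleKW(gs), tolerance = 1e-10)
  }
})

test_that("metrics are invariant to subject permutation", {
  set.seed(15)
  yt <- sample(rep(c("AD", "non-AD"), 15))
  yp <- sample(rep(c("AD", "non-AD"), 15))
  sc <- rnorm(30)
  p <- sample(30)
  expect_equal(classificationMetrics(yt, yp, sc),
               classificationMetrics(yt[p], yp[p], sc[p]))
})
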