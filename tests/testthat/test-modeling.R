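test_that("ANOVA-F selection recovers planted mean shifts", {
  # k = feature count -> identity
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c("AD", "non-AD"), each = 10)
  expect_equal(as.integer(selectTopKAnova(X, y, 2)), 1:2)

  hits <- 0
  for (r in 1:100) {
    set.seed(r)
    X <- matrix(rnorm(200 * 20), 200, 20)
    planted <- c(3, 9, 17)
    X[1:100, planted] <- X[1:100, planted] + 2
    y <- rep(c("AD", "non-AD"), each = 100)
    sel <- selectTopKAnova(X, y, 3)
    if (setequal(sel, planted)) hits <- hits + 1
  }
  expect_gte(hits, 95)

  # constant feature has F = 0 and is never selected over a shifted one
  X2 <- cbind(const = rep(1, 20), shifted = c(rnorm(10, 2), rnorm(10)))
  expect_equal(as.integer(selectTopKAnova(X2, y[seq(1, 200, 10)], 1)), 2L)
  expect_equal(unname(attr(selectTopKAnova(X2, y[seq(1, 200, 10)], 1),
                           "scores")[1]), 0)
})

test_that("correlation-F selection is sign-invariant and recovers planted
           linear features", {
  set.seed(2)
  mmse <- runif(50, 0, 30)
  X <- cbind(mmse, -mmse, matrix(rnorm(50 * 5), 50))
  s <- attr(selectTopKMmseCorr(X, mmse, 2), "scores")
  expect_equal(s[1], s[2], tolerance = 1e-6)
  expect_true(all(s[1:2] > max(s[3:7])))

  hits <- 0
  for (r in 1:100) {
    set.seed(r + 500)
    mm <- runif(60, 0, 30)
    X <- matrix(rnorm(60 * 30), 60, 30)
    X[, 11] <- mm + rnorm(60, sd = 3)
    if (selectTopKMmseCorr(X, mm, 1)[1] == 11) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("selection ranks agree with stats::aov / cor.test", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c("AD", "non-AD"), each = 20)
  f <- attr(selectTopKAnova(X, y, 1), "scores")
  fRef <- vapply(1:6, function(j)
    summary(aov(X[, j] ~ factor(y)))[[1]]$`F value`[1], 1)
  expect_equal(f, fRef, tolerance = 1e-8)

  mm <- rnorm(40)
  s <- attr(selectTopKMmseCorr(X, mm, 1), "scores")
  sRef <- vapply(1:6, function(j) {
    r <- cor(X[, j], mm); r^2 / (1 - r^2) * (40 - 2)
  }, 1)
  expect_equal(s, sRef, tolerance = 1e-8)
})

test_that("svm with fixed hyperparameters separates separable data", {
  set.seed(4)
  X <- rbind(matrix(rnorm(100, 5), 50, 2), matrix(rnorm(100, -5), 50, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c("AD", "non-AD"), each = 50)
  m <- fitClassifier(modelSpec("svm_rbf", k = 2), X, y)
  pr <- predict(m, X)
  expect_equal(mean(pr$label == y), 1)
  expect_true(all(pr$score[y == "AD"] > pr$score[y == "non-AD"]))
  expect_error(fitClassifier(modelSpec("svm_rbf", k = 2), X,
                             rep("AD", 100)), "one class")
})

test_that("all classifier families stay near chance on permuted labels", {
  set.seed(10)
  X <- matrix(rnorm(100 * 20), 100, 20)
  colnames(X) <- sprintf("f%02d", 1:20)
  y <- sample(rep(c("AD", "non-AD"), each = 50))
  plan <- cvPlan(as.character(1:100), "kfold", k = 10, seed = 2,
                 labels = y)
  rownames(X) <- as.character(1:100)
  fs <- FeatureSet(matrix(0, 509, 100,
                          dimnames = list(featureRegistry()$name,
                                          as.character(1:100))),
                   data.frame(subject_id = as.character(1:100), age = 70,
                              sex = "F", label = y, mmse = 20))
  # overwrite the first 20 rows with the noise features
  SummarizedExperiment::assay(fs, "features")[1:20, ] <- t(X)
  for (fam in c("svm_rbf", "rf", "nb", "nn")) {
    rep_ <- runCv(plan, modelSpec(fam, k = 5), fs, seeds = 1)
    expect_gte(rep_$mean["accuracy"], 0.35)
    expect_lte(rep_$mean["accuracy"], 0.65)
  }
})

test_that("rf and nn are seed-reproducible; svm and nb ignore the seed", {
  set.seed(20)
  X <- matrix(rnorm(60 * 8), 60, 8)
  colnames(X) <- sprintf("f%d", 1:8)
  X[, 1] <- X[, 1] + rep(c(1.5, 0), each = 30)
  y <- rep(c("AD", "non-AD"), each = 30)
  for (fam in c("rf", "nn")) {
    a <- predict(fitClassifier(modelSpec(fam, k = 4, seed = 7), X, y), X)
    b <- predict(fitClassifier(modelSpec(fam, k = 4, seed = 7), X, y), X)
    expect_identical(a, b)
  }
  s1 <- predict(fitClassifier(modelSpec("svm_rbf", k = 4, seed = 1), X, y),
                X)
  s2 <- predict(fitClassifier(modelSpec("svm_rbf", k = 4, seed = 99), X,
                              y), X)
  expect_identical(s1, s2)
})

test_that("ridge limits: alpha = 0 equals least squares, alpha -> Inf
           shrinks to zero", {
  set.seed(30)
  X <- matrix(rnorm(80 * 5), 80, 5)
  colnames(X) <- sprintf("f%d", 1:5)
  mmse <- 15 + 2 * X[, 1] - 3 * X[, 4] + rnorm(80, sd = 0.5)
  r0 <- fitRegressor(modelSpec("ridge", k = 5, alpha = 0), X, mmse)
  lr <- fitRegressor(modelSpec("linreg", k = 5), X, mmse)
  expect_equal(r0@fit$beta, lr@fit$beta, tolerance = 1e-8)

  # cross-check against MASS::lm.ridge at a positive penalty (lm.ridge
  # standardizes with population rather than sample scale, hence the
  # loose tolerance)
  alpha <- 7
  rr <- fitRegressor(modelSpec("ridge", k = 5, alpha = alpha), X, mmse)
  Z <- scale(X[, rr@selection$indices])
  mr <- MASS::lm.ridge(mmse ~ Z, lambda = alpha)
  expect_equal(unname(rr@fit$beta), unname(coef(mr)[-1]),
               tolerance = 0.01)

  rInf <- fitRegressor(modelSpec("ridge", k = 5, alpha = 1e9), X, mmse)
  expect_lt(max(abs(rInf@fit$beta)), 1e-5)
})

test_that("MMSE predictions are clipped to [0, 30] and clipping never
           hurts", {
  set.seed(31)
  X <- matrix(rnorm(40 * 3), 40, 3)
  colnames(X) <- c("a", "b", "c")
  mmse <- pmin(pmax(20 + 8 * X[, 1], 0), 30)
  m <- fitRegressor(modelSpec("linreg", k = 3), X, mmse)
  Xnew <- matrix(c(5, 0, 0, -5, 0, 0), 2, 3, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c")))
  p <- predictMMSE(m, Xnew)
  expect_true(all(p >= 0 & p <= 30))
  raw <- predict(m, X)
  expect_lte(mean((pmin(pmax(raw, 0), 30) - mmse)^2),
             mean((raw - mmse)^2))
})

test_that("naive Bayes uses balanced priors and floored variances", {
  set.seed(33)
  X <- matrix(rnorm(30 * 4), 30, 4)
  colnames(X) <- sprintf("f%d", 1:4)
  y <- rep(c("AD", "non-AD"), c(10, 20))   # imbalanced on purpose
  m <- fitClassifier(modelSpec("nb", k = 4), X, y)
  pri <- m@fit$apriori / sum(m@fit$apriori)
  expect_equal(unname(pri), c(0.5, 0.5))
  expect_true(all(vapply(m@fit$tables, function(tb) all(tb[, 2] > 0),
                         TRUE)))
})

test_that("fitted models round-trip with a registry guard", {
  set.seed(40)
  X <- matrix(rnorm(40 * 4), 40, 4)
  colnames(X) <- sprintf("f%d", 1:4)
  y <- rep(c("AD", "non-AD"), each = 20)
  m <- fitClassifier(modelSpec("svm_rbf", k = 2), X, y)
  path <- tempfile(fileext = ".rds")
  saveFittedModel(m, path)
  m2 <- loadFittedModel(path)
  expect_identical(predict(m2, X), predict(m, X))

  bad <- readRDS(path)
  bad$registry_hash <- 0L
  saveRDS(bad, path)
  expect_error(loadFittedModel(path), "different feature registry")
})
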