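# Evaluation protocol: LOSO and stratified k-fold CV, three-seed
# averaging, majority-vote test predictions, metrics and the
# Kruskal-Wallis model comparison.

#' Build a cross-validation plan
#'
#' LOSO assigns each subject its own test fold; k-fold shuffles subjects
#' (stratified by label when labels are given) into k folds. Folds always
#' partition the subjects. If a k-fold draw leaves any fold single-class
#' in its training part, the draw is repeated; an impossible configuration
#' errors.
#'
#' @param subjects character vector of subject ids.
#' @param scheme "loso" or "kfold".
#' @param k folds for kfold (default 10).
#' @param seed shuffling seed.
#' @param labels optional labels for stratification.
#' @return list of class `CVPlan` with `folds` (test-subject list),
#'   `scheme`, `seed`.
#' @export
cvPlan <- function(subjects, scheme = c("loso", "kfold"), k = 10L,
                   seed = 1L, labels = NULL) {
  scheme <- match.arg(scheme)
  n <- length(subjects)
  if (scheme == "loso") {
    folds <- as.list(subjects)
  } else {
    if (k > n) stop("more folds than subjects")
    draw <- function(s) {
      set.seed(s)
      fold <- integer(n)
      if (is.null(labels)) {
        fold <- sample(rep(seq_len(k), length.out = n))
      } else {
        # deal shuffled subjects class by class round-robin over folds so
        # folds stay label-balanced and all k folds are used
        order_ <- unlist(lapply(unique(labels), function(cl)
          sample(which(labels == cl))))
        fold[order_] <- rep(seq_len(k), length.out = n)
      }
      fold
    }
    fold <- draw(seed)
    if (!is.null(labels)) {
      tries <- 0
      while (any(vapply(seq_len(k), function(f)
        length(unique(labels[fold != f])) < 2, TRUE))) {
        tries <- tries + 1
        if (tries > 25) stop("cannot build folds with both classes in train")
        fold <- draw(seed + 1000L * tries)
      }
    }
    folds <- lapply(seq_len(k), function(f) subjects[fold == f])
    folds <- folds[lengths(folds) > 0]
  }
  structure(list(folds = folds, scheme = scheme, seed = seed,
                 subjects = subjects),
            class = "CVPlan")
}

#' Classification metrics with AD as the positive class
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 computed
#' from the confusion table with positive class "AD", plus AUROC from
#' continuous scores by the rank statistic (Mann-Whitney). With a
#' single-class truth vector, undefined rates are returned as NA.
#'
#' @param y_true,y_pred label vectors ("AD"/"non-AD").
#' @param scores optional continuous scores, larger = more AD-like; when
#'   missing, the predicted label is used as the score.
#' @return named numeric vector: accuracy, precision, recall,
#'   specificity, f1, auroc.
#' @export
classificationMetrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  tp <- sum(y_true == "AD" & y_pred == "AD")
  fp <- sum(y_true != "AD" & y_pred == "AD")
  tn <- sum(y_true != "AD" & y_pred != "AD")
  fn <- sum(y_true == "AD" & y_pred != "AD")
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  if (is.null(scores)) scores <- as.numeric(y_pred == "AD")
  pos <- scores[y_true == "AD"]; neg <- scores[y_true != "AD"]
  auroc <- if (length(pos) && length(neg)) {
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  } else NA_real_
  c(accuracy = acc, precision = prec, recall = rec, specificity = spec,
    f1 = f1, auroc = auroc)
}

#' Regression metrics
#'
#' @param y_true,y_pred numeric vectors.
#' @return named vector with `rmse` and `mae`.
#' @export
regressionMetrics <- function(y_true, y_pred) {
  c(rmse = sqrt(mean((y_true - y_pred)^2)),
    mae = mean(abs(y_true - y_pred)))
}

#' Run the cross-validated protocol
#'
#' For every seed: selection and model are refit inside each fold's
#' training subjects only (z-scoring likewise), held-out subjects are
#' predicted, predictions are pooled over folds and metrics computed.
#' Reports per-seed metrics and their mean across seeds.
#'
#' @param plan a [cvPlan()].
#' @param spec a [ModelSpec-class].
#' @param fs a [FeatureSet-class]; for regression families the MMSE column
#'   is the target.
#' @param seeds integer seeds (default 1:3, averaged).
#' @return list of class `EvalReport`: `per_seed` (metric matrix),
#'   `mean` (seed-averaged metrics), `predictions` (long data.frame of
#'   fold-level predictions).
#' @export
runCv <- function(plan, spec, fs, seeds = 1:3) {
  X <- featureMatrix(fs)
  task <- if (spec@family %in% c("linreg", "ridge")) "regression"
          else "classification"
  y <- if (task == "classification") as.character(featureLabels(fs))
       else featureMMSE(fs)
  names(y) <- rownames(X)

  perSeed <- list()
  predRows <- list()
  for (s in seeds) {
    preds <- character(0); scores <- numeric(0); truth <- character(0)
    regp <- numeric(0); regt <- numeric(0); subjAll <- character(0)
    for (fi in seq_along(plan$folds)) {
      testIds <- plan$folds[[fi]]
      trainIds <- setdiff(plan$subjects, testIds)
      sp <- spec; sp@seed <- as.numeric(s)
      if (task == "classification") {
        m <- fitClassifier(sp, X[trainIds, , drop = FALSE], y[trainIds])
        pr <- predict(m, X[testIds, , drop = FALSE])
        preds <- c(preds, pr$label); scores <- c(scores, pr$score)
        truth <- c(truth, y[testIds])
      } else {
        m <- fitRegressor(sp, X[trainIds, , drop = FALSE],
                          as.numeric(y[trainIds]))
        regp <- c(regp, predictMMSE(m, X[testIds, , drop = FALSE]))
        regt <- c(regt, as.numeric(y[testIds]))
      }
      subjAll <- c(subjAll, testIds)
    }
    if (task == "classification") {
      perSeed[[as.character(s)]] <- classificationMetrics(truth, preds,
                                                          scores)
      predRows[[as.character(s)]] <- data.frame(
        seed = s, subject_id = subjAll, truth = truth, pred = preds,
        score = scores)
    } else {
      perSeed[[as.character(s)]] <- regressionMetrics(regt, regp)
      predRows[[as.character(s)]] <- data.frame(
        seed = s, subject_id = subjAll, truth = regt, pred = regp,
        score = regp)
    }
  }
  mat <- do.call(rbind, perSeed)
  structure(list(per_seed = mat, mean = colMeans(mat),
                 predictions = do.call(rbind, predRows),
                 spec = spec, scheme = plan$scheme),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("EvalReport (", x$scheme, " CV, ", nrow(x$per_seed), " seeds)\n",
      sep = "")
  print(round(x$mean, 4))
  invisible(x)
}

#' Majority vote over an odd number of fitted models
#'
#' Each model predicts labels for `X`; the per-subject modal label is
#' returned. An even voter count is a configuration error.
#'
#' @param models list of fitted classification [FittedModel-class]s
#'   (typically 3, trained with different seeds).
#' @param X feature matrix.
#' @return character vector of labels.
#' @export
majorityVotePredict <- function(models, X) {
  if (length(models) %% 2 == 0)
    stop("majority vote requires an odd number of models")
  votes <- vapply(models, function(m) predict(m, X)$label,
                  character(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  apply(votes, 1, function(v) names(which.max(table(v))))
}

#' Compare per-run accuracies of two or more models
#'
#' Kruskal-Wallis rank test (with tie correction) over the per-run
#' accuracy lists of each model, as used to compare classifier families.
#'
#' @param per_run_accuracies named list: model -> numeric accuracies.
#' @return list with `H` (statistic), `p` (chi-square p-value), `df`.
#' @examples
#' compareModelsKW(list(a = c(0.7, 0.72, 0.71), b = c(0.8, 0.81, 0.79)))
#' @export
compareModelsKW <- function(per_run_accuracies) {
  if (length(per_run_accuracies) < 2)
    stop("need at least two models to compare")
  if (any(lengths(per_run_accuracies) < 2))
    stop("need at least two observations per model")
  x <- unlist(per_run_accuracies, use.names = FALSE)
  g <- factor(rep(names(per_run_accuracies),
                  lengths(per_run_accuracies)))
  if (stats::var(x) == 0) return(list(H = 0, p = 1,
                                      df = nlevels(g) - 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}
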