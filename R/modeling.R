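# Univariate feature selection, the four classifier families and the two
# MMSE regressors, with their fixed hyperparameters.

#' Construct a ModelSpec
#'
#' Default hyperparameters are the tuned settings used throughout the
#' analysis protocol: svm_rbf(gamma = 0.001, C = 100), rf(200 trees,
#' min-split 2, min-leaf 2, bootstrap), nb(Gaussian, balanced priors,
#' variance smoothing 1e-10), nn(two hidden layers of 10 ReLU units, Adam,
#' 200 epochs, full batch, learning rate 1e-3), ridge(penalty alpha on
#' standardized features), linreg (ordinary least squares).
#'
#' @param family model family.
#' @param k number of features kept by univariate selection.
#' @param seed seed for stochastic families (rf, nn).
#' @param ... hyperparameter overrides (e.g. `alpha = 10` for ridge).
#' @return a [ModelSpec-class].
#' @examples
#' modelSpec("svm_rbf", k = 10)
#' modelSpec("ridge", k = 25, alpha = 10)
#' @export
modelSpec <- function(family, k = 10, seed = 1L, ...) {
  defaults <- switch(family,
    svm_rbf = list(gamma = 0.001, cost = 100),
    nn = list(units = c(10L, 10L), epochs = 200L, lr = 1e-3),
    rf = list(ntree = 200L, nodesize = 2L),
    nb = list(var_smoothing = 1e-10),
    linreg = list(),
    ridge = list(alpha = 1),
    stop("unknown family: ", family))
  hyper <- utils::modifyList(defaults, list(...))
  new("ModelSpec", family = family, hyper = hyper,
      k = as.numeric(k), seed = as.numeric(seed))
}

#' Top-k selection by one-way ANOVA F
#'
#' Ranks features by the one-way ANOVA F statistic between the two
#' class-conditional distributions and returns the indices of the k
#' largest; ties break toward the lower index. A feature with zero
#' within- and between-class variance has F = 0.
#'
#' @param X numeric matrix, subjects x features.
#' @param y binary labels (factor or character).
#' @param k number of features to keep.
#' @return integer vector of k column indices, with the F scores as the
#'   `scores` attribute (full-length).
#' @export
selectTopKAnova <- function(X, y, k) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2) stop("exactly two classes required")
  if (k > ncol(X)) stop("k exceeds feature count")
  g <- split(seq_along(y), y)
  n <- length(y)
  grand <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (idx in g) {
    mu <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + length(idx) * (mu - grand)^2
    ssw <- ssw + colSums((X[idx, , drop = FALSE] -
                            matrix(mu, length(idx), ncol(X), byrow = TRUE))^2)
  }
  msb <- ssb / (length(g) - 1)
  msw <- ssw / (n - length(g))
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  idx <- order(-f, seq_along(f))[seq_len(k)]
  structure(sort(idx), scores = f)
}

#' Top-k selection by correlation F against MMSE
#'
#' Ranks features by the F statistic derived from the squared Pearson
#' correlation with the MMSE score, F = r^2/(1 - r^2) * (n - 2)
#' (monotone in |r|, hence sign-invariant); constant features score 0;
#' ties break toward the lower index.
#'
#' @param X numeric matrix, subjects x features.
#' @param mmse numeric scores.
#' @param k number of features to keep.
#' @return integer vector of k column indices with `scores` attribute.
#' @export
selectTopKMmseCorr <- function(X, mmse, k) {
  if (k > ncol(X)) stop("k exceeds feature count")
  n <- nrow(X)
  sdx <- apply(X, 2, stats::sd)
  sy <- stats::sd(mmse)
  r <- rep(0, ncol(X))
  ok <- sdx > 0 & sy > 0
  if (any(ok))
    r[ok] <- suppressWarnings(as.numeric(stats::cor(X[, ok, drop = FALSE],
                                                    mmse)))
  r[is.na(r)] <- 0
  r2 <- pmin(r^2, 1 - 1e-12)
  f <- r2 / (1 - r2) * (n - 2)
  idx <- order(-f, seq_along(f))[seq_len(k)]
  structure(sort(idx), scores = f)
}

# ---- tiny MLP with Adam (2 hidden ReLU layers), binary cross-entropy ---

.mlpInit <- function(sizes, seed) {
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

.mlpForward <- function(par, X) {
  L <- length(par$W)
  acts <- list(X)
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% par$W[[l]] +
      matrix(par$b[[l]], nrow(X), length(par$b[[l]]), byrow = TRUE)
    acts[[l + 1]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  acts
}

.mlpTrain <- function(X, y01, units, epochs, lr, seed) {
  sizes <- c(ncol(X), units, 1L)
  par <- .mlpInit(sizes, seed)
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  for (t in seq_len(epochs)) {
    acts <- .mlpForward(par, X)
    p <- acts[[L + 1]]
    delta <- (p - y01) / n                     # dL/dz at the output
    for (l in rev(seq_len(L))) {
      gW <- t(acts[[l]]) %*% delta
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(par$W[[l]])) * (acts[[l]] > 0)
      }
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      mhW <- mW[[l]] / (1 - b1^t); vhW <- vW[[l]] / (1 - b2^t)
      mhb <- mb[[l]] / (1 - b1^t); vhb <- vb[[l]] / (1 - b2^t)
      par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  par
}

# ---- classifier / regressor fitting -----------------------------------

.zscoreFit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

.zscoreApply <- function(X, sc) {
  scale(X, center = sc$center, scale = sc$scale)[, , drop = FALSE]
}

#' Fit a classification pipeline
#'
#' Top-k ANOVA-F selection fit on the training matrix, then the family's
#' predictor with its fixed hyperparameters. SVM and NN consume z-scored
#' features (training statistics); RF and NB take raw features. The naive
#' Bayes model uses balanced class priors and a variance floor of
#' `var_smoothing` times the largest feature variance.
#'
#' @param spec a [ModelSpec-class] with a classification family.
#' @param X numeric matrix, subjects x features.
#' @param y binary labels; "AD" is the positive class.
#' @return a [FittedModel-class].
#' @export
fitClassifier <- function(spec, X, y) {
  y <- factor(y, levels = c("non-AD", "AD"))
  if (nlevels(droplevels(y)) < 2) stop("training labels contain one class")
  if (ncol(X) < spec@k) stop("k exceeds feature count")
  sel <- selectTopKAnova(X, y, spec@k)
  Xs <- X[, sel, drop = FALSE]
  scaler <- NULL
  if (spec@family %in% c("svm_rbf", "nn")) {
    scaler <- .zscoreFit(Xs)
    Xs <- .zscoreApply(Xs, scaler)
  }
  fit <- switch(spec@family,
    svm_rbf = e1071::svm(Xs, y, kernel = "radial",
                         gamma = spec@hyper$gamma, cost = spec@hyper$cost,
                         scale = FALSE, probability = FALSE),
    rf = {
      set.seed(spec@seed)
      randomForest::randomForest(Xs, y, ntree = spec@hyper$ntree,
                                 nodesize = spec@hyper$nodesize)
    },
    nb = {
      m <- e1071::naiveBayes(as.data.frame(Xs), y)
      m$apriori <- stats::setNames(
        rep(1 / nlevels(y), nlevels(y)) * length(y), levels(y))
      floorVar <- spec@hyper$var_smoothing * max(apply(Xs, 2, stats::var))
      m$tables <- lapply(m$tables, function(tb) {
        tb[, 2] <- sqrt(tb[, 2]^2 + floorVar)
        tb
      })
      m
    },
    nn = {
      y01 <- matrix(as.numeric(y == "AD"), ncol = 1)
      .mlpTrain(Xs, y01, spec@hyper$units, spec@hyper$epochs,
                spec@hyper$lr, spec@seed)
    },
    stop("not a classification family: ", spec@family))
  new("FittedModel", spec = spec,
      selection = list(indices = as.integer(sel),
                       scores = attr(sel, "scores")),
      scaler = scaler, fit = fit, task = "classification",
      featureNames = colnames(X) %||% as.character(seq_len(ncol(X))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit an MMSE regression pipeline
#'
#' Correlation-F top-k selection, z-scoring with training statistics, then
#' ordinary least squares (`linreg`) or closed-form ridge with penalty
#' `alpha` on the standardized coefficients (intercept unpenalized).
#'
#' @param spec a [ModelSpec-class] with family "linreg" or "ridge".
#' @param X numeric matrix, subjects x features.
#' @param mmse numeric scores.
#' @return a [FittedModel-class].
#' @export
fitRegressor <- function(spec, X, mmse) {
  if (ncol(X) < spec@k) stop("k exceeds feature count")
  sel <- selectTopKMmseCorr(X, mmse, spec@k)
  Xs <- X[, sel, drop = FALSE]
  scaler <- .zscoreFit(Xs)
  Z <- .zscoreApply(Xs, scaler)
  alpha <- if (spec@family == "ridge") spec@hyper$alpha else 0
  p <- ncol(Z)
  beta <- solve(crossprod(Z) + diag(alpha, p), crossprod(Z, mmse))
  fit <- list(beta = as.numeric(beta), intercept = mean(mmse))
  new("FittedModel", spec = spec,
      selection = list(indices = as.integer(sel),
                       scores = attr(sel, "scores")),
      scaler = scaler, fit = fit, task = "regression",
      featureNames = colnames(X) %||% as.character(seq_len(ncol(X))))
}

#' Predict with a fitted pipeline
#'
#' For classifiers returns a data.frame with `label` and a continuous
#' `score` (decision value / class probability / network output) with
#' larger values favoring "AD". For regressors use [predictMMSE()].
#'
#' @param object a [FittedModel-class].
#' @param X feature matrix with the same columns as at fit time.
#' @param ... unused.
#' @return data.frame with columns `label`, `score`.
#' @export
setMethod("predict", "FittedModel", function(object, X, ...) {
  Xs <- X[, object@selection$indices, drop = FALSE]
  if (!is.null(object@scaler)) Xs <- .zscoreApply(Xs, object@scaler)
  if (object@task == "regression") {
    raw <- as.numeric(Xs %*% object@fit$beta) + object@fit$intercept
    return(raw)
  }
  fam <- object@spec@family
  if (fam == "svm_rbf") {
    pr <- stats::predict(object@fit, Xs, decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    # e1071 orients the decision value by training-class order; flip so
    # positive always means AD
    if (grepl("^AD", colnames(attr(pr, "decision.values"))[1])) dv <- dv
    else dv <- -dv
    return(data.frame(label = as.character(pr), score = dv))
  }
  if (fam == "rf") {
    pv <- stats::predict(object@fit, Xs, type = "prob")[, "AD"]
    return(data.frame(label = ifelse(pv >= 0.5, "AD", "non-AD"),
                      score = pv))
  }
  if (fam == "nb") {
    pv <- stats::predict(object@fit, as.data.frame(Xs), type = "raw")[, "AD"]
    return(data.frame(label = ifelse(pv >= 0.5, "AD", "non-AD"),
                      score = pv))
  }
  if (fam == "nn") {
    p <- .mlpForward(object@fit, Xs)[[length(object@fit$W) + 1]]
    return(data.frame(label = ifelse(p >= 0.5, "AD", "non-AD"),
                      score = as.numeric(p)))
  }
  stop("unsupported family")
})

#' Save / load a fitted model
#'
#' Serializes a [FittedModel-class] together with a hash of the feature
#' registry; loading refuses a model saved under a different registry,
#' so selected feature indices can never silently point at the wrong
#' columns.
#'
#' @param model a [FittedModel-class].
#' @param path file path.
#' @return `path` invisibly; for [loadFittedModel()], the model.
#' @export
saveFittedModel <- function(model, path) {
  payload <- list(version = 1L,
                  registry_hash = .registryHash(),
                  model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveFittedModel
#' @export
loadFittedModel <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$registry_hash, .registryHash()))
    stop("model was fitted under a different feature registry")
  payload$model
}

.registryHash <- function() {
  reg <- featureRegistry()
  .strHash(paste(reg$name, collapse = "|"))
}

#' Clipped MMSE predictions
#'
#' Raw regression predictions clipped into the valid MMSE range \[0, 30\].
#'
#' @param model a fitted regression [FittedModel-class].
#' @param X feature matrix.
#' @return numeric predictions in \[0, 30\].
#' @examples
#' # predictions 34.2 and -1.7 clip to 30 and 0
#' @export
predictMMSE <- function(model, X) {
  stopifnot(model@task == "regression")
  .clip(predict(model, X), 0, 30)
}
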