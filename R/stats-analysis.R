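# Feature differentiation analysis (per-feature Welch t-tests with
# Bonferroni correction) and MMSE regression-weight reporting.

#' Per-feature group differentiation
#'
#' For every feature, a Welch two-sample t-test between the AD and non-AD
#' groups; flags significance at `alpha` (raw) and at the Bonferroni level
#' `alpha / m` with m = number of features tested. A feature with zero
#' variance in both groups and equal means has t = 0 and p = 1 by
#' convention.
#'
#' @param fs a [FeatureSet-class] (or list with `X` subjects x features
#'   and `label`).
#' @param alpha base significance level (default 0.05).
#' @return data.frame of class `DifferentiationReport`: per feature
#'   mean_ad, mean_nonad, t, p, sig_raw, sig_bonferroni; attributes
#'   `n_sig_raw`, `n_sig_bonferroni`, `bonferroni_threshold`.
#' @export
differentiateFeatures <- function(fs, alpha = 0.05) {
  if (is(fs, "FeatureSet")) {
    X <- featureMatrix(fs)
    label <- as.character(featureLabels(fs))
  } else {
    X <- fs$X; label <- as.character(fs$label)
  }
  ad <- X[label == "AD", , drop = FALSE]
  ct <- X[label != "AD", , drop = FALSE]
  if (!nrow(ad) || !nrow(ct)) stop("both groups must be non-empty")
  m <- ncol(X)

  res <- vapply(seq_len(m), function(j) {
    a <- ad[, j]; b <- ct[, j]
    va <- stats::var(a); vb <- stats::var(b)
    if (va == 0 && vb == 0) {
      d <- mean(a) - mean(b)
      if (d == 0) return(c(mean(a), mean(b), 0, 1))
      return(c(mean(a), mean(b), sign(d) * Inf, 0))
    }
    tt <- stats::t.test(a, b)
    c(mean(a), mean(b), unname(tt$statistic), tt$p.value)
  }, numeric(4))

  out <- data.frame(
    feature = colnames(X) %||% as.character(seq_len(m)),
    mean_ad = res[1, ], mean_nonad = res[2, ],
    t = res[3, ], p = res[4, ])
  thr <- alpha / m
  out$sig_raw <- out$p < alpha
  out$sig_bonferroni <- out$p < thr
  attr(out, "n_sig_raw") <- sum(out$sig_raw)
  attr(out, "n_sig_bonferroni") <- sum(out$sig_bonferroni)
  attr(out, "bonferroni_threshold") <- thr
  class(out) <- c("DifferentiationReport", "data.frame")
  out
}

#' MMSE regression-weight report
#'
#' Runs LOSO cross-validation of the given ridge (or linear) spec, records
#' each feature's standardized coefficient per fold (0 when unselected in
#' that fold), averages across folds, attaches each feature's Pearson
#' correlation with MMSE (with Bonferroni-level significance over all
#' features) and reports the features with the five highest and five
#' lowest mean weights. With fewer than 10 ever-selected features, all of
#' them are reported.
#'
#' @param fs a [FeatureSet-class] with MMSE for every subject.
#' @param spec a regression [ModelSpec-class] (default ridge k=25,
#'   alpha=10).
#' @param alpha base level for the correlation significance flag.
#' @return list of class `WeightReport`: `weights` (per-feature data.frame
#'   sorted by |mean weight|), `top` (the 10 reported rows).
#' @export
weightReport <- function(fs, spec = modelSpec("ridge", k = 25, alpha = 10),
                         alpha = 0.05) {
  X <- featureMatrix(fs)
  mmse <- featureMMSE(fs)
  if (anyNA(mmse)) stop("MMSE required for every subject")
  n <- nrow(X); m <- ncol(X)
  wsum <- numeric(m)
  for (i in seq_len(n)) {
    fit <- fitRegressor(spec, X[-i, , drop = FALSE], mmse[-i])
    wsum[fit@selection$indices] <- wsum[fit@selection$indices] +
      fit@fit$beta
  }
  wmean <- wsum / n

  sdx <- apply(X, 2, stats::sd)
  r <- rep(0, m)
  ok <- sdx > 0
  r[ok] <- as.numeric(stats::cor(X[, ok, drop = FALSE], mmse))
  # correlation p-value via the t transform
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  pcor <- 2 * stats::pt(-abs(tstat), df = n - 2)

  wr <- data.frame(
    feature = colnames(X) %||% as.character(seq_len(m)),
    mean_weight = wmean, correlation = r, p_correlation = pcor,
    sig_bonferroni = pcor < alpha / m,
    sign_concordant = sign(wmean) == sign(r) | wmean == 0)
  wr <- wr[order(-abs(wr$mean_weight)), ]
  rownames(wr) <- NULL

  ever <- wr[wr$mean_weight != 0, ]
  if (nrow(ever) < 10) {
    top <- ever
  } else {
    bySigned <- ever[order(-ever$mean_weight), ]
    top <- rbind(utils::head(bySigned, 5), utils::tail(bySigned, 5))
  }
  structure(list(weights = wr, top = top, spec = spec),
            class = "WeightReport")
}

#' @export
print.WeightReport <- function(x, ...) {
  cat("WeightReport: top features by signed mean LOSO weight\n")
  print(x$top[, c("feature", "mean_weight", "correlation",
                  "sig_bonferroni")], digits = 3)
  invisible(x)
}

#' Write a differentiation report to CSV
#' @param report a `DifferentiationReport`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeDifferentiationCSV <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
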