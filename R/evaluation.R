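## Performance metrics and reports. Agreement is summarized by a *pooled*
## Cohen's kappa: one confusion matrix aggregated over all test folds,
## rather than an average of per-fold kappas (averaging inflates the
## estimate's variance around mid-range values). Per-class one-vs-rest
## metrics, balanced accuracy (mean recall), sleep-architecture summaries
## and a t-SNE feature-space embedding complete the report.

.confusion <- function(truth, pred, levels) {
  table(factor(as.character(truth), levels = levels),
        factor(as.character(pred), levels = levels))
}

.kappaFromConfusion <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-15) return(NA_real_)  # degenerate single-class pool
  (po - pe) / (1 - pe)
}

#' Pooled Cohen's kappa over all test folds
#'
#' Aggregates all fold predictions into one confusion matrix and computes
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement from the pooled
#' marginals. A degenerate single-class pool yields `NA` with a warning.
#'
#' @param x a [CVResult-class], or a truth factor when `pred` is given.
#' @param pred predictions aligned with `x` (when `x` is a factor).
#' @return numeric kappa in \[-1, 1\].
#' @export
pooledKappa <- function(x, pred = NULL) {
  if (is(x, "CVResult")) {
    truth <- pooledTruth(x); pred <- pooledPred(x); lv <- x@classLevels
  } else {
    truth <- x
    lv <- union(levels(factor(truth)), levels(factor(pred)))
  }
  if (length(unique(as.character(truth))) < 2) {
    warning("single-class pooled truth: kappa undefined")
    return(NA_real_)
  }
  .kappaFromConfusion(.confusion(truth, pred, lv))
}

#' Qualitative agreement band for a kappa value
#'
#' Bands: below 0 worse-than-chance, 0-0.20 slight, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1 near-perfect
#' (boundaries belong to the lower band's upper edge).
#'
#' @param value kappa in \[-1, 1\].
#' @return character label.
#' @export
kappaBand <- function(value) {
  if (is.na(value) || value < -1 || value > 1)
    stop("kappa must lie in [-1, 1]")
  if (value < 0) "worse-than-chance"
  else if (value <= 0.20) "slight"
  else if (value <= 0.40) "fair"
  else if (value <= 0.60) "moderate"
  else if (value <= 0.80) "substantial"
  else "near-perfect"
}

#' F-beta score from precision and sensitivity
#'
#' `F_beta = (1 + beta^2) * precision * sensitivity /
#'  (beta^2 * precision + sensitivity)`, with `beta = 1` by default.
#'
#' @param precision,sensitivity rates in \[0, 1\].
#' @param beta weight of sensitivity relative to precision.
#' @return numeric score (0 when both inputs are 0).
#' @export
fBetaScore <- function(precision, sensitivity, beta = 1) {
  den <- beta^2 * precision + sensitivity
  ifelse(den == 0, 0, (1 + beta^2) * precision * sensitivity / den)
}

#' Per-class metrics and pooled confusion report
#'
#' One-vs-rest specificity, precision and sensitivity per class, F1 with
#' beta = 1, and balanced accuracy (arithmetic mean of per-class
#' sensitivity), all from the pooled confusion matrix; per-fold mean and
#' SEM of F1 and balanced accuracy are reported alongside. An empty
#' predicted class yields precision 0.
#'
#' @param results a [CVResult-class].
#' @return a [MetricsReport-class].
#' @export
perClassMetrics <- function(results) {
  lv <- results@classLevels
  truth <- pooledTruth(results); pred <- pooledPred(results)
  cm <- .confusion(truth, pred, lv)
  n <- sum(cm)
  per <- t(vapply(lv, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    c(specificity = spec, precision = prec, sensitivity = sens,
      f1 = fBetaScore(prec, if (is.na(sens)) 0 else sens))
  }, numeric(4)))
  perDf <- as.data.frame(per)
  rownames(perDf) <- lv
  balAcc <- mean(perDf$sensitivity, na.rm = TRUE)
  # micro-averaged recall equals overall accuracy; assert on every report
  acc <- sum(diag(cm)) / n
  stopifnot(abs(acc - sum(diag(cm)) / sum(cm)) < 1e-12)
  foldVals <- vapply(results@folds, function(f) {
    fcm <- .confusion(f$truth, f$pred, lv)
    sens <- diag(fcm) / pmax(rowSums(fcm), 1)
    c(f1 = .weightedF1(factor(as.character(f$truth), levels = lv),
                       factor(as.character(f$pred), levels = lv)),
      balanced_accuracy = mean(sens[rowSums(fcm) > 0]))
  }, numeric(2))
  foldStats <- data.frame(
    metric = rownames(foldVals),
    mean = rowMeans(foldVals),
    sem = apply(foldVals, 1, sd) / sqrt(ncol(foldVals)))
  pct <- sweep(cm, 1, pmax(rowSums(cm), 1), "/") * 100
  new("MetricsReport", pooledKappa = .kappaFromConfusion(cm),
      perClass = perDf, balancedAccuracy = balAcc,
      confusion = unclass(as.matrix(cm)),
      confusionPct = unclass(as.matrix(pct)),
      foldStats = foldStats, nEpochs = as.integer(n))
}

#' Sleep-architecture summary from an epoch label sequence
#'
#' Total sleep time is 0.5 min per non-Wake epoch; stage percentages are of
#' total recording time; awakenings are maximal Wake runs occurring strictly
#' inside the sleep period (after the first non-Wake epoch and before the
#' last non-Wake epoch).
#'
#' @param labels per-epoch stage labels (any resolution; "Wake" is special).
#' @return a [SleepArchitecture-class].
#' @export
sleepArchitecture <- function(labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) >= 1)
  nEp <- length(labels)
  isWake <- labels == "Wake"
  tst <- 0.5 * sum(!isWake)
  pct <- table(labels) / nEp * 100
  nAw <- 0L
  if (any(!isWake)) {
    a <- min(which(!isWake)); b <- max(which(!isWake))
    if (b > a) {
      r <- rle(isWake[a:b])
      nAw <- sum(r$values)
    }
  }
  new("SleepArchitecture", tstMin = tst,
      stagePct = setNames(as.numeric(pct), names(pct)),
      nAwakenings = as.integer(nAw), nEpochs = as.integer(nEp))
}

#' Two-dimensional t-SNE embedding of a feature matrix
#'
#' Exact t-distributed stochastic neighbour embedding: per-row Gaussian
#' bandwidths are calibrated to the target perplexity by bisection, the
#' symmetrized affinities are matched to a Student-t low-dimensional kernel
#' by gradient descent with early exaggeration and momentum. Defaults follow
#' the feature-space visualization convention used here: perplexity 40,
#' 300 iterations. When fewer than `3 * perplexity + 1` rows are supplied
#' the perplexity is shrunk with a warning.
#'
#' @param X numeric matrix (rows = epochs).
#' @param perplexity target perplexity.
#' @param iterations gradient-descent iterations.
#' @param seed integer seed for the random initialization.
#' @return matrix with one 2-D coordinate row per input row.
#' @export
tsneEmbedding <- function(X, perplexity = 40, iterations = 300, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 4)
  if (n < 3 * perplexity + 1) {
    perplexity <- max(2, floor((n - 1) / 3))
    warning("too few rows; perplexity shrunk to ", perplexity)
  }
  D2 <- as.matrix(dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; pj <- w }
      else {
        pj <- w / sw
        H <- -sum(pj[pj > 0] * log(pj[pj > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2
                                          else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2
                                 else beta / 2 }
    }
    P[i, -i] <- pj
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withr::local_seed(as.integer(seed))
  Y <- matrix(rnorm(n * 2, 0, 1e-4), n, 2)
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  exag <- 4; eta <- 200
  for (iter in seq_len(iterations)) {
    Pe <- if (iter <= 50) P * exag else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= 20) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Write an evaluation report bundle
#'
#' JSON metrics (sorted keys), confusion-matrix CSVs (counts and row
#' percentages), an optional sleep-architecture JSON and a markdown
#' summary, regenerated deterministically from the same CVResult.
#'
#' @param results a [CVResult-class].
#' @param dir output directory.
#' @param architecture optional [SleepArchitecture-class].
#' @return invisibly, the [MetricsReport-class] written.
#' @export
writeReport <- function(results, dir, architecture = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- perClassMetrics(results)
  metrics <- list(
    framework = results@framework,
    resolution = results@resolution,
    n_epochs = rep@nEpochs,
    pooled_kappa = rep@pooledKappa,
    kappa_band = kappaBand(rep@pooledKappa),
    balanced_accuracy = rep@balancedAccuracy,
    per_class = cbind(class = rownames(rep@perClass), rep@perClass),
    fold_stats = rep@foldStats)
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write.csv(rep@confusion, file.path(dir, "confusion_counts.csv"))
  write.csv(round(rep@confusionPct, 4),
            file.path(dir, "confusion_rowpct.csv"))
  if (!is.null(architecture))
    jsonlite::write_json(
      list(total_sleep_time_min = architecture@tstMin,
           stage_percentages = as.list(architecture@stagePct),
           n_awakenings = architecture@nAwakenings),
      file.path(dir, "sleep_architecture.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  md <- c(sprintf("# Sleep staging report (%s, %d-stage)",
                  results@framework, results@resolution),
          "",
          sprintf("- pooled Cohen's kappa: %.3f (%s)", rep@pooledKappa,
                  kappaBand(rep@pooledKappa)),
          sprintf("- balanced accuracy: %.3f", rep@balancedAccuracy),
          sprintf("- pooled test epochs: %d", rep@nEpochs))
  writeLines(md, file.path(dir, "summary.md"))
  invisible(rep)
}

#' Plot predicted vs true hypnogram step lines
#'
#' @param truth,pred aligned per-epoch label factors.
#' @param main plot title.
#' @return invisibly NULL; draws on the active device.
#' @export
plotHypnogram <- function(truth, pred, main = "Hypnogram: truth vs predicted") {
  lv <- levels(factor(truth))
  yT <- as.integer(factor(as.character(truth), levels = lv))
  yP <- as.integer(factor(as.character(pred), levels = lv))
  t <- (seq_along(yT) - 1) * 0.5  # minutes
  graphics::plot(t, yT, type = "s", lwd = 2, col = "black", yaxt = "n",
                 xlab = "time (min)", ylab = "", main = main,
                 ylim = c(0.8, length(lv) + 0.2))
  graphics::lines(t, yP + 0.05, type = "s", col = "firebrick")
  graphics::axis(2, at = seq_along(lv), labels = lv, las = 1)
  graphics::legend("topright", legend = c("truth", "predicted"),
                   col = c("black", "firebrick"), lwd = c(2, 1), bty = "n")
  invisible(NULL)
}
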