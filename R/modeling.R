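## Classifier training under the two evaluation frameworks: population
## (leave-one-subject-out outer folds) and personal (stratified 10-fold
## within one subject's night). Within each outer training set: correlation
## pruning (|r| > 0.95), recursive-feature-elimination ladder, and an inner
## stratified 10-fold grid search scored by weighted F1; class imbalance is
## handled by class weights + random undersampling (bagging / random
## forest) or SMOTE (gradient boosting / XGBoost), applied to training
## folds only.

#' Construct a ModelSpec
#'
#' The imbalance strategy is fixed by the algorithm: class weights plus
#' random undersampling for `balanced_bagging` and `balanced_random_forest`;
#' SMOTE for `gradient_boosting` and `xgboost`. The default grid spans
#' trees in \{100, 300\} and depth in \{3, 6\}, plus learning rate
#' \{0.05, 0.1\} for the boosting variants.
#'
#' @param algorithm one of `"balanced_bagging"`, `"balanced_random_forest"`,
#'   `"gradient_boosting"`, `"xgboost"`.
#' @param grid named list of hyperparameter vectors; `NULL` for defaults.
#'   Recognized names: `num_trees`, `max_depth`, `learning_rate`.
#' @param seed integer seed for all modeling randomness.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(algorithm = "balanced_random_forest", grid = NULL,
                      seed = 1L) {
  boosting <- algorithm %in% c("gradient_boosting", "xgboost")
  if (is.null(grid)) {
    grid <- list(num_trees = c(100, 300), max_depth = c(3, 6))
    if (boosting) grid$learning_rate <- c(0.05, 0.1)
  }
  new("ModelSpec", algorithm = algorithm,
      strategy = if (boosting) "smote" else "weights_undersample",
      grid = grid, seed = as.integer(seed))
}

#' Drop highly correlated feature columns
#'
#' Greedy scan in the fixed column order: a column whose absolute Pearson
#' correlation with any earlier kept column exceeds the threshold (strictly)
#' is dropped. Deterministic.
#'
#' @param X numeric matrix (rows = epochs, columns = features).
#' @param threshold correlation threshold (default 0.95).
#' @return list with `X` (reduced matrix), `kept`, `dropped` (names).
#' @export
dropCorrelatedFeatures <- function(X, threshold = 0.95) {
  stopifnot(nrow(X) >= 2)
  cm <- suppressWarnings(abs(cor(X)))
  cm[is.na(cm)] <- 0           # constant columns correlate with nothing
  p <- ncol(X)
  keep <- logical(p); keep[1] <- TRUE
  # strict "greater than": a float tolerance keeps |r| == threshold pairs
  for (j in seq_len(p)[-1])
    keep[j] <- all(cm[j, which(keep)] <= threshold + 1e-10)
  list(X = X[, keep, drop = FALSE],
       kept = colnames(X)[keep],
       dropped = colnames(X)[!keep])
}

#' Z-score features within each subject
#'
#' Per subject and feature: `(x - mean) / SD` over that subject's night;
#' features with zero SD become 0 for that subject. Sample SD (n-1).
#'
#' @param X numeric matrix (rows = epochs).
#' @param subject character/factor subject id per row.
#' @return normalized matrix of the same shape.
#' @export
zscoreWithinSubject <- function(X, subject) {
  stopifnot(nrow(X) == length(subject))
  for (s in unique(subject)) {
    ii <- which(subject == s)
    mu <- colMeans(X[ii, , drop = FALSE])
    sg <- apply(X[ii, , drop = FALSE], 2, sd)
    Xc <- sweep(X[ii, , drop = FALSE], 2, mu, "-")
    sg[sg == 0] <- Inf          # constant feature -> all zeros
    X[ii, ] <- sweep(Xc, 2, sg, "/")
  }
  X
}

#' Rebalance a training set
#'
#' `"undersample"` randomly reduces every class to the minority count;
#' `"smote"` grows every minority class to the majority count with
#' synthetic rows interpolated between k=5 same-class nearest neighbours
#' (a class with a single member falls back to random oversampling, with a
#' message); `"classweights"` leaves rows untouched and returns
#' inverse-frequency weights.
#'
#' @param X numeric matrix (rows = observations).
#' @param y factor labels.
#' @param method `"undersample"`, `"smote"` or `"classweights"`.
#' @param k SMOTE neighbourhood size.
#' @param seed integer seed.
#' @return list with `X`, `y` and `weights` (per returned row).
#' @export
rebalance <- function(X, y, method = c("undersample", "smote",
                                       "classweights"), k = 5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(nlevels(droplevels(y)) >= 2)
  withr::local_seed(as.integer(seed))
  counts <- table(y)
  counts <- counts[counts > 0]
  if (method == "classweights") {
    w <- as.numeric(1 / counts[as.character(y)])
    return(list(X = X, y = y, weights = w * length(y) / sum(w)))
  }
  if (method == "undersample") {
    nMin <- min(counts)
    idx <- unlist(lapply(names(counts), function(cl) {
      ii <- which(y == cl)
      if (length(ii) > nMin) sample(ii, nMin) else ii
    }))
    idx <- sort(idx)
    return(list(X = X[idx, , drop = FALSE], y = droplevels(y[idx]),
                weights = rep(1, length(idx))))
  }
  # SMOTE
  nMax <- max(counts)
  Xs <- list(X); ys <- list(as.character(y))
  for (cl in names(counts)) {
    need <- nMax - counts[[cl]]
    if (need == 0) next
    ii <- which(y == cl)
    if (length(ii) < 2) {
      message("SMOTE: class '", cl,
              "' has < 2 members; falling back to random oversampling")
      pick <- sample(ii, need, replace = TRUE)
      Xs[[length(Xs) + 1L]] <- X[pick, , drop = FALSE]
      ys[[length(ys) + 1L]] <- rep(cl, need)
      next
    }
    Xc <- X[ii, , drop = FALSE]
    D <- as.matrix(dist(Xc))
    diag(D) <- Inf
    kk <- min(k, length(ii) - 1L)
    nbr <- apply(D, 1, function(d) order(d)[seq_len(kk)])
    nbr <- matrix(nbr, nrow = kk)
    base <- sample(length(ii), need, replace = TRUE)
    pickN <- vapply(base, function(b) nbr[sample.int(kk, 1L), b], numeric(1))
    gap <- runif(need)
    Xs[[length(Xs) + 1L]] <-
      Xc[base, , drop = FALSE] +
      gap * (Xc[pickN, , drop = FALSE] - Xc[base, , drop = FALSE])
    ys[[length(ys) + 1L]] <- rep(cl, need)
  }
  list(X = do.call(rbind, Xs),
       y = factor(unlist(ys), levels = levels(y)),
       weights = rep(1, sum(vapply(Xs, nrow, integer(1)))))
}

## Fit one classifier on an already-normalized training matrix, applying the
## spec's imbalance strategy, and return a predict closure.
.fitModel <- function(X, y, spec, params, seed) {
  lv <- levels(y)
  if (spec@strategy == "weights_undersample") {
    rb <- rebalance(X, y, "undersample", seed = seed)
    w <- rebalance(rb$X, rb$y, "classweights", seed = seed)$weights
    mtry <- if (spec@algorithm == "balanced_bagging") ncol(X)
            else max(1L, floor(sqrt(ncol(X))))
    fit <- ranger::ranger(
      x = as.data.frame(rb$X), y = droplevels(rb$y),
      num.trees = params$num_trees, max.depth = params$max_depth,
      mtry = min(mtry, ncol(X)), case.weights = w,
      seed = seed, num.threads = 1L)
    predictFun <- function(Xnew) {
      p <- predict(fit, data = as.data.frame(Xnew),
                   num.threads = 1L)$predictions
      factor(as.character(p), levels = lv)
    }
  } else {
    rb <- rebalance(X, y, "smote", seed = seed)
    yNum <- as.integer(droplevels(rb$y)) - 1L
    lvUsed <- levels(droplevels(rb$y))
    nc <- length(lvUsed)
    xp <- list(max_depth = params$max_depth, eta = params$learning_rate,
               nthread = 1L, verbosity = 0)
    if (spec@algorithm == "gradient_boosting") {
      # classic GBM settings: exact greedy splits, no regularization
      xp$lambda <- 0; xp$alpha <- 0; xp$tree_method <- "exact"
    }
    if (nc > 2) { xp$objective <- "multi:softmax"; xp$num_class <- nc }
    else xp$objective <- "binary:logistic"
    xp$seed <- seed
    dtr <- xgboost::xgb.DMatrix(as.matrix(rb$X), label = yNum)
    fit <- xgboost::xgb.train(params = xp, data = dtr,
                              nrounds = params$num_trees, verbose = 0)
    predictFun <- function(Xnew) {
      p <- predict(fit, xgboost::xgb.DMatrix(as.matrix(Xnew)))
      cls <- if (nc > 2) lvUsed[p + 1L] else lvUsed[(p > 0.5) + 1L]
      factor(cls, levels = lv)
    }
  }
  list(predict = predictFun, levels = lv)
}

## Weighted F1 over classes present in the truth, weights = class support.
.weightedF1 <- function(truth, pred) {
  lv <- levels(truth)
  f1 <- vapply(lv, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  support <- as.numeric(table(truth))
  if (sum(support) == 0) return(0)
  sum(f1 * support) / sum(support)
}

## Stratified fold assignment: within each class, shuffled round-robin.
.stratifiedFolds <- function(y, k, seed) {
  withr::local_seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in levels(droplevels(y))) {
    ii <- sample(which(y == cl))
    fold[ii] <- rep_len(seq_len(k), length(ii))
  }
  fold
}

## Recursive feature elimination ladder: refit, rank by importance, halve,
## down to `minFeatures`. Returns a list of nested feature-name sets.
.rfeLadder <- function(X, y, spec, seed, minFeatures = 8L) {
  feats <- colnames(X)
  ladder <- list(feats)
  while (length(feats) > minFeatures) {
    imp <- .featureImportance(X[, feats, drop = FALSE], y, spec, seed)
    nKeep <- max(minFeatures, floor(length(feats) / 2))
    feats <- names(sort(imp, decreasing = TRUE))[seq_len(nKeep)]
    ladder[[length(ladder) + 1L]] <- feats
  }
  ladder
}

.featureImportance <- function(X, y, spec, seed) {
  if (spec@strategy == "weights_undersample") {
    rb <- rebalance(X, y, "undersample", seed = seed)
    fit <- ranger::ranger(x = as.data.frame(rb$X), y = droplevels(rb$y),
                          num.trees = 100, importance = "impurity",
                          seed = seed, num.threads = 1L)
    imp <- fit$variable.importance
  } else {
    rb <- rebalance(X, y, "smote", seed = seed)
    yNum <- as.integer(droplevels(rb$y)) - 1L
    nc <- nlevels(droplevels(rb$y))
    xp <- list(max_depth = 4, eta = 0.1, nthread = 1L, seed = seed)
    if (nc > 2) { xp$objective <- "multi:softmax"; xp$num_class <- nc }
    else xp$objective <- "binary:logistic"
    dtr <- xgboost::xgb.DMatrix(as.matrix(rb$X), label = yNum)
    fit <- xgboost::xgb.train(params = xp, data = dtr, nrounds = 50,
                              verbose = 0)
    it <- xgboost::xgb.importance(model = fit)
    imp <- setNames(rep(0, ncol(X)), colnames(X))
    imp[it$Feature] <- it$Gain
  }
  # guarantee full coverage with a stable ordering
  out <- setNames(rep(0, ncol(X)), colnames(X))
  out[names(imp)] <- imp
  out
}

## One outer fold: prune, build RFE ladder, inner grid search by weighted
## F1, refit best configuration, predict the held-out rows.
.outerFold <- function(Xtr, ytr, Xte, spec, innerFolds, seed,
                       corThreshold) {
  pr <- dropCorrelatedFeatures(Xtr, corThreshold)
  Xtr <- pr$X
  Xte <- Xte[, pr$kept, drop = FALSE]
  ladder <- .rfeLadder(Xtr, ytr, spec, seed)
  gridDf <- expand.grid(spec@grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  fold <- .stratifiedFolds(ytr, innerFolds, seed)
  nInner <- max(fold)
  best <- NULL; bestScore <- -Inf
  for (li in seq_along(ladder)) {
    feats <- ladder[[li]]
    for (gi in seq_len(nrow(gridDf))) {
      params <- as.list(gridDf[gi, , drop = FALSE])
      scores <- numeric(nInner)
      for (f in seq_len(nInner)) {
        tr <- fold != f
        # guard: a class absent from this inner training split is excluded
        yIn <- droplevels(ytr[tr])
        if (nlevels(yIn) < 2) { scores[f] <- 0; next }
        m <- .fitModel(Xtr[tr, feats, drop = FALSE], ytr[tr], spec,
                       params, seed + 13L * f)
        pHat <- m$predict(Xtr[!tr, feats, drop = FALSE])
        # classes absent from the inner test truth carry zero support weight
        scores[f] <- .weightedF1(ytr[!tr], pHat)
      }
      sc <- mean(scores)
      # ties favour fewer features (later ladder rungs), then earlier grid rows
      if (sc > bestScore + 1e-12 ||
          (abs(sc - bestScore) <= 1e-12 && !is.null(best) &&
           length(feats) < length(best$features))) {
        bestScore <- sc
        best <- list(features = feats, params = params)
      }
    }
  }
  m <- .fitModel(Xtr[, best$features, drop = FALSE], ytr, spec,
                 best$params, seed)
  list(pred = m$predict(Xte[, best$features, drop = FALSE]),
       selected_features = best$features,
       hyperparameters = best$params,
       inner_score = bestScore)
}

.labelColumn <- function(nClasses) paste0("label", nClasses)

#' Nested cross-validation of a sleep-stage classifier
#'
#' Population framework: leave-one-subject-out outer folds (requires >= 3
#' subjects). Personal framework: stratified 10-fold outer CV on a single
#' subject's epochs. Within every outer training set: correlation pruning
#' (|r| > 0.95), within-subject z-scoring (applied per subject over the full
#' night, before fold splitting, mirroring per-subject normalization),
#' recursive feature elimination, and an inner stratified 10-fold grid
#' search maximizing weighted F1; the best configuration is refit with
#' rebalancing on the full outer training set and applied once to the
#' held-out fold. All randomness derives from `spec@seed`.
#'
#' @param table an [EpochFeatureTable-class].
#' @param spec a [ModelSpec-class].
#' @param framework `"population"` or `"personal"`.
#' @param resolution number of collapsed stages (2, 3 or 4).
#' @param innerFolds inner CV folds (default 10).
#' @param outerFolds outer folds for the personal framework (default 10).
#' @param corThreshold correlation-pruning threshold.
#' @return a [CVResult-class].
#' @export
nestedCV <- function(table, spec, framework = c("population", "personal"),
                     resolution = 2, innerFolds = 10, outerFolds = 10,
                     corThreshold = 0.95) {
  framework <- match.arg(framework)
  resolution <- as.integer(resolution)
  X <- t(SummarizedExperiment::assay(table, "features"))
  cd <- SummarizedExperiment::colData(table)
  subject <- as.character(cd$subject_id)
  y <- factor(as.character(cd[[.labelColumn(resolution)]]),
              levels = stageLevels(resolution))
  X <- zscoreWithinSubject(X, subject)
  folds <- list()
  if (framework == "population") {
    subjects <- unique(subject)
    if (length(subjects) < 3)
      stop("population framework needs at least 3 subjects")
    for (i in seq_along(subjects)) {
      te <- subject == subjects[i]
      ytr <- droplevels(y[!te])
      if (nlevels(ytr) < 2) stop("outer training set has a single class")
      of <- .outerFold(X[!te, , drop = FALSE], ytr, X[te, , drop = FALSE],
                       spec, innerFolds, spec@seed + 101L * i, corThreshold)
      folds[[i]] <- c(list(fold_id = subjects[i],
                           truth = y[te],
                           pred = factor(as.character(of$pred),
                                         levels = levels(y))),
                      of[c("selected_features", "hyperparameters")])
    }
  } else {
    if (length(unique(subject)) != 1)
      stop("personal framework operates on a single subject's table")
    fold <- .stratifiedFolds(y, outerFolds, spec@seed)
    for (f in seq_len(max(fold))) {
      te <- fold == f
      ytr <- droplevels(y[!te])
      of <- .outerFold(X[!te, , drop = FALSE], ytr, X[te, , drop = FALSE],
                       spec, innerFolds, spec@seed + 101L * f, corThreshold)
      folds[[f]] <- c(list(fold_id = sprintf("fold%02d", f),
                           truth = y[te],
                           pred = factor(as.character(of$pred),
                                         levels = levels(y))),
                      of[c("selected_features", "hyperparameters")])
    }
  }
  new("CVResult", folds = folds, framework = framework,
      resolution = resolution, classLevels = levels(y))
}

#' Run personal models for every subject in a table
#'
#' Applies the personal-framework [nestedCV()] to each subject's epochs
#' separately.
#'
#' @inheritParams nestedCV
#' @return named list of [CVResult-class], one per subject.
#' @export
personalModels <- function(table, spec, resolution = 2, innerFolds = 10,
                           outerFolds = 10, corThreshold = 0.95) {
  cd <- SummarizedExperiment::colData(table)
  subjects <- unique(as.character(cd$subject_id))
  res <- lapply(subjects, function(s)
    nestedCV(table[, cd$subject_id == s], spec, "personal", resolution,
             innerFolds, outerFolds, corThreshold))
  names(res) <- subjects
  res
}

#' Train a final deployable model on a full feature table
#'
#' Prunes correlated features, z-scores within subject, fits the
#' `ModelSpec`'s algorithm with its rebalancing strategy on all rows, and returns a
#' self-contained bundle (selected features, normalization statistics,
#' seed and config) that can be saved with [saveRDS()] and reloaded for
#' identical predictions.
#'
#' @param table an [EpochFeatureTable-class].
#' @param spec a [ModelSpec-class].
#' @param resolution stage resolution (2, 3 or 4).
#' @param params hyperparameters; defaults to the first grid point.
#' @return object of class `"somnoModel"` with a `predict` method taking a
#'   feature matrix (raw scale) and a subject vector.
#' @export
trainFinal <- function(table, spec, resolution = 2, params = NULL) {
  X <- t(SummarizedExperiment::assay(table, "features"))
  cd <- SummarizedExperiment::colData(table)
  subject <- as.character(cd$subject_id)
  y <- factor(as.character(cd[[.labelColumn(as.integer(resolution))]]),
              levels = stageLevels(resolution))
  Xz <- zscoreWithinSubject(X, subject)
  pr <- dropCorrelatedFeatures(Xz)
  if (is.null(params))
    params <- lapply(spec@grid, `[`, 1)
  m <- .fitModel(pr$X, y, spec, params, spec@seed)
  structure(list(model = m, features = pr$kept, params = params,
                 algorithm = spec@algorithm, seed = spec@seed,
                 resolution = as.integer(resolution),
                 classLevels = levels(y)),
            class = "somnoModel")
}

#' @export
predict.somnoModel <- function(object, newdata, subject = NULL, ...) {
  if (is.null(subject)) subject <- rep("s", nrow(newdata))
  Xz <- zscoreWithinSubject(as.matrix(newdata), subject)
  object$model$predict(Xz[, object$features, drop = FALSE])
}

#' @export
print.somnoModel <- function(x, ...) {
  cat("somnoModel:", x$algorithm, "|", x$resolution, "stages |",
      length(x$features), "features | seed", x$seed, "\n")
  invisible(x)
}
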