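# build a CVResult directly from truth/pred label vectors
cvFromLabels <- function(truth, pred, levels, nFolds = 1) {
  idx <- split(seq_along(truth), rep_len(seq_len(nFolds), length(truth)))
  folds <- lapply(seq_along(idx), function(i)
    list(fold_id = paste0("f", i),
         truth = factor(truth[idx[[i]]], levels = levels),
         pred = factor(pred[idx[[i]]], levels = levels),
         selected_features = character(0), hyperparameters = list()))
  new("CVResult", folds = folds, framework = "personal",
      resolution = if (length(levels) %in% 2:4) length(levels) else 2L,
      classLevels = levels)
}

# expand a confusion matrix (rows = truth) into label vectors
labelsFromConfusion <- function(cm, levels) {
  truth <- pred <- character(0)
  for (i in seq_along(levels)) for (j in seq_along(levels)) {
    truth <- c(truth, rep(levels[i], cm[i, j]))
    pred <- c(pred, rep(levels[j], cm[i, j]))
  }
  list(truth = truth, pred = pred)
}

test_that("pooled kappa reproduces the hand confusion-matrix value", {
  cm <- matrix(c(45, 5, 15, 35), 2, byrow = TRUE)
  lp <- labelsFromConfusion(cm, c("Wake", "Sleep"))
  # p_o = 0.8, p_e = 0.5 -> kappa = 0.6 exactly
  expect_equal(pooledKappa(factor(lp$truth), factor(lp$pred)), 0.6)

  cv <- cvFromLabels(lp$truth, lp$pred, c("Wake", "Sleep"), nFolds = 4)
  expect_equal(pooledKappa(cv), 0.6)

  # perfect agreement and constant predictions
  expect_equal(pooledKappa(factor(lp$truth), factor(lp$truth)), 1.0)
  expect_equal(pooledKappa(factor(lp$truth),
                           factor(rep("Wake", 100),
                                  levels = c("Wake", "Sleep"))), 0)
  expect_warning(k <- pooledKappa(factor(rep("Wake", 10)),
                                  factor(rep("Wake", 10))), "single-class")
  expect_true(is.na(k))
})

test_that("pooling equals per-fold kappa when folds share one confusion", {
  cm <- matrix(c(40, 10, 8, 42), 2, byrow = TRUE)
  lp <- labelsFromConfusion(cm, c("Wake", "Sleep"))
  folds <- lapply(1:3, function(i)
    list(fold_id = paste0("f", i),
         truth = factor(lp$truth, levels = c("Wake", "Sleep")),
         pred = factor(lp$pred, levels = c("Wake", "Sleep")),
         selected_features = character(0), hyperparameters = list()))
  cv <- new("CVResult", folds = folds, framework = "personal",
            resolution = 2L, classLevels = c("Wake", "Sleep"))
  perFold <- pooledKappa(factor(lp$truth), factor(lp$pred))
  expect_equal(pooledKappa(cv), perFold)
})

test_that("kappa banding matches the quoted cut points", {
  expect_equal(kappaBand(-0.1), "worse-than-chance")
  expect_equal(kappaBand(0), "slight")
  expect_equal(kappaBand(0.20), "slight")
  expect_equal(kappaBand(0.21), "fair")
  expect_equal(kappaBand(0.40), "fair")
  expect_equal(kappaBand(0.60), "moderate")
  expect_equal(kappaBand(0.66), "substantial")
  expect_equal(kappaBand(0.80), "substantial")
  expect_equal(kappaBand(0.81), "near-perfect")
  expect_equal(kappaBand(1), "near-perfect")
  expect_error(kappaBand(1.2), "\\[-1, 1\\]")
})

test_that("F-beta arithmetic and identities hold", {
  expect_equal(fBetaScore(0.8, 0.6), 2 * 0.48 / 1.4)
  expect_equal(round(fBetaScore(0.8, 0.6), 4), 0.6857)
  for (p in c(0.2, 0.5, 0.9)) expect_equal(fBetaScore(p, p), p)
  expect_equal(fBetaScore(0, 0), 0)
})

test_that("per-class metrics summarize the pooled confusion", {
  withr::local_seed(41)
  lv <- c("Wake", "Light", "Deep", "REM")
  truth <- sample(lv, 400, replace = TRUE, prob = c(0.1, 0.5, 0.15, 0.25))
  pred <- ifelse(runif(400) < 0.7, truth, sample(lv, 400, replace = TRUE))
  cv <- cvFromLabels(truth, pred, lv, nFolds = 5)
  rep <- perClassMetrics(cv)
  expect_s4_class(rep, "MetricsReport")
  expect_equal(rep@nEpochs, 400L)
  expect_equal(sum(rep@confusion), 400)
  expect_true(all(rep@perClass >= 0 & rep@perClass <= 1, na.rm = TRUE))
  # balanced accuracy is the mean per-class sensitivity
  expect_equal(rep@balancedAccuracy, mean(rep@perClass$sensitivity))
  # confusion CSV-style row sums equal per-class truth counts
  expect_equal(unname(rowSums(rep@confusion)),
               as.integer(table(factor(truth, levels = lv))))

  # perfect classifier: everything is 1
  repP <- perClassMetrics(cvFromLabels(truth, truth, lv))
  expect_true(all(abs(as.matrix(repP@perClass) - 1) < 1e-12))
  expect_equal(repP@balancedAccuracy, 1)
  expect_equal(repP@pooledKappa, 1)
})

test_that("two-class balanced accuracy is (sens + spec)/2 of the positive class", {
  withr::local_seed(42)
  lv <- c("Wake", "Sleep")
  truth <- sample(lv, 200, replace = TRUE, prob = c(0.3, 0.7))
  pred <- ifelse(runif(200) < 0.8, truth, sample(lv, 200, replace = TRUE))
  rep <- perClassMetrics(cvFromLabels(truth, pred, lv))
  expect_equal(rep@balancedAccuracy,
               (rep@perClass["Wake", "sensitivity"] +
                rep@perClass["Wake", "specificity"]) / 2)
})

test_that("sleep architecture counts awakenings strictly inside sleep", {
  arch <- sleepArchitecture(c("Wake", "Light", "Light", "Wake", "Wake",
                              "REM", "Wake"))
  expect_equal(totalSleepTime(arch), 1.5)
  expect_equal(nAwakenings(arch), 1L)  # the two-epoch run; trailing Wake excluded
  expect_equal(sum(stagePercentages(arch)), 100)

  allW <- sleepArchitecture(rep("Wake", 10))
  expect_equal(totalSleepTime(allW), 0)
  expect_equal(nAwakenings(allW), 0L)

  noW <- sleepArchitecture(rep(c("Light", "REM"), 5))
  expect_equal(nAwakenings(noW), 0L)
  expect_equal(totalSleepTime(noW), 5)
  expect_equal(unname(stagePercentages(noW)["Light"]), 50)
})

test_that("t-SNE embeds deterministically with shrinking perplexity", {
  withr::local_seed(43)
  X <- rbind(matrix(rnorm(60 * 5), 60, 5),
             matrix(rnorm(60 * 5, mean = 6), 60, 5))
  Y <- tsneEmbedding(X, perplexity = 20, iterations = 120, seed = 2)
  expect_equal(dim(Y), c(120L, 2L))
  Y2 <- tsneEmbedding(X, perplexity = 20, iterations = 120, seed = 2)
  expect_identical(Y, Y2)
  # the two well-separated blobs stay separated in the embedding
  d11 <- mean(dist(Y[1:60, ])); d12 <- mean(as.matrix(dist(Y))[1:60, 61:120])
  expect_gt(d12, d11)
  expect_warning(tsneEmbedding(X[1:20, ], perplexity = 40, iterations = 20),
                 "perplexity shrunk")
})

test_that("on a heterogeneous cohort, features cluster by subject over stage", {
  skip_if_not_installed("cluster")
  coh <- generateCohort(4, heterogeneity = 3, seed = 17, durationH = 0.5)
  tab <- buildFeatureTable(coh)
  X <- scale(t(SummarizedExperiment::assay(tab, "features")))
  cd <- SummarizedExperiment::colData(tab)
  Y <- tsneEmbedding(X, perplexity = 30, iterations = 250, seed = 4)
  d <- dist(Y)
  silSubject <- mean(cluster::silhouette(
    as.integer(factor(cd$subject_id)), d)[, 3])
  silStage <- mean(cluster::silhouette(
    as.integer(factor(cd$label2)), d)[, 3])
  expect_gt(silSubject, silStage)
})

test_that("report bundles are complete and reproducible", {
  withr::local_seed(44)
  lv <- c("Wake", "Sleep")
  truth <- sample(lv, 120, replace = TRUE)
  pred <- ifelse(runif(120) < 0.85, truth, sample(lv, 120, replace = TRUE))
  cv <- cvFromLabels(truth, pred, lv, nFolds = 3)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  arch <- sleepArchitecture(pred)
  writeReport(cv, d1, architecture = arch)
  writeReport(cv, d2, architecture = arch)
  for (f in c("metrics.json", "confusion_counts.csv", "confusion_rowpct.csv",
              "sleep_architecture.json", "summary.md")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # metrics JSON round-trips
  m <- jsonlite::read_json(file.path(d1, "metrics.json"))
  expect_equal(m$pooled_kappa, pooledKappa(cv), tolerance = 1e-12)
  cm <- as.matrix(read.csv(file.path(d1, "confusion_counts.csv"),
                           row.names = 1))
  expect_equal(unname(rowSums(cm)),
               as.integer(table(factor(truth, levels = lv))))
})
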