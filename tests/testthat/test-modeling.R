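test_that("correlation pruning drops duplicates with a strict threshold", {
  withr::local_seed(21)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  Xdup <- cbind(X, a2 = X[, "a"])
  pr <- dropCorrelatedFeatures(Xdup)
  expect_setequal(pr$kept, c("a", "b", "c"))
  expect_equal(pr$dropped, "a2")

  # a pair at exactly r = 0.95 is kept ("greater than" is strict)
  u <- scale(rnorm(n))[, 1]
  v <- scale(residuals(lm(rnorm(n) ~ u)))[, 1]
  y <- 0.95 * u + sqrt(1 - 0.95^2) * v
  Xexact <- cbind(u = u, y = y)
  expect_equal(abs(cor(u, y)), 0.95, tolerance = 1e-12)
  expect_length(dropCorrelatedFeatures(Xexact)$dropped, 0)

  # independent columns are untouched
  expect_length(dropCorrelatedFeatures(X)$dropped, 0)
})

test_that("within-subject z-scoring removes subject baselines", {
  withr::local_seed(22)
  base <- matrix(rnorm(60 * 4), 60, 4,
                 dimnames = list(NULL, paste0("f", 1:4)))
  X <- rbind(base, base + 50)  # same dynamics, shifted baseline
  subj <- rep(c("a", "b"), each = 60)
  Z <- zscoreWithinSubject(X, subj)
  expect_lt(max(abs(colMeans(Z[subj == "a", ]))), 1e-9)
  expect_lt(max(abs(apply(Z[subj == "b", ], 2, sd) - 1)), 1e-9)
  expect_equal(Z[subj == "a", ], Z[subj == "b", ], ignore_attr = TRUE)

  # constant feature maps to zero
  Xc <- cbind(X, cst = rep(7, 120))
  Zc <- zscoreWithinSubject(Xc, subj)
  expect_true(all(Zc[, "cst"] == 0))
})

test_that("rebalancing equalizes class counts as specified", {
  withr::local_seed(23)
  X <- matrix(rnorm(120 * 2), 120, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- factor(rep(c("A", "B"), c(100, 20)))

  un <- rebalance(X, y, "undersample", seed = 7)
  expect_equal(as.integer(table(un$y)), c(20L, 20L))

  sm <- rebalance(X, y, "smote", seed = 7)
  expect_equal(as.integer(table(sm$y)), c(100L, 100L))
  # synthetic minority rows lie on segments between original minority rows
  orig <- X[y == "B", ]
  synth <- sm$X[-seq_len(120), , drop = FALSE]
  onSegment <- apply(synth, 1, function(p) {
    for (i in seq_len(nrow(orig) - 1)) for (j in seq(i + 1, nrow(orig))) {
      ab <- orig[j, ] - orig[i, ]
      lam <- sum((p - orig[i, ]) * ab) / sum(ab^2)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
          sqrt(sum((p - orig[i, ] - lam * ab)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  })
  expect_true(all(onSegment))

  cw <- rebalance(X, y, "classweights", seed = 7)
  expect_equal(nrow(cw$X), 120)
  # inverse-frequency: every class contributes equal total weight
  expect_equal(sum(cw$weights[y == "A"]), sum(cw$weights[y == "B"]))

  # balanced input is left unchanged
  yb <- factor(rep(c("A", "B"), each = 50))
  Xb <- X[1:100, ]
  expect_equal(nrow(rebalance(Xb, yb, "undersample", seed = 1)$X), 100)
  expect_equal(nrow(rebalance(Xb, yb, "smote", seed = 1)$X), 100)

  # degenerate single-member class falls back to oversampling under SMOTE
  y1 <- factor(rep(c("A", "B"), c(119, 1)))
  expect_message(sm1 <- rebalance(X, y1, "smote", seed = 1), "falling back")
  expect_equal(as.integer(table(sm1$y)), c(119L, 119L))
})

test_that("personal nested CV covers every epoch once, stratified", {
  tab <- toyTable(nSubjects = 1, epochsPerSubject = 120, separation = 3,
                  seed = 31)
  spec <- modelSpec("balanced_random_forest",
                    grid = list(num_trees = 50), seed = 5)
  cv <- nestedCV(tab, spec, "personal", resolution = 2, innerFolds = 5)
  expect_s4_class(cv, "CVResult")
  expect_length(cvFolds(cv), 10)
  truths <- pooledTruth(cv)
  expect_length(truths, 120)  # every epoch tested exactly once

  # stratification: fold class counts within one of the expected share
  y <- SummarizedExperiment::colData(tab)$label2
  pWake <- mean(y == "Wake")
  for (f in cvFolds(cv)) {
    nf <- length(f$truth)
    expect_lte(abs(sum(f$truth == "Wake") - pWake * nf), 1 + 1e-9)
  }

  # the separable toy problem is essentially solved
  expect_gt(pooledKappa(cv), 0.8)

  # determinism end to end
  cv2 <- nestedCV(tab, spec, "personal", resolution = 2, innerFolds = 5)
  expect_identical(pooledPred(cv), pooledPred(cv2))
  expect_identical(lapply(cvFolds(cv), `[[`, "hyperparameters"),
                   lapply(cvFolds(cv2), `[[`, "hyperparameters"))
})

test_that("population nested CV leaves one subject out per fold", {
  tab <- toyTable(nSubjects = 5, epochsPerSubject = 60, seed = 32)
  spec <- modelSpec("balanced_random_forest",
                    grid = list(num_trees = 50), seed = 5)
  cv <- nestedCV(tab, spec, "population", resolution = 2, innerFolds = 5)
  expect_length(cvFolds(cv), 5)
  ids <- vapply(cvFolds(cv), `[[`, character(1), "fold_id")
  expect_setequal(ids, unique(SummarizedExperiment::colData(tab)$subject_id))
  expect_length(pooledTruth(cv), 300)
  expect_error(nestedCV(toyTable(nSubjects = 2, seed = 1), spec,
                        "population"), "3 subjects")
  expect_error(nestedCV(tab, spec, "personal"), "single subject")
})

test_that("boosting path with SMOTE trains and predicts deterministically", {
  tab <- toyTable(nSubjects = 1, epochsPerSubject = 100, seed = 33)
  spec <- modelSpec("xgboost",
                    grid = list(num_trees = 30, max_depth = 3,
                                learning_rate = 0.1), seed = 9)
  expect_identical(spec@strategy, "smote")
  cv <- nestedCV(tab, spec, "personal", resolution = 2,
                 innerFolds = 3, outerFolds = 5)
  expect_length(pooledTruth(cv), 100)
  expect_gt(pooledKappa(cv), 0.5)
  cv2 <- nestedCV(tab, spec, "personal", resolution = 2,
                  innerFolds = 3, outerFolds = 5)
  expect_identical(pooledPred(cv), pooledPred(cv2))
})

test_that("final models persist and reload with identical predictions", {
  tab <- toyTable(nSubjects = 2, epochsPerSubject = 80, seed = 34)
  spec <- modelSpec("balanced_bagging", grid = list(num_trees = 50),
                    seed = 3)
  m <- trainFinal(tab, spec, resolution = 2)
  expect_s3_class(m, "somnoModel")
  expect_true(all(m$features %in%
                  SummarizedExperiment::rowData(tab)$feature))
  Xnew <- t(SummarizedExperiment::assay(tab, "features"))
  subj <- SummarizedExperiment::colData(tab)$subject_id
  p1 <- predict(m, Xnew, subject = subj)
  f <- tempfile(fileext = ".rds")
  saveRDS(m, f)
  m2 <- readRDS(f)
  expect_identical(predict(m2, Xnew, subject = subj), p1)
  expect_length(p1, ncol(tab))
})
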