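# Shared synthetic fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixtureNight <- function(durationH = 0.5, seed = 3L, ...) {
  key <- paste("night", durationH, seed, ...)
  if (is.null(.fixtures[[key]])) {
    cfg <- syntheticSubjectConfig("fx", durationH = durationH,
                                  seed = seed, ...)
    hyp <- generateHypnogram(cfg)
    .fixtures[[key]] <- list(config = cfg, hypnogram = hyp,
                             recording = generateRecording(cfg, hyp))
  }
  .fixtures[[key]]
}

fixtureTable <- function(durationH = 0.5, seed = 3L) {
  key <- paste("table", durationH, seed)
  if (is.null(.fixtures[[key]])) {
    fx <- fixtureNight(durationH, seed)
    .fixtures[[key]] <- buildFeatureTable(list(fx))
  }
  .fixtures[[key]]
}

# Small toy feature table for modeling tests: Gaussian features whose means
# shift by class, with optional per-subject baseline offsets.
toyTable <- function(nSubjects = 1, epochsPerSubject = 120, nFeatures = 10,
                     separation = 2, subjectOffset = 0, seed = 1L,
                     pWake = 0.25) {
  withr::with_seed(seed, {
    cds <- list(); mats <- list()
    for (s in seq_len(nSubjects)) {
      lab5 <- sample(c("Wake", "N2"), epochsPerSubject, replace = TRUE,
                     prob = c(pWake, 1 - pWake))
      X <- matrix(rnorm(epochsPerSubject * nFeatures), epochsPerSubject)
      X[lab5 == "Wake", seq_len(3)] <-
        X[lab5 == "Wake", seq_len(3)] + separation
      X <- X + subjectOffset * rnorm(1)
      colnames(X) <- paste0("f", seq_len(nFeatures))
      mats[[s]] <- t(X)
      cds[[s]] <- data.frame(
        subject_id = sprintf("t%02d", s),
        epoch_index = seq_len(epochsPerSubject) - 1L,
        label5 = factor(lab5, levels = c("Wake", "N1", "N2", "N3", "REM")),
        label2 = mapLabels(lab5, 2), label3 = mapLabels(lab5, 3),
        label4 = mapLabels(lab5, 4), valid = TRUE)
    }
    X <- do.call(cbind, mats)
    cd <- do.call(rbind, cds)
    colnames(X) <- sprintf("%s_e%04d", cd$subject_id, cd$epoch_index)
    rownames(cd) <- colnames(X)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(features = X),
      rowData = S4Vectors::DataFrame(
        feature = rownames(X),
        modality = rep("ACC", nrow(X))),
      colData = S4Vectors::DataFrame(cd))
    new("EpochFeatureTable", se)
  })
}

# build an RRSeries-like epoch input from interval values (ms)
peaksFromRR <- function(rr, t0 = 0) t0 + cumsum(rr) / 1000
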