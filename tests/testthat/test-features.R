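test_that("epoch segmentation drops trailing partial epochs", {
  cfg <- syntheticSubjectConfig("a", durationH = 100 / 3600, seed = 2)
  hyp <- generateHypnogram(cfg)  # rounds to 3 epochs
  rec <- generateRecording(cfg, hyp)
  segs <- segmentEpochs(rec, hyp)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$t0, c(0, 30, 60))
  expect_equal(segs$t1, c(30, 60, 90))
})

test_that("accelerometer features follow population conventions", {
  n <- 1560
  cst <- rep(1, n)
  alt <- rep(c(0, 1), n / 2)
  f <- accFeatures(cst, alt, 2 * alt + rnorm(n, 0, 1e-9))
  expect_equal(unname(f["acc_mean_x"]), 1)
  expect_equal(unname(f["acc_sd_x"]), 0)
  expect_equal(unname(f["acc_variance_x"]), 0)
  expect_equal(unname(f["acc_range_x"]), 0)
  expect_equal(unname(f["acc_rms_x"]), 1)
  expect_equal(unname(f["acc_mean_y"]), 0.5)
  expect_equal(unname(f["acc_rms_y"]), sqrt(0.5))
  expect_equal(unname(f["acc_variance_y"]), 0.25)
  # pairs with the constant axis: rho 0, p 1
  expect_equal(unname(f[c("acc_rho_xy", "acc_rho_xz")]), c(0, 0))
  expect_equal(unname(f[c("acc_p_xy", "acc_p_xz")]), c(1, 1))
  # y and z are perfectly correlated by construction
  expect_equal(unname(f["acc_rho_yz"]), 1, tolerance = 1e-6)
  expect_lt(unname(f["acc_p_yz"]), 1e-10)
  expect_length(f, 33)

  # ordering invariants on random data
  withr::with_seed(5, {
    g <- accFeatures(rnorm(n), rnorm(n), rnorm(n))
    for (ax in c("x", "y", "z")) {
      expect_equal(unname(g[paste0("acc_range_", ax)]),
                   unname(g[paste0("acc_max_", ax)] -
                          g[paste0("acc_min_", ax)]))
      expect_equal(unname(g[paste0("acc_variance_", ax)]),
                   unname(g[paste0("acc_sd_", ax)])^2)
    }
  })
})

test_that("HRV time-domain features match hand enumeration", {
  rr <- c(800, 820, 845, 900)
  f <- ecgFeatures(rr, peaksFromRR(rr), 0, 30)
  # successive diffs {20, 25, 55}; strict inequality
  expect_equal(unname(f["nn20"]), 2)
  expect_equal(unname(f["nn50"]), 1)
  expect_equal(unname(f["pnn20"]), 200 / 3, tolerance = 1e-9)
  expect_equal(unname(f["pnn50"]), 100 / 3, tolerance = 1e-9)
  expect_equal(unname(f["rr_mean"]), mean(rr))
  expect_equal(unname(f["hr_min"]), 60000 / 900)

  cst <- rep(1000, 10)
  g <- ecgFeatures(cst, peaksFromRR(cst), 0, 30)
  expect_equal(unname(g["sdnn"]), 0)
  expect_equal(unname(g["rmssd"]), 0)
  expect_equal(unname(g["hr_mean"]), 60)

  expect_null(ecgFeatures(c(800, 900), c(1, 2), 0, 30))
  expect_length(f, 19)
})

test_that("a pure 0.25 Hz tachogram puts its power in the HF band", {
  t <- 0; peaks <- numeric(0); rr <- numeric(0)
  while (t < 30) {
    iv <- 1000 + 50 * sin(2 * pi * 0.25 * t)
    t <- t + iv / 1000
    peaks <- c(peaks, t); rr <- c(rr, iv)
  }
  f <- ecgFeatures(rr, peaks, 0, 30)
  expect_lt(abs(f[["hf_peak"]] - 0.25), 1 / 30)  # window-limited resolution
  expect_gte(f[["hf_power"]], 10 * f[["lf_power"]])
  expect_gt(f[["lf_hf_ratio"]], 0)
})

test_that("temperature features implement the distal-proximal gradient", {
  f <- tempFeatures(rep(35.5, 30), rep(34.0, 30))
  expect_equal(unname(f["dpg_mean"]), -1.5)
  expect_equal(unname(f["dpg_range"]), 0)

  g <- tempFeatures(rep(35, 3), rep(35, 3))
  expect_true(all(g[c("dpg_mean", "dpg_min", "dpg_max")] == 0))

  h <- tempFeatures(c(35, 35, 35), c(33, 34, 35))
  expect_equal(unname(h[c("dpg_mean", "dpg_min", "dpg_max", "dpg_range")]),
               c(-1, -2, 0, 2))
  expect_null(tempFeatures(numeric(0), rep(35, 3)))
})

test_that("oximetry features count desaturation time and events", {
  cst <- rep(98, 150)
  f <- spo2Features(cst, prevMean = 98)
  expect_true(all(f[c(paste0("tsa", c(95, 90, 85, 80, 70)),
                      paste0("odi", 2:5), "spo2_variance", "spo2_di")] == 0))

  # 10 samples at 88 (2 s below 90), previous epoch mean 97
  dip <- c(rep(97, 70), rep(88, 10), rep(97, 70))
  g <- spo2Features(dip, prevMean = 97)
  expect_equal(unname(g["tsa90"]), 2.0)
  expect_equal(unname(g["tsa85"]), 0)
  expect_true(all(g[paste0("odi", 2:5)] == 1))

  # two separated shallow dips to 94: two ODI3 events, no ODI5 events
  two <- c(rep(97, 40), rep(94, 10), rep(97, 50), rep(94, 10), rep(97, 40))
  h <- spo2Features(two, prevMean = 97)
  expect_equal(unname(h["odi3"]), 2)
  expect_equal(unname(h["odi5"]), 0)

  # no previous epoch: ODI defined as 0
  expect_true(all(spo2Features(dip, prevMean = NA)[paste0("odi", 2:5)] == 0))
  expect_length(f, 15)
})

test_that("stage labels collapse per the 2/3/4-stage mappings", {
  expect_equal(as.character(mapLabels("N3", 4)), "Deep")
  expect_equal(as.character(mapLabels("N1", 2)), "Sleep")
  expect_equal(as.character(mapLabels(c("N1", "N2"), 4)),
               c("Light", "Light"))
  expect_equal(as.character(mapLabels("REM", 3)), "REM")
  for (k in 2:4)
    expect_equal(as.character(mapLabels("Wake", k)), "Wake")
  expect_error(mapLabels("Dozing", 2), "unknown stage")
  expect_error(mapLabels("Wake", 5))
})

test_that("the assembled feature table is complete, finite and ordered", {
  tab <- fixtureTable()
  expect_s4_class(tab, "EpochFeatureTable")
  expect_equal(nrow(tab), 73)
  expect_equal(ncol(tab), 60)  # clean 0.5 h night: every epoch valid
  expect_equal(nrow(S4Vectors::metadata(tab)$excluded), 0)
  X <- SummarizedExperiment::assay(tab, "features")
  expect_true(all(is.finite(X)))

  md <- table(SummarizedExperiment::rowData(tab)$modality)
  expect_equal(as.integer(md[c("ACC", "ECG", "TEMP", "SPO2")]),
               c(33L, 19L, 6L, 15L))

  # per-epoch ordering invariants across the whole night
  expect_true(all(X["pnn50", ] <= X["pnn20", ] + 1e-12))
  expect_true(all(X["nn50", ] <= X["nn20", ]))
  tsa <- X[paste0("tsa", c(70, 80, 85, 90, 95)), , drop = FALSE]
  expect_true(all(diff(tsa) >= 0))            # TSA70 <= ... <= TSA95
  expect_true(all(tsa >= 0 & tsa <= 30))
  odi <- X[paste0("odi", c(5, 4, 3, 2)), , drop = FALSE]
  expect_true(all(diff(odi) >= 0))            # ODI5 <= ... <= ODI2
  for (ax in c("x", "y", "z"))
    expect_equal(unname(X[paste0("acc_variance_", ax), ]),
                 unname(X[paste0("acc_sd_", ax), ])^2, tolerance = 1e-9)
  expect_equal(unname(X["acc_range_x", ]),
               unname(X["acc_max_x", ] - X["acc_min_x", ]))

  # feature extraction is pure: rebuilding gives the identical table
  tab2 <- buildFeatureTable(list(fixtureNight()))
  expect_identical(SummarizedExperiment::assay(tab2, "features"), X)
})

test_that("epochs failing the physiological screen are excluded", {
  fx <- fixtureNight()
  rec <- injectSpo2Dip(fx$recording, epochIndex = 20, value = 45)
  rec <- injectBradycardia(rec, epochIndex = 40, bpm = 34)
  tab <- buildFeatureTable(list(list(config = fx$config, recording = rec,
                                     hypnogram = fx$hypnogram)))
  excl <- S4Vectors::metadata(tab)$excluded
  expect_equal(sort(excl$epoch_index), c(20, 40))
  expect_setequal(excl$reason,
                  c("spo2_min_below_50", "hr_min_below_40"))
  expect_equal(ncol(tab), 58)
  expect_false(any(SummarizedExperiment::colData(tab)$epoch_index
                   %in% c(20, 40)))
})
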