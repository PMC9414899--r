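# Brute-force reference implementations, kept deliberately naive (explicit
# loops, no shared code with the package) so they can serve as independent
# oracles for the vectorized package functions.

oracle_nn <- function(rr, x) {
  cnt <- 0L
  for (i in seq_len(length(rr) - 1L))
    if (abs(rr[i + 1L] - rr[i]) > x) cnt <- cnt + 1L
  cnt
}

oracle_pnn <- function(rr, x) 100 * oracle_nn(rr, x) / (length(rr) - 1L)

oracle_sdnn <- function(rr) {
  m <- 0
  for (v in rr) m <- m + v
  m <- m / length(rr)
  s <- 0
  for (v in rr) s <- s + (v - m)^2
  sqrt(s / length(rr))
}

oracle_rmssd <- function(rr) {
  s <- 0
  n <- length(rr) - 1L
  for (i in seq_len(n)) s <- s + (rr[i + 1L] - rr[i])^2
  sqrt(s / n)
}

oracle_tsa <- function(spo2, threshold, fs = 5) {
  cnt <- 0L
  for (v in spo2) if (v < threshold) cnt <- cnt + 1L
  cnt / fs
}

# events = maximal runs >= 2 points below the previous-epoch mean; an event
# counts toward ODIx when its deepest sample reaches x points below
oracle_odi <- function(spo2, prevMean, threshold) {
  if (is.na(prevMean)) return(0L)
  events <- 0L
  inRun <- FALSE
  depth <- 0
  for (v in c(spo2, prevMean)) {   # sentinel closes a trailing run
    below <- (prevMean - v) >= 2
    if (below) {
      if (!inRun) depth <- 0
      depth <- max(depth, prevMean - v)
    } else if (inRun && depth >= threshold) events <- events + 1L
    inRun <- below
  }
  events
}

oracle_dpg <- function(chest, limb) {
  n <- min(length(chest), length(limb))
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- limb[i] - chest[i]
  c(mean = sum(d) / n, min = min(d), max = max(d),
    range = max(d) - min(d))
}

oracle_kappa <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  cls <- sort(unique(c(truth, pred)))
  n <- length(truth)
  po <- 0
  for (i in seq_len(n)) if (truth[i] == pred[i]) po <- po + 1
  po <- po / n
  pe <- 0
  for (cl in cls) {
    nt <- 0; np <- 0
    for (i in seq_len(n)) {
      if (truth[i] == cl) nt <- nt + 1
      if (pred[i] == cl) np <- np + 1
    }
    pe <- pe + (nt / n) * (np / n)
  }
  (po - pe) / (1 - pe)
}

oracle_class_f1 <- function(truth, pred, cl) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
    if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
    if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
}

oracle_balanced_accuracy <- function(truth, pred) {
  cls <- sort(unique(as.character(truth)))
  recalls <- numeric(length(cls))
  for (j in seq_along(cls)) {
    tp <- 0; nt <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cls[j]) {
        nt <- nt + 1
        if (pred[i] == cls[j]) tp <- tp + 1
      }
    }
    recalls[j] <- tp / nt
  }
  mean(recalls)
}

# stationary distribution of a row-stochastic matrix by eigen-decomposition
oracle_stationary <- function(tm) {
  e <- eigen(t(tm))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}
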