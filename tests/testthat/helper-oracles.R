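# Independent oracles used to validate the package's algorithms.
# These deliberately use different algorithms from the implementation:
# exhaustive enumeration instead of dynamic programming, definitional
# formulas instead of the packaged metric code, pairwise comparison
# instead of the trapezoidal ROC construction.

rand_rna <- function(n) paste(sample(c("A", "U", "G", "C"), n,
                                     replace = TRUE), collapse = "")

# Exhaustive enumeration of every antiparallel duplex structure: chains of
# canonical pairs (i ascending on strand a, j descending on strand b) with
# stack energies for adjacent pairs and the linear loop penalty otherwise.
brute_duplex_mfe <- function(a, b, params = mircnn::default_duplex_params()) {
  x <- match(strsplit(a, "", fixed = TRUE)[[1]], c("A", "U", "G", "C"))
  y <- match(strsplit(b, "", fixed = TRUE)[[1]], c("A", "U", "G", "C"))
  n <- length(x); m <- length(y)
  cp <- unname(params$can_pair)
  best <- 0
  step_energy <- function(pi, pj, i, j) {
    if (i == pi + 1L && j == pj - 1L) {
      params$stack[x[pi], x[i], y[pj], y[j]]
    } else {
      params$loop_base + params$loop_per_nt * ((i - pi - 1L) + (pj - j - 1L))
    }
  }
  rec <- function(pi, pj, acc) {
    if (pi >= n || pj <= 1L) return(invisible())
    for (i in (pi + 1L):n) {
      for (j in seq_len(pj - 1L)) {
        if (!cp[x[i], y[j]]) next
        e <- acc + step_energy(pi, pj, i, j)
        if (e < best) best <<- e
        rec(i, j, e)
      }
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (!cp[x[i], y[j]]) next
      e <- params$init
      if (e < best) best <- e
      rec(i, j, e)
    }
  }
  best
}

# Definitional metric formulas, written independently of the package.
oracle_metrics <- function(TP, TN, FP, FN) {
  den_mcc <- sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN) * sqrt(TP + FP)
  list(
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else 0,
    specificity = if (TN + FP > 0) TN / (TN + FP) else 0,
    f1 = if (2 * TP + FP + FN > 0) (2 * TP) / (2 * TP + FP + FN) else 0,
    mcc = if (den_mcc > 0) (TP * TN - FP * FN) / den_mcc else 0,
    accuracy = (TP + TN) / (TP + TN + FP + FN))
}

# AUC as the Mann-Whitney probability that a random positive outscores a
# random negative (ties count one half).
oracle_auc_mw <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Brute-force anti-complementarity scan: counts length-4 windows of `pad`
# that are the exact antiparallel Watson-Crick complement of any length-4
# window of `mirna`.
count_pad_pair_hits <- function(pad, mirna) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  pb <- strsplit(pad, "", fixed = TRUE)[[1]]
  mb <- strsplit(mirna, "", fixed = TRUE)[[1]]
  hits <- 0L
  if (length(pb) < 4L || length(mb) < 4L) return(0L)
  for (i in seq_len(length(pb) - 3L)) {
    for (j in seq_len(length(mb) - 3L)) {
      w <- pb[i:(i + 3L)]
      v <- mb[j:(j + 3L)]
      if (all(w == comp[rev(v)])) hits <- hits + 1L
    }
  }
  hits
}

# Tiny dataset-table factory for structural tests.
toy_table <- function(n, seed = 1L) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    data.frame(
      chimera_seq = vapply(seq_len(n), function(i) rand_rna(110),
                           character(1)),
      label = rep_len(c(1L, 0L), n),
      stringsAsFactors = FALSE)
  })
}
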