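# Independent naive reference implementations ("oracles"). These deliberately
# use explicit per-element loops and no code from R/, so that agreement with
# the package's vectorized implementations is meaningful.

oracle_grid <- seq(0, 1, by = 0.01)

# per-term AUPR: descending-threshold step integration, explicit counting
oracle_term_aupr <- function(scores, truth) {
  auc <- 0
  rc_prev <- 0
  for (t in rev(oracle_grid)) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(scores)) {
      pred <- scores[i] >= t
      if (pred && truth[i] == 1) tp <- tp + 1
      if (pred && truth[i] == 0) fp <- fp + 1
      if (!pred && truth[i] == 1) fn <- fn + 1
    }
    if (tp + fp == 0) next
    pr <- tp / (tp + fp)
    rc <- tp / (tp + fn)
    auc <- auc + (rc - rc_prev) * pr
    rc_prev <- rc
  }
  auc
}

oracle_macro_aupr <- function(P, Y) {
  vals <- c()
  for (j in seq_len(ncol(Y))) {
    if (sum(Y[, j]) == 0) next
    vals <- c(vals, oracle_term_aupr(P[, j], Y[, j]))
  }
  mean(vals)
}

oracle_fmax <- function(P, Y) {
  n <- nrow(P)
  best <- -Inf; best_t <- NA
  for (t in oracle_grid) {
    prs <- c(); rcs <- numeric(n)
    for (i in seq_len(n)) {
      tp <- 0; np <- 0; nt <- 0
      for (j in seq_len(ncol(P))) {
        pred <- P[i, j] >= t
        if (pred) np <- np + 1
        if (Y[i, j] == 1) nt <- nt + 1
        if (pred && Y[i, j] == 1) tp <- tp + 1
      }
      if (np > 0) prs <- c(prs, tp / np)
      rcs[i] <- if (nt > 0) tp / nt else 0
    }
    if (!length(prs)) next
    avg_pr <- mean(prs); avg_rc <- mean(rcs)
    if (avg_pr + avg_rc == 0) next
    f <- 2 * avg_pr * avg_rc / (avg_pr + avg_rc)
    if (f > best) { best <- f; best_t <- t }
  }
  list(fmax = best, threshold = best_t)
}

oracle_mcc <- function(P, Y, t) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    pred <- P[i, j] >= t
    if (pred && Y[i, j] == 1) tp <- tp + 1
    if (pred && Y[i, j] == 0) fp <- fp + 1
    if (!pred && Y[i, j] == 1) fn <- fn + 1
    if (!pred && Y[i, j] == 0) tn <- tn + 1
  }
  den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# Smin oracle: naive nested loops; `anc` maps term -> ancestor terms (used to
# close predicted sets), `cic` maps term -> conditional IC.
oracle_smin <- function(P, Y, cic, anc) {
  terms <- colnames(P)
  n <- nrow(P)
  best <- Inf
  for (t in oracle_grid) {
    ru <- 0; mi <- 0
    for (i in seq_len(n)) {
      pred <- terms[P[i, ] >= t]
      closed <- pred
      for (p in pred) closed <- union(closed, anc[[p]])
      closed <- intersect(closed, terms)
      truth <- terms[Y[i, ] == 1]
      for (c in setdiff(truth, closed)) ru <- ru + cic[[c]]
      for (c in setdiff(closed, truth)) mi <- mi + cic[[c]]
    }
    s <- sqrt((ru / n)^2 + (mi / n)^2)
    if (s < best) best <- s
  }
  best
}

# Dense naive GCN evaluation (explicit normalization matrices).
oracle_gcn <- function(X, A, weights) {
  At <- A + diag(nrow(A))
  Dm <- diag(1 / sqrt(rowSums(At)))
  S <- Dm %*% At %*% Dm
  H <- X
  for (W in weights) H <- pmax(S %*% H %*% W, 0)
  H
}

oracle_softmax_row <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# BFS transitive closure of the parent relation for one term.
oracle_closure <- function(dag, terms) {
  out <- terms
  queue <- terms
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    for (p in dag$parents[[t]]) {
      if (!p %in% out) {
        out <- c(out, p)
        queue <- c(queue, p)
      }
    }
  }
  sort(out)
}

# Central finite-difference gradient of scalar-valued fn(params) w.r.t.
# selected entries of each parameter matrix.
fd_grad_entries <- function(fn, params, name, entries, h = 1e-5) {
  vapply(seq_len(nrow(entries)), function(k) {
    i <- entries[k, 1]; j <- entries[k, 2]
    up <- params; up[[name]][i, j] <- up[[name]][i, j] + h
    dn <- params; dn[[name]][i, j] <- dn[[name]][i, j] - h
    (fn(up) - fn(dn)) / (2 * h)
  }, numeric(1))
}

# Deterministic sample of entry indices from a matrix (all if small).
pick_entries <- function(mat, max_n = 12L, seed = 1L) {
  idx <- which(array(TRUE, dim(mat)), arr.ind = TRUE)
  if (nrow(idx) <= max_n) return(idx)
  set.seed(seed)
  idx[sample(nrow(idx), max_n), , drop = FALSE]
}
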