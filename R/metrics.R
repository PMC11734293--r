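# CAFA evaluation metrics: function-centric AUPR, protein-centric Fmax, MCC
# at the Fmax threshold, and the information-theoretic Smin. All metrics use
# the same threshold grid t in {0.00, 0.01, ..., 1.00}; "predicted at t"
# means score >= t.

metric_grid <- function() seq(0, 1, by = 0.01)

#' Area under the precision-recall curve for one GO term
#'
#' Step-wise integration over the 101-point threshold grid visited in
#' descending order (so recall increments are non-negative):
#' AUPR_f = sum_t (rc_f(t) - rc_f(t_prev)) * pr_f(t). Thresholds at which no
#' protein is predicted positive are skipped.
#'
#' @param scores numeric n-vector of predicted scores in \[0, 1\].
#' @param truth binary n-vector with at least one positive.
#' @return scalar in \[0, 1\].
#' @export
term_aupr <- function(scores, truth) {
  npos <- sum(truth)
  if (npos < 1L) stop("term has no positive proteins; exclude it from evaluation")
  auc <- 0
  rc_prev <- 0
  for (t in rev(metric_grid())) {
    pred <- scores >= t
    if (!any(pred)) next
    tp <- sum(pred & truth == 1)
    pr <- tp / sum(pred)
    rc <- tp / npos
    auc <- auc + (rc - rc_prev) * pr
    rc_prev <- rc
  }
  auc
}

#' Macro-averaged function-centric AUPR
#'
#' Unweighted mean of [term_aupr()] over the terms with at least one positive
#' test protein (N_f counts evaluable terms only).
#'
#' @param P n x C score matrix.
#' @param Y n x C binary truth matrix.
#' @return scalar; per-term values in attribute "per_term".
#' @export
macro_aupr <- function(P, Y) {
  P <- as.matrix(P); Y <- as.matrix(Y)
  if (!all(dim(P) == dim(Y))) stop("P and Y shapes differ")
  evaluable <- which(colSums(Y) > 0)
  if (!length(evaluable)) stop("no terms with a positive test protein")
  per <- vapply(evaluable, function(j) term_aupr(P[, j], Y[, j]), numeric(1))
  names(per) <- colnames(P)[evaluable]
  structure(mean(per), per_term = per)
}

#' Protein-centric Fmax
#'
#' At each threshold t, precision is averaged over the m(t) proteins with at
#' least one score >= t and recall over all n proteins; Fmax is the maximum
#' harmonic mean over the grid. Thresholds with m(t) = 0 are skipped; ties in
#' the maximum resolve toward the smaller threshold.
#'
#' @param P n x C score matrix (every protein needs >= 1 true term).
#' @param Y n x C binary truth matrix.
#' @return list(fmax, threshold).
#' @export
fmax <- function(P, Y) {
  P <- as.matrix(P); Y <- as.matrix(Y)
  if (!all(dim(P) == dim(Y))) stop("P and Y shapes differ")
  empty <- which(rowSums(Y) == 0)
  if (length(empty))
    stop("protein(s) with empty truth: ",
         paste(if (is.null(rownames(Y))) empty else rownames(Y)[empty],
               collapse = ", "))
  n <- nrow(P)
  best <- -Inf; best_t <- NA_real_
  for (t in metric_grid()) {
    pred <- P >= t
    npred <- rowSums(pred)
    sel <- npred > 0
    if (!any(sel)) next
    tp <- rowSums(pred & Y == 1)
    avg_pr <- mean((tp / npred)[sel])
    avg_rc <- mean(tp / rowSums(Y))
    if (avg_pr + avg_rc == 0) next
    f <- 2 * avg_pr * avg_rc / (avg_pr + avg_rc)
    if (f > best) {
      best <- f
      best_t <- t
    }
  }
  list(fmax = best, threshold = best_t)
}

#' Matthews correlation coefficient at the Fmax threshold
#'
#' All n x C protein-term pairs are binarized at score >= t and pooled into a
#' single (micro) confusion matrix. If any factor of the denominator is zero
#' the MCC is defined as 0.
#'
#' @param P n x C score matrix.
#' @param Y n x C binary truth matrix.
#' @param threshold binarization threshold, typically `fmax(P, Y)$threshold`.
#' @return scalar in \[-1, 1\].
#' @export
mcc_at_fmax <- function(P, Y, threshold) {
  pred <- as.matrix(P) >= threshold
  truth <- as.matrix(Y) == 1
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  mcc_from_counts(tp, tn, fp, fn)
}

mcc_from_counts <- function(tp, tn, fp, fn) {
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
}

#' Minimum semantic distance Smin
#'
#' For each threshold, remaining uncertainty ru(t) is the mean over proteins
#' of the summed conditional IC of true-but-unpredicted terms and
#' misinformation mi(t) the mean conditional IC of predicted-but-untrue
#' terms; Smin = min_t sqrt(ru^2 + mi^2). Both truth and predicted sets are
#' closed under ancestor propagation before the set differences.
#'
#' @param P n x C score matrix (columns named by term id).
#' @param Y n x C binary truth matrix (propagation-closed).
#' @param ic an [compute_ic()] table providing conditional IC per term.
#' @param dag ontology used to close predicted sets; NULL skips closure
#'   (e.g. when scores are already hierarchy-consistent).
#' @return list(smin, threshold, ru, mi).
#' @export
smin <- function(P, Y, ic, dag = NULL) {
  P <- as.matrix(P); Y <- as.matrix(Y)
  terms <- colnames(P)
  if (is.null(terms)) stop("P must have term ids as column names")
  missing_ic <- setdiff(terms, ic$term)
  if (length(missing_ic))
    stop("term(s) missing conditional IC: ", paste(missing_ic, collapse = ", "))
  cic <- stats::setNames(ic$cond_ic, ic$term)[terms]
  anc <- if (is.null(dag)) NULL else ancestor_map(dag)
  n <- nrow(P)
  grid <- metric_grid()
  best <- Inf; best_t <- NA_real_; best_ru <- NA_real_; best_mi <- NA_real_
  true_sets <- lapply(seq_len(n), function(i) terms[Y[i, ] == 1])
  for (t in grid) {
    ru <- 0; mi <- 0
    for (i in seq_len(n)) {
      pred <- terms[P[i, ] >= t]
      if (!is.null(anc) && length(pred))
        pred <- intersect(unique(c(pred, unlist(anc[pred], use.names = FALSE))),
                          terms)
      ti <- true_sets[[i]]
      ru <- ru + sum(cic[setdiff(ti, pred)])
      mi <- mi + sum(cic[setdiff(pred, ti)])
    }
    ru <- ru / n; mi <- mi / n
    s <- sqrt(ru^2 + mi^2)
    if (s < best) {
      best <- s; best_t <- t; best_ru <- ru; best_mi <- mi
    }
  }
  list(smin = best, threshold = best_t, ru = best_ru, mi = best_mi)
}

#' Evaluate a prediction matrix with all CAFA metrics
#'
#' @param P n x C score matrix (columns named by term).
#' @param Y n x C binary truth matrix.
#' @param ic optional IC table (enables Smin).
#' @param dag optional ontology (closes predicted sets for Smin; enables the
#'   per-IC-bucket AUPR breakdown when `ic` is given).
#' @return list of class `eval_result` with aupr, fmax, threshold, mcc, smin
#'   and per-term/per-bucket tables.
#' @export
evaluate_predictions <- function(P, Y, ic = NULL, dag = NULL) {
  au <- macro_aupr(P, Y)
  fm <- fmax(P, Y)
  res <- list(
    aupr = as.numeric(au),
    per_term_aupr = attr(au, "per_term"),
    fmax = fm$fmax,
    threshold = fm$threshold,
    mcc = mcc_at_fmax(P, Y, fm$threshold)
  )
  if (!is.null(ic)) {
    sm <- smin(P, Y, ic, dag)
    res$smin <- sm$smin
    res$smin_threshold <- sm$threshold
    per <- res$per_term_aupr
    bucket <- ic_category(stats::setNames(ic$ic, ic$term)[names(per)])
    res$aupr_by_ic <- tapply(per, bucket, mean)
  }
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("AUPR=%.4f Fmax=%.4f (t*=%.2f) MCC=%.4f%s\n",
              x$aupr, x$fmax, x$threshold, x$mcc,
              if (is.null(x$smin)) "" else sprintf(" Smin=%.4f", x$smin)))
  invisible(x)
}

#' Read / write CAFA-style prediction TSV
#'
#' Format: `protein_id<TAB>GO_term<TAB>score`, scores rounded to 3 decimals
#' on writing.
#'
#' @param P n x C score matrix with protein row names and term column names.
#' @param path file path.
#' @export
write_predictions <- function(P, path) {
  df <- data.frame(
    protein = rep(rownames(P), times = ncol(P)),
    term = rep(colnames(P), each = nrow(P)),
    score = sprintf("%.3f", as.numeric(P))
  )
  df <- df[order(df$protein, df$term), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @param terms optional term vocabulary defining the column order.
#' @export
read_predictions <- function(path, terms = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("protein", "term", "score"))
  prot <- unique(df$protein)
  if (is.null(terms)) terms <- sort(unique(df$term))
  P <- matrix(0, length(prot), length(terms), dimnames = list(prot, terms))
  keep <- df$term %in% terms
  P[cbind(match(df$protein[keep], prot), match(df$term[keep], terms))] <-
    df$score[keep]
  P
}
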