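# The three training objectives and their combination. Exported functions
# evaluate the losses on plain matrices (natural logarithms everywhere, with
# probabilities clipped to [eps, 1-eps] before any log); the training loop
# builds the same quantities on the autodiff tape and the test suite asserts
# both paths agree.

LOSS_EPS <- 1e-7

clip_prob <- function(p, eps = LOSS_EPS) pmin(pmax(p, eps), 1 - eps)

#' Supervised multilabel binary cross-entropy
#'
#' Mean over all M x C protein-term pairs of the binary cross-entropy between
#' predicted probabilities and binary labels.
#'
#' @param yhat M x C matrix of probabilities in (0, 1).
#' @param y M x C binary label matrix.
#' @return non-negative scalar (natural-log units).
#' @export
supervised_bce <- function(yhat, y) {
  yhat <- as.matrix(yhat); y <- as.matrix(y)
  if (!all(dim(yhat) == dim(y))) stop("yhat and y shapes differ")
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  p <- clip_prob(yhat)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Entropy-aware sample weight for the adversarial loss
#'
#' The multilabel prediction entropy is the mean per-class binary entropy
#' H(yhat) = mean_c -\[p log p + (1-p) log(1-p)\]; the weight
#' w = 1 + exp(-H) lies in (1, 2\] and up-weights confidently predicted
#' (easier to transfer) samples.
#'
#' @param yhat probability vector (length C) or M x C matrix (one weight per
#'   row).
#' @return scalar (or vector) weight in (1, 2\].
#' @export
entropy_weight <- function(yhat) {
  Y <- if (is.matrix(yhat)) yhat else matrix(yhat, nrow = 1L)
  p <- clip_prob(Y)
  H <- rowMeans(-(p * log(p) + (1 - p) * log(1 - p)))
  w <- 1 + exp(-H)
  if (is.matrix(yhat)) w else w[[1L]]
}

#' Entropy-conditioned adversarial domain loss
#'
#' Binary cross-entropy of the domain discriminator evaluated on the
#' randomized multilinear map of (embedding, prediction) pairs, with
#' per-sample entropy weights computed on detached predictions:
#' L_adv = -(1/M) sum_i w_i^s log D(T(z_i^s, yhat_i^s))
#'         -(1/M) sum_j w_j^t log(1 - D(T(z_j^t, yhat_j^t))).
#'
#' @param z_s,yhat_s M x D and M x C source batch.
#' @param z_t,yhat_t M x D and M x C target batch.
#' @param model a [gala_model()] (its discriminator and frozen R matrices).
#' @return scalar loss (natural-log units).
#' @export
adversarial_loss <- function(z_s, yhat_s, z_t, yhat_t, model) {
  if (nrow(z_s) != nrow(z_t)) stop("source/target batch sizes differ")
  M <- nrow(z_s)
  Tm_s <- t(apply(cbind(seq_len(M)), 1L, function(i)
    multilinear_map(z_s[i, ], yhat_s[i, ], model$frozen$R_z, model$frozen$R_y)))
  Tm_t <- t(apply(cbind(seq_len(M)), 1L, function(i)
    multilinear_map(z_t[i, ], yhat_t[i, ], model$frozen$R_z, model$frozen$R_y)))
  D_s <- clip_prob(discriminate(Tm_s, model))
  D_t <- clip_prob(discriminate(Tm_t, model))
  w_s <- entropy_weight(yhat_s)
  w_t <- entropy_weight(yhat_t)
  -mean(w_s * log(D_s)) - mean(w_t * log(1 - D_t))
}

#' Contrastive label embedding alignment loss
#'
#' With s_ij the cosine similarity between graph embedding z_i and label
#' embedding b_j,
#' L_con = -(1/M) sum_i log( exp(s_ii/tau) / sum_{j != i} exp(s_ij/tau) ).
#' As printed the positive pair is excluded from the denominator, so the loss
#' can be negative; `include_positive = TRUE` gives the standard InfoNCE
#' form.
#'
#' @param z M x D graph embeddings (M >= 2).
#' @param b M x D label embeddings.
#' @param tau temperature.
#' @param include_positive include the positive pair in the denominator.
#' @return scalar loss.
#' @export
alignment_loss <- function(z, b, tau = 0.1, include_positive = FALSE) {
  z <- as.matrix(z); b <- as.matrix(b)
  if (nrow(z) < 2L) stop("alignment loss needs a batch of at least 2")
  if (any(sqrt(rowSums(z^2)) == 0) || any(sqrt(rowSums(b^2)) == 0))
    stop("cannot normalize a zero-norm row vector")
  tp <- tape_new()
  zn <- tp_rownorm(tp, tp_leaf(tp, z))
  bn <- tp_rownorm(tp, tp_leaf(tp, b))
  sim <- tp_mm(tp, zn, bn, tb = TRUE)
  tp_val(tp, tp_align_loss(tp, sim, tau, include_positive))
}

#' Total training loss
#'
#' Unweighted sum of the supervised, adversarial and alignment losses.
#'
#' @param l_sup,l_adv,l_con scalar loss parts (defaults 0 for disabled parts).
#' @return list of class `loss_breakdown` with fields l_sup, l_adv, l_con,
#'   l_total.
#' @export
total_loss <- function(l_sup, l_adv = 0, l_con = 0) {
  parts <- list(l_sup = l_sup, l_adv = l_adv, l_con = l_con)
  for (nm in names(parts)) {
    if (!is.finite(parts[[nm]])) stop("non-finite loss part: ", nm)
  }
  parts$l_total <- l_sup + l_adv + l_con
  class(parts) <- "loss_breakdown"
  parts
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total=%.4f (sup=%.4f adv=%.4f con=%.4f)\n",
              x$l_total, x$l_sup, x$l_adv, x$l_con))
  invisible(x)
}
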