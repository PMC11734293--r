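# Forward computation of the graph transformer. Every exported operation
# evaluates through the autodiff tape (single code path for values and
# gradients); the internal forward_batch() is what training, prediction and
# Grad-CAM build on.
#
# Architecture: N-layer GCN over the contact map with symmetric normalization
# and self-loops -> per-head meta-node attention (K learnable queries attend
# over residue keys/values produced by two single-layer GCNs shared across
# heads) -> concatenation + one-hidden-layer MLP merge -> attention pooling
# over the K meta-nodes -> linear classifier with sigmoid outputs.

# Start a tape with one leaf per parameter tensor.
fwd_start <- function(model) {
  tp <- tape_new(1024L)
  pid <- lapply(model$params, function(w) tp_leaf(tp, w))
  list(tp = tp, pid = pid)
}

# GCN stack: H^{l+1} = ReLU(S H^l W^l), H^0 = X, with S the normalized
# adjacency (self-loops added). Dropout masks (if given) are applied between
# layers, inverted-scale convention.
gcn_stack_tp <- function(ctx, Xid, S, n_layers, masks = NULL, prefix = "gcn_W") {
  tp <- ctx$tp
  H <- Xid
  for (l in seq_len(n_layers)) {
    H <- tp_spmm(tp, S, H)
    H <- tp_mm(tp, H, ctx$pid[[paste0(prefix, l)]])
    H <- tp_relu(tp, H)
    if (!is.null(masks) && l < n_layers) H <- tp_mulconst(tp, H, masks[[l]])
  }
  H
}

# Keys / values from single-layer GCNs on top of H (shared across heads).
key_value_tp <- function(ctx, Hid, S) {
  tp <- ctx$tp
  K <- tp_relu(tp, tp_mm(tp, tp_spmm(tp, S, Hid), ctx$pid$att_key_W))
  V <- tp_relu(tp, tp_mm(tp, tp_spmm(tp, S, Hid), ctx$pid$att_val_W))
  list(K = K, V = V)
}

# One head of meta-node attention on one graph's keys/values:
# Gamma = softmax(Q K^T / sqrt(D)) V.
meta_attention_tp <- function(ctx, Kid, Vid, head, D) {
  tp <- ctx$tp
  scores <- tp_scale(tp, tp_mm(tp, ctx$pid[[paste0("att_q", head)]], Kid, tb = TRUE),
                     1 / sqrt(D))
  W <- tp_softmax_rows(tp, scores)
  list(gamma = tp_mm(tp, W, Vid), weights = W)
}

# Concatenate heads and merge with the one-hidden-layer MLP FC1.
merge_heads_tp <- function(ctx, gamma_ids) {
  tp <- ctx$tp
  conc <- tp_concat_cols(tp, gamma_ids)
  hidden <- tp_relu(tp, tp_addbias(tp, tp_mm(tp, conc, ctx$pid$fc1_W1), ctx$pid$fc1_b1))
  tp_addbias(tp, tp_mm(tp, hidden, ctx$pid$fc1_W2), ctx$pid$fc1_b2)
}

# Attention pooling over meta-nodes: z = softmax(q (U K)^T / sqrt(D)) U V.
pool_tp <- function(ctx, Uid, D) {
  tp <- ctx$tp
  UK <- tp_mm(tp, Uid, ctx$pid$pool_K)
  scores <- tp_scale(tp, tp_mm(tp, ctx$pid$pool_q, UK, tb = TRUE), 1 / sqrt(D))
  W <- tp_softmax_rows(tp, scores)
  list(z = tp_mm(tp, tp_mm(tp, W, Uid), ctx$pid$pool_V), weights = W)
}

# Two-layer label projector b = P(y): linear -> ReLU -> linear.
projector_tp <- function(ctx, Yid) {
  tp <- ctx$tp
  hid <- tp_relu(tp, tp_addbias(tp, tp_mm(tp, Yid, ctx$pid$proj_W1), ctx$pid$proj_b1))
  tp_addbias(tp, tp_mm(tp, hid, ctx$pid$proj_W2), ctx$pid$proj_b2)
}

# Discriminator probability with clipping to (eps, 1-eps).
discriminator_tp <- function(ctx, Tid, eps = 1e-7) {
  tp <- ctx$tp
  hid <- tp_relu(tp, tp_addbias(tp, tp_mm(tp, Tid, ctx$pid$disc_W1), ctx$pid$disc_b1))
  out <- tp_sigmoid(tp, tp_addbias(tp, tp_mm(tp, hid, ctx$pid$disc_W2), ctx$pid$disc_b2))
  tp_clip(tp, out, eps, 1 - eps)
}

# Multilinear map T(z, yhat) = (1/sqrt(d)) (z R_z^T) elementwise* (yhat R_y^T)
# for row-stacked batches.
multilinear_tp <- function(ctx, Zid, Yhatid, model) {
  tp <- ctx$tp
  d <- model$config$multilinear_dim
  Rz <- tp_leaf(tp, model$frozen$R_z)
  Ry <- tp_leaf(tp, model$frozen$R_y)
  tp_scale(tp, tp_mul(tp, tp_mm(tp, Zid, Rz, tb = TRUE),
                      tp_mm(tp, Yhatid, Ry, tb = TRUE)), 1 / sqrt(d))
}

# Full batched forward over a disjoint union of graphs. Graph adjacencies are
# combined block-diagonally so no cross-graph edges or attention exist;
# results match per-graph evaluation. Returns tape ids for the batched node
# embeddings H (the Grad-CAM feature map), per-graph rows, stacked z, logits
# and sigmoid probabilities.
forward_batch <- function(model, graphs, training = FALSE, Slist = NULL) {
  if (!length(graphs)) stop("empty graph batch")
  sizes <- vapply(graphs, function(g) nchar(g$sequence), integer(1))
  if (any(sizes < 1L)) stop("empty graph in batch")
  cfg <- model$config
  ctx <- fwd_start(model)
  tp <- ctx$tp
  if (is.null(Slist)) Slist <- lapply(graphs, function(g) norm_adjacency(g$adjacency))
  S <- if (length(graphs) == 1L) Slist[[1]] else Matrix::bdiag(Slist)
  X <- do.call(rbind, lapply(graphs, function(g) g$features))
  if (ncol(X) != cfg$feature_dim)
    stop("feature dimensionality ", ncol(X), " does not match model (",
         cfg$feature_dim, ")")
  masks <- NULL
  if (training && cfg$dropout > 0 && cfg$n_layers > 1L) {
    keep <- 1 - cfg$dropout
    masks <- lapply(seq_len(cfg$n_layers - 1L), function(l) {
      matrix(stats::rbinom(nrow(X) * cfg$dim, 1L, keep) / keep, nrow(X), cfg$dim)
    })
  }
  Xid <- tp_leaf(tp, X)
  Hid <- gcn_stack_tp(ctx, Xid, S, cfg$n_layers, masks)
  kv <- key_value_tp(ctx, Hid, S)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rows <- lapply(seq_along(graphs), function(i) starts[i]:ends[i])
  att_rows <- list()
  zids <- integer(length(graphs))
  for (i in seq_along(graphs)) {
    Kg <- tp_slice_rows(tp, kv$K, rows[[i]])
    Vg <- tp_slice_rows(tp, kv$V, rows[[i]])
    gammas <- integer(cfg$heads)
    wts <- vector("list", cfg$heads)
    for (k in seq_len(cfg$heads)) {
      att <- meta_attention_tp(ctx, Kg, Vg, k, cfg$dim)
      gammas[k] <- att$gamma
      wts[[k]] <- tp_val(tp, att$weights)
    }
    Uid <- merge_heads_tp(ctx, gammas)
    pl <- pool_tp(ctx, Uid, cfg$dim)
    zids[i] <- pl$z
    att_rows[[i]] <- list(meta = wts, pool = tp_val(tp, pl$weights))
  }
  Zid <- if (length(zids) == 1L) zids[1] else tp_rbind(tp, zids)
  logits <- tp_addbias(tp, tp_mm(tp, Zid, ctx$pid$clf_W), ctx$pid$clf_b)
  yhat <- tp_sigmoid(tp, logits)
  list(ctx = ctx, tp = tp, Hid = Hid, rows = rows, Zid = Zid,
       logits_id = logits, yhat_id = yhat, attention = att_rows)
}

#' GCN forward pass
#'
#' Applies the layer-wise rule H^{l+1} = ReLU(D^{-1/2} (A+I) D^{-1/2} H^l W^l)
#' with H^0 = X and returns the final embedding matrix H.
#'
#' @param X |V| x F feature matrix.
#' @param A binary symmetric adjacency (zero diagonal).
#' @param weights list of layer weight matrices (F x D, then D x D).
#' @return |V| x D embedding matrix.
#' @export
gcn_forward <- function(X, A, weights) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(A)) stop("X rows (", nrow(X), ") do not match A (", nrow(A), ")")
  tp <- tape_new()
  ctx <- list(tp = tp, pid = stats::setNames(
    lapply(weights, function(w) tp_leaf(tp, w)),
    paste0("gcn_W", seq_along(weights))
  ))
  Hid <- gcn_stack_tp(ctx, tp_leaf(tp, X), norm_adjacency(A), length(weights))
  tp_val(tp, Hid)
}

#' Meta-node attention for one head
#'
#' Keys and values are produced by two single-layer GCNs over the final node
#' embeddings; the K learnable meta-node queries of the requested head attend
#' over the |V| residues: Gamma = softmax(Q K^T / sqrt(D)) V.
#'
#' @param H |V| x D node embedding matrix.
#' @param A adjacency matrix.
#' @param model a [gala_model()].
#' @param head head index in 1..heads.
#' @return K x D meta-node embedding matrix; attention weights (rows summing
#'   to 1 over residues) in attribute "weights".
#' @export
meta_node_attention <- function(H, A, model, head = 1L) {
  ctx <- fwd_start(model)
  Hid <- tp_leaf(ctx$tp, as.matrix(H))
  kv <- key_value_tp(ctx, Hid, norm_adjacency(A))
  att <- meta_attention_tp(ctx, kv$K, kv$V, head, model$config$dim)
  structure(tp_val(ctx$tp, att$gamma), weights = tp_val(ctx$tp, att$weights))
}

#' Merge per-head meta-node embeddings
#'
#' Concatenates the h head matrices along the feature axis and maps back to
#' K x D through the one-hidden-layer MLP FC1.
#'
#' @param gammas list of h K x D matrices.
#' @param model a [gala_model()].
#' @return K x D merged meta-node embedding matrix U.
#' @export
multihead_merge <- function(gammas, model) {
  shapes <- vapply(gammas, function(g) paste(dim(g), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L)
    stop("head shape mismatch: ", paste(shapes, collapse = ", "))
  ctx <- fwd_start(model)
  ids <- vapply(gammas, function(g) tp_leaf(ctx$tp, as.matrix(g)), integer(1))
  tp_val(ctx$tp, merge_heads_tp(ctx, ids))
}

#' Attention pooling of meta-nodes into a graph embedding
#'
#' z = softmax(q_P (U K_P)^T / sqrt(D)) U V_P, with the softmax taken over
#' the K meta-nodes.
#'
#' @param U K x D meta-node embedding matrix.
#' @param model a [gala_model()].
#' @return length-D graph embedding; pooling weights in attribute "weights".
#' @export
attention_pool <- function(U, model) {
  ctx <- fwd_start(model)
  Uid <- tp_leaf(ctx$tp, as.matrix(U))
  pl <- pool_tp(ctx, Uid, model$config$dim)
  structure(as.numeric(tp_val(ctx$tp, pl$z)), weights = tp_val(ctx$tp, pl$weights))
}

#' Classify a graph embedding
#'
#' @param z length-D embedding (or M x D matrix).
#' @param model a [gala_model()].
#' @return probabilities in (0,1)^C with the pre-sigmoid logits (used by
#'   Grad-CAM) in attribute "logits".
#' @export
classify <- function(z, model) {
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  if (any(!is.finite(Z))) stop("z must be finite")
  ctx <- fwd_start(model)
  Zid <- tp_leaf(ctx$tp, Z)
  logits <- tp_addbias(ctx$tp, tp_mm(ctx$tp, Zid, ctx$pid$clf_W), ctx$pid$clf_b)
  probs <- tp_val(ctx$tp, tp_sigmoid(ctx$tp, logits))
  eps <- 1e-7
  structure(pmin(pmax(probs, eps), 1 - eps), logits = tp_val(ctx$tp, logits))
}

#' Embed a binary label vector in the representation space
#'
#' b = P(y) with P a two-layer MLP (linear -> ReLU -> linear).
#'
#' @param y binary vector of length C (or M x C matrix).
#' @param model a [gala_model()].
#' @return embedding of dimension D (matrix if y was a matrix).
#' @export
embed_labels <- function(y, model) {
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  if (!all(Y %in% c(0, 1))) stop("y must be binary")
  ctx <- fwd_start(model)
  B <- tp_val(ctx$tp, projector_tp(ctx, tp_leaf(ctx$tp, Y)))
  if (is.matrix(y)) B else as.numeric(B)
}

#' Randomized multilinear map
#'
#' T(z, yhat) = (1/sqrt(d)) (R_z z) * (R_y yhat) with * the elementwise
#' product; R_z and R_y are the model's frozen random matrices (or supplied
#' explicitly).
#'
#' @param z embedding vector (length dim(z)).
#' @param yhat predicted probability vector (length C).
#' @param R_z d x dim(z) matrix.
#' @param R_y d x C matrix.
#' @return vector of dimension d.
#' @export
multilinear_map <- function(z, yhat, R_z, R_y) {
  if (ncol(R_z) != length(z) || ncol(R_y) != length(yhat) ||
      nrow(R_z) != nrow(R_y))
    stop("multilinear map shape mismatch")
  d <- nrow(R_z)
  as.numeric((R_z %*% z) * (R_y %*% yhat)) / sqrt(d)
}

#' Domain discriminator probability
#'
#' Two-layer MLP with sigmoid output, interpreted as the probability that the
#' sample comes from the source domain; clipped to (eps, 1-eps).
#'
#' @param T_vec multilinear-map vector of dimension d (or M x d matrix).
#' @param model a [gala_model()].
#' @return probability in (0, 1).
#' @export
discriminate <- function(T_vec, model) {
  Tm <- if (is.matrix(T_vec)) T_vec else matrix(T_vec, nrow = 1L)
  ctx <- fwd_start(model)
  out <- tp_val(ctx$tp, discriminator_tp(ctx, tp_leaf(ctx$tp, Tm)))
  if (is.matrix(T_vec)) out else as.numeric(out)
}

#' Full forward pass over a batch of protein graphs
#'
#' Graphs are batched as a disjoint union (block-diagonal adjacency with a
#' graph-membership index), so no cross-graph edges or attention exist and
#' the result equals per-graph evaluation.
#'
#' @param graphs list of [protein_graph()] objects.
#' @param model a [gala_model()].
#' @return list with `z` (M x D graph embeddings), `yhat` (M x C sigmoid
#'   probabilities), `logits` (M x C), `H` (stacked final GCN feature maps)
#'   and `rows` (per-graph row indices into H).
#' @export
gala_forward <- function(graphs, model) {
  fb <- forward_batch(model, graphs, training = FALSE)
  ids <- vapply(graphs, function(g) g$id, character(1))
  z <- tp_val(fb$tp, fb$Zid); rownames(z) <- ids
  yhat <- tp_val(fb$tp, fb$yhat_id); rownames(yhat) <- ids
  logits <- tp_val(fb$tp, fb$logits_id); rownames(logits) <- ids
  list(z = z, yhat = yhat, logits = logits,
       H = tp_val(fb$tp, fb$Hid), rows = fb$rows, attention = fb$attention)
}
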