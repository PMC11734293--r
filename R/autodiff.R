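# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every differentiable computation in the package (GCN stack, meta-node
# attention, pooling, classifier, projector, discriminator, losses) is
# recorded on a tape of nodes; tp_backward() replays it in reverse to
# accumulate gradients. Nodes are referenced by integer id. Values are base R
# matrices (scalars are 1x1 matrices or length-1 numerics). Gradients are
# validated against central finite differences in the test suite.

tape_new <- function(capacity = 512L) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", capacity)
  tp$parents <- vector("list", capacity)
  tp$backs <- vector("list", capacity)
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, parents = NULL, back = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    grow <- length(tp$vals)
    tp$vals <- c(tp$vals, vector("list", grow))
    tp$parents <- c(tp$parents, vector("list", grow))
    tp$backs <- c(tp$backs, vector("list", grow))
  }
  tp$vals[[n]] <- value
  tp$parents[[n]] <- parents
  tp$backs[[n]] <- back
  tp$n <- n
  n
}

tp_val <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

# Leaf node: a parameter or constant input. Leaves have no backward function;
# their accumulated gradient is read out after tp_backward().
tp_leaf <- function(tp, value) tp_push(tp, value)

# Dense matrix product with optional transposes: op(A) %*% op(B).
tp_mm <- function(tp, a, b, ta = FALSE, tb = FALSE) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  val <- if (!ta && !tb) A %*% B
  else if (ta && !tb) crossprod(A, B)
  else if (!ta && tb) tcrossprod(A, B)
  else t(B %*% A)
  tp_push(tp, val, c(a, b), function(g) {
    if (!ta && !tb) list(tcrossprod(g, B), crossprod(A, g))
    else if (ta && !tb) list(tcrossprod(B, g), A %*% g)
    else if (!ta && tb) list(g %*% B, crossprod(g, A))
    else list(t(g %*% B), t(A %*% g))
  })
}

# Sparse (constant) times dense node: S %*% H with S a symmetric sparse matrix
# such as a normalized adjacency. Only H carries gradient.
tp_spmm <- function(tp, S, h) {
  force(h)
  H <- tp$vals[[h]]
  tp_push(tp, as.matrix(S %*% H), h, function(g) {
    list(as.matrix(Matrix::crossprod(S, g)))
  })
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b), function(g) list(g, g))
}

# Add a 1 x ncol bias row vector node to every row of a matrix node.
tp_addbias <- function(tp, a, bias) {
  force(a); force(bias)
  A <- tp$vals[[a]]; B <- tp$vals[[bias]]
  val <- sweep(A, 2L, as.numeric(B), `+`)
  tp_push(tp, val, c(a, bias), function(g) {
    list(g, matrix(colSums(g), nrow = 1L))
  })
}

tp_addconst <- function(tp, a, k) {
  force(a)
  tp_push(tp, tp$vals[[a]] + k, a, function(g) list(g))
}

tp_scale <- function(tp, a, k) {
  force(a)
  tp_push(tp, tp$vals[[a]] * k, a, function(g) list(g * k))
}

tp_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  tp_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

# Elementwise product with a constant matrix (e.g. a dropout mask).
tp_mulconst <- function(tp, a, M) {
  force(a)
  tp_push(tp, tp$vals[[a]] * M, a, function(g) list(g * M))
}

tp_relu <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  val <- pmax(A, 0)
  tp_push(tp, val, a, function(g) list(g * (A > 0)))
}

tp_sigmoid <- function(tp, a) {
  force(a)
  S <- 1 / (1 + exp(-tp$vals[[a]]))
  tp_push(tp, S, a, function(g) list(g * S * (1 - S)))
}

tp_log <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  tp_push(tp, log(A), a, function(g) list(g / A))
}

# Clamp to [lo, hi]; subgradient zero where clipped.
tp_clip <- function(tp, a, lo, hi) {
  force(a)
  A <- tp$vals[[a]]
  inside <- A > lo & A < hi
  tp_push(tp, pmin(pmax(A, lo), hi), a, function(g) list(g * inside))
}

# Row-wise softmax. Jacobian-vector product: S * (g - rowSums(g * S)).
tp_softmax_rows <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  A <- A - apply(A, 1L, max)
  E <- exp(A)
  S <- E / rowSums(E)
  tp_push(tp, S, a, function(g) list(S * (g - rowSums(g * S))))
}

# Normalize every row to unit Euclidean norm.
tp_rownorm <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  r <- sqrt(rowSums(A^2))
  if (any(r == 0)) stop("cannot normalize a zero-norm row vector")
  N <- A / r
  tp_push(tp, N, a, function(g) {
    list(g / r - A * (rowSums(g * A) / r^3))
  })
}

tp_concat_cols <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tp$vals[[i]])
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_push(tp, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

tp_rbind <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tp$vals[[i]])
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_push(tp, do.call(rbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

tp_slice_rows <- function(tp, a, idx) {
  force(a)
  A <- tp$vals[[a]]
  nr <- nrow(A); nc <- ncol(A)
  tp_push(tp, A[idx, , drop = FALSE], a, function(g) {
    G <- matrix(0, nr, nc)
    G[idx, ] <- g
    list(G)
  })
}

tp_sum <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  tp_push(tp, sum(A), a, function(g) list(array(g, dim(A))))
}

tp_element <- function(tp, a, i, j) {
  force(a)
  A <- tp$vals[[a]]
  tp_push(tp, A[i, j], a, function(g) {
    G <- matrix(0, nrow(A), ncol(A))
    G[i, j] <- g
    list(G)
  })
}

# Mean binary cross-entropy over all entries, with probability clipping folded
# in (zero subgradient where clipped). `y` is a constant binary matrix.
tp_bce <- function(tp, yhat, y, eps = 1e-7) {
  force(yhat)
  P <- tp$vals[[yhat]]
  inside <- P > eps & P < 1 - eps
  Pc <- pmin(pmax(P, eps), 1 - eps)
  nobs <- length(Pc)
  val <- -sum(y * log(Pc) + (1 - y) * log(1 - Pc)) / nobs
  tp_push(tp, val, yhat, function(g) {
    list(g * inside * (-(y / Pc) + (1 - y) / (1 - Pc)) / nobs)
  })
}

# Contrastive label-alignment loss from an M x M cosine-similarity matrix
# (rows: graph embeddings, columns: label embeddings). As printed in the
# model's objective the positive pair is EXCLUDED from the denominator, so the
# loss can be negative; `include_positive` switches to the standard InfoNCE
# denominator.
tp_align_loss <- function(tp, sim, tau, include_positive = FALSE) {
  force(sim)
  S <- tp$vals[[sim]]
  M <- nrow(S)
  if (M < 2L) stop("alignment loss needs a batch of at least 2")
  E <- exp(S / tau)
  denomE <- E
  if (!include_positive) diag(denomE) <- 0
  denom <- rowSums(denomE)
  val <- -mean(diag(S) / tau - log(denom))
  tp_push(tp, val, sim, function(g) {
    Grad <- (denomE / denom) / (M * tau)       # d(log denom)/dS
    diag(Grad) <- diag(Grad) - 1 / (M * tau)   # d(-s_ii/tau)/dS
    list(g * Grad)
  })
}

# Reverse sweep from node `id` (typically a scalar loss). Returns a list of
# gradients indexed by node id; leaves hold the parameter gradients.
tp_backward <- function(tp, id, seed = 1) {
  grads <- vector("list", tp$n)
  v <- tp$vals[[id]]
  grads[[id]] <- if (is.matrix(v)) array(seed, dim(v)) else seed
  for (k in seq.int(id, 1L)) {
    g <- grads[[k]]
    if (is.null(g)) next
    back <- tp$backs[[k]]
    if (is.null(back)) next
    pg <- back(g)
    ps <- tp$parents[[k]]
    for (m in seq_along(ps)) {
      gm <- pg[[m]]
      if (is.null(gm)) next
      pid <- ps[[m]]
      grads[[pid]] <- if (is.null(grads[[pid]])) gm else grads[[pid]] + gm
    }
  }
  grads
}
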