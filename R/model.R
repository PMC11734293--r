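# Model configuration, parameter initialization and checkpointing.

#' Model configuration
#'
#' Architecture hyperparameters. Defaults are desk-scale choices: `n_layers`
#' GCN layers of width `dim`, `meta_nodes` learnable query vectors per
#' attention head, `heads` attention heads, a randomized multilinear map of
#' dimension `multilinear_dim` conditioning the domain discriminator, and
#' temperature `tau` for the contrastive label-alignment loss.
#'
#' @param feature_dim node feature dimension F (25 for one-hot only).
#' @param n_classes number of GO terms C in the label vocabulary.
#' @param n_layers number of GCN layers N.
#' @param dim hidden embedding dimension D.
#' @param meta_nodes number of meta-node queries K.
#' @param heads number of attention heads h.
#' @param multilinear_dim dimension d of the randomized multilinear map.
#' @param tau contrastive temperature.
#' @param dropout dropout rate between GCN layers during training.
#' @param disc_hidden discriminator hidden width.
#' @param include_positive_in_denominator if TRUE the alignment loss uses the
#'   standard InfoNCE denominator (positive pair included); default FALSE
#'   keeps the printed form which excludes it.
#' @param seed integer governing parameter initialization and the frozen
#'   random projection matrices.
#' @return list of class `gala_config`.
#' @export
gala_config <- function(feature_dim, n_classes, n_layers = 2L, dim = 128L,
                        meta_nodes = 8L, heads = 4L, multilinear_dim = 512L,
                        tau = 0.1, dropout = 0.2, disc_hidden = NULL,
                        include_positive_in_denominator = FALSE, seed = 1L) {
  cfg <- list(
    feature_dim = as.integer(feature_dim), n_classes = as.integer(n_classes),
    n_layers = as.integer(n_layers), dim = as.integer(dim),
    meta_nodes = as.integer(meta_nodes), heads = as.integer(heads),
    multilinear_dim = as.integer(multilinear_dim), tau = tau,
    dropout = dropout,
    disc_hidden = as.integer(if (is.null(disc_hidden)) dim else disc_hidden),
    include_positive_in_denominator = include_positive_in_denominator,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_layers >= 1, cfg$dim >= 1, cfg$meta_nodes >= 1,
            cfg$heads >= 1, cfg$multilinear_dim >= 1, cfg$tau > 0,
            cfg$dropout >= 0, cfg$dropout < 1)
  class(cfg) <- "gala_config"
  cfg
}

glorot <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Construct a model with freshly initialized parameters
#'
#' Weights use Glorot-uniform initialization, biases start at zero. The two
#' random projection matrices of the multilinear map are sampled exactly once
#' here from the standard normal distribution (a symmetric distribution with
#' unit variance) and are never updated; they are serialized with the model.
#'
#' @param config a [gala_config()].
#' @return object of class `gala_model` with fields `params` (named list of
#'   matrices), `frozen` (R_z, R_y), `config`.
#' @export
gala_model <- function(config) {
  stopifnot(inherits(config, "gala_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  Fd <- config$feature_dim; D <- config$dim; C <- config$n_classes
  K <- config$meta_nodes; h <- config$heads; d <- config$multilinear_dim
  Dh <- config$disc_hidden
  p <- list()
  for (l in seq_len(config$n_layers)) {
    p[[paste0("gcn_W", l)]] <- glorot(if (l == 1L) Fd else D, D)
  }
  for (k in seq_len(h)) {
    p[[paste0("att_q", k)]] <- glorot(K, D)
  }
  p$att_key_W <- glorot(D, D)
  p$att_val_W <- glorot(D, D)
  p$fc1_W1 <- glorot(h * D, D); p$fc1_b1 <- matrix(0, 1, D)
  p$fc1_W2 <- glorot(D, D);     p$fc1_b2 <- matrix(0, 1, D)
  p$pool_q <- glorot(1, D)
  p$pool_K <- glorot(D, D)
  p$pool_V <- glorot(D, D)
  p$clf_W <- glorot(D, C); p$clf_b <- matrix(0, 1, C)
  p$proj_W1 <- glorot(C, D); p$proj_b1 <- matrix(0, 1, D)
  p$proj_W2 <- glorot(D, D); p$proj_b2 <- matrix(0, 1, D)
  p$disc_W1 <- glorot(d, Dh); p$disc_b1 <- matrix(0, 1, Dh)
  p$disc_W2 <- glorot(Dh, 1); p$disc_b2 <- matrix(0, 1, 1)
  frozen <- list(
    R_z = matrix(stats::rnorm(d * D), d, D),
    R_y = matrix(stats::rnorm(d * C), d, C)
  )
  structure(list(params = p, frozen = frozen, config = config),
            class = "gala_model")
}

#' @export
print.gala_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<gala_model: %d GCN layers, D=%d, K=%d meta-nodes, %d heads, d=%d, C=%d (%d parameters)>\n",
    x$config$n_layers, x$config$dim, x$config$meta_nodes, x$config$heads,
    x$config$multilinear_dim, x$config$n_classes, np))
  invisible(x)
}

# names of the discriminator parameter tensors (their own optimizer)
disc_param_names <- function(model) {
  grep("^disc_", names(model$params), value = TRUE)
}

#' Save / load a model checkpoint
#'
#' A single archive holding all learnable parameters, the frozen random
#' matrices, the configuration and the seed; reloading is bit-exact.
#'
#' @param model a `gala_model` (or trained state, see [gala_train()]).
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint file: ", path)
  readRDS(path)
}
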