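# Domain-adversarial training loop. Each step samples a mini-batch of M
# graphs from the labeled source domain and M from the unlabeled target
# domain, runs the batched forward for both, and combines three objectives:
#   l_sup  supervised BCE on the source batch,
#   l_adv  entropy-weighted discriminator BCE on the multilinear map of both
#          batches (only when the target domain is used),
#   l_con  contrastive label-embedding alignment on the source batch.
# The discriminator descends on l_adv with its own SGD optimizer; the
# encoder/classifier/projector descend on l_sup + l_con - lambda * l_adv
# (gradient reversal at the multilinear-map input) with Adam.

#' Training configuration
#'
#' @param batch_size M, graphs per domain per step (>= 2 when label alignment
#'   is on).
#' @param epochs passes over the source set; the target iterator cycles
#'   independently.
#' @param lr Adam learning rate for encoder/classifier/projector.
#' @param disc_lr,disc_momentum SGD settings for the domain discriminator.
#' @param lambda gradient-reversal coefficient.
#' @param use_target_domain ablation flag "adv": train the discriminator
#'   adversarially against the unlabeled target domain.
#' @param use_label_alignment ablation flag "cl": add the contrastive
#'   label-embedding alignment loss.
#' @param patience early-stopping patience in epochs on validation Fmax
#'   (0 disables early stopping; requires validation data).
#' @param seed governs batch sampling order and dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, epochs = 10L, lr = 1e-4,
                         disc_lr = 0.03, disc_momentum = 0.9, lambda = 1.0,
                         use_target_domain = TRUE, use_label_alignment = TRUE,
                         patience = 10L, seed = 1L) {
  cfg <- list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              lr = lr, disc_lr = disc_lr, disc_momentum = disc_momentum,
              lambda = lambda, use_target_domain = isTRUE(use_target_domain),
              use_label_alignment = isTRUE(use_label_alignment),
              patience = as.integer(patience), seed = as.integer(seed))
  if (cfg$use_label_alignment && cfg$batch_size < 2L)
    stop("label alignment requires batch_size >= 2")
  class(cfg) <- "train_config"
  cfg
}

adam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}

sgd_new <- function(params, lr, momentum = 0.9) {
  list(lr = lr, momentum = momentum, v = lapply(params, function(p) p * 0))
}

sgd_step <- function(opt, params, grads) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$v[[nm]] <- opt$momentum * opt$v[[nm]] + g
    params[[nm]] <- params[[nm]] - opt$lr * opt$v[[nm]]
  }
  list(opt = opt, params = params)
}

# Build all enabled losses on one tape and return scalar ids plus values.
# Entropy weights for l_adv are computed on detached predictions.
build_losses <- function(model, fb_s, Y_s, fb_t, tcfg) {
  tp <- fb_s$tp
  ctx <- fb_s$ctx
  l_sup_id <- tp_bce(tp, fb_s$yhat_id, Y_s, LOSS_EPS)
  l_con_id <- NULL
  if (tcfg$use_label_alignment) {
    Bid <- projector_tp(ctx, tp_leaf(tp, Y_s))
    zn <- tp_rownorm(tp, fb_s$Zid)
    bn <- tp_rownorm(tp, Bid)
    sim <- tp_mm(tp, zn, bn, tb = TRUE)
    l_con_id <- tp_align_loss(tp, sim, model$config$tau,
                              model$config$include_positive_in_denominator)
  }
  l_adv_id <- NULL
  if (tcfg$use_target_domain) {
    M <- nrow(Y_s)
    T_s <- multilinear_tp(ctx, fb_s$Zid, fb_s$yhat_id, model)
    T_t <- multilinear_tp(ctx, fb_t$Zid, fb_t$yhat_id, model)
    D_s <- discriminator_tp(ctx, T_s)
    D_t <- discriminator_tp(ctx, T_t)
    w_s <- matrix(entropy_weight(tp_val(tp, fb_s$yhat_id)), ncol = 1L)
    w_t <- matrix(entropy_weight(tp_val(tp, fb_t$yhat_id)), ncol = 1L)
    src <- tp_sum(tp, tp_mulconst(tp, tp_log(tp, D_s), w_s))
    tgt <- tp_sum(tp, tp_mulconst(
      tp, tp_log(tp, tp_addconst(tp, tp_scale(tp, D_t, -1), 1)), w_t))
    l_adv_id <- tp_scale(tp, tp_add(tp, src, tgt), -1 / M)
  }
  list(tp = tp, ctx = ctx, l_sup = l_sup_id, l_adv = l_adv_id, l_con = l_con_id)
}

# Map leaf gradients back to parameter names.
param_grads <- function(ctx, grads) {
  out <- lapply(ctx$pid, function(id) grads[[id]])
  out[!vapply(out, is.null, logical(1))]
}

#' Train a model with domain-adversarial alignment
#'
#' @param model a freshly constructed (or resumed) [gala_model()].
#' @param source list(graphs, labels): labeled source-domain graphs with an
#'   M x C binary label matrix aligned to the model's term vocabulary.
#' @param target list(graphs): unlabeled target-domain graphs (required when
#'   `use_target_domain`); labels are never read.
#' @param config a [train_config()].
#' @param validation optional list(graphs, labels) for per-epoch
#'   protein-centric Fmax logging and early stopping/model selection.
#' @param log_file optional path; per-step loss breakdowns are appended as
#'   JSON lines.
#' @param verbose print per-epoch progress.
#' @return object of class `gala_trained`: fields `model` (best checkpoint),
#'   `final_model`, `history` (per-step losses), `epoch_log`, `config`.
#' @export
gala_train <- function(model, source, target = NULL, config = train_config(),
                       validation = NULL, log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "gala_model"), inherits(config, "train_config"))
  n_s <- length(source$graphs)
  if (n_s < 1L) stop("empty source domain")
  if (config$use_target_domain && length(target$graphs) < 1L)
    stop("empty target domain but use_target_domain is on")
  Y <- as.matrix(source$labels)
  if (nrow(Y) != n_s) stop("source labels do not match source graphs")
  M <- min(config$batch_size, n_s)
  if (config$use_label_alignment && M < 2L)
    stop("label alignment requires batch_size >= 2")

  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  S_src <- lapply(source$graphs, function(g) norm_adjacency(g$adjacency))
  S_tgt <- if (config$use_target_domain)
    lapply(target$graphs, function(g) norm_adjacency(g$adjacency))
  params <- model$params
  opt_main <- adam_new(params, config$lr)
  disc_names <- disc_param_names(model)
  main_names <- setdiff(names(params), disc_names)
  opt_disc <- sgd_new(params[disc_names], config$disc_lr, config$disc_momentum)

  history <- list()
  epoch_log <- list()
  best_fmax <- -Inf
  best_params <- params
  stall <- 0L
  step <- 0L
  tgt_pool <- integer(0)
  con <- if (!is.null(log_file)) file(log_file, "w")
  if (!is.null(con)) on.exit(close(con))

  for (epoch in seq_len(config$epochs)) {
    order_s <- sample.int(n_s)
    nsteps <- ceiling(n_s / M)
    for (s in seq_len(nsteps)) {
      take <- order_s[((((s - 1L) * M) + seq_len(M) - 1L) %% n_s) + 1L]
      model$params <- params
      fb_s <- forward_batch(model, source$graphs[take], training = TRUE,
                            Slist = S_src[take])
      fb_t <- NULL
      if (config$use_target_domain) {
        if (length(tgt_pool) < M)
          tgt_pool <- c(tgt_pool, sample.int(length(target$graphs)))
        jt <- tgt_pool[seq_len(M)]
        tgt_pool <- tgt_pool[-seq_len(M)]
        fb_t <- forward_batch_shared(model, target$graphs[jt], fb_s$ctx,
                                     training = TRUE, Slist = S_tgt[jt])
      }
      ls <- build_losses(model, fb_s, Y[take, , drop = FALSE], fb_t, config)
      l_sup <- tp_val(ls$tp, ls$l_sup)
      l_adv <- if (is.null(ls$l_adv)) 0 else tp_val(ls$tp, ls$l_adv)
      l_con <- if (is.null(ls$l_con)) 0 else tp_val(ls$tp, ls$l_con)
      if (!is.finite(l_sup)) stop("NaN/Inf in l_sup at step ", step + 1L)
      if (!is.finite(l_adv)) stop("NaN/Inf in l_adv at step ", step + 1L)
      if (!is.finite(l_con)) stop("NaN/Inf in l_con at step ", step + 1L)

      # gradients of l_sup (+ l_con) for the main parameter group
      g_main_id <- ls$l_sup
      if (!is.null(ls$l_con)) g_main_id <- tp_add(ls$tp, ls$l_sup, ls$l_con)
      g_main <- param_grads(ls$ctx, tp_backward(ls$tp, g_main_id))
      g_main <- g_main[intersect(names(g_main), main_names)]
      if (!is.null(ls$l_adv)) {
        g_adv <- param_grads(ls$ctx, tp_backward(ls$tp, ls$l_adv))
        # gradient reversal: encoder ascends on l_adv
        for (nm in intersect(names(g_adv), main_names)) {
          g_main[[nm]] <- (if (is.null(g_main[[nm]])) 0 else g_main[[nm]]) -
            config$lambda * g_adv[[nm]]
        }
        upd <- sgd_step(opt_disc, params[disc_names],
                        g_adv[intersect(names(g_adv), disc_names)])
        opt_disc <- upd$opt
        params[disc_names] <- upd$params
      }
      upd <- adam_step(opt_main, params[main_names], g_main)
      opt_main <- upd$opt
      params[main_names] <- upd$params

      step <- step + 1L
      rec <- list(step = step, epoch = epoch, l_sup = l_sup, l_adv = l_adv,
                  l_con = l_con, l_total = l_sup + l_adv + l_con)
      history[[step]] <- rec
      if (!is.null(con))
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }

    val_fmax <- NA_real_
    if (!is.null(validation)) {
      model$params <- params
      Pv <- gala_predict(validation$graphs, structure(list(model = model),
                                                     class = "gala_trained"))
      val_fmax <- fmax(Pv, as.matrix(validation$labels))$fmax
      if (val_fmax > best_fmax) {
        best_fmax <- val_fmax
        best_params <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
    epoch_log[[epoch]] <- list(epoch = epoch, val_fmax = val_fmax,
                               l_total = history[[step]]$l_total)
    if (verbose)
      message(sprintf("epoch %d: l_total=%.4f val_fmax=%s", epoch,
                      history[[step]]$l_total,
                      if (is.na(val_fmax)) "-" else sprintf("%.4f", val_fmax)))
    if (!is.null(validation) && config$patience > 0L && stall >= config$patience)
      break
  }

  if (is.null(validation)) best_params <- params
  best_model <- model; best_model$params <- best_params
  final_model <- model; final_model$params <- params
  structure(list(model = best_model, final_model = final_model,
                 history = do.call(rbind, lapply(history, as.data.frame)),
                 epoch_log = do.call(rbind, lapply(epoch_log, as.data.frame)),
                 best_val_fmax = if (is.finite(best_fmax)) best_fmax else NA_real_,
                 config = config),
            class = "gala_trained")
}

# Forward a second batch on an existing tape/context (shared parameters), so
# source and target losses can be differentiated jointly.
forward_batch_shared <- function(model, graphs, ctx, training = FALSE,
                                 Slist = NULL) {
  if (!length(graphs)) stop("empty graph batch")
  cfg <- model$config
  tp <- ctx$tp
  if (is.null(Slist)) Slist <- lapply(graphs, function(g) norm_adjacency(g$adjacency))
  S <- if (length(graphs) == 1L) Slist[[1]] else Matrix::bdiag(Slist)
  X <- do.call(rbind, lapply(graphs, function(g) g$features))
  sizes <- vapply(graphs, function(g) nchar(g$sequence), integer(1))
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
  zids <- integer(length(graphs))
  for (i in seq_along(graphs)) {
    Kg <- tp_slice_rows(tp, kv$K, rows[[i]])
    Vg <- tp_slice_rows(tp, kv$V, rows[[i]])
    gammas <- integer(cfg$heads)
    for (k in seq_len(cfg$heads)) {
      gammas[k] <- meta_attention_tp(ctx, Kg, Vg, k, cfg$dim)$gamma
    }
    zids[i] <- pool_tp(ctx, merge_heads_tp(ctx, gammas), cfg$dim)$z
  }
  Zid <- if (length(zids) == 1L) zids[1] else tp_rbind(tp, zids)
  logits <- tp_addbias(tp, tp_mm(tp, Zid, ctx$pid$clf_W), ctx$pid$clf_b)
  yhat <- tp_sigmoid(tp, logits)
  list(ctx = ctx, tp = tp, Hid = Hid, rows = rows, Zid = Zid,
       logits_id = logits, yhat_id = yhat)
}

#' Predict GO term scores for a set of graphs
#'
#' Deterministic evaluation-mode forward pass (no dropout).
#'
#' @param graphs list of [protein_graph()] objects (may be empty).
#' @param trained a [gala_train()] result (or a bare `gala_model`).
#' @param batch_size graphs per forward batch.
#' @return n x C score matrix in \[0, 1\], rows named by protein id, columns
#'   by term (when the model carries a vocabulary).
#' @export
gala_predict <- function(graphs, trained, batch_size = 32L) {
  model <- if (inherits(trained, "gala_trained")) trained$model else trained
  C <- model$config$n_classes
  terms <- model$terms
  if (!length(graphs)) {
    return(matrix(numeric(0), 0L, C,
                  dimnames = list(NULL, as.character(terms))))
  }
  chunks <- split(seq_along(graphs), ceiling(seq_along(graphs) / batch_size))
  out <- do.call(rbind, lapply(chunks, function(ix) {
    gala_forward(graphs[ix], model)$yhat
  }))
  rownames(out) <- vapply(graphs, function(g) g$id, character(1))
  if (!is.null(terms)) colnames(out) <- as.character(terms)
  out
}

#' Graph embeddings from a trained encoder
#'
#' @param graphs list of protein graphs.
#' @param trained trained state or model.
#' @param batch_size graphs per forward batch.
#' @return n x D embedding matrix.
#' @export
gala_embed <- function(graphs, trained, batch_size = 32L) {
  model <- if (inherits(trained, "gala_trained")) trained$model else trained
  chunks <- split(seq_along(graphs), ceiling(seq_along(graphs) / batch_size))
  out <- do.call(rbind, lapply(chunks, function(ix) {
    gala_forward(graphs[ix], model)$z
  }))
  rownames(out) <- vapply(graphs, function(g) g$id, character(1))
  out
}
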