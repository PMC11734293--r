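# Gradient-check machinery shared by test-gradients.R and the acceptance
# suite. Entropy weights in the adversarial loss are detached by design, so
# the finite-difference objective holds them fixed at their base-point
# values.

grad_setup <- function() {
  memo("grad_setup", function() {
    fx <- get_fixture()
    model <- tiny_model(seed = 3)
    src <- fx$source$graphs[1:2]
    tgt <- fx$target$graphs[1:2]
    Y <- fixture_labels(fx)[1:2, , drop = FALSE]
    list(fx = fx, model = model, src = src, tgt = tgt, Y = Y)
  })
}

# plain-value losses as functions of the parameter list (FD objectives)
loss_fns <- function(setup) {
  model <- setup$model
  base_s <- gala_forward(setup$src, model)
  base_t <- gala_forward(setup$tgt, model)
  w_s0 <- entropy_weight(base_s$yhat)
  w_t0 <- entropy_weight(base_t$yhat)
  with_params <- function(p) { m <- model; m$params <- p; m }
  list(
    l_sup = function(p) {
      supervised_bce(gala_forward(setup$src, with_params(p))$yhat, setup$Y)
    },
    l_con = function(p) {
      m <- with_params(p)
      alignment_loss(gala_forward(setup$src, m)$z, embed_labels(setup$Y, m),
                     tau = m$config$tau)
    },
    l_adv = function(p) {
      m <- with_params(p)
      o_s <- gala_forward(setup$src, m); o_t <- gala_forward(setup$tgt, m)
      Ts <- t(sapply(1:2, function(i) multilinear_map(
        o_s$z[i, ], o_s$yhat[i, ], m$frozen$R_z, m$frozen$R_y)))
      Tt <- t(sapply(1:2, function(i) multilinear_map(
        o_t$z[i, ], o_t$yhat[i, ], m$frozen$R_z, m$frozen$R_y)))
      -mean(w_s0 * log(discriminate(Ts, m))) -
        mean(w_t0 * log(1 - discriminate(Tt, m)))
    }
  )
}

# analytic gradients of all three losses from one recorded tape
analytic_grads <- function(setup) {
  model <- setup$model
  tcfg <- train_config(batch_size = 2, use_target_domain = TRUE,
                       use_label_alignment = TRUE)
  fb_s <- gala:::forward_batch(model, setup$src)
  fb_t <- gala:::forward_batch_shared(model, setup$tgt, fb_s$ctx)
  ls <- gala:::build_losses(model, fb_s, setup$Y, fb_t, tcfg)
  list(
    values = c(l_sup = gala:::tp_val(ls$tp, ls$l_sup),
               l_adv = gala:::tp_val(ls$tp, ls$l_adv),
               l_con = gala:::tp_val(ls$tp, ls$l_con)),
    l_sup = gala:::param_grads(ls$ctx, gala:::tp_backward(ls$tp, ls$l_sup)),
    l_adv = gala:::param_grads(ls$ctx, gala:::tp_backward(ls$tp, ls$l_adv)),
    l_con = gala:::param_grads(ls$ctx, gala:::tp_backward(ls$tp, ls$l_con))
  )
}

check_grads <- function(fn, grads, params, tol = 1e-4, max_entries = 6L) {
  worst <- 0
  for (nm in names(params)) {
    entries <- pick_entries(params[[nm]], max_entries, seed = nchar(nm))
    fd <- fd_grad_entries(fn, params, nm, entries)
    an <- if (is.null(grads[[nm]])) rep(0, nrow(entries))
    else grads[[nm]][entries]
    rel <- abs(an - fd) / pmax(abs(an) + abs(fd), 1e-6)
    worst <- max(worst, rel)
    expect_true(all(rel < tol | abs(an - fd) < 1e-8),
                label = sprintf("gradient of %s (worst rel %.2e)", nm, max(rel)))
  }
  worst
}

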