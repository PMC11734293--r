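test_that("GCN forward matches the dense normalized-propagation formula", {
  m <- tiny_model()
  W <- m$params[c("gcn_W1", "gcn_W2")]
  # single node, no edges: normalization is the identity
  x <- matrix(rnorm(25), 1, 25)
  expect_equal(gcn_forward(x, matrix(0, 1, 1), W["gcn_W1"]),
               pmax(x %*% W$gcn_W1, 0), ignore_attr = TRUE)
  # zero features stay zero through any stack
  expect_equal(gcn_forward(matrix(0, 4, 25), diag(0, 4), W),
               matrix(0, 4, 8), ignore_attr = TRUE)
  # 3-node path graph vs explicit matrix products
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  set.seed(9)
  X <- matrix(rnorm(3 * 25), 3, 25)
  expect_equal(gcn_forward(X, A, W), oracle_gcn(X, A, W), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(gcn_forward(X[1:2, ], A, W), "match")
})

test_that("meta-node attention reduces to known closed forms and the oracle", {
  m <- tiny_model()
  A1 <- matrix(0, 1, 1)
  H1 <- matrix(rnorm(8), 1, 8)
  # |V| = 1: softmax of a scalar is 1, so Gamma rows all equal the value row
  g1 <- meta_node_attention(H1, A1, m, head = 1)
  V1 <- pmax(as.matrix(gala:::norm_adjacency(A1) %*% H1) %*% m$params$att_val_W, 0)
  expect_equal(unname(g1[1, ]), unname(V1[1, ]), tolerance = 1e-12)
  expect_equal(unname(g1[2, ]), unname(V1[1, ]), tolerance = 1e-12)

  # K = 2, |V| = 3 seeded case vs step-by-step evaluation
  set.seed(21)
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  H <- matrix(rnorm(24), 3, 8)
  out <- meta_node_attention(H, A, m, head = 2)
  S <- as.matrix(gala:::norm_adjacency(A))
  K <- pmax(S %*% H %*% m$params$att_key_W, 0)
  V <- pmax(S %*% H %*% m$params$att_val_W, 0)
  Q <- m$params$att_q2
  scores <- Q %*% t(K) / sqrt(8)
  Wt <- t(apply(scores, 1, oracle_softmax_row))
  expect_equal(unname(out), unname(Wt %*% V), tolerance = 1e-12,
               ignore_attr = TRUE)
  # attention rows are a probability distribution over residues
  expect_equal(rowSums(attr(out, "weights")), c(1, 1), tolerance = 1e-6)
  expect_true(all(attr(out, "weights") >= 0))
})

test_that("identical value rows make meta-node attention constant", {
  # if every value row equals v, any convex combination equals v
  m <- tiny_model()
  tpc <- gala:::fwd_start(m)
  v <- rnorm(8)
  Kid <- gala:::tp_leaf(tpc$tp, matrix(rnorm(40), 5, 8))
  Vid <- gala:::tp_leaf(tpc$tp, matrix(v, 5, 8, byrow = TRUE))
  att <- gala:::meta_attention_tp(tpc, Kid, Vid, 1, 8)
  G <- gala:::tp_val(tpc$tp, att$gamma)
  expect_equal(G, matrix(v, 2, 8, byrow = TRUE), tolerance = 1e-12)
})

test_that("multihead merge equals concat-then-MLP oracle", {
  m <- tiny_model()
  set.seed(4)
  gs <- list(matrix(rnorm(16), 2, 8), matrix(rnorm(16), 2, 8))
  U <- multihead_merge(gs, m)
  conc <- cbind(gs[[1]], gs[[2]])
  hid <- pmax(sweep(conc %*% m$params$fc1_W1, 2, m$params$fc1_b1, `+`), 0)
  expect_equal(U, sweep(hid %*% m$params$fc1_W2, 2, m$params$fc1_b2, `+`),
               tolerance = 1e-12)
  # zero inputs with zero biases give zero
  m0 <- m; m0$params$fc1_b1[] <- 0; m0$params$fc1_b2[] <- 0
  expect_equal(multihead_merge(list(matrix(0, 2, 8), matrix(0, 2, 8)), m0),
               matrix(0, 2, 8))
  expect_error(multihead_merge(list(gs[[1]], matrix(0, 3, 8)), m), "mismatch")
})

test_that("attention pooling matches the explicit formula and closed forms", {
  m <- tiny_model()
  set.seed(5)
  U <- matrix(rnorm(3 * 8), 3, 8)
  z <- attention_pool(U, m)
  scores <- m$params$pool_q %*% t(U %*% m$params$pool_K) / sqrt(8)
  w <- oracle_softmax_row(as.numeric(scores))
  expect_equal(z, as.numeric(w %*% U %*% m$params$pool_V), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(sum(attr(z, "weights")), 1, tolerance = 1e-6)
  # identical meta-node rows: weights sum to 1 so z = u V_P
  u <- rnorm(8)
  zi <- attention_pool(matrix(u, 3, 8, byrow = TRUE), m)
  expect_equal(zi, as.numeric(matrix(u, 1) %*% m$params$pool_V),
               ignore_attr = TRUE, tolerance = 1e-12)
  # K = 1: single weight equals 1
  z1 <- attention_pool(matrix(u, 1, 8), m)
  expect_equal(z1, as.numeric(matrix(u, 1) %*% m$params$pool_V),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("classifier, projector, multilinear map and discriminator check out", {
  m <- tiny_model()
  # zero classifier: every probability is one half
  m0 <- m; m0$params$clf_W[] <- 0; m0$params$clf_b[] <- 0
  expect_equal(as.numeric(classify(rnorm(8), m0)), rep(0.5, 15))
  # seeded affine + sigmoid oracle; logits exposed
  z <- rnorm(8)
  got <- classify(z, m)
  logit <- sweep(matrix(z, 1) %*% m$params$clf_W, 2, m$params$clf_b, `+`)
  expect_equal(attr(got, "logits"), logit, tolerance = 1e-12)
  expect_equal(as.numeric(got), as.numeric(1 / (1 + exp(-logit))),
               tolerance = 1e-9)
  # saturated logits stay inside (0, 1)
  msat <- m; msat$params$clf_b[] <- 1e4
  expect_true(all(classify(rep(0, 8), msat) <= 1 - 1e-7))

  # label projector: two-layer MLP oracle; determinism; zero case
  y <- as.numeric(rbinom(15, 1, 0.4))
  b <- embed_labels(y, m)
  hid <- pmax(sweep(matrix(y, 1) %*% m$params$proj_W1, 2, m$params$proj_b1, `+`), 0)
  expect_equal(b, as.numeric(sweep(hid %*% m$params$proj_W2, 2,
                                   m$params$proj_b2, `+`)), tolerance = 1e-12)
  expect_equal(embed_labels(y, m), b)
  expect_error(embed_labels(y + 0.5, m), "binary")
  m0b <- m; m0b$params$proj_b1[] <- 0; m0b$params$proj_b2[] <- 0
  expect_equal(embed_labels(rep(0, 15), m0b), rep(0, 8))

  # multilinear map: identity-matrix example and elementwise oracle
  expect_equal(multilinear_map(c(1, 2), c(1, 0), diag(2), diag(2)),
               c(1 / sqrt(2), 0))
  expect_equal(multilinear_map(z, rep(0, 15), m$frozen$R_z, m$frozen$R_y),
               rep(0, 6))
  yh <- runif(15)
  expect_equal(multilinear_map(z, yh, m$frozen$R_z, m$frozen$R_y),
               as.numeric((m$frozen$R_z %*% z) * (m$frozen$R_y %*% yh)) / sqrt(6),
               tolerance = 1e-12)
  expect_error(multilinear_map(z[1:3], yh, m$frozen$R_z, m$frozen$R_y),
               "mismatch")

  # discriminator: zero weights give 0.5; output clipped; MLP oracle
  md <- m; md$params$disc_W1[] <- 0; md$params$disc_b1[] <- 0
  md$params$disc_W2[] <- 0; md$params$disc_b2[] <- 0
  expect_equal(discriminate(rnorm(6), md), 0.5)
  tv <- rnorm(6)
  hid2 <- pmax(sweep(matrix(tv, 1) %*% m$params$disc_W1, 2, m$params$disc_b1, `+`), 0)
  o <- 1 / (1 + exp(-sweep(hid2 %*% m$params$disc_W2, 2, m$params$disc_b2, `+`)))
  expect_equal(discriminate(tv, m), as.numeric(o), tolerance = 1e-9)
  expect_true(discriminate(tv, m) > 1e-7 && discriminate(tv, m) < 1 - 1e-7)
})

test_that("frozen random matrices are unit-variance and reproducible", {
  cfg <- tiny_config(seed = 11)
  m1 <- gala_model(cfg)
  m2 <- gala_model(cfg)
  expect_identical(m1$frozen, m2$frozen)   # sampled once per seed, serialized
  set.seed(1)
  big <- gala_model(gala_config(feature_dim = 25, n_classes = 50,
                                multilinear_dim = 256, dim = 32, seed = 2))
  expect_equal(mean(big$frozen$R_z), 0, tolerance = 0.05)
  expect_equal(stats::var(as.numeric(big$frozen$R_z)), 1, tolerance = 0.05)
})

test_that("batched forward equals per-graph forward and is order-equivariant", {
  fx <- get_fixture()
  m <- tiny_model()
  graphs <- c(fx$source$graphs[1:3])
  batch <- gala_forward(graphs, m)
  for (i in 1:3) {
    single <- gala_forward(graphs[i], m)
    expect_equal(unname(batch$z[i, ]), unname(single$z[1, ]), tolerance = 1e-5)
    expect_equal(unname(batch$yhat[i, ]), unname(single$yhat[1, ]),
                 tolerance = 1e-5)
  }
  perm <- gala_forward(graphs[c(3, 1, 2)], m)
  expect_equal(unname(perm$z), unname(batch$z[c(3, 1, 2), ]), tolerance = 1e-12)
  expect_error(gala_forward(list(), m), "empty")
})

test_that("forward is invariant to residue relabeling", {
  fx <- get_fixture()
  m <- tiny_model()
  g <- fx$source$graphs[[1]]
  n <- nchar(g$sequence)
  set.seed(33)
  p <- sample(n)
  sym <- strsplit(g$sequence, "")[[1]]
  gp <- protein_graph(g$id, paste(sym[p], collapse = ""),
                      adjacency = g$adjacency[p, p])
  z1 <- gala_forward(list(g), m)$z
  z2 <- gala_forward(list(gp), m)$z
  expect_equal(z1, z2, tolerance = 1e-5)
})

test_that("forward outputs are finite across graph sizes and weights sum to 1", {
  m <- tiny_model()
  set.seed(8)
  for (n in c(1L, 2L, 17L, 120L)) {
    coords <- matrix(rnorm(3 * n, sd = 5), n, 3)
    g <- protein_graph(paste0("s", n),
                       paste(sample(LETTERS[1:20], n, TRUE), collapse = ""),
                       coords = coords)
    out <- gala_forward(list(g), m)
    expect_true(all(is.finite(out$z)) && all(is.finite(out$yhat)))
    for (att in out$attention) {
      for (w in att$meta) expect_equal(rowSums(w), rep(1, 2), tolerance = 1e-6)
      expect_equal(sum(att$pool), 1, tolerance = 1e-6)
    }
  }
})

test_that("checkpoints reload bit-exactly", {
  m <- tiny_model(seed = 99)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$frozen, m$frozen)
  fx <- get_fixture()
  expect_identical(gala_forward(fx$source$graphs[1], m)$yhat,
                   gala_forward(fx$source$graphs[1], m2)$yhat)
})
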