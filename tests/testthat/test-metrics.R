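random_pred_truth <- function(seed, n = 20, C = 15) {
  set.seed(seed)
  Y <- matrix(rbinom(n * C, 1, 0.3), n, C)
  # ensure each protein has truth and each instance is evaluable
  for (i in which(rowSums(Y) == 0)) Y[i, sample(C, 1)] <- 1
  P <- matrix(round(runif(n * C), 2), n, C)
  list(P = P, Y = Y)
}

test_that("term AUPR matches closed forms", {
  truth <- c(1, 1, 0, 0, 0)
  expect_equal(term_aupr(truth, truth), 1.0)      # perfect separation
  # constant 0.5 scores with half positives: single PR point (0.5, 1)
  expect_equal(term_aupr(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(term_aupr(runif(5), rep(0, 5)), "no positive")
})

test_that("term AUPR equals the brute-force grid oracle on seeded vectors", {
  for (seed in 1:10) {
    set.seed(seed)
    truth <- rbinom(30, 1, 0.4)
    if (sum(truth) == 0) truth[1] <- 1
    scores <- round(runif(30), 2)
    expect_equal(term_aupr(scores, truth), oracle_term_aupr(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("macro AUPR averages evaluable terms only", {
  d <- random_pred_truth(1)
  expect_equal(as.numeric(macro_aupr(d$Y, d$Y)), 1.0)
  # two-term mean
  P <- cbind(c(1, 0, 0.5), c(0.2, 0.9, 0.1))
  Y <- cbind(c(1, 0, 0), c(0, 1, 1))
  expect_equal(as.numeric(macro_aupr(P, Y)),
               (term_aupr(P[, 1], Y[, 1]) + term_aupr(P[, 2], Y[, 2])) / 2)
  # all-negative columns are excluded, not counted as zero
  Y0 <- cbind(Y, 0)
  P0 <- cbind(P, runif(3))
  expect_equal(as.numeric(macro_aupr(P0, Y0)), as.numeric(macro_aupr(P, Y)))
  expect_error(macro_aupr(P, P * 0), "no terms")
})

test_that("Fmax matches closed forms, the oracle, and the documented tie rule", {
  d <- random_pred_truth(2)
  fm <- fmax(d$Y, d$Y)
  expect_equal(fm$fmax, 1.0)
  expect_gt(fm$threshold, 0)
  # single protein, truth {a}, both terms scored 1.0: F1 = 2/3
  expect_equal(fmax(matrix(c(1, 1), 1, 2), matrix(c(1, 0), 1, 2))$fmax, 2 / 3,
               tolerance = 1e-12)
  # empty-truth protein is an error naming the protein
  Ybad <- d$Y; Ybad[3, ] <- 0; rownames(Ybad) <- paste0("prot", 1:20)
  expect_error(fmax(d$P, Ybad), "prot3")
})

test_that("protein-centric metrics equal naive oracles on seeded instances", {
  for (seed in 1:10) {
    d <- random_pred_truth(seed + 100)
    fm <- fmax(d$P, d$Y)
    ofm <- oracle_fmax(d$P, d$Y)
    expect_equal(fm$fmax, ofm$fmax, tolerance = 1e-12)
    expect_equal(fm$threshold, ofm$threshold)
    expect_equal(mcc_at_fmax(d$P, d$Y, fm$threshold),
                 oracle_mcc(d$P, d$Y, fm$threshold), tolerance = 1e-12)
    expect_equal(as.numeric(macro_aupr(d$P, d$Y)), oracle_macro_aupr(d$P, d$Y),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to protein and term reordering", {
  d <- random_pred_truth(7)
  pi_ <- sample(nrow(d$P)); pj <- sample(ncol(d$P))
  expect_equal(fmax(d$P[pi_, pj], d$Y[pi_, pj])$fmax, fmax(d$P, d$Y)$fmax)
  expect_equal(as.numeric(macro_aupr(d$P[pi_, pj], d$Y[pi_, pj])),
               as.numeric(macro_aupr(d$P, d$Y)))
})

test_that("Fmax is monotone as predictions move toward the truth", {
  d <- random_pred_truth(9)
  prev <- -Inf
  for (alpha in seq(0, 1, 0.25)) {
    f <- fmax(d$P + alpha * (d$Y - d$P), d$Y)$fmax
    expect_gte(f + 1e-12, prev)
    prev <- f
  }
})

test_that("MCC closed forms: balanced counts give 0, printed counts match Eq", {
  expect_equal(gala:::mcc_from_counts(1, 1, 1, 1), 0)
  expect_equal(gala:::mcc_from_counts(3, 4, 1, 2),
               (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6))
  # perfect binarization
  d <- random_pred_truth(3)
  expect_equal(mcc_at_fmax(d$Y, d$Y, 0.5), 1)
})

test_that("Smin hits its degenerate closed forms and the nested-loop oracle", {
  fx <- get_fixture()
  ann <- c(fx$source$annotations, fx$target$annotations)
  Y <- label_matrix(ann, fx$index)
  ic <- fx$ic
  Y <- Y[, intersect(colnames(Y), ic$term)]  # evaluation vocabulary
  # exact binarization at some threshold: Smin = 0
  sm0 <- smin(Y * 0.7, Y, ic, fx$dag)
  expect_equal(sm0$smin, 0)
  # no predictions at any threshold > 0... all-zero scores predict everything
  # only at t = 0; compare against mean total conditional IC of the truth
  P0 <- Y * 0
  sm <- smin(P0, Y, ic, fx$dag)
  cic <- stats::setNames(ic$cond_ic, ic$term)
  ru_all <- mean(vapply(seq_len(nrow(Y)), function(i)
    sum(cic[colnames(Y)[Y[i, ] == 1]]), numeric(1)))
  expect_lte(sm$smin, ru_all + 1e-12)

  # seeded fixture vs exhaustive oracle (predictions get hierarchy-closed)
  set.seed(5)
  P <- matrix(round(runif(length(Y)), 2), nrow(Y), ncol(Y),
              dimnames = dimnames(Y))
  anc <- gala:::ancestor_map(fx$dag)
  expect_equal(smin(P, Y, ic, fx$dag)$smin, oracle_smin(P, Y, as.list(cic), anc),
               tolerance = 1e-12)
  # missing conditional IC is a named error
  ic2 <- ic[ic$term != colnames(Y)[1], ]
  expect_error(smin(P, Y, ic2, fx$dag), colnames(Y)[1], fixed = TRUE)
})

test_that("prediction TSV round-trips at 3-decimal precision", {
  d <- random_pred_truth(4, n = 5, C = 3)
  rownames(d$P) <- paste0("prot", 1:5)
  colnames(d$P) <- sprintf("GO:900001%d", 1:3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(d$P, path)
  back <- read_predictions(path, terms = colnames(d$P))
  expect_equal(back[rownames(d$P), ], d$P, tolerance = 5e-4)
})

test_that("evaluate_predictions bundles all metrics with IC buckets", {
  fx <- get_fixture()
  ann <- c(fx$source$annotations, fx$target$annotations)
  Y <- label_matrix(ann, fx$index)
  Y <- Y[, intersect(colnames(Y), fx$ic$term)]
  set.seed(6)
  P <- pmin(pmax(Y * 0.8 + matrix(runif(length(Y), 0, 0.3), nrow(Y)), 0), 1)
  dimnames(P) <- dimnames(Y)
  res <- evaluate_predictions(P, Y, ic = fx$ic, dag = fx$dag)
  expect_true(all(c("aupr", "fmax", "mcc", "smin") %in% names(res)))
  expect_gte(res$mcc, -1); expect_lte(res$mcc, 1)
  expect_true(all(names(res$aupr_by_ic) %in% c("IC<5", "5<IC<10", "IC>10")))
})
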