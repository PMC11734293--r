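# Shared fixtures and small model builders. Heavy objects are memoized so
# multiple test files can reuse them within one run.

.gala_test_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.gala_test_cache[[key]])) .gala_test_cache[[key]] <- fn()
  .gala_test_cache[[key]]
}

get_fixture <- function() memo("fixture", make_fixture)

# Desk-scale model used by oracle and gradient tests: small enough that full
# finite-difference sweeps stay fast.
tiny_config <- function(feature_dim = 25, n_classes = 15, seed = 3, ...) {
  gala_config(feature_dim = feature_dim, n_classes = n_classes, n_layers = 2L,
              dim = 8L, meta_nodes = 2L, heads = 2L, multilinear_dim = 6L,
              dropout = 0, seed = seed, ...)
}

tiny_model <- function(seed = 3, ...) gala_model(tiny_config(seed = seed, ...))

fixture_labels <- function(fx, which = c("source", "target")) {
  which <- match.arg(which)
  label_matrix(fx[[which]]$annotations, fx$index)
}

# A tiny hand-written PDB fixture (three residues, optionally a second chain
# or a residue lacking its C-alpha) used by the structure-reading tests.
write_test_pdb <- function(path, two_chains = FALSE, drop_ca_res = NULL) {
  mk <- function(serial, atom, res3, chain, resno, x, y, z) {
    sprintf("ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            serial, formatC(atom, width = 4), res3, chain, resno, x, y, z, 1.0, 0.0)
  }
  res <- list(list("ALA", 1, 0, 0, 0), list("GLY", 2, 3.8, 0, 0),
              list("TRP", 3, 7.6, 0, 0))
  lines <- character(0)
  serial <- 0L
  for (r in res) {
    serial <- serial + 1L
    lines <- c(lines, mk(serial, " N  ", r[[1]], "A", r[[2]],
                         r[[3]] - 1, r[[4]], r[[5]]))
    if (!identical(r[[2]], drop_ca_res)) {
      serial <- serial + 1L
      lines <- c(lines, mk(serial, " CA ", r[[1]], "A", r[[2]],
                           r[[3]], r[[4]], r[[5]]))
    }
  }
  if (two_chains) {
    serial <- serial + 1L
    lines <- c(lines, mk(serial, " CA ", "LYS", "B", 1, 0, 10, 0))
    serial <- serial + 1L
    lines <- c(lines, mk(serial, " CA ", "SER", "B", 2, 3.8, 10, 0))
  }
  writeLines(c(lines, "END"), path)
  path
}
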