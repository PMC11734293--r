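# Toy 5-term OBO text: root, two children, one grandchild reached through a
# diamond, plus an optional obsolete term.
toy_obo <- function(path, obsolete = FALSE) {
  lines <- c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: molecular_function",
    "",
    "[Term]", "id: GO:0000002", "name: left", "namespace: molecular_function",
    "is_a: GO:0000001 ! root",
    "",
    "[Term]", "id: GO:0000003", "name: right", "namespace: molecular_function",
    "relationship: part_of GO:0000001 ! root",
    "",
    "[Term]", "id: GO:0000004", "name: diamond leaf",
    "namespace: molecular_function",
    "is_a: GO:0000002 ! left", "is_a: GO:0000003 ! right",
    "",
    "[Term]", "id: GO:0000005", "name: deep leaf",
    "namespace: molecular_function",
    "is_a: GO:0000004 ! diamond leaf"
  )
  if (obsolete) {
    lines <- c(lines, "", "[Term]", "id: GO:0000099", "name: gone",
               "namespace: molecular_function", "is_obsolete: true")
  }
  writeLines(lines, path)
  path
}

test_that("OBO parsing keeps is_a/part_of edges and drops obsolete terms", {
  path <- withr::local_tempfile(fileext = ".obo")
  toy_obo(path)
  dag <- parse_obo(path)
  expect_setequal(dag$terms, sprintf("GO:000000%d", 1:5))
  expect_equal(sum(lengths(dag$parents)), 5L)  # 4 is_a + 1 part_of
  expect_setequal(dag$parents$`GO:0000004`, c("GO:0000002", "GO:0000003"))
  expect_equal(unname(dag$roots), "GO:0000001")

  toy_obo(path, obsolete = TRUE)
  expect_false("GO:0000099" %in% parse_obo(path)$terms)
})

test_that("a manufactured cycle is rejected with a named cycle", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: GO:0000010", "namespace: molecular_function",
    "is_a: GO:0000011",
    "", "[Term]", "id: GO:0000011", "namespace: molecular_function",
    "is_a: GO:0000010"
  ), path)
  expect_error(parse_obo(path), "cycle.*GO:00000")
})

test_that("propagation closes under ancestors, is idempotent and monotone", {
  path <- withr::local_tempfile(fileext = ".obo")
  toy_obo(path)
  dag <- parse_obo(path)
  ann <- list(p1 = "GO:0000005")
  prop <- propagate_annotations(ann, dag)
  # leaf implies every ancestor up to the root (diamond counted once)
  expect_equal(prop$p1, sort(sprintf("GO:000000%d", 1:5)))
  # idempotent on an already-closed set
  expect_equal(propagate_annotations(prop, dag), prop)
  # matches BFS closure oracle on the diamond
  expect_equal(prop$p1, oracle_closure(dag, "GO:0000005"))
  # monotone: superset in => superset out
  bigger <- propagate_annotations(list(p1 = c("GO:0000005", "GO:0000003")), dag)
  expect_true(all(prop$p1 %in% bigger$p1))
  expect_error(propagate_annotations(list(p1 = "GO:9999999"), dag),
               "GO:9999999")
})

test_that("information content follows -log2 of annotation frequency", {
  path <- withr::local_tempfile(fileext = ".obo")
  toy_obo(path)
  dag <- parse_obo(path)
  # 1024 proteins: all have the root; 512 carry the left child
  ann <- lapply(seq_len(1024), function(i) {
    if (i <= 512) c("GO:0000001", "GO:0000002") else "GO:0000001"
  })
  names(ann) <- paste0("p", seq_len(1024))
  ic <- compute_ic(ann, dag)
  expect_equal(ic$p[ic$term == "GO:0000002"], 0.5)
  expect_equal(ic$ic[ic$term == "GO:0000002"], 1.0)
  expect_equal(ic$ic[ic$term == "GO:0000001"], 0)        # root: P = 1
  expect_equal(ic$cond_ic[ic$term == "GO:0000001"], 0)   # root: marginal IC
})

test_that("conditional IC equals hand-counted ratios on a 3-level fixture", {
  path <- withr::local_tempfile(fileext = ".obo")
  toy_obo(path)
  dag <- parse_obo(path)
  # 8 proteins; 6 carry term 2; 3 of those carry term 4 (parents 2 AND 3);
  # term 3 in 4 proteins; both parents of 4 co-occur in 3 proteins + 1 extra
  ann <- list(
    a = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"),
    b = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"),
    c = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"),
    d = c("GO:0000001", "GO:0000002", "GO:0000003"),
    e = c("GO:0000001", "GO:0000002"),
    f = c("GO:0000001", "GO:0000002"),
    g = c("GO:0000001"),
    h = c("GO:0000001")
  )
  ic <- compute_ic(ann, dag)
  # IC(2 | 1) = -log2(count(2) / count(parents of 2 = {1})) = -log2(6/8)
  expect_equal(ic$cond_ic[ic$term == "GO:0000002"], -log2(6 / 8))
  # IC(4 | {2,3}): proteins with both 2 and 3 = {a,b,c,d} -> -log2(3/4)
  expect_equal(ic$cond_ic[ic$term == "GO:0000004"], -log2(3 / 4))
  # IC non-increasing child -> parent after propagation
  for (t in ic$term) {
    for (p in dag$parents[[t]]) {
      if (p %in% ic$term)
        expect_lte(ic$ic[ic$term == p], ic$ic[ic$term == t])
    }
  }
})

test_that("IC buckets use the documented boundary rule", {
  expect_equal(ic_category(c(4.9, 5.0, 5.1, 10.0, 10.2, 0)),
               c("IC<5", "IC<5", "5<IC<10", "5<IC<10", "IC>10", "IC<5"))
  expect_error(ic_category(-1), "non-negative")
})

test_that("annotation and IC tables round-trip through TSV", {
  ann <- list(p1 = c("GO:0000001", "GO:0000002"), p2 = "GO:0000001")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  expect_equal(read_annotations(path), ann)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  obo <- withr::local_tempfile(fileext = ".obo")
  toy_obo(obo)
  ic <- compute_ic(propagate_annotations(ann, parse_obo(obo)), parse_obo(obo))
  write_ic_table(ic, path2)
  expect_equal(read_ic_table(path2)$cond_ic, ic$cond_ic, tolerance = 1e-9)
})
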