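# Synthetic two-domain benchmark with planted structure. Source and target
# domains share the label space (a small GO-like DAG whose leaf terms are
# planted as 3-mer sequence motifs) but differ in sequence length, long-range
# contact density and residue composition, so classification, domain
# alignment and residue attribution are all verifiable without downloads.

SYN_MOTIFS <- c("ACD", "EFG", "HIK", "LMN", "PQR", "STV", "WYA", "CEH",
                "DGK", "FIM")

#' Specification of the synthetic benchmark
#'
#' Defaults state the benchmark's world: a labeled source domain of shorter,
#' sparser proteins (lengths 40-80, long-range contact probability 0.05) and
#' a shifted unlabeled target domain (lengths 80-150, probability 0.15) with
#' a different residue-composition bias; 400 training graphs per domain, 100
#' source validation and 100 target test graphs; a 15-term DAG (1 root, 4
#' mid-level, 10 leaf terms, some with two parents); each leaf term's 3-mer
#' motif is spliced into a protein's sequence with probability
#' `leaf_activation` and a leaf label is active iff its motif occurs in the
#' final sequence (noise-free by default so attribution ground truth exists).
#'
#' @param seed generator seed; identical spec + seed reproduce the data
#'   exactly.
#' @param n_train,n_val,n_test graphs per domain and split.
#' @param len_source,len_target length ranges.
#' @param p_source,p_target long-range contact probabilities.
#' @param leaf_activation probability a leaf motif is planted in a protein.
#' @param label_noise probability of flipping a leaf label after scanning
#'   (default 0 keeps labels motif-determined).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 17L, n_train = 400L, n_val = 100L,
                           n_test = 100L, len_source = c(40L, 80L),
                           len_target = c(80L, 150L), p_source = 0.05,
                           p_target = 0.15, leaf_activation = 0.25,
                           label_noise = 0) {
  structure(list(seed = as.integer(seed), n_train = as.integer(n_train),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 len_source = as.integer(len_source),
                 len_target = as.integer(len_target),
                 p_source = p_source, p_target = p_target,
                 leaf_activation = leaf_activation, label_noise = label_noise,
                 motifs = SYN_MOTIFS),
            class = "synthetic_spec")
}

#' Toy GO-like DAG for the synthetic benchmark
#'
#' One molecular-function root, 4 mid-level terms and 10 leaf terms; the
#' first three leaves have two parents (diamonds). Acyclic by construction.
#'
#' @param spec a [synthetic_spec()] (shape is currently fixed).
#' @return list(dag, index, motif_terms): the `go_dag`, the full
#'   [build_term_index()]-compatible term vocabulary and the leaf term ->
#'   motif table.
#' @export
make_go_dag <- function(spec = synthetic_spec()) {
  root <- "GO:9000000"
  mids <- sprintf("GO:900000%d", 1:4)
  leaves <- sprintf("GO:90000%02d", 11:20)
  parents <- c(
    stats::setNames(list(character(0)), root),
    stats::setNames(lapply(mids, function(m) root), mids),
    stats::setNames(lapply(seq_along(leaves), function(i) {
      p <- mids[((i - 1L) %% 4L) + 1L]
      if (i <= 3L) p <- c(p, mids[(i %% 4L) + 1L])  # diamonds
      p
    }), leaves)
  )
  terms <- c(root, mids, leaves)
  dag <- structure(list(
    terms = terms,
    namespace = stats::setNames(rep("molecular_function", length(terms)), terms),
    name = stats::setNames(paste("synthetic term", seq_along(terms)), terms),
    parents = parents
  ), class = "go_dag")
  dag$roots <- dag_roots(dag)
  motif_terms <- stats::setNames(spec$motifs, leaves)
  index <- structure(sort(terms), class = "term_index",
                     namespace = "molecular_function")
  list(dag = dag, index = index, motif_terms = motif_terms)
}

# Domain-specific residue sampling weights over the 20 standard amino acids.
domain_composition <- function(domain) {
  aas <- GALA_ALPHABET[1:20]
  w <- stats::setNames(rep(1, 20), aas)
  if (domain == "source") {
    w[c("A", "D", "E", "K", "L", "R")] <- 2
  } else {
    w[c("F", "G", "I", "P", "S", "T", "V", "Y")] <- 2
  }
  w / sum(w)
}

# Helix-like C-alpha coordinates (rise 1.5 A, radius 2.3 A, 100 deg/residue)
# with Gaussian perturbation, so PDB writing and contact-map construction can
# be exercised on synthetic proteins.
helix_coords <- function(n, noise = 0.3) {
  i <- seq_len(n)
  theta <- i * 100 * pi / 180
  cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i) +
    matrix(stats::rnorm(3 * n, sd = noise), n, 3)
}

# One synthetic protein: random sequence with domain composition, planted
# motifs, chain-backbone + Bernoulli long-range contacts.
synth_protein <- function(id, domain, spec, motif_terms, dag_anc) {
  lr <- if (domain == "source") spec$len_source else spec$len_target
  p <- if (domain == "source") spec$p_source else spec$p_target
  L <- sample(lr[1]:lr[2], 1L)
  comp <- domain_composition(domain)
  seqv <- sample(names(comp), L, replace = TRUE, prob = comp)
  plant <- stats::runif(length(motif_terms)) < spec$leaf_activation
  slots <- seq_len(L - 2L)
  used <- logical(L)
  for (k in which(plant)) {
    free <- slots[!vapply(slots, function(s) any(used[s:(s + 2L)]), logical(1))]
    if (!length(free)) break
    s <- if (length(free) == 1L) free else sample(free, 1L)
    seqv[s:(s + 2L)] <- strsplit(motif_terms[[k]], "")[[1]]
    used[s:(s + 2L)] <- TRUE
  }
  sequence <- paste(seqv, collapse = "")
  # adjacency: backbone plus long-range contacts
  A <- matrix(0, L, L)
  A[cbind(1:(L - 1L), 2:L)] <- 1
  upper <- which(upper.tri(A) & row(A) < col(A) - 1L)
  A[upper[stats::runif(length(upper)) < p]] <- 1
  A <- pmax(A, t(A))
  g <- protein_graph(id, sequence, adjacency = A, coords = helix_coords(L))
  # leaf labels: motif occurrence in the final sequence (noise-free rule)
  active <- names(motif_terms)[vapply(motif_terms, function(m)
    grepl(m, sequence, fixed = TRUE), logical(1))]
  if (spec$label_noise > 0) {
    flip <- names(motif_terms)[stats::runif(length(motif_terms)) < spec$label_noise]
    active <- union(setdiff(active, flip), setdiff(flip, active))
  }
  terms <- if (length(active))
    sort(unique(c(active, unlist(dag_anc[active], use.names = FALSE))))
  else character(0)
  list(graph = g, terms = terms)
}

#' Generate one domain of the synthetic benchmark
#'
#' @param spec a [synthetic_spec()].
#' @param domain "source" or "target".
#' @param n number of proteins (defaults to `spec$n_train`).
#' @param prefix id prefix (defaults to the domain name).
#' @param require_labeled resample any protein that received no labels, so
#'   every returned protein is annotated (used for labeled splits, which
#'   exclude unannotated proteins).
#' @param seed RNG seed (defaults to `spec$seed`); generation is a pure
#'   function of spec + seed.
#' @return list(graphs, annotations): the graphs and the propagated
#'   protein -> term sets (unannotated proteins map to empty sets).
#' @export
make_domain <- function(spec, domain = c("source", "target"), n = spec$n_train,
                        prefix = NULL, require_labeled = FALSE,
                        seed = spec$seed) {
  domain <- match.arg(domain)
  if (is.null(prefix)) prefix <- domain
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  md <- make_go_dag(spec)
  anc <- ancestor_map(md$dag)
  graphs <- vector("list", n)
  ann <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      pr <- synth_protein(sprintf("%s_%04d", prefix, i), domain, spec,
                          md$motif_terms, anc)
      if (!require_labeled || length(pr$terms)) break
    }
    graphs[[i]] <- pr$graph
    ann[[i]] <- pr$terms
  }
  names(ann) <- vapply(graphs, function(g) g$id, character(1))
  list(graphs = graphs, annotations = ann)
}

#' The tiny frozen fixture used throughout the test suite
#'
#' 8 graphs (4 per domain, all labeled), the 15-term DAG, fixed seed 17 and
#' shortened lengths (source 30-40, target 40-50) so gradient and oracle
#' tests run fast. Regeneration is deterministic.
#'
#' @return list(source, target, dag, index, motif_terms, ic): domains as from
#'   [make_domain()], ontology objects, and an IC table computed from the 8
#'   proteins.
#' @export
make_fixture <- function() {
  spec <- synthetic_spec(seed = 17L, n_train = 4L,
                         len_source = c(30L, 40L), len_target = c(40L, 50L))
  md <- make_go_dag(spec)
  src <- make_domain(spec, "source", n = 4L, require_labeled = TRUE, seed = 17L)
  tgt <- make_domain(spec, "target", n = 4L, require_labeled = TRUE, seed = 18L)
  ann <- c(src$annotations, tgt$annotations)
  list(source = src, target = tgt, dag = md$dag, index = md$index,
       motif_terms = md$motif_terms, ic = compute_ic(ann, md$dag))
}

#' Positions of a term's motif residues in a graph's sequence
#'
#' Ground-truth "site" residues for attribution tests: the indices covered by
#' every occurrence of the leaf term's planted 3-mer.
#'
#' @param graph a synthetic [protein_graph()].
#' @param motif 3-mer string.
#' @return integer vector of 1-based residue indices (possibly empty).
#' @export
motif_positions <- function(graph, motif) {
  hits <- gregexpr(motif, graph$sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  sort(unique(as.integer(outer(hits, 0:(nchar(motif) - 1L), `+`))))
}

#' Write a generated domain to disk (FASTA, per-protein PDB, annotations TSV)
#'
#' @param dom a [make_domain()] result.
#' @param dir output directory (created if needed).
#' @export
write_domain <- function(dom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "sequences.fasta")
  con <- file(fasta, "w")
  for (g in dom$graphs) {
    writeLines(c(paste0(">", g$id), g$sequence), con)
  }
  close(con)
  pdbdir <- file.path(dir, "pdb")
  dir.create(pdbdir, showWarnings = FALSE)
  for (g in dom$graphs) {
    write_ca_pdb(g, file.path(pdbdir, paste0(g$id, ".pdb")))
  }
  ann <- dom$annotations[lengths(dom$annotations) > 0]
  if (length(ann)) write_annotations(ann, file.path(dir, "annotations.tsv"))
  invisible(dir)
}
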