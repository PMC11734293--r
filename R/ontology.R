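# Gene Ontology handling: OBO parsing, ancestor propagation of annotations,
# information content, and specificity stratification.

NAMESPACE_CODES <- c(molecular_function = "MF", biological_process = "BP",
                     cellular_component = "CC")

#' Parse an OBO ontology file
#'
#' Reads `[Term]` stanzas keeping `is_a` and `relationship: part_of` edges
#' (the CAFA convention); obsolete terms are dropped and acyclicity is
#' verified.
#'
#' @param path OBO-format file.
#' @return object of class `go_dag`: fields `terms` (character vector),
#'   `namespace` (named), `name` (named), `parents` (named list child ->
#'   parents), `roots` (named by namespace).
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); ns <- character(0); nm <- character(0)
  parents <- list()
  for (s in seq_along(starts)) {
    block <- lines[starts[s]:(bounds[s + 1L] - 1L)]
    getv <- function(key) {
      hit <- block[startsWith(block, paste0(key, ": "))]
      sub(paste0("^", key, ": "), "", hit)
    }
    if (length(getv("is_obsolete")) && any(getv("is_obsolete") == "true")) next
    id <- getv("id")[1]
    if (is.na(id) || !length(id)) next
    isa <- sub(" !.*$", "", getv("is_a"))
    rel <- getv("relationship")
    po <- sub(" !.*$", "", sub("^part_of ", "", rel[startsWith(rel, "part_of ")]))
    ids <- c(ids, id)
    ns[id] <- if (length(getv("namespace"))) getv("namespace")[1] else NA_character_
    nm[id] <- if (length(getv("name"))) getv("name")[1] else id
    parents[[id]] <- unique(c(isa, po))
  }
  # drop dangling parent references (e.g. to obsolete terms)
  parents <- lapply(parents, function(p) p[p %in% ids])
  dag <- structure(
    list(terms = ids, namespace = ns[ids], name = nm[ids], parents = parents[ids]),
    class = "go_dag"
  )
  cyc <- find_cycle(dag)
  if (!is.null(cyc))
    stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
  dag$roots <- dag_roots(dag)
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag: %d terms, %d edges, roots: %s>\n",
              length(x$terms), sum(lengths(x$parents)),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

# Kahn toposort; returns NULL if acyclic, otherwise one cycle as a path.
find_cycle <- function(dag) {
  indeg <- lengths(dag$parents)  # edges child -> parent; process parents first
  children <- split(
    rep(names(dag$parents), lengths(dag$parents)),
    unlist(dag$parents, use.names = FALSE)
  )
  # count of unresolved parents per term
  remaining <- lengths(dag$parents)
  queue <- dag$terms[remaining == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(dag$terms)) return(NULL)
  # walk parent pointers inside the unresolved subgraph to exhibit one cycle
  bad <- dag$terms[remaining > 0L]
  cur <- bad[1]; path <- cur
  repeat {
    nxt <- intersect(dag$parents[[cur]], bad)[1]
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt)
    cur <- nxt
  }
}

dag_roots <- function(dag) {
  is_root <- lengths(dag$parents) == 0L
  r <- dag$terms[is_root]
  stats::setNames(r, dag$namespace[r])
}

# Ancestor closure (term itself excluded) for every term, computed once by
# dynamic programming over a topological order.
ancestor_map <- function(dag) {
  anc <- vector("list", length(dag$terms))
  names(anc) <- dag$terms
  remaining <- lengths(dag$parents)
  children <- split(
    rep(names(dag$parents), lengths(dag$parents)),
    unlist(dag$parents, use.names = FALSE)
  )
  queue <- dag$terms[remaining == 0L]
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    pa <- dag$parents[[t]]
    anc[[t]] <- unique(c(pa, unlist(anc[pa], use.names = FALSE)))
    for (ch in children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  anc
}

#' Propagate annotations to all ancestors
#'
#' Closes every protein's term set under the parent relation: a term implies
#' all of its ancestors up to the namespace root. Idempotent.
#'
#' @param annotations named list, protein id -> character vector of term ids.
#' @param dag a [parse_obo()] ontology.
#' @return named list of propagated term sets (sorted, unique).
#' @export
propagate_annotations <- function(annotations, dag) {
  all_terms <- unique(unlist(annotations, use.names = FALSE))
  unknown <- setdiff(all_terms, dag$terms)
  if (length(unknown))
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  anc <- ancestor_map(dag)
  lapply(annotations, function(ts) {
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
}

#' Ordered term vocabulary for one namespace
#'
#' Terms of the namespace with at least one positive (propagated) training
#' annotation, in stable lexicographic order; positions define the label
#' vector layout.
#'
#' @param annotations propagated annotation list.
#' @param dag ontology.
#' @param namespace one of "MF", "BP", "CC" (or full OBO namespace name).
#' @return character vector of term ids (class `term_index`).
#' @export
build_term_index <- function(annotations, dag, namespace = "MF") {
  long <- names(NAMESPACE_CODES)[match(namespace, NAMESPACE_CODES)]
  if (!is.na(long)) namespace <- long
  used <- unique(unlist(annotations, use.names = FALSE))
  terms <- sort(intersect(used, dag$terms[dag$namespace == namespace]))
  if (!length(terms)) stop("no annotated terms in namespace ", namespace)
  structure(terms, class = "term_index", namespace = namespace)
}

#' Binary label matrix for a set of proteins
#'
#' @param annotations propagated annotation list.
#' @param index a [build_term_index()] vocabulary.
#' @param ids protein ids (default all annotated ones).
#' @return binary matrix, rows = proteins, columns = index terms.
#' @export
label_matrix <- function(annotations, index, ids = names(annotations)) {
  Y <- matrix(0, length(ids), length(index),
              dimnames = list(ids, as.character(index)))
  for (i in seq_along(ids)) {
    hit <- intersect(annotations[[ids[i]]], index)
    Y[i, hit] <- 1
  }
  Y
}

#' Information content of GO terms
#'
#' From propagated training annotations over n proteins: marginal probability
#' P(GO_i) = count_i / n, marginal IC = -log2 P(GO_i), and conditional IC
#' IC(c | Pa(c)) = -log2( count(c) / count(proteins annotated with all
#' parents of c) ), with roots using their marginal IC. Terms with zero count
#' are absent from the table. Base-2 logarithms throughout (configurable).
#'
#' @param annotations propagated annotation list (the training set).
#' @param dag ontology.
#' @param log_base logarithm base for IC (default 2).
#' @return data.frame(term, count, p, ic, cond_ic) of class `ic_table`.
#' @export
compute_ic <- function(annotations, dag, log_base = 2) {
  n <- length(annotations)
  if (n < 1L) stop("need at least one annotated protein")
  tab <- table(unlist(annotations, use.names = FALSE))
  terms <- intersect(dag$terms, names(tab))
  count <- as.integer(tab[terms])
  p <- count / n
  ic <- -log(p, base = log_base)
  cond <- numeric(length(terms))
  sets <- annotations
  for (i in seq_along(terms)) {
    pa <- dag$parents[[terms[i]]]
    if (!length(pa)) {
      cond[i] <- ic[i]
      next
    }
    denom <- sum(vapply(sets, function(s) all(pa %in% s), logical(1)))
    if (denom == 0) {
      warning("term ", terms[i], " has no proteins annotated with all parents; excluded")
      cond[i] <- NA_real_
      next
    }
    cond[i] <- -log(count[i] / denom, base = log_base)
  }
  out <- data.frame(term = terms, count = count, p = p, ic = ic,
                    cond_ic = cond, stringsAsFactors = FALSE)
  out <- out[!is.na(out$cond_ic), ]
  class(out) <- c("ic_table", "data.frame")
  out
}

#' Stratify terms by information-content specificity
#'
#' Buckets at thresholds 5 and 10 bits; boundary values go to the lower
#' bucket (ic = 5 is "IC<5", ic = 10 is "5<IC<10").
#'
#' @param ic numeric vector of IC values (bits), all >= 0.
#' @return character vector in {"IC<5", "5<IC<10", "IC>10"}.
#' @export
ic_category <- function(ic) {
  if (any(!is.finite(ic) | ic < 0)) stop("ic must be finite and non-negative")
  ifelse(ic <= 5, "IC<5", ifelse(ic <= 10, "5<IC<10", "IC>10"))
}

#' Write / read an IC table as TSV
#' @param ic an [compute_ic()] table.
#' @param path file path.
#' @export
write_ic_table <- function(ic, path) {
  utils::write.table(ic, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ic_table
#' @export
read_ic_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("ic_table", "data.frame")
  out
}

#' Read protein -> GO annotations from a two-column TSV
#'
#' Format: `protein_id<TAB>GO:NNNNNNN`, one pair per line, no header.
#'
#' @param path TSV file.
#' @return named list protein id -> character vector of terms.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("protein", "term"))
  split(df$term, df$protein)
}

#' @rdname read_annotations
#' @param annotations named list protein -> terms.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    protein = rep(names(annotations), lengths(annotations)),
    term = unlist(annotations, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Serialize a toy DAG as a minimal OBO file (used by the synthetic module).
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag$terms) {
    writeLines(c(
      "",
      "[Term]",
      paste0("id: ", t),
      paste0("name: ", dag$name[[t]]),
      paste0("namespace: ", dag$namespace[[t]]),
      vapply(dag$parents[[t]], function(p) paste0("is_a: ", p), character(1))
    ), con)
  }
  invisible(path)
}
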