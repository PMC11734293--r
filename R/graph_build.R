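# Construction of protein graphs: contact maps from C-alpha coordinates,
# one-hot residue features, optional external per-residue embeddings, and
# minimal PDB input/output.

# Fixed 25-symbol residue alphabet: the 20 standard amino acids
# (alphabetical), then the extended symbols selenocysteine (U), pyrrolysine
# (O), the ambiguity codes B and Z, and the catch-all X. Any symbol outside
# this alphabet is encoded as X.
GALA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
  "U", "O", "B", "Z", "X"
)

AA3TO1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y", SEC = "U", PYL = "O", ASX = "B", GLX = "Z",
  MSE = "M"
)

#' Residue-residue contact map from C-alpha coordinates
#'
#' Two residues are adjacent when the Euclidean distance between their
#' C-alpha atoms is strictly less than `threshold` angstroms. The diagonal is
#' zero; self-loops are only ever added inside the graph convolution.
#'
#' @param coords numeric |V| x 3 matrix of C-alpha coordinates in angstroms.
#' @param threshold contact distance cutoff in angstroms (default 10).
#' @return binary symmetric |V| x |V| matrix with zero diagonal.
#' @export
build_contact_map <- function(coords, threshold = 10) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L || ncol(coords) != 3L)
    stop("coords must be a |V| x 3 matrix with |V| >= 1")
  bad <- which(!apply(is.finite(coords), 1L, all))
  if (length(bad))
    stop("non-finite coordinates at residue index ", paste(bad, collapse = ", "))
  D <- as.matrix(stats::dist(coords))
  A <- (D < threshold) * 1
  diag(A) <- 0
  dimnames(A) <- NULL
  A
}

#' One-hot encode a residue sequence
#'
#' Each residue becomes a row with a single 1 at the column of its symbol in
#' the fixed 25-symbol alphabet ([GALA_ALPHABET]); symbols outside the
#' alphabet map to the X column.
#'
#' @param sequence residue-symbol string.
#' @return binary length(sequence) x 25 matrix.
#' @export
one_hot_encode <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a non-empty string")
  sym <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(sym, GALA_ALPHABET)
  idx[is.na(idx)] <- match("X", GALA_ALPHABET)
  X <- matrix(0, length(sym), length(GALA_ALPHABET))
  X[cbind(seq_along(sym), idx)] <- 1
  colnames(X) <- GALA_ALPHABET
  X
}

#' Decode a one-hot matrix back to a residue string
#' @param X binary matrix with one 1 per row, 25 columns.
#' @return residue string.
#' @export
one_hot_decode <- function(X) {
  paste(GALA_ALPHABET[max.col(X)], collapse = "")
}

#' Build the node feature matrix
#'
#' Concatenates the one-hot residue block with an optional external
#' per-residue embedding matrix (e.g. the output of a protein language
#' model). Column order is one-hot block first, embedding block second.
#'
#' @param sequence residue string of length |V|.
#' @param embeddings optional |V| x E numeric matrix.
#' @return |V| x F matrix with F = 25 or 25 + E.
#' @export
build_features <- function(sequence, embeddings = NULL) {
  X <- one_hot_encode(sequence)
  if (is.null(embeddings)) return(X)
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) != nrow(X))
    stop("embedding rows (", nrow(embeddings), ") do not match sequence length (",
         nrow(X), ")")
  out <- cbind(X, embeddings)
  colnames(out) <- NULL
  out
}

#' Deterministic pseudo-embedding provider
#'
#' Stand-in for an external protein language model: a fixed, seed-dependent
#' function of residue symbol and position. Used in tests and the synthetic
#' benchmark; real embeddings are supplied as files, never computed here.
#'
#' @param sequence residue string.
#' @param dim embedding dimension.
#' @param seed integer mixed into the hash.
#' @return length(sequence) x dim matrix.
#' @export
pseudo_embeddings <- function(sequence, dim = 32L, seed = 1L) {
  sym <- strsplit(toupper(sequence), "")[[1]]
  code <- match(sym, GALA_ALPHABET)
  code[is.na(code)] <- match("X", GALA_ALPHABET)
  i <- seq_along(sym)
  j <- seq_len(dim)
  outer(code * 0.731 + i * 0.137, j * 0.389, function(a, b) sin(a * b + seed * 0.917))
}

#' Assemble a protein graph
#'
#' @param id protein identifier.
#' @param sequence residue string.
#' @param adjacency binary symmetric contact matrix (zero diagonal). If NULL
#'   and `coords` given, built with [build_contact_map()].
#' @param coords optional |V| x 3 C-alpha coordinates (angstroms).
#' @param embeddings optional |V| x E external embedding matrix.
#' @param threshold contact threshold used when adjacency is derived.
#' @param resno optional author residue numbers (defaults to 1..|V|).
#' @return object of class `protein_graph` with fields id, sequence,
#'   adjacency, features, coords, resno.
#' @export
protein_graph <- function(id, sequence, adjacency = NULL, coords = NULL,
                          embeddings = NULL, threshold = 10, resno = NULL) {
  n <- nchar(sequence)
  if (is.null(adjacency)) {
    if (is.null(coords)) stop("either adjacency or coords must be supplied")
    adjacency <- build_contact_map(coords, threshold)
  }
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != n || ncol(adjacency) != n)
    stop("adjacency dimension does not match sequence length")
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n) stop("coords rows do not match sequence length")
  }
  if (is.null(resno)) resno <- seq_len(n)
  g <- list(
    id = id,
    sequence = sequence,
    adjacency = adjacency,
    features = build_features(sequence, embeddings),
    coords = coords,
    resno = resno
  )
  class(g) <- "protein_graph"
  g
}

#' @export
print.protein_graph <- function(x, ...) {
  cat(sprintf("<protein_graph %s: %d residues, %d contacts, %d features%s>\n",
              x$id, nchar(x$sequence), sum(x$adjacency) / 2, ncol(x$features),
              if (is.null(x$coords)) "" else ", coords"))
  invisible(x)
}

# Symmetrically normalized adjacency with self-loops,
# D^{-1/2} (A + I) D^{-1/2}, as a sparse matrix for the GCN.
norm_adjacency <- function(A) {
  At <- A + diag(nrow(A))
  d <- 1 / sqrt(rowSums(At))
  Matrix::Matrix(At * outer(d, d), sparse = TRUE)
}

#' Read one chain of a PDB file
#'
#' Minimal fixed-width parser for ATOM records: first model only, one C-alpha
#' per residue, highest-occupancy altloc. Residues present in the chain but
#' lacking a C-alpha atom are skipped with a warning. The sequence is derived
#' from the ATOM records so that sequence and coordinates always co-index.
#'
#' @param path PDB file.
#' @param chain chain identifier; default `NULL` takes the first chain.
#' @return list(sequence, coords, resno, chain).
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  atom <- lines[substr(lines, 1, 6) == "ATOM  "]
  if (!length(atom)) stop("no ATOM records in ", path)
  chains <- substr(atom, 22, 22)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    stop("chain '", chain, "' not found; available chains: ",
         paste(sort(unique(chains)), collapse = ", "))
  atom <- atom[chains == chain]
  reskey <- paste0(trimws(substr(atom, 23, 26)), substr(atom, 27, 27))
  resname <- trimws(substr(atom, 18, 20))
  atname <- trimws(substr(atom, 13, 16))
  occ <- suppressWarnings(as.numeric(substr(atom, 55, 60)))
  occ[is.na(occ)] <- 1
  keys <- unique(reskey)
  seqc <- character(0); xyz <- NULL; resno <- integer(0); skipped <- character(0)
  for (k in keys) {
    rows <- which(reskey == k)
    ca <- rows[atname[rows] == "CA"]
    if (!length(ca)) {
      skipped <- c(skipped, k)
      next
    }
    ca <- ca[which.max(occ[ca])]
    seqc <- c(seqc, {
      s <- AA3TO1[resname[ca]]
      if (is.na(s)) "X" else s
    })
    xyz <- rbind(xyz, as.numeric(c(substr(atom[ca], 31, 38),
                                   substr(atom[ca], 39, 46),
                                   substr(atom[ca], 47, 54))))
    resno <- c(resno, as.integer(trimws(substr(atom[ca], 23, 26))))
  }
  if (!length(seqc)) stop("no C-alpha atoms found for chain '", chain, "' in ", path)
  if (length(skipped))
    warning("skipped ", length(skipped), " residue(s) lacking a C-alpha atom: ",
            paste(skipped, collapse = ", "))
  list(sequence = paste(seqc, collapse = ""), coords = unname(xyz),
       resno = resno, chain = chain)
}

# Write a C-alpha-only PDB file for a protein graph (synthetic data,
# attribution projection). `bfactor` optionally fills the temperature column.
write_ca_pdb <- function(graph, path, bfactor = NULL) {
  if (is.null(graph$coords)) stop("graph has no coordinates")
  n <- nchar(graph$sequence)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  sym <- strsplit(graph$sequence, "")[[1]]
  three <- names(AA3TO1)[match(sym, AA3TO1)]
  three[is.na(three)] <- "UNK"
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, three[i], graph$resno[i],
            graph$coords[i, 1], graph$coords[i, 2], graph$coords[i, 3],
            1.00, bfactor[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write / read a dense numeric matrix in the package's text container
#'
#' Plain-text format with a shape header line `#galamat <nrow> <ncol>`
#' followed by whitespace-separated values in row-major order. Used for
#' external embedding matrices and precomputed contact maps.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix_file` returns the matrix.
#' @export
write_matrix_file <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#galamat %d %d", nrow(m), ncol(m)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_file
#' @export
read_matrix_file <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\\s+")[[1]]
  if (hdr[1] != "#galamat") stop("not a galamat file: ", path)
  nr <- as.integer(hdr[2]); nc <- as.integer(hdr[3])
  vals <- scan(path, skip = 1L, quiet = TRUE)
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}
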