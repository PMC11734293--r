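# Grad-CAM residue attribution on contact-map graphs. The feature map is the
# output of the final graph convolution layer F (L x D); the gradient of the
# pre-sigmoid logit of the chosen GO term with respect to F weights it:
#   CAM_i = ReLU( sum_j W_ij F_ij / D ),  W = d(logit) / dF,
# then the profile is min-max normalized to [0, 100] per protein.

#' Residue contribution profile for one predicted GO term
#'
#' @param graph a [protein_graph()].
#' @param trained trained state or `gala_model`.
#' @param term GO term id (must be in the model vocabulary) or column index.
#' @return object of class `cam_profile`: fields id, term, scores (length L
#'   in \[0, 100\]), raw (pre-normalization values).
#' @export
cam_profile <- function(graph, trained, term) {
  model <- if (inherits(trained, "gala_trained")) trained$model else trained
  if (is.character(term)) {
    if (is.null(model$terms)) stop("model carries no term vocabulary; pass a column index")
    cls <- match(term, as.character(model$terms))
    if (is.na(cls)) stop("unknown term: ", term)
  } else {
    cls <- as.integer(term)
    if (cls < 1L || cls > model$config$n_classes) stop("term index out of range")
    term <- if (!is.null(model$terms)) as.character(model$terms)[cls] else as.character(cls)
  }
  fb <- forward_batch(model, list(graph), training = FALSE)
  logit_el <- tp_element(fb$tp, fb$logits_id, 1L, cls)
  grads <- tp_backward(fb$tp, logit_el)
  Fm <- tp_val(fb$tp, fb$Hid)
  W <- grads[[fb$Hid]]
  if (is.null(W)) W <- Fm * 0
  raw <- pmax(rowSums(W * Fm) / ncol(Fm), 0)
  scores <- normalize_cam(raw)
  structure(list(id = graph$id, term = term, scores = scores, raw = raw,
                 resno = graph$resno),
            class = "cam_profile")
}

# Min-max normalization to [0, 100]; a constant (incl. all-zero) raw profile
# maps to all zeros so degenerate gradients never blow up.
normalize_cam <- function(raw) {
  rng <- max(raw) - min(raw)
  if (rng == 0) return(raw * 0)
  (raw - min(raw)) / rng * 100
}

#' @export
print.cam_profile <- function(x, ...) {
  cat(sprintf("<cam_profile %s / %s: %d residues, max score at residue %d>\n",
              x$id, x$term, length(x$scores), which.max(x$scores)))
  invisible(x)
}

#' Project a contribution profile onto a structure's B-factor column
#'
#' Writes a copy of the PDB with the temperature-factor column of every atom
#' of each residue in the chain replaced by the residue's contribution score
#' (fixed-width columns 61-66, two decimals).
#'
#' @param profile a [cam_profile()] (or a plain numeric vector of scores).
#' @param structure_path input PDB file.
#' @param out_path output PDB file.
#' @param chain chain identifier (default: first chain in the file).
#' @return out_path, invisibly.
#' @export
cam_to_pdb <- function(profile, structure_path, out_path, chain = NULL) {
  scores <- if (inherits(profile, "cam_profile")) profile$scores else profile
  lines <- readLines(structure_path, warn = FALSE)
  is_atom <- substr(lines, 1, 6) == "ATOM  "
  chains <- substr(lines[is_atom], 22, 22)
  if (is.null(chain)) chain <- chains[1]
  sel <- which(is_atom)[chains == chain]
  if (!length(sel)) stop("chain '", chain, "' not found in ", structure_path)
  reskey <- paste0(trimws(substr(lines[sel], 23, 26)), substr(lines[sel], 27, 27))
  keys <- unique(reskey)
  if (length(keys) != length(scores))
    stop("profile length (", length(scores), ") does not match residue count (",
         length(keys), ") of chain ", chain)
  bf <- sprintf("%6.2f", scores[match(reskey, keys)])
  lines[sel] <- paste0(substr(lines[sel], 1, 60), bf,
                       substring(lines[sel], 67))
  writeLines(lines, out_path)
  invisible(out_path)
}

#' ROC-AUC of a contribution profile against known site residues
#'
#' Rank-based (Mann-Whitney) AUC of the CAM scores as a ranking of site
#' versus non-site residues; ties count 0.5.
#'
#' @param profile a [cam_profile()] or numeric score vector.
#' @param sites integer indices (1-based) of the site residues; must be a
#'   non-empty proper subset.
#' @return scalar in \[0, 1\].
#' @export
cam_site_auc <- function(profile, sites) {
  scores <- if (inherits(profile, "cam_profile")) profile$scores else profile
  sites <- unique(as.integer(sites))
  if (!length(sites) || length(sites) >= length(scores) ||
      any(sites < 1L | sites > length(scores)))
    stop("sites must be a non-empty proper subset of residue indices")
  lab <- seq_along(scores) %in% sites
  r <- rank(scores)
  n1 <- sum(lab); n0 <- sum(!lab)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write a contribution profile as TSV
#'
#' Columns: residue_index (0-based), author_residue_number, symbol,
#' cam_score.
#'
#' @param profile a [cam_profile()].
#' @param graph the profiled [protein_graph()] (for symbols/numbering).
#' @param path output TSV.
#' @export
write_cam_tsv <- function(profile, graph, path) {
  df <- data.frame(
    residue_index = seq_along(profile$scores) - 1L,
    author_residue_number = graph$resno,
    symbol = strsplit(graph$sequence, "")[[1]],
    cam_score = sprintf("%.4f", profile$scores)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
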