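#' @useDynLib songphylo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimize runif rnorm rexp rbinom pchisq pt qchisq
#'   sd var median cor quantile setNames rpois complete.cases
#' @importFrom utils read.csv write.csv head capture.output
NULL

# ---- validation -------------------------------------------------------------

#' Validate a phylogeny
#'
#' Checks the structural invariants every downstream likelihood relies on:
#' a single root, one parent per non-root node, unique tip labels, and
#' finite non-negative branch lengths.
#'
#' @param tree an object of class `"phylo"` (ape).
#' @return `tree`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0")
  }
  child <- tree$edge[, 2L]
  if (anyDuplicated(child)) stop("a node has more than one parent")
  all_nodes <- seq_len(n_tip + tree$Nnode)
  roots <- setdiff(all_nodes, child)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  invisible(tree)
}

# positional scan for unbalanced parentheses so parse errors name the offset
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at end of string")
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("malformed Newick: missing terminal ';' at position ", nchar(text))
  }
  invisible(TRUE)
}

# ---- Newick I/O -------------------------------------------------------------

#' Parse a Newick string into a validated phylogeny
#'
#' Wraps [ape::read.tree()] with strict validation and deterministic
#' polytomy resolution: children of a polytomy are ordered by their smallest
#' descendant tip label and combined left-to-right with zero-length branches,
#' so repeated parses of the same string give byte-identical trees and all
#' likelihoods are unaffected (they are invariant to zero-length resolution).
#'
#' @param text a Newick string (single tree, branch lengths required on all
#'   non-root edges).
#' @param resolve_polytomies logical; resolve multifurcations into binary
#'   nodes with zero-length branches (default `TRUE`).
#' @return a validated `"phylo"` object.
#' @export
parse_newick <- function(text, resolve_polytomies = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: ape could not parse the string")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (is.null(tree$edge.length)) stop("Newick string lacks branch lengths")
  if (resolve_polytomies && !ape::is.binary(tree)) {
    tree <- sort_children(tree)
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  validate_phylogeny(tree)
  tree
}

#' Read a Newick file
#'
#' @param path path to a file containing a single Newick tree.
#' @inheritParams parse_newick
#' @return a validated `"phylo"` object.
#' @export
read_newick <- function(path, resolve_polytomies = TRUE) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""),
               resolve_polytomies = resolve_polytomies)
}

#' Write a phylogeny as Newick
#'
#' Emits branch lengths with 10 significant digits; internal node labels,
#' if present, are preserved.
#'
#' @param tree a `"phylo"` object.
#' @param path optional file path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# reorder children of every node by smallest descendant tip label
sort_children <- function(tree) {
  n_tip <- length(tree$tip.label)
  min_lab <- character(n_tip + tree$Nnode)
  min_lab[seq_len(n_tip)] <- tree$tip.label
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    if (min_lab[p] == "" || min_lab[ch] < min_lab[p]) min_lab[p] <- min_lab[ch]
  }
  # rebuild the edge list recursively with sibling order by min label
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- split(tree$edge.length, tree$edge[, 1L])
  root <- n_tip + 1L
  new_edge <- matrix(0L, nrow(tree$edge), 2L)
  new_len <- numeric(nrow(tree$edge))
  k <- 0L
  rec <- function(node) {
    ch <- kids[[as.character(node)]]
    if (is.null(ch)) return(invisible(NULL))
    ln <- elen[[as.character(node)]]
    ord <- order(min_lab[ch])
    for (j in ord) {
      k <<- k + 1L
      new_edge[k, ] <<- c(node, ch[j])
      new_len[k] <<- ln[j]
      rec(ch[j])
    }
  }
  rec(root)
  out <- tree
  out$edge <- new_edge
  out$edge.length <- new_len
  attr(out, "order") <- "cladewise"
  out
}

# ---- pruning ----------------------------------------------------------------

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips not in `keep`, suppressing the resulting unary nodes and
#' summing their branch lengths, so root-to-tip depths of retained taxa are
#' unchanged.
#'
#' @param tree a `"phylo"` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `"phylo"` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  out <- ape::keep.tip(tree, keep)
  validate_phylogeny(out)
  out
}

# ---- covariance -------------------------------------------------------------

#' Phylogenetic covariance matrix
#'
#' Under Brownian motion the covariance of two tips is the root-to-tip path
#' length they share. Computed by a single edge sweep: each edge adds its
#' length to all pairs of tips descended from it.
#'
#' @param tree a `"phylo"` object.
#' @return a symmetric positive semi-definite matrix with tip-label dimnames;
#'   diagonal entries are root-to-tip depths.
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree)
  n_tip <- length(tree$tip.label)
  desc <- edge_tip_descendants(tree)
  C <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nrow(tree$edge))) {
    d <- desc[[i]]
    C[d, d] <- C[d, d] + tree$edge.length[i]
  }
  C
}

# list, per edge (row of tree$edge), of tip indices descended from that edge
edge_tip_descendants <- function(tree) {
  n_tip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  idx <- match(paste(po$edge[, 1L], po$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  node_desc <- vector("list", n_tip + tree$Nnode)
  for (t in seq_len(n_tip)) node_desc[[t]] <- t
  out <- vector("list", nrow(tree$edge))
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    out[[idx[i]]] <- node_desc[[ch]]
    node_desc[[p]] <- c(node_desc[[p]], node_desc[[ch]])
  }
  out
}

# root-to-node depths for all nodes (tips and internals)
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- numeric(n_tip + tree$Nnode)
  pr <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pr$edge))) {
    depth[pr$edge[i, 2L]] <- depth[pr$edge[i, 1L]] + pr$edge.length[i]
  }
  depth
}
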