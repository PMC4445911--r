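#' Read phylogenies from a Newick or NEXUS file
#'
#' Autodetects the format (a file whose first non-blank line is `#NEXUS` is
#' read with [ape::read.nexus()], anything else with [ape::read.tree()]) and
#' returns the trees in file order as a plain list of `phylo` objects. Tip
#' labels are normalised (whitespace collapsed to underscores) so they match
#' trait-table species identifiers exactly.
#'
#' @param path Path to a tree file containing one or more rooted trees with
#'   branch lengths.
#' @param underscore If `TRUE` (default), unify spaces and underscores in tip
#'   labels.
#' @return A list of `phylo` objects.
#' @export
parse_trees <- function(path, underscore = TRUE) {
  if (!file.exists(path)) stopf("tree file not found: %s", path)
  first <- ""
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0) stopf("no trees found in %s", path)
  first <- toupper(trimws(nonblank[1]))
  if (startsWith(first, "#NEXUS")) {
    trees <- ape::read.nexus(path)
  } else {
    check_newick_balance(paste(lines, collapse = "\n"))
    trees <- tryCatch(ape::read.tree(path),
                      error = function(e) stopf("malformed Newick in %s: %s",
                                                path, conditionMessage(e)))
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0 || is.null(trees[[1]])) {
    stopf("no trees found in %s", path)
  }
  lapply(trees, function(tr) {
    tr$tip.label <- normalise_labels(tr$tip.label, underscore = underscore)
    tr
  })
}

# Cheap structural pre-check so a malformed Newick reports the character
# offset of the first unbalanced parenthesis.
check_newick_balance <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stopf("malformed Newick: unmatched ')' at character %d", i)
    }
  }
  if (depth != 0L) {
    stopf("malformed Newick: %d unmatched '(' by end of input (offset %d)",
          depth, length(chars))
  }
  invisible(TRUE)
}

#' Prune a phylogeny to a set of taxa
#'
#' Returns the induced subtree on the requested taxa; internal degree-2 nodes
#' are collapsed with their branch lengths summed, so root-to-tip depths and
#' shared path lengths are preserved. Requested taxa absent from the tree are
#' reported in a warning and in `attr(, "mismatch")`, never silently dropped.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels to keep.
#' @param underscore Passed to the label normalisation.
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, taxa, underscore = TRUE) {
  taxa <- normalise_labels(as.character(taxa), underscore = underscore)
  tips <- normalise_labels(tree$tip.label, underscore = underscore)
  tree$tip.label <- tips
  found <- intersect(taxa, tips)
  missing_taxa <- setdiff(taxa, tips)
  if (length(found) < 2) {
    stopf("fewer than 2 of the requested taxa are in the tree (%d of %d)",
          length(found), length(taxa))
  }
  if (length(missing_taxa) > 0) {
    warn(sprintf("prune_to_taxa: %d taxa not in tree: %s",
                 length(missing_taxa),
                 paste(head(missing_taxa, 10), collapse = ", ")))
  }
  # keep the stem from the old root to the new root as a root edge so that
  # root-to-tip depths (and hence the VCV) are preserved exactly
  out <- ape::keep.tip(tree, found)
  d_old <- ape::node.depth.edgelength(tree)[match(found, tree$tip.label)]
  d_new <- ape::node.depth.edgelength(out)[match(found, out$tip.label)]
  stem <- mean(d_old - d_new)
  if (stem > 1e-12) out$root.edge <- stem
  attr(out, "mismatch") <- missing_taxa
  out
}

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the covariance of a trait between two tips is
#' proportional to the branch length shared on their root-to-tip paths, i.e.
#' the depth of their most recent common ancestor; the variance of a tip is
#' its root-to-tip depth. `vcv_from_tree()` returns this matrix with rows and
#' columns keyed by tip label.
#'
#' @param tree A rooted `phylo` with non-negative branch lengths.
#' @return A symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
vcv_from_tree <- function(tree) {
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch length in tree")
  V <- ape::vcv.phylo(tree)
  # a root edge is shared history of every tip pair: add it everywhere
  if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    V <- V + tree$root.edge
  }
  V
}

#' Pagel's lambda transformation of a VCV
#'
#' Multiplies every off-diagonal entry of the phylogenetic covariance matrix
#' by lambda while leaving tip variances unchanged. lambda = 1 keeps the full
#' Brownian structure; lambda = 0 erases shared history, making species
#' independent.
#'
#' @param V A phylogenetic VCV matrix.
#' @param lambda Scalar in \[0, 1\].
#' @return The transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stopf("lambda must be a single value in [0, 1]")
  }
  d <- diag(V)
  W <- V * lambda
  diag(W) <- d
  W
}
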