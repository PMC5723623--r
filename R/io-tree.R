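#' Read a dated ultrametric tree from a newick file
#'
#' Thin wrapper around [ape::read.tree()] with the validation the stratified
#' likelihood needs: a single rooted binary tree, branch lengths present
#' (interpreted as Ma), unique tip labels. Internal labels and quoted labels
#' are preserved; annotations other than branch lengths are ignored. Node
#' ages (Ma before present) are computed as tree height minus root-to-node
#' distance.
#'
#' @param path Path to a newick file, or a list with `text =` a newick string.
#' @param check_ultrametric If `TRUE` (default), reject trees whose tip ages
#'   deviate from 0 by more than `1e-6 *` tree height. Disable to read trees
#'   that still need [sanitize_branch_lengths()].
#' @return An [ape::phylo] object with class `c("dated_tree", "phylo")`.
#' @seealso [node_ages()], [write_newick()], [sanitize_branch_lengths()]
#' @export
read_newick <- function(path, check_ultrametric = TRUE) {
  txt <- if (is.list(path) && !is.null(path$text)) path$text else paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_syntax(txt)
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) abort("malformed newick: ape could not parse the string")
  if (inherits(tr, "multiPhylo")) abort("file contains more than one tree")
  as_dated_tree(tr, check_ultrametric = check_ultrametric)
}

# minimal structural scan so syntax errors carry a character offset
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) abort(sprintf("malformed newick: unbalanced ')' at character %d", i))
    }
  }
  if (depth != 0L) abort(sprintf("malformed newick: %d unclosed '(' at end of string", depth))
  if (!grepl(";", txt, fixed = TRUE)) abort(sprintf("malformed newick: missing ';' terminator at character %d", nchar(txt)))
  invisible(TRUE)
}

#' Validate a phylo object as a dated tree
#'
#' @param tree An [ape::phylo] object.
#' @inheritParams read_newick
#' @return The tree, classed `c("dated_tree", "phylo")`.
#' @export
as_dated_tree <- function(tree, check_ultrametric = TRUE) {
  if (!inherits(tree, "phylo")) abort("not a phylo object")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length)) abort("tree has missing branch lengths")
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  if (!ape::is.binary(tree)) abort("tree must be fully bifurcating")
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels")
  if (check_ultrametric) assert_ultrametric(tree)
  class(tree) <- unique(c("dated_tree", class(tree)))
  tree
}

#' Node ages of a dated tree
#'
#' @param tree A `dated_tree` / [ape::phylo] object.
#' @return Numeric vector of ages (Ma before present) indexed by node id
#'   (tips `1..n`, then internal nodes, ape convention).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(ape::Ntip(tree))])
  height - depth
}

#' Tree height (root age) in Ma
#' @param tree A dated tree.
#' @return Root age.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

assert_ultrametric <- function(tree, tol_factor = 1e-6) {
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  h <- tree_height(tree)
  bad <- abs(ages[seq_len(n)]) > tol_factor * h
  if (any(bad)) {
    abort(sprintf(
      "tree is not ultrametric: %d tip(s) have nonzero age (max |age| = %.3g, tolerance %.3g); e.g. %s",
      sum(bad), max(abs(ages[seq_len(n)])), tol_factor * h,
      paste(head(tree$tip.label[bad], 3), collapse = ", ")
    ))
  }
  invisible(tree)
}

#' Write a dated tree to newick
#'
#' @param tree A tree.
#' @param path Output path; if `NULL`, the newick string is returned.
#' @param digits Significant digits for branch lengths (default 12; enough
#'   for 1e-9 round-trip stability on trees hundreds of Ma tall).
#' @return `path` invisibly, or the newick string when `path` is `NULL`.
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Repair nonpositive branch lengths
#'
#' Dated consensus trees (e.g. MCC trees) occasionally carry zero or
#' negative branch lengths that a likelihood over time segments cannot use.
#' Two repair policies are available:
#'
#' * `"epsilon"` (default): every nonpositive length is replaced by
#'   `1e-6 *` tree height.
#' * `"add-constant"`: every nonpositive length is increased by exactly
#'   `constant` (a replication mode mirroring a manual +0.3 edit sometimes
#'   applied to published trees).
#'
#' Either repair shifts the depths of the edited branch's descendants, so
#' afterwards the tree is re-checked and, if ultrametricity broke,
#' terminal branches are extended so that all tip ages return to zero.
#'
#' The function always succeeds, warns once per edited branch, and attaches
#' the edit report as attribute `"edits"` (a tibble with parent/child node,
#' old and new length). Applying it to a clean tree returns the tree
#' unchanged with an empty report. Idempotent.
#'
#' @param tree A tree (need not pass the ultrametricity check yet).
#' @param policy `"epsilon"` or `"add-constant"`.
#' @param constant Amount added under `"add-constant"` (default 0.3).
#' @return The repaired `dated_tree`, with attribute `"edits"`.
#' @export
sanitize_branch_lengths <- function(tree, policy = c("epsilon", "add-constant"), constant = 0.3) {
  policy <- match.arg(policy)
  if (!inherits(tree, "phylo")) abort("not a phylo object")
  h <- tree_height(tree)
  bad <- which(tree$edge.length <= 0)
  old <- tree$edge.length[bad]
  if (length(bad)) {
    new <- if (policy == "epsilon") rep(1e-6 * h, length(bad)) else old + constant
    tree$edge.length[bad] <- new
    for (i in seq_along(bad)) {
      warn(sprintf(
        "branch %d (node %d -> %d): length %.6g replaced by %.6g",
        bad[i], tree$edge[bad[i], 1], tree$edge[bad[i], 2], old[i], new[i]
      ))
    }
    tree <- rezero_tips(tree)
  }
  edits <- tibble::tibble(
    edge = bad,
    parent = tree$edge[bad, 1], child = tree$edge[bad, 2],
    old_length = old, new_length = tree$edge.length[bad]
  )
  tree <- as_dated_tree(tree)
  attr(tree, "edits") <- edits
  tree
}

# extend terminal branches so every tip age is exactly 0
rezero_tips <- function(tree) {
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  if (all(abs(ages[seq_len(n)]) <= 1e-6 * tree_height(tree))) return(tree)
  tip_edge <- match(seq_len(n), tree$edge[, 2])
  tree$edge.length[tip_edge] <- tree$edge.length[tip_edge] + ages[seq_len(n)]
  if (any(tree$edge.length[tip_edge] <= 0)) {
    abort("cannot re-zero tip ages: a terminal branch would become nonpositive")
  }
  tree
}
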