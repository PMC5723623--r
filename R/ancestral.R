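#' Marginal ancestral range probabilities
#'
#' Computes, for every internal node, the marginal probability of each
#' range state conditional on the tip ranges and the supplied parameters
#' (typically maximum-likelihood estimates), under the same stratified
#' transition matrices and cladogenetic event table as
#' [stratified_loglik()]. Marginals are obtained by combining the "down"
#' partials from the pruning pass with "up" partials propagated from the
#' root (re-rooting algebra); each node's vector sums to 1 and places zero
#' mass on the null range.
#'
#' @inheritParams stratified_loglik
#' @return An object of class `node_range_probs`: a list with `probs`
#'   (matrix, one row per internal node id, one column per state label),
#'   the `space`, the `tree` and the achieved `loglik`.
#' @seealso [crown_probs()], [stem_probs()]
#' @export
ancestral_marginals <- function(tree, geog, config, model, params,
                                root_prior = "uniform", max_range_size = NULL) {
  fit <- stratified_loglik(tree, geog, config, model, params,
    root_prior = root_prior, max_range_size = max_range_size, internals = TRUE
  )
  if (!is.finite(fit$loglik)) abort("likelihood is zero under these parameters; no marginals")
  S <- length(fit$space$mask)
  ntip <- ape::Ntip(fit$tree)
  nnode <- fit$tree$Nnode
  root <- ntip + 1L
  up <- vector("list", ntip + nnode)
  up[[root]] <- fit$prior
  cl <- fit$clado
  edges <- fit$postorder_edge

  probs <- matrix(NA_real_, nnode, S, dimnames = list(root:(ntip + nnode), fit$space$label))
  probs[1, ] <- norm1(up[[root]] * fit$part[[root]])

  for (k in rev(seq_len(nrow(edges)))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    sib_k <- setdiff(fit$pending[[p]], k)
    w_sib <- fit$edge_w[[sib_k]]
    up_p <- up[[p]]
    # distribute the parent's up-vector through the cladogenetic events,
    # weighting by the sibling subtree's propagated partial
    contrib <- up_p[cl$parent] * cl$prob * w_sib[cl$right]
    up_top <- numeric(S)
    agg <- rowsum(contrib, group = cl$left)
    up_top[as.integer(rownames(agg))] <- agg[, 1]
    u <- as.numeric(crossprod(fit$edge_M[[k]], up_top))
    s <- sum(u)
    if (s > 0) u <- u / s
    up[[ch]] <- u
    if (ch > ntip) {
      probs[ch - ntip, ] <- norm1(u * fit$part[[ch]])
    }
  }
  structure(
    list(probs = probs, space = fit$space, tree = fit$tree, loglik = fit$loglik),
    class = "node_range_probs"
  )
}

norm1 <- function(v) {
  s <- sum(v)
  if (s <= 0 || !is.finite(s)) abort("cannot normalize a zero/non-finite probability vector")
  v / s
}

#' @export
print.node_range_probs <- function(x, ...) {
  cat(sprintf(
    "<node_range_probs> %d internal nodes x %d states (lnL %.4f)\n",
    nrow(x$probs), ncol(x$probs), x$loglik
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.node_range_probs <- function(x, ...) {
  tibble::tibble(
    node = rep(as.integer(rownames(x$probs)), each = ncol(x$probs)),
    state = rep(colnames(x$probs), nrow(x$probs)),
    prob = as.numeric(t(x$probs))
  ) |> dplyr::filter(.data$prob > 0)
}

mrca_node <- function(tree, tips) {
  bad <- setdiff(tips, tree$tip.label)
  if (length(bad)) abort(sprintf("tips not in tree: %s", paste(bad, collapse = ", ")))
  if (length(tips) == 1L) {
    return(tree$edge[match(match(tips, tree$tip.label), tree$edge[, 2]), 1])
  }
  ape::getMRCA(tree, tips)
}

#' Marginal probabilities at crown and stem nodes
#'
#' `crown_probs()` returns the marginal range probabilities at the most
#' recent common ancestor of `tips`; `stem_probs()` at that node's parent
#' (the stem node, i.e. the divergence from the sister lineage). For a
#' single tip the "crown" is its direct ancestor node.
#'
#' @param x A `node_range_probs` object.
#' @param tips Character vector of tip labels delimiting the clade.
#' @return A named numeric probability vector over states.
#' @export
crown_probs <- function(x, tips) {
  x$probs[as.character(mrca_node(x$tree, tips)), ]
}

#' @rdname crown_probs
#' @export
stem_probs <- function(x, tips) {
  node <- mrca_node(x$tree, tips)
  root <- ape::Ntip(x$tree) + 1L
  if (node == root) abort("the clade's crown is the root; it has no stem node")
  parent <- x$tree$edge[match(node, x$tree$edge[, 2]), 1]
  x$probs[as.character(parent), ]
}

#' Highest-probability state of a probability vector
#'
#' @param p Named probability vector (as returned by [crown_probs()]).
#' @return One-row tibble with `state`, `prob` and a `tie` flag (ties are
#'   broken lexicographically by state label).
#' @export
top_state <- function(p) {
  best <- max(p)
  cand <- sort(names(p)[p >= best - 1e-12])
  tibble::tibble(state = cand[1], prob = unname(best), tie = length(cand) > 1L)
}
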