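#' Simulate a dated Yule tree
#'
#' Pure-birth simulation: starting from the root split with two lineages,
#' successive exponential waiting times with rate `k * lambda` (k = current
#' lineage count) separate speciation events; the lineage that splits is
#' chosen uniformly. When the requested tip count is reached, a final
#' waiting time with rate `n * lambda` runs to the present, so the returned
#' tree is ultrametric.
#'
#' @param n_tips Number of tips (>= 2).
#' @param lambda Birth rate per lineage per Ma (> 0).
#' @param seed Integer seed (mandatory: simulated inputs must be
#'   reproducible).
#' @param target_height Optional height (Ma); the tree is rescaled to it.
#' @return A `dated_tree` with tips `t1 ... tn`.
#' @export
#' @examples
#' tr <- simulate_yule_tree(10, lambda = 0.1, seed = 1)
simulate_yule_tree <- function(n_tips, lambda, seed, target_height = NULL) {
  if (n_tips < 2) abort("need at least 2 tips")
  if (lambda <= 0) abort("lambda must be positive")
  if (missing(seed) || is.null(seed)) abort("a seed is required")
  set.seed(seed)
  # children[[i]]: the two daughter lineage ids of lineage i (NULL = tip)
  birth <- c(0, 0)
  children <- list(NULL, NULL)
  alive <- c(1L, 2L)
  t <- 0
  repeat {
    k <- length(alive)
    t <- t + rexp(1, k * lambda)
    if (k == n_tips) break
    who <- alive[sample.int(k, 1)]
    id1 <- length(birth) + 1L
    id2 <- length(birth) + 2L
    birth <- c(birth, t, t)
    children <- c(children, list(NULL, NULL))
    children[[who]] <- c(id1, id2)
    alive <- c(setdiff(alive, who), id1, id2)
  }
  present <- t
  scale <- if (is.null(target_height)) 1 else target_height / present
  tip_counter <- new.env(parent = emptyenv())
  tip_counter$i <- 0L
  nwk <- function(id) {
    end <- if (is.null(children[[id]])) present else birth[[children[[id]][1]]]
    len <- (end - birth[[id]]) * scale
    if (is.null(children[[id]])) {
      tip_counter$i <- tip_counter$i + 1L
      sprintf("t%d:%.12g", tip_counter$i, len)
    } else {
      sprintf("(%s,%s):%.12g", nwk(children[[id]][1]), nwk(children[[id]][2]), len)
    }
  }
  txt <- sprintf("(%s,%s);", nwk(1L), nwk(2L))
  as_dated_tree(ape::read.tree(text = txt))
}

# rates out of a range state under one epoch's multipliers:
# returns tibble-free list of target state indices and rates
state_rates <- function(space, state, d, e, m) {
  n <- length(space$areas)
  mask <- space$mask[state]
  members <- mask_areas(mask, n)
  to <- integer(0); rate <- numeric(0)
  if (length(members) < space$max_range_size) {
    for (a in setdiff(seq_len(n), members)) {
      k <- space$index_of[bitwOr(mask, bitwShiftL(1L, a - 1L)) + 1L]
      r <- d * sum(m[members, a])
      if (!is.na(k) && r > 0) { to <- c(to, k); rate <- c(rate, r) }
    }
  }
  if (e > 0) {
    for (a in members) {
      k <- space$index_of[bitwAnd(mask, bitwNot(bitwShiftL(1L, a - 1L))) + 1L]
      to <- c(to, k); rate <- c(rate, e)
    }
  }
  list(to = to, rate = rate)
}

#' Simulate range evolution along a dated tree
#'
#' Generative counterpart of [stratified_loglik()]: the root range is drawn
#' uniformly from the non-null states (or fixed); along every branch,
#' anagenetic gains and losses are simulated with the exact Gillespie
#' algorithm under the epoch-local rate matrix, truncating event waiting
#' times at epoch boundaries so rates switch exactly where the epochs do;
#' at every internal node a cladogenetic event is drawn from the model's
#' event table. A lineage whose range hits the null range is extinct in
#' place; replicates in which any tip ends up with a null range are
#' rejected and redrawn (tree and tip set stay fixed), up to `max_tries`.
#'
#' @inheritParams stratified_loglik
#' @param params Named vector with `d`, `e` and optionally `j`.
#' @param root_range Optional range label (e.g. `"AN"` or `"ANSA"`) or
#'   character vector of areas for the root; drawn uniformly if `NULL`.
#' @param seed Integer seed (mandatory).
#' @param max_tries Cap on whole-replicate redraws when tips go extinct.
#' @return A list with `geog` (a `geog_tbl` of tip ranges), `node_states`
#'   (state index per node, pre-split states at internal nodes), `events`
#'   (tibble log of anagenetic events) and `tries`.
#' @export
simulate_ranges <- function(tree, config, model, params, seed, root_range = NULL,
                            max_range_size = NULL, max_tries = 100) {
  if (missing(seed) || is.null(seed)) abort("a seed is required")
  spec <- model_spec(model)
  d <- params[["d"]]; e <- params[["e"]]
  j <- if ("j" %in% names(params)) params[["j"]] else 0
  tree <- as_dated_tree(tree)
  space <- build_state_space(config$areas, max_range_size %||% length(config$areas))
  ages <- node_ages(tree)
  h <- tree_height(tree)
  if (h >= max(config$boundaries)) abort("tree is older than the last epoch boundary")
  clado <- clado_table(space, spec$name, j = j)
  clado_by_parent <- split(clado[c("left", "right", "prob")], clado$parent)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  set.seed(seed)

  root_state <- if (is.null(root_range)) NULL else state_index(space, root_range)

  for (try in seq_len(max_tries)) {
    node_state <- rep(NA_integer_, ntip + tree$Nnode)
    events <- list()
    node_state[root] <- root_state %||% (1L + sample.int(length(space$mask) - 1L, 1))
    ok <- TRUE
    # preorder: parents before children
    po <- rev(seq_len(nrow(tree$edge)))
    edge_order <- ape::reorder.phylo(tree, "postorder")$edge[po, , drop = FALSE]
    # draw the cladogenetic daughters at a node the first time one of its
    # child edges is visited
    daughters <- vector("list", ntip + tree$Nnode)
    for (kk in seq_len(nrow(edge_order))) {
      p <- edge_order[kk, 1]; ch <- edge_order[kk, 2]
      ps <- node_state[p]
      if (ps == 1L) { # extinct ancestor: whole subtree is extinct
        node_state[ch] <- 1L
        next
      }
      if (is.null(daughters[[p]])) {
        ev <- clado_by_parent[[as.character(ps)]]
        pick <- ev[sample.int(nrow(ev), 1, prob = ev$prob), ]
        daughters[[p]] <- c(pick$left, pick$right)
        daughters[[paste0("used", p)]] <- 0L
      }
      used <- daughters[[paste0("used", p)]] + 1L
      daughters[[paste0("used", p)]] <- used
      st <- daughters[[p]][used]
      # anagenesis from age[p] down to age[ch]
      a <- ages[p]; a_lo <- ages[ch]
      while (a > a_lo + 1e-12 && st != 1L) {
        ep <- epoch_index(config, a - min(1e-9, (a - a_lo) / 2))
        seg_lo <- max(a_lo, config$boundaries[ep])
        rates <- state_rates(space, st, d, e, config$matrices[[ep]])
        tot <- sum(rates$rate)
        if (tot <= 0) { a <- seg_lo; next }
        dt <- rexp(1, tot)
        if (a - dt <= seg_lo) { a <- seg_lo; next }
        a <- a - dt
        st_new <- rates$to[sample.int(length(rates$to), 1, prob = rates$rate)]
        events[[length(events) + 1L]] <- tibble::tibble(
          edge_parent = p, edge_child = ch, age = a,
          from = space$label[st], to = space$label[st_new],
          type = if (space$size[st_new] > space$size[st]) "gain" else "loss"
        )
        st <- st_new
      }
      node_state[ch] <- st
    }
    if (any(node_state[seq_len(ntip)] == 1L)) ok <- FALSE
    if (ok) {
      bits <- t(vapply(node_state[seq_len(ntip)], function(s) {
        as.integer(bitwAnd(bitwShiftR(space$mask[s], 0:(length(space$areas) - 1L)), 1L))
      }, integer(length(space$areas))))
      geog <- new_geog(bits, tree$tip.label, space$areas)
      return(list(
        geog = geog,
        node_states = setNames(space$label[node_state], seq_along(node_state)),
        events = if (length(events)) dplyr::bind_rows(events) else tibble::tibble(),
        tries = try
      ))
    }
  }
  abort(sprintf(
    "all %d replicates produced extinct (null-range) tips; lower e relative to d", max_tries
  ))
}

#' Generate a synthetic node-age table
#'
#' Emulates the shape of a crown/stem age table with 95% HPD bounds:
#' mean ages drawn uniformly, HPD half-widths drawn uniformly, stems offset
#' above crowns. Known counts of window-overlapping and younger rows can
#' be planted for classifier tests; planted rows are constructed so the
#' whole crown/stem pair falls inside (respectively below) the window.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param window Window used for planting (default GAARlandia, 33-35 Ma).
#' @param n_overlapping,n_younger Planted counts; the remaining rows are
#'   drawn without constraint.
#' @param age_range Range of unconstrained crown means (Ma).
#' @param max_halfwidth Largest HPD half-width (Ma).
#' @param areas Labels sampled for `top_area`.
#' @return An age-table tibble accepted by [window_summary()] etc.
#' @export
make_age_fixture <- function(n, seed, window = gaarlandia_window(),
                             n_overlapping = 0, n_younger = 0,
                             age_range = c(1, 60), max_halfwidth = 10,
                             areas = caribbean_areas()) {
  if (n_overlapping + n_younger > n) abort("planted counts exceed n")
  if (missing(seed) || is.null(seed)) abort("a seed is required")
  set.seed(seed)
  kind <- sample(c(
    rep("overlap", n_overlapping), rep("young", n_younger),
    rep("free", n - n_overlapping - n_younger)
  ))
  row <- function(i) {
    k <- kind[i]
    if (k == "overlap") {
      crown <- runif(1, window[[1]], window[[2]])
      stem <- crown + runif(1, 0, 5)
    } else if (k == "young") {
      crown <- runif(1, 0.5, window[[1]] * 0.5)
      stem <- runif(1, crown, window[[1]] * 0.8)
    } else {
      crown <- runif(1, age_range[1], age_range[2])
      stem <- crown + runif(1, 0, 15)
    }
    wc <- runif(1, 0, max_halfwidth); ws <- runif(1, 0, max_halfwidth)
    if (k == "young") {
      wc <- min(wc, (window[[1]] - crown) * 0.9)
      ws <- min(ws, (window[[1]] - stem) * 0.9)
    }
    if (k == "overlap") { # keep the crown interval inside reach of the window
      wc <- max(wc, 0)
    }
    tibble::tibble(
      genus = sprintf("g%03d", i),
      crown_mean = crown, crown_lo = max(0, crown - wc), crown_hi = crown + wc,
      stem_mean = stem, stem_lo = max(0, stem - ws), stem_hi = stem + ws,
      top_area = sample(areas, 1), top_prob = runif(1, 0.2, 1),
      clade = sprintf("g%03d", i)
    )
  }
  purrr::map_dfr(seq_len(n), row)
}
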