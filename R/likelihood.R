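#' @noRd
expm_mat <- function(Q, dt) {
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
  # numerical guard: clip the tiny negative entries expm can produce
  P[P < 0] <- 0
  P
}

# propagator for one epoch's rate matrix: eigendecomposition when well
# conditioned (then exp(Q t) v costs O(S^2) per branch segment), otherwise
# scaling-and-squaring with a per-duration cache
make_propagator <- function(Q) {
  eig <- tryCatch(eigen(Q), error = function(err) NULL)
  if (!is.null(eig)) {
    W <- tryCatch(solve(eig$vectors), error = function(err) NULL)
    if (!is.null(W)) {
      err <- max(abs(Re(eig$vectors %*% (eig$values * W)) - Q))
      if (is.finite(err) && err < 1e-9 * max(1, max(abs(Q)))) {
        return(list(type = "eigen", V = eig$vectors, W = W, lambda = eig$values, Q = Q))
      }
    }
  }
  list(type = "expm", Q = Q, cache = new.env(parent = emptyenv()))
}

prop_vec <- function(prop, dt, v) {
  if (prop$type == "eigen") {
    out <- Re(prop$V %*% (exp(prop$lambda * dt) * (prop$W %*% v)))
    out[out < 0] <- 0
    drop(out)
  } else {
    key <- sprintf("%.12g", dt)
    P <- prop$cache[[key]]
    if (is.null(P)) {
      P <- expm_mat(prop$Q, dt)
      prop$cache[[key]] <- P
    }
    drop(P %*% v)
  }
}

prop_mat <- function(prop, dt) {
  if (prop$type == "eigen") {
    P <- Re(prop$V %*% (exp(prop$lambda * dt) * prop$W))
    P[P < 0] <- 0
    P
  } else {
    expm_mat(prop$Q, dt)
  }
}

# cut the age interval [age_child, age_parent] at every epoch boundary it
# crosses; returns segments youngest first, each with its epoch index
edge_segments <- function(config, age_child, age_parent, tol = 1e-9) {
  b <- config$boundaries
  cuts <- b[b > age_child + tol & b < age_parent - tol]
  pts <- c(age_child, cuts, age_parent)
  lapply(seq_len(length(pts) - 1L), function(s) {
    list(epoch = epoch_index(config, pts[s]), dt = pts[s + 1] - pts[s])
  })
}

# propagate a child-side partial to the parent side of an edge, applying
# per-segment transition matrices in age order (youngest first)
propagate_edge <- function(props, config, age_child, age_parent, v) {
  for (seg in edge_segments(config, age_child, age_parent)) {
    if (seg$dt <= 0) next
    v <- prop_vec(props[[seg$epoch]], seg$dt, v)
  }
  v
}

# full transition matrix over one edge (only needed for marginals), so
# that L_parent_side = M %*% L_child
edge_matrix <- function(props, config, age_child, age_parent, S) {
  M <- NULL
  for (seg in edge_segments(config, age_child, age_parent)) {
    if (seg$dt <= 0) next
    P <- prop_mat(props[[seg$epoch]], seg$dt)
    M <- if (is.null(M)) P else P %*% M
  }
  if (is.null(M)) diag(S) else M
}

# shared validation and precomputation for likelihood-based operations
prepare_biogeo <- function(tree, geog, config, max_range_size = NULL) {
  tree <- as_dated_tree(tree)
  validate_geog(geog, tree)
  if (!identical(attr(geog, "areas") %||% setdiff(names(geog), "taxon"), config$areas)) {
    abort("geography areas and epoch-config areas differ (labels or order)")
  }
  space <- build_state_space(config$areas, max_range_size %||% length(config$areas))
  h <- tree_height(tree)
  if (h >= config$boundaries[length(config$boundaries)]) {
    abort(sprintf(
      "tree height %.3g Ma reaches beyond the last epoch boundary %g Ma",
      h, config$boundaries[length(config$boundaries)]
    ))
  }
  gm <- geog_matrix(geog)[tree$tip.label, , drop = FALSE]
  tip_state <- vapply(seq_len(nrow(gm)), function(i) {
    mask <- sum(bitwShiftL(1L, which(gm[i, ] == 1L) - 1L))
    ix <- space$index_of[mask + 1L]
    if (is.na(ix)) {
      abort(sprintf(
        "tip '%s' occupies %d areas but max_range_size is %d; raise max_range_size",
        rownames(gm)[i], sum(gm[i, ]), space$max_range_size
      ))
    }
    ix
  }, integer(1))
  ages <- node_ages(tree)
  # treat sub-tolerance tip ages as exactly 0
  ages[seq_len(ape::Ntip(tree))] <- 0
  list(tree = tree, space = space, tip_state = tip_state, ages = ages)
}

root_prior_vector <- function(space, root_prior) {
  S <- length(space$mask)
  if (is.numeric(root_prior)) {
    if (length(root_prior) != S) abort("numeric root prior must have one entry per state")
    if (root_prior[1] != 0) abort("root prior must place no mass on the null range")
    return(root_prior / sum(root_prior))
  }
  if (!identical(root_prior, "uniform")) abort("root_prior must be 'uniform' or a numeric vector")
  pr <- rep(1 / (S - 1), S)
  pr[1] <- 0
  pr
}

#' Stratified pruning log-likelihood
#'
#' Felsenstein pruning over the range state space with time-stratified
#' anagenetic transition matrices. Each branch is cut at every epoch
#' boundary it crosses; per segment the transition matrix is the matrix
#' exponential of the epoch-specific rate matrix, and segment matrices are
#' multiplied in age order. Daughter partial likelihoods are combined at
#' internal nodes through the cladogenetic event table of the chosen model;
#' at the root the likelihood is averaged over all non-null states
#' (uniform root prior by default; pluggable).
#'
#' @param tree A dated ultrametric tree whose tips match `geog`.
#' @param geog A `geog_tbl` over the same areas as `config`.
#' @param config An `epoch_config`; the tree must be younger than its last
#'   boundary.
#' @param model Model name, e.g. `"DEC"`, `"DEC+J"` (see [biogeo_models()]).
#' @param params Named numeric vector with `d`, `e` and (for `+J` models)
#'   `j`.
#' @param root_prior `"uniform"` (over non-null states) or a numeric
#'   vector of state weights with zero mass on the null range.
#' @param max_range_size Cap on ancestral range size; defaults to the
#'   number of areas.
#' @return Log-likelihood (natural log). With `internals = TRUE`, a list
#'   also carrying the per-node partials and per-edge transition matrices
#'   used by [ancestral_marginals()].
#' @param internals Return internal quantities (used by the marginal
#'   ancestral-state computation).
#' @export
stratified_loglik <- function(tree, geog, config, model, params,
                              root_prior = "uniform", max_range_size = NULL,
                              internals = FALSE) {
  machine <- biogeo_machine(tree, geog, config, model,
    root_prior = root_prior, max_range_size = max_range_size
  )
  machine$eval(params, internals = internals)
}

# precompiles everything that does not depend on (d, e, j) -- validation,
# state space, tip states, traversal order, event structure -- and returns
# an evaluator; this is what makes optimization loops cheap
biogeo_machine <- function(tree, geog, config, model,
                           root_prior = "uniform", max_range_size = NULL) {
  spec <- model_spec(model)
  prep <- prepare_biogeo(tree, geog, config, max_range_size)
  space <- prep$space
  S <- length(space$mask)
  tr <- prep$tree
  ntip <- ape::Ntip(tr)
  nnode <- tr$Nnode
  prior <- root_prior_vector(space, root_prior)
  events <- clado_events(space, spec)
  po <- ape::reorder.phylo(tr, "postorder")
  n_edge <- nrow(po$edge)
  tip_part <- lapply(seq_len(ntip), function(i) {
    v <- numeric(S)
    v[prep$tip_state[i]] <- 1
    v
  })
  segs <- lapply(seq_len(n_edge), function(k) {
    edge_segments(config, prep$ages[po$edge[k, 2]], prep$ages[po$edge[k, 1]])
  })

  eval_fn <- function(params, internals = FALSE) {
    d <- params[["d"]]; e <- params[["e"]]
    j <- if ("j" %in% names(params)) params[["j"]] else 0
    if (d < 0 || e < 0) abort("rates d and e must be nonnegative")
    if (j > 0 && !spec$founder) abort(sprintf("model %s has no founder parameter", spec$name))
    # propagators are built lazily: epochs the tree never reaches cost nothing
    props <- vector("list", length(config$matrices))
    get_prop <- function(i) {
      if (is.null(props[[i]])) {
        props[[i]] <<- make_propagator(build_q_matrix(space, d, e, config$matrices[[i]]))
      }
      props[[i]]
    }
    clado <- clado_weighted(events, j)
    cl_parent <- clado$parent; cl_left <- clado$left; cl_right <- clado$right; cl_prob <- clado$prob

    part <- vector("list", ntip + nnode)
    part[seq_len(ntip)] <- tip_part
    edge_w <- vector("list", n_edge)
    edge_M <- if (internals) vector("list", n_edge) else NULL
    pending <- vector("list", ntip + nnode)
    loga <- 0
    for (k in seq_len(n_edge)) {
      p <- po$edge[k, 1]; ch <- po$edge[k, 2]
      if (internals) {
        M <- NULL
        for (seg in segs[[k]]) {
          if (seg$dt <= 0) next
          P <- prop_mat(get_prop(seg$epoch), seg$dt)
          M <- if (is.null(M)) P else P %*% M
        }
        if (is.null(M)) M <- diag(S)
        edge_M[[k]] <- M
        w <- as.numeric(M %*% part[[ch]])
      } else {
        w <- part[[ch]]
        for (seg in segs[[k]]) {
          if (seg$dt > 0) w <- prop_vec(get_prop(seg$epoch), seg$dt, w)
        }
        w <- as.numeric(w)
      }
      edge_w[[k]] <- w
      pending[[p]] <- c(pending[[p]], k)
      if (length(pending[[p]]) == 2L) {
        wl <- edge_w[[pending[[p]][1]]]
        wr <- edge_w[[pending[[p]][2]]]
        contrib <- cl_prob * wl[cl_left] * wr[cl_right]
        v <- numeric(S)
        agg <- rowsum(contrib, group = cl_parent)
        v[as.integer(rownames(agg))] <- agg[, 1]
        s <- sum(v)
        if (s <= 0 || !is.finite(s)) return(if (internals) list(loglik = -Inf) else -Inf)
        part[[p]] <- v / s
        loga <- loga + log(s)
      }
    }
    root <- ntip + 1L
    ll <- log(sum(prior * part[[root]])) + loga
    if (!internals) {
      return(ll)
    }
    list(
      loglik = ll, space = space, tree = tr, ages = prep$ages,
      postorder_edge = po$edge, edge_w = edge_w, edge_M = edge_M,
      part = part, pending = pending, prior = prior,
      clado = clado, tip_state = prep$tip_state
    )
  }
  list(eval = eval_fn, space = space, tree = tr, spec = spec)
}
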