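# Independent brute-force likelihood/marginal oracle: exhaustive summation
# over all assignments of pre-split states to internal nodes, with its own
# branch segmentation. Shares only the primitive ingredients (rate matrix,
# event probabilities, matrix exponential) with the pruning implementation.

oracle_edge_matrix <- function(space, config, d, e, age_child, age_parent) {
  b <- config$boundaries
  cuts <- sort(unique(c(age_child, b[b > age_child + 1e-9 & b < age_parent - 1e-9], age_parent)))
  M <- diag(length(space$mask))
  for (s in seq_len(length(cuts) - 1)) {
    ep <- findInterval(cuts[s], b)
    Q <- build_q_matrix(space, d, e, config$matrices[[ep]])
    M <- as.matrix(Matrix::expm(Matrix::Matrix(Q * (cuts[s + 1] - cuts[s])))) %*% M
  }
  M
}

oracle_enumerate <- function(tree, geog, config, model, params, max_range_size = NULL) {
  space <- build_state_space(config$areas, max_range_size %||% length(config$areas))
  S <- length(space$mask)
  d <- params[["d"]]; e <- params[["e"]]
  j <- if ("j" %in% names(params)) params[["j"]] else 0
  clado <- clado_table(space, model, j = j)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ages <- stratbiogeo::node_ages(tree)
  ages[seq_len(ntip)] <- 0
  gm <- geog_matrix(geog)[tree$tip.label, , drop = FALSE]
  tip_state <- apply(gm, 1, function(r) {
    state_index(space, sum(bitwShiftL(1L, which(r == 1L) - 1L)))
  })
  Ms <- lapply(seq_len(nrow(tree$edge)), function(k) {
    oracle_edge_matrix(space, config, d, e, ages[tree$edge[k, 2]], ages[tree$edge[k, 1]])
  })
  internal <- (ntip + 1):(ntip + nnode)
  prior <- c(0, rep(1 / (S - 1), S - 1))
  grid <- as.matrix(expand.grid(rep(list(2:S), nnode)))
  events_by_parent <- split(seq_len(nrow(clado)), clado$parent)
  joint <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    sigma <- grid[gidx, ]
    p_total <- prior[sigma[1]]
    for (ni in seq_len(nnode)) {
      node <- internal[ni]
      kids <- which(tree$edge[, 1] == node)
      ev <- events_by_parent[[as.character(sigma[ni])]]
      tsum <- 0
      for (ee in ev) {
        l <- clado$left[ee]; r <- clado$right[ee]
        f <- clado$prob[ee]
        for (side in 1:2) {
          k <- kids[side]
          ch <- tree$edge[k, 2]
          top <- if (side == 1) l else r
          s_child <- if (ch <= ntip) tip_state[ch] else sigma[ch - ntip]
          f <- f * Ms[[k]][top, s_child]
        }
        tsum <- tsum + f
      }
      p_total <- p_total * tsum
    }
    joint[gidx] <- p_total
  }
  list(
    loglik = log(sum(joint)),
    marginal = function(node) {
      col <- node - ntip
      v <- numeric(S)
      for (s in 2:S) v[s] <- sum(joint[grid[, col] == s])
      v / sum(v)
    }
  )
}

# small random instance shared by likelihood / marginal oracle tests
random_instance <- function(seed, n_tips = 4, areas = c("A", "B", "C"),
                            stratified = TRUE) {
  set.seed(seed)
  tr <- simulate_yule_tree(n_tips, lambda = 0.15, seed = seed * 13 + 1)
  config <- if (stratified) {
    h <- tree_height(tr)
    m1 <- matrix(runif(9, 0.2, 1), 3, 3); diag(m1) <- 1
    m2 <- matrix(runif(9, 0.2, 1), 3, 3); diag(m2) <- 1
    epoch_config(areas, c(0, h * 0.4, h * 2 + 1), list(m1, m2), name = "sim2epoch")
  } else {
    epoch_config(areas, c(0, tree_height(tr) * 2 + 1), list(matrix(1, 3, 3)), name = "one")
  }
  bits <- matrix(rbinom(n_tips * 3, 1, 0.5), n_tips, 3)
  bits[rowSums(bits) == 0, sample(3, 1)] <- 1L
  geog <- new_geog(bits, tr$tip.label, areas)
  params <- c(d = runif(1, 0.01, 0.1), e = runif(1, 0.005, 0.05), j = runif(1, 0, 1.5))
  list(tree = tr, config = config, geog = geog, params = params)
}
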