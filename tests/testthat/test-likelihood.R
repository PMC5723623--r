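make_tip_geog <- function(tree, labels, areas) {
  sp <- build_state_space(areas)
  bits <- t(vapply(labels, function(l) {
    as.integer(bitwAnd(bitwShiftR(sp$mask[state_index(sp, l)], 0:(length(areas) - 1L)), 1L))
  }, integer(length(areas))))
  new_geog(bits, tree$tip.label, areas)
}

test_that("two identical tips with zero rates give lnL = -log(#non-null states)", {
  tr <- read_newick(list(text = "(A:1,B:1);"))
  g <- make_tip_geog(tr, c("AN", "AN"), caribbean_areas())
  cfg <- preset_epoch_config("null")
  ll <- stratified_loglik(tr, g, cfg, "DEC", c(d = 0, e = 0))
  expect_equal(ll, -log(31), tolerance = 1e-12)
  # same analytic value for the other families
  expect_equal(stratified_loglik(tr, g, cfg, "DIVALIKE", c(d = 0, e = 0)), -log(31), tolerance = 1e-12)
  expect_equal(stratified_loglik(tr, g, cfg, "BAYAREALIKE", c(d = 0, e = 0)), -log(31), tolerance = 1e-12)
})

test_that("pruning equals the exhaustive oracle on random small instances", {
  for (seed in 1:6) {
    inst <- random_instance(seed, n_tips = 4)
    models <- c("DEC+J", "DIVALIKE+J", "BAYAREALIKE+J", "DEC")
    for (model in models) {
      params <- inst$params
      if (!model_spec(model)$founder) params["j"] <- 0
      ll <- stratified_loglik(inst$tree, inst$geog, inst$config, model, params)
      orc <- oracle_enumerate(inst$tree, inst$geog, inst$config, model, params)
      expect_equal(ll, orc$loglik, tolerance = 1e-10)
    }
  }
})

test_that("stratification with identical epochs is vacuous", {
  tr <- simulate_yule_tree(20, 0.1, seed = 7)
  set.seed(2)
  bits <- matrix(rbinom(100, 1, 0.4), 20, 5)
  bits[rowSums(bits) == 0, 1] <- 1L
  g <- new_geog(bits, tr$tip.label, caribbean_areas())
  p <- c(d = 0.02, e = 0.01, j = 0.5)
  null <- preset_epoch_config("null")
  ones <- preset_epoch_config("complex1")
  ones$matrices <- lapply(ones$matrices, function(m) {
    m[, ] <- 1
    m
  })
  expect_equal(
    stratified_loglik(tr, g, null, "DEC+J", p),
    stratified_loglik(tr, g, ones, "DEC+J", p),
    tolerance = 1e-10
  )
})

test_that("splitting an epoch into identical halves leaves lnL unchanged", {
  inst <- random_instance(3, n_tips = 6)
  cfg <- inst$config
  b <- cfg$boundaries
  mid <- (b[1] + b[2]) / 2
  refined <- epoch_config(cfg$areas, c(b[1], mid, b[2], b[3]),
    list(cfg$matrices[[1]], cfg$matrices[[1]], cfg$matrices[[2]]),
    name = "refined"
  )
  ll1 <- stratified_loglik(inst$tree, inst$geog, cfg, "DEC+J", inst$params)
  ll2 <- stratified_loglik(inst$tree, inst$geog, refined, "DEC+J", inst$params)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("lnL is invariant to tip order and to consistent area relabeling", {
  inst <- random_instance(5, n_tips = 5)
  ll <- stratified_loglik(inst$tree, inst$geog, inst$config, "DEC+J", inst$params)
  # permute geography rows
  g2 <- inst$geog[rev(seq_len(nrow(inst$geog))), ]
  attr(g2, "areas") <- attr(inst$geog, "areas")
  class(g2) <- class(inst$geog)
  expect_equal(stratified_loglik(inst$tree, g2, inst$config, "DEC+J", inst$params), ll, tolerance = 1e-12)
  # relabel areas consistently everywhere (reverse order)
  perm <- 3:1
  areas2 <- inst$config$areas[perm]
  cfg2 <- epoch_config(areas2, inst$config$boundaries,
    lapply(inst$config$matrices, function(m) m[perm, perm]),
    name = "relabeled"
  )
  g3 <- new_geog(geog_matrix(inst$geog)[, perm], inst$geog$taxon, areas2)
  expect_equal(stratified_loglik(inst$tree, g3, cfg2, "DEC+J", inst$params), ll, tolerance = 1e-10)
})

test_that("transition matrices are stochastic over every epoch and segment", {
  sp <- build_state_space(caribbean_areas())
  cfg <- preset_epoch_config("complex1")
  for (i in seq_along(cfg$matrices)) {
    Q <- build_q_matrix(sp, 0.05, 0.02, cfg$matrices[[i]])
    expect_equal(rowSums(Q), rep(0, nrow(Q)), tolerance = 1e-12)
    for (dt in c(0.5, 7, 80)) {
      P <- stratbiogeo:::prop_mat(stratbiogeo:::make_propagator(Q), dt)
      expect_true(all(P >= 0))
      expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-10)
    }
  }
})

test_that("oversized tip ranges and overtall trees produce clear errors", {
  tr <- read_newick(list(text = "(A:1,B:1);"))
  g <- make_tip_geog(tr, c("ANCA", "AN"), caribbean_areas())
  cfg <- preset_epoch_config("null")
  expect_error(
    stratified_loglik(tr, g, cfg, "DEC", c(d = 0.1, e = 0), max_range_size = 1),
    "max_range_size"
  )
  tall <- read_newick(list(text = "(A:400,B:400);"))
  g2 <- make_tip_geog(tall, c("AN", "AN"), caribbean_areas())
  expect_error(stratified_loglik(tall, g2, cfg, "DEC", c(d = 0.1, e = 0)), "epoch")
})
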