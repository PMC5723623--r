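test_that("Yule trees are ultrametric, deterministic and correctly sized", {
  tr <- simulate_yule_tree(2, lambda = 1, seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  expect_s3_class(tr, "dated_tree")
  tr50 <- simulate_yule_tree(50, lambda = 0.2, seed = 9)
  expect_equal(ape::Ntip(tr50), 50)
  expect_true(ape::is.ultrametric(tr50, tol = 1e-8))
  # bit-for-bit determinism
  expect_identical(
    write_newick(simulate_yule_tree(20, 0.3, seed = 4)),
    write_newick(simulate_yule_tree(20, 0.3, seed = 4))
  )
  # target-height rescaling
  trh <- simulate_yule_tree(20, 0.3, seed = 4, target_height = 12)
  expect_equal(tree_height(trh), 12, tolerance = 1e-9)
})

test_that("lineage-through-time growth matches the Yule expectation", {
  # E[N(t)] = 2 exp(lambda t) measured at half the typical height
  lambda <- 0.4
  t_probe <- 3
  counts <- vapply(1:300, function(s) {
    tr <- simulate_yule_tree(60, lambda, seed = 5000 + s)
    h <- tree_height(tr)
    if (h <= t_probe) {
      return(NA_real_)
    }
    ages <- node_ages(tr)
    # lineages alive at age (h - t_probe): 2 + splits older than that age
    2 + sum(ages[-seq_len(ape::Ntip(tr))] > h - t_probe) - 1
  }, numeric(1))
  counts <- counts[!is.na(counts)]
  expected <- 2 * exp(lambda * t_probe)
  expect_gt(length(counts), 200)
  expect_equal(mean(counts), expected, tolerance = 0.1)
})

test_that("range simulation respects structural limits of the process", {
  areas <- c("A", "B", "C")
  cfg <- epoch_config(areas, c(0, 100), list(matrix(1, 3, 3)), name = "flat")
  tr <- simulate_yule_tree(15, 0.3, seed = 21, target_height = 10)
  # zero multipliers + singleton root: no anagenetic or cladogenetic change
  # is possible, so every tip keeps the root range
  m0 <- cfg$matrices[[1]] * 0
  diag(m0) <- 1
  cfg0 <- epoch_config(areas, c(0, 100), list(m0), name = "blocked")
  fixed <- simulate_ranges(tr, cfg0, "DEC", c(d = 0.4, e = 0), seed = 3, root_range = "A")
  gm <- geog_matrix(fixed$geog)
  expect_true(all(gm[, "A"] == 1 & gm[, "B"] == 0 & gm[, "C"] == 0))
  expect_equal(nrow(fixed$events), 0)
  # pure gain without cladogenetic range change (BAYAREALIKE copies the
  # parent range): every tip is a superset of the root range and every
  # anagenetic event is a gain
  gain <- simulate_ranges(tr, cfg, "BAYAREALIKE", c(d = 0.15, e = 0), seed = 5, root_range = "A")
  expect_true(all(geog_matrix(gain$geog)[, "A"] == 1))
  if (nrow(gain$events)) expect_true(all(gain$events$type == "gain"))
  # determinism
  s1 <- simulate_ranges(tr, cfg, "DEC+J", c(d = 0.1, e = 0.02, j = 1), seed = 8)
  s2 <- simulate_ranges(tr, cfg, "DEC+J", c(d = 0.1, e = 0.02, j = 1), seed = 8)
  expect_identical(geog_matrix(s1$geog), geog_matrix(s2$geog))
  # impossible regime errors with advice
  expect_error(
    simulate_ranges(tr, cfg, "DEC", c(d = 1e-4, e = 2), seed = 2, max_tries = 5),
    "lower e"
  )
})

test_that("simulated event rates calibrate against the Q definition", {
  # single lineage pair of areas: occupancy-weighted gain rate ~ d * m
  areas <- c("A", "B")
  m <- matrix(c(1, 0.6, 1, 1), 2, 2, byrow = TRUE)
  cfg <- epoch_config(areas, c(0, 1e5), list(m), name = "cal")
  d <- 0.05
  # long two-tip trees accumulate many branch-Ma cheaply
  total_time <- 0
  gains_ab <- 0
  time_in_a <- 0
  for (s in 1:60) {
    tr <- read_newick(list(text = "(A:400,B:400);"))
    sim <- simulate_ranges(tr, cfg, "DEC", c(d = d, e = 0), seed = 100 + s, root_range = "A")
    ev <- sim$events
    # time spent in state {A} on each branch before the first gain
    firsts <- if (nrow(ev)) tapply(ev$age, ev$edge_child, max) else numeric(0)
    for (ch in 1:2) {
      t_gain <- if (as.character(ch) %in% names(firsts)) 400 - firsts[[as.character(ch)]] else 400
      time_in_a <- time_in_a + t_gain
      gains_ab <- gains_ab + as.integer(as.character(ch) %in% names(firsts))
    }
  }
  rate_hat <- gains_ab / time_in_a
  expect_equal(rate_hat, d * m[1, 2], tolerance = 0.25)
})

test_that("age fixtures plant known window classes and always partition", {
  fx <- make_age_fixture(30, seed = 13, n_overlapping = 7, n_younger = 12)
  ws <- window_summary(fx)
  counts <- setNames(ws$counts$n, ws$counts$class)
  expect_gte(unname(counts["overlapping"]), 7L)
  expect_gte(unname(counts["younger"]), 12L)
  expect_equal(sum(ws$counts$n), 30L)
  expect_true(all(fx$crown_lo <= fx$crown_mean & fx$crown_mean <= fx$crown_hi))
  # degenerate zero-width intervals still classify
  fx0 <- make_age_fixture(5, seed = 2, max_halfwidth = 0)
  expect_equal(sum(window_summary(fx0)$counts$n), 5L)
  # partition property over many random tables
  for (s in 1:25) {
    n <- sample(5:40, 1)
    expect_equal(sum(window_summary(make_age_fixture(n, seed = s))$counts$n), n)
  }
})

test_that("the true parameters beat strongly perturbed ones in mean lnL", {
  areas <- c("A", "B", "C")
  cfg <- epoch_config(areas, c(0, 200), list(matrix(1, 3, 3)), name = "flat")
  truth <- c(d = 0.03, e = 0.005)
  diffs <- vapply(1:8, function(r) {
    tr <- simulate_yule_tree(40, 0.25, seed = 300 + r, target_height = 15)
    sim <- simulate_ranges(tr, cfg, "DEC", truth, seed = 400 + r)
    stratified_loglik(tr, sim$geog, cfg, "DEC", truth) -
      stratified_loglik(tr, sim$geog, cfg, "DEC", c(d = truth[["d"]] * 10, e = truth[["e"]]))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
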