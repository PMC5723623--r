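test_that("state space has the right size, order and null state", {
  expect_length(build_state_space(caribbean_areas(), 5)$mask, 32)
  sp2 <- build_state_space(c("A", "B"), 2)
  expect_equal(sp2$label, c("null", "A", "B", "AB"))
  sp32 <- build_state_space(c("A", "B", "C"), 2)
  expect_length(sp32$mask, 7)
  # ordered by size then lexicographically in area order
  expect_equal(sp32$label, c("null", "A", "B", "C", "AB", "AC", "BC"))
  expect_error(build_state_space(c("A", "B"), 3), "max_range_size")
  # index <-> mask bijection
  sp <- build_state_space(caribbean_areas(), 3)
  expect_equal(sp$index_of[sp$mask + 1L], seq_along(sp$mask))
})

test_that("Q matrix implements multiplier-weighted gains and per-area losses", {
  sp <- build_state_space(c("A", "B"))
  m1 <- matrix(1, 2, 2)
  d <- 0.3; e <- 0.07
  Q <- build_q_matrix(sp, d, e, m1)
  iA <- state_index(sp, "A"); iB <- state_index(sp, "B"); iAB <- state_index(sp, "AB")
  expect_equal(Q[iA, iAB], d)
  expect_equal(Q[iA, 1], e)
  expect_equal(Q[iAB, iA], e)
  expect_equal(Q[iAB, iB], e)
  expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12)
  expect_equal(Q[1, ], rep(0, 4)) # null absorbing

  # zero multiplier blocks the gain
  m0 <- matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(build_q_matrix(sp, d, e, m0)[iA, iAB], 0)

  # gain rate sums multipliers over occupied source areas
  sp3 <- build_state_space(c("A", "B", "C"))
  m3 <- matrix(1, 3, 3); m3[1, 3] <- 0.5; m3[2, 3] <- 0.1
  Q3 <- build_q_matrix(sp3, 0.02, 0, m3)
  expect_equal(Q3[state_index(sp3, "AB"), state_index(sp3, "ABC")], 0.012)
})

test_that("max_range_size caps range expansion", {
  sp <- build_state_space(c("A", "B", "C"), 2)
  Q <- build_q_matrix(sp, 0.1, 0.01, matrix(1, 3, 3))
  iAB <- state_index(sp, "AB")
  expect_equal(sum(Q[iAB, -iAB] > 0), 2) # only the two losses
})

test_that("cladogenetic tables enumerate the allowed events per family", {
  sp <- build_state_space(c("A", "B"))
  # singleton parent: sympatry only
  for (fam in c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    tb <- clado_table(sp, fam)
    one <- tb[tb$parent == state_index(sp, "A"), ]
    expect_equal(nrow(one), 1)
    expect_equal(one$prob, 1)
    expect_equal(one$left, one$right)
  }
  # DEC widespread parent: 4 subset sympatry + 2 vicariance, each 1/6
  dec <- clado_table(sp, "DEC")
  ab <- dec[dec$parent == state_index(sp, "AB"), ]
  expect_equal(nrow(ab), 6)
  expect_equal(ab$prob, rep(1 / 6, 6))
  expect_equal(sum(ab$type == "vicariance"), 2)
  expect_equal(sum(ab$type == "subset_sympatry"), 4)
  # DIVALIKE: vicariance only; BAYAREALIKE: identity only
  diva <- clado_table(sp, "DIVALIKE")
  expect_equal(sort(unique(diva$type[diva$parent == state_index(sp, "AB")])), "vicariance")
  bay <- clado_table(sp, "BAYAREALIKE")
  bab <- bay[bay$parent == state_index(sp, "AB"), ]
  expect_equal(bab$type, "identity")
  expect_equal(bab$prob, 1)
})

test_that("DIVALIKE allows wide vicariance that DEC forbids", {
  sp <- build_state_space(c("A", "B", "C", "D"))
  p <- state_index(sp, "ABCD")
  dec <- clado_table(sp, "DEC")
  diva <- clado_table(sp, "DIVALIKE")
  dec_splits <- dec[dec$parent == p & dec$type == "vicariance", ]
  diva_splits <- diva[diva$parent == p & diva$type == "vicariance", ]
  expect_true(all(pmin(sp$size[dec_splits$left], sp$size[dec_splits$right]) == 1))
  expect_true(any(pmin(sp$size[diva_splits$left], sp$size[diva_splits$right]) == 2))
})

test_that("founder weights follow the (3 - j)/3 vs j parameterization", {
  sp <- build_state_space(c("A", "B"))
  tb <- clado_table(sp, "DEC+J", j = 1.5)
  pa <- tb[tb$parent == state_index(sp, "A"), ]
  founder <- pa[pa$type == "founder", ]
  expect_equal(nrow(founder), 2) # both daughter orders
  expect_equal(sum(founder$prob), 2 * 1.5 / (2 * 1.5 + 0.5), tolerance = 1e-12)
  # j = 0 reduces a +J model to its base model
  expect_equal(clado_table(sp, "DEC+J", j = 0), clado_table(sp, "DEC"))
  expect_error(clado_table(sp, "DEC", j = 0.5), "founder")
  expect_error(clado_table(sp, "DEC+J", j = 3.5), "0, 3")
})

test_that("clado distributions normalize for every parent and family", {
  sp <- build_state_space(caribbean_areas(), 3)
  for (model in biogeo_models()) {
    j <- if (model_spec(model)$founder) 0.3 else 0
    tb <- clado_table(sp, model, j = j)
    sums <- as.numeric(tapply(tb$prob, tb$parent, sum))
    expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
    expect_false(1 %in% tb$parent) # no events from the null range
  }
})
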