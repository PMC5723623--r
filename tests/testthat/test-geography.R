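test_that("preset configurations match the archived epoch matrices", {
  null <- preset_epoch_config("null")
  expect_length(null$matrices, 1)
  expect_true(all(null$matrices[[1]] == 1))

  c1 <- preset_epoch_config("complex1")
  expect_equal(c1$boundaries, c(0, 15, 33, 35, 50, 130, 378))
  # GAARlandia epoch: full Antilles-South America connectivity
  expect_equal(multiplier_at(c1, 34, "SA", "AN"), 1)
  expect_equal(multiplier_at(c1, 34, "AN", "SA"), 1)
  # pre-isthmus epoch: reduced North-South America link
  expect_equal(multiplier_at(c1, 20, "SA", "NA"), 0.1)
  expect_equal(multiplier_at(c1, 20, "NA", "SA"), 0.1)
  # recent epoch: Central America fully connected to both Americas
  expect_equal(multiplier_at(c1, 5, "CA", "NA"), 1)
  expect_equal(multiplier_at(c1, 5, "SA", "AN"), 0.5)
  # deepest epoch: no dispersal from/to the not-yet-formed Antilles
  expect_equal(multiplier_at(c1, 200, "AN", "SA"), 0)
  expect_equal(multiplier_at(c1, 200, "SA", "AN"), 0)
  expect_equal(multiplier_at(c1, 200, "CA", "SA"), 0.01)

  c2 <- preset_epoch_config("complex2")
  expect_equal(multiplier_at(c2, 5, "SA", "AN"), 0.75)
  expect_equal(multiplier_at(c2, 5, "SA", "NA"), 0.75)
  expect_equal(multiplier_at(c2, 5, "AN", "SA"), 0.5)
})

test_that("the two complex scenarios differ in exactly 2 cells of 1 epoch", {
  c1 <- preset_epoch_config("complex1")
  c2 <- preset_epoch_config("complex2")
  diffs <- vapply(seq_along(c1$matrices), function(i) {
    sum(c1$matrices[[i]] != c2$matrices[[i]])
  }, numeric(1))
  expect_equal(sum(diffs > 0), 1)
  expect_equal(sum(diffs), 2)
})

test_that("preset matrices are valid multiplier matrices", {
  for (nm in c("null", "complex1", "complex2")) {
    cfg <- preset_epoch_config(nm)
    for (m in cfg$matrices) {
      expect_true(all(m >= 0 & m <= 1))
      expect_true(all(diag(m) == 1))
    }
  }
})

test_that("epoch lookup is half-open toward the past and total on [0, 378)", {
  c1 <- preset_epoch_config("complex1")
  # boundary age belongs to the older-side epoch above it
  expect_equal(multiplier_at(c1, 15, "SA", "NA"), 0.1) # 15 falls in 15-33
  expect_equal(multiplier_at(c1, 33, "SA", "AN"), 1) # 33 falls in 33-35
  expect_equal(multiplier_at(c1, 35, "SA", "AN"), 0.5) # 35 falls in 35-50
  expect_error(multiplier_at(c1, 378, "SA", "AN"), "older than the model")
  expect_error(multiplier_at(c1, 400, "SA", "AN"), "older than the model")
  # diagonal is always 1 and the null preset is constant in age
  null <- preset_epoch_config("null")
  for (age in c(0, 14.999, 15, 100, 377.9)) {
    expect_equal(multiplier_at(null, age, "AN", "SA"), 1)
    expect_equal(multiplier_at(c1, age, "RW", "RW"), 1)
  }
})

test_that("epoch configs survive a YAML round trip", {
  c2 <- preset_epoch_config("complex2")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_epoch_config(c2, f)
  back <- read_epoch_config(f)
  expect_equal(back$boundaries, c2$boundaries)
  expect_equal(back$areas, c2$areas)
  for (i in seq_along(c2$matrices)) {
    expect_equal(unname(back$matrices[[i]]), unname(c2$matrices[[i]]))
  }
})

test_that("occurrence coding matches a brute-force point-in-polygon oracle", {
  skip_if_not_installed("pracma")
  set.seed(42)
  # two disjoint unit squares
  sq <- function(x0, y0) cbind(lon = c(x0, x0 + 1, x0 + 1, x0), lat = c(y0, y0, y0 + 1, y0 + 1))
  polys <- list(A = sq(0, 0), B = sq(2, 0))
  pts <- tibble::tibble(
    taxon = sample(sprintf("t%d", 1:10), 100, replace = TRUE),
    lon = runif(100, -0.5, 3.5), lat = runif(100, -0.5, 1.5)
  )
  g <- suppressWarnings(code_occurrences(pts, polys))
  m <- geog_matrix(g)
  for (a in c("A", "B")) {
    p <- polys[[a]]
    oracle_in <- pracma::inpolygon(pts$lon, pts$lat, p[, 1], p[, 2], boundary = TRUE)
    expected <- sort(unique(pts$taxon[oracle_in]))
    expect_equal(sort(rownames(m)[m[, a] == 1]), expected)
  }
})

test_that("occurrence overrides replace rows and boundary points count inside", {
  polys <- list(AN = cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1)))
  pts <- tibble::tibble(taxon = c("in", "edge", "out"), lon = c(0, 1, 5), lat = c(0, 0, 5))
  g <- suppressWarnings(code_occurrences(pts, polys, overrides = list(out = "1")))
  m <- geog_matrix(g)
  expect_equal(unname(m[c("in", "edge", "out"), "AN"]), c(1L, 1L, 1L))
  expect_length(attr(g, "uncoded"), 0)
  expect_warning(code_occurrences(pts, polys), "uncoded")
  g2 <- suppressWarnings(code_occurrences(pts, polys))
  expect_equal(attr(g2, "uncoded"), "out")
})
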