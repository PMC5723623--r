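#' Construct a time-stratified dispersal multiplier configuration
#'
#' An epoch configuration slices time (in Ma before present) into epochs and
#' attaches to each epoch a directional dispersal multiplier matrix
#' `m[source, dest]` with entries in `[0, 1]` and unit diagonal. Multipliers
#' scale the anagenetic dispersal rate `d` between pairs of areas; a zero
#' entry forbids dispersal along that link during the epoch (e.g. before an
#' area existed), a one reflects full connectivity (e.g. a land bridge).
#'
#' Epoch intervals are half-open toward the past, `[lower, upper)`: an age
#' exactly on a boundary belongs to the younger epoch above it.
#'
#' @param areas Character vector of area labels (defines matrix order).
#' @param boundaries Numeric vector of epoch boundaries in Ma, starting at 0,
#'   strictly increasing. `length(boundaries) - 1` epochs are defined.
#' @param matrices List of square multiplier matrices, one per epoch,
#'   youngest first, each with `dimnames` equal to `areas` (added if absent).
#' @param name Tag for the configuration (`"null"`, `"complex1"`,
#'   `"complex2"` or any custom string).
#' @return An object of class `epoch_config`.
#' @seealso [preset_epoch_config()], [multiplier_at()]
#' @export
epoch_config <- function(areas, boundaries, matrices, name = "custom") {
  if (boundaries[1] != 0) abort("epoch boundaries must start at 0")
  if (any(diff(boundaries) <= 0)) abort("epoch boundaries must be strictly increasing")
  n_epoch <- length(boundaries) - 1L
  if (length(matrices) != n_epoch) {
    abort(sprintf("need %d multiplier matrices for %d epochs, got %d", n_epoch, n_epoch, length(matrices)))
  }
  n <- length(areas)
  matrices <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(n, n))) abort("multiplier matrix dimensions must match the area set")
    if (any(m < 0 | m > 1)) abort("multiplier entries must lie in [0, 1]")
    if (any(diag(m) != 1)) abort("multiplier matrix diagonal must be 1")
    dimnames(m) <- list(areas, areas)
    m
  })
  structure(
    list(areas = areas, boundaries = as.numeric(boundaries), matrices = matrices, name = name),
    class = "epoch_config"
  )
}

#' @export
print.epoch_config <- function(x, ...) {
  cat(sprintf(
    "<epoch_config '%s'> %d areas (%s), %d epoch(s): %s Ma\n",
    x$name, length(x$areas), paste(x$areas, collapse = ", "),
    length(x$matrices),
    paste(sprintf("%g-%g", head(x$boundaries, -1), x$boundaries[-1]), collapse = ", ")
  ))
  invisible(x)
}

# Epoch multiplier matrices for the Caribbean presets, area order
# AN, CA, NA, RW, SA, rows = source. The three youngest epochs follow the
# archived matrices; epochs 4-6 are reconstructions from the narrative
# paleogeography (symmetric links; see the methods vignette).
caribbean_epoch_matrices <- function(south_to_north_boost = 0) {
  A <- function(v) matrix(v, 5, 5, byrow = TRUE)
  m1 <- A(c(
    1.0, 0.5, 0.5, 0.1, 0.5,
    0.5, 1.0, 1.0, 0.1, 1.0,
    0.5, 1.0, 1.0, 0.1, 0.5,
    0.1, 0.1, 0.1, 1.0, 0.1,
    0.5, 1.0, 0.5, 0.1, 1.0
  ))
  # directional south-to-north variant raises SA->AN and SA->NA only
  m1[5, 1] <- m1[5, 1] + south_to_north_boost
  m1[5, 3] <- m1[5, 3] + south_to_north_boost
  m2 <- A(c(
    1.0, 0.5, 0.5, 0.1, 0.5,
    0.5, 1.0, 1.0, 0.1, 1.0,
    0.5, 1.0, 1.0, 0.1, 0.1,
    0.1, 0.1, 0.1, 1.0, 0.1,
    0.5, 1.0, 0.1, 0.1, 1.0
  ))
  m3 <- A(c(
    1.0, 0.5, 0.5, 0.1, 1.0,
    0.5, 1.0, 1.0, 0.1, 1.0,
    0.5, 1.0, 1.0, 0.1, 0.1,
    0.1, 0.1, 0.1, 1.0, 0.1,
    1.0, 1.0, 0.1, 0.1, 1.0
  ))
  m4 <- A(c(
    1.00, 0.50, 0.50, 0.10, 0.50,
    0.50, 1.00, 0.10, 0.01, 0.10,
    0.50, 0.10, 1.00, 0.10, 0.10,
    0.10, 0.01, 0.10, 1.00, 0.10,
    0.50, 0.10, 0.10, 0.10, 1.00
  ))
  m5 <- A(c(
    1.00, 0.01, 0.10, 0.01, 0.10,
    0.01, 1.00, 0.01, 0.01, 0.01,
    0.10, 0.01, 1.00, 0.01, 0.01,
    0.01, 0.01, 0.01, 1.00, 0.01,
    0.10, 0.01, 0.01, 0.01, 1.00
  ))
  m6 <- A(c(
    1.00, 0.00, 0.00, 0.00, 0.00,
    0.00, 1.00, 0.01, 0.01, 0.01,
    0.00, 0.01, 1.00, 0.01, 0.01,
    0.00, 0.01, 0.01, 1.00, 0.01,
    0.00, 0.01, 0.01, 0.01, 1.00
  ))
  list(m1, m2, m3, m4, m5, m6)
}

#' Preset Caribbean epoch configurations
#'
#' Three dispersal scenarios over the areas [caribbean_areas()]:
#'
#' * `"null"`: a single epoch spanning 0-378 Ma with every multiplier 1
#'   (no time stratification, equal dispersal everywhere).
#' * `"complex1"`: six epochs (0-15, 15-33, 33-35, 35-50, 50-130,
#'   130-378 Ma) with symmetric connectivity constraints; the 33-35 Ma
#'   epoch sets the Antilles-South America link to 1 to represent the
#'   hypothesized GAARlandia land bridge.
#' * `"complex2"`: identical to `"complex1"` except that in the 0-15 Ma
#'   epoch the directional multipliers SA->AN and SA->NA are raised by
#'   0.25 (to 0.75), favouring south-to-north dispersal.
#'
#' @param name One of `"null"`, `"complex1"`, `"complex2"`.
#' @return An `epoch_config`.
#' @export
#' @examples
#' cfg <- preset_epoch_config("complex1")
#' multiplier_at(cfg, 34, "SA", "AN") # 1: the GAARlandia window
preset_epoch_config <- function(name = c("null", "complex1", "complex2")) {
  name <- match.arg(name)
  areas <- caribbean_areas()
  switch(name,
    null = epoch_config(
      areas, c(0, 378), list(matrix(1, 5, 5)), name = "null"
    ),
    complex1 = epoch_config(
      areas, c(0, 15, 33, 35, 50, 130, 378),
      caribbean_epoch_matrices(0), name = "complex1"
    ),
    complex2 = epoch_config(
      areas, c(0, 15, 33, 35, 50, 130, 378),
      caribbean_epoch_matrices(0.25), name = "complex2"
    )
  )
}

# index of the epoch whose [lower, upper) interval contains `age`
epoch_index <- function(config, age) {
  b <- config$boundaries
  if (any(age < b[1] | age >= b[length(b)])) {
    abort(sprintf(
      "age %g Ma is outside the configured epochs [%g, %g); the tree is older than the model",
      max(age), b[1], b[length(b)]
    ))
  }
  findInterval(age, b, rightmost.closed = FALSE)
}

#' Dispersal multiplier at a given age
#'
#' Looks up the multiplier `m[source, dest]` of the epoch whose half-open
#' interval `[lower, upper)` contains `age`.
#'
#' @param config An `epoch_config`.
#' @param age Age in Ma before present; must satisfy
#'   `0 <= age < max(boundaries)`.
#' @param source,dest Area labels.
#' @return Multiplier in `[0, 1]`.
#' @export
multiplier_at <- function(config, age, source, dest) {
  i <- epoch_index(config, age)
  config$matrices[[i]][source, dest]
}

#' Read or write an epoch configuration as YAML
#'
#' The YAML layout is `areas: [...]`, `name: ...`, and `epochs:` a list of
#' `{from:, to:, matrix: [[...], ...]}` entries, youngest first, with matrix
#' rows in area order (rows = source area).
#'
#' @param path File path.
#' @param config An `epoch_config` (for writing).
#' @return `read_epoch_config()` returns an `epoch_config`;
#'   `write_epoch_config()` returns `path` invisibly.
#' @export
read_epoch_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$areas) || is.null(y$epochs)) abort("epoch YAML needs 'areas' and 'epochs' keys")
  froms <- vapply(y$epochs, function(e) as.numeric(e$from), numeric(1))
  tos <- vapply(y$epochs, function(e) as.numeric(e$to), numeric(1))
  ord <- order(froms)
  froms <- froms[ord]; tos <- tos[ord]
  if (any(abs(froms[-1] - tos[-length(tos)]) > 1e-9)) abort("epochs must tile time without gaps")
  mats <- lapply(y$epochs[ord], function(e) do.call(rbind, e$matrix))
  epoch_config(unlist(y$areas), c(froms[1], tos), mats, name = y$name %||% "custom")
}

#' @rdname read_epoch_config
#' @export
write_epoch_config <- function(config, path) {
  b <- config$boundaries
  y <- list(
    name = config$name,
    areas = config$areas,
    epochs = lapply(seq_along(config$matrices), function(i) {
      list(
        from = b[i], to = b[i + 1],
        matrix = lapply(seq_len(nrow(config$matrices[[i]])), function(r) unname(config$matrices[[i]][r, ]))
      )
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
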