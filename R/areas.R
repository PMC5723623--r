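#' Operational areas of the Caribbean analysis
#'
#' The five operational areas used throughout the package presets:
#' Antilles (AN), Central America (CA), North America (NA), rest of the
#' world (RW) and South America (SA). Area order is significant: it fixes
#' the bit positions of range bitmasks and the row/column order of every
#' dispersal multiplier matrix.
#'
#' @return Character vector of area labels.
#' @export
#' @examples
#' caribbean_areas()
caribbean_areas <- function() {
  c("AN", "CA", "NA", "RW", "SA")
}

#' Build the range state space over a set of areas
#'
#' States are subsets of the area set of size at most `max_range_size`,
#' including the empty (null) range. The null range is index 1; the
#' remaining states are ordered by subset size, then lexicographically by
#' area order, so the ordering is deterministic for a given area vector.
#'
#' @param areas Character vector of unique area labels (order matters).
#' @param max_range_size Largest allowed range size; defaults to all areas.
#' @return An object of class `range_state_space`: a list with elements
#'   `areas`, `max_range_size`, `mask` (integer bitmask per state),
#'   `label` (e.g. `"ANCA"`, `"null"` for the empty range), `size`
#'   (range sizes) and `index_of` (lookup from bitmask to state index).
#' @export
#' @examples
#' sp <- build_state_space(caribbean_areas())
#' length(sp$mask) # 32 states including the null range
build_state_space <- function(areas, max_range_size = length(areas)) {
  if (anyDuplicated(areas)) abort("area labels must be unique")
  n <- length(areas)
  if (max_range_size < 1 || max_range_size > n) {
    abort(sprintf("max_range_size must be in [1, %d], got %s", n, max_range_size))
  }
  masks <- 0L
  for (k in seq_len(max_range_size)) {
    sets <- combn(seq_len(n), k, simplify = FALSE)
    masks <- c(masks, vapply(sets, function(ix) sum(bitwShiftL(1L, ix - 1L)), integer(1)))
  }
  labels <- vapply(masks, function(m) {
    if (m == 0L) "null" else paste(areas[bitwAnd(bitwShiftR(m, seq_len(n) - 1L), 1L) == 1L], collapse = "")
  }, character(1))
  index_of <- rep(NA_integer_, 2^n)
  index_of[masks + 1L] <- seq_along(masks)
  structure(
    list(
      areas = areas,
      max_range_size = max_range_size,
      mask = masks,
      label = labels,
      size = vapply(masks, function(m) sum(bitwAnd(bitwShiftR(m, 0:(n - 1L)), 1L)), integer(1)),
      index_of = index_of
    ),
    class = "range_state_space"
  )
}

#' @export
print.range_state_space <- function(x, ...) {
  cat(sprintf(
    "<range_state_space> %d areas (%s), max range size %d, %d states\n",
    length(x$areas), paste(x$areas, collapse = ", "), x$max_range_size, length(x$mask)
  ))
  invisible(x)
}

# areas (index vector) contained in a bitmask
mask_areas <- function(mask, n) {
  which(bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L)
}

# bitmask for a set of area labels
areas_to_mask <- function(labels, areas) {
  ix <- match(labels, areas)
  if (anyNA(ix)) abort(sprintf("unknown area label(s): %s", paste(labels[is.na(ix)], collapse = ", ")))
  sum(bitwShiftL(1L, ix - 1L))
}

#' Look up the state index of a range
#'
#' @param space A `range_state_space`.
#' @param range Either a character vector of area labels, a single
#'   concatenated label (e.g. `"ANCA"`), or an integer bitmask.
#' @return Integer state index.
#' @export
state_index <- function(space, range) {
  if (is.numeric(range)) {
    mask <- as.integer(range)
  } else if (length(range) == 1L && !range %in% space$areas && range != "null") {
    ix <- match(range, space$label)
    if (is.na(ix)) abort(sprintf("range label '%s' is not a state of this space", range))
    return(ix)
  } else if (length(range) == 1L && range == "null") {
    return(1L)
  } else {
    mask <- areas_to_mask(range, space$areas)
  }
  ix <- space$index_of[mask + 1L]
  if (is.na(ix)) {
    abort(sprintf(
      "range of size %d exceeds max_range_size %d; raise max_range_size",
      sum(bitwAnd(bitwShiftR(mask, 0:(length(space$areas) - 1L)), 1L)), space$max_range_size
    ))
  }
  ix
}
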