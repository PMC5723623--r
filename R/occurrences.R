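#' Code occurrence points into a presence-absence geography table
#'
#' Assigns each taxon a presence bit for area X iff at least one of its
#' points falls inside any polygon of X, by the even-odd ray-casting rule
#' with polygon boundaries counting as inside. Manual overrides replace the
#' whole computed row for a taxon (mirroring the manual correction step any
#' automated occurrence coding needs). Taxa that end up with an all-zero
#' row, or that have neither points nor an override, are collected in the
#' `"uncoded"` attribute rather than silently kept.
#'
#' @param points Data frame with columns `taxon`, `lon`, `lat` (degrees).
#' @param polygons Named list, one element per area; each element is a list
#'   of closed rings, a ring being a matrix/data frame with columns
#'   `lon`, `lat` (first vertex need not be repeated).
#' @param overrides Optional named list mapping taxon to either a binary
#'   string (e.g. `"01000"`, in area order) or a character vector of areas.
#' @param taxa Optional taxon universe; defaults to taxa seen in `points`
#'   plus those in `overrides`.
#' @return A `geog_tbl` with attribute `"uncoded"` listing problem taxa.
#' @export
code_occurrences <- function(points, polygons, overrides = list(), taxa = NULL) {
  areas <- names(polygons)
  if (is.null(areas) || any(!nzchar(areas))) abort("polygons must be a named list (names = area labels)")
  taxa <- taxa %||% union(unique(points$taxon), names(overrides))
  bits <- matrix(0L, length(taxa), length(areas), dimnames = list(taxa, areas))
  for (a in areas) {
    rings <- polygons[[a]]
    if (!is.list(rings) || !is.null(dim(rings))) rings <- list(rings)
    inside <- rep(FALSE, nrow(points))
    for (ring in rings) {
      ring <- as.matrix(as.data.frame(ring))
      inside <- inside | point_in_ring(points$lon, points$lat, ring[, 1], ring[, 2])
    }
    hit <- unique(points$taxon[inside])
    bits[intersect(hit, taxa), a] <- 1L
  }
  for (tx in names(overrides)) {
    ov <- overrides[[tx]]
    row <- if (length(ov) == 1L && grepl("^[01]+$", ov)) {
      if (nchar(ov) != length(areas)) abort(sprintf("override for '%s' has %d bits, %d areas", tx, nchar(ov), length(areas)))
      as.integer(strsplit(ov, "")[[1]])
    } else {
      as.integer(areas %in% ov)
    }
    bits[tx, ] <- row
  }
  uncoded <- rownames(bits)[rowSums(bits) == 0]
  if (length(uncoded)) {
    warn(sprintf("uncoded taxa (no point in any polygon, no override): %s", paste(uncoded, collapse = ", ")))
  }
  out <- new_geog(bits, rownames(bits), areas)
  attr(out, "uncoded") <- uncoded
  out
}

# even-odd ray casting; points on an edge or vertex count as inside
point_in_ring <- function(px, py, xv, yv) {
  n <- length(xv)
  if (abs(xv[1] - xv[n]) < 1e-300 && abs(yv[1] - yv[n]) < 1e-300) {
    xv <- xv[-n]; yv <- yv[-n]; n <- n - 1L
  }
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- xv[j]; y1 <- yv[j]; x2 <- xv[i]; y2 <- yv[i]
    # boundary test: point within the segment's bounding box and collinear
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    on_seg <- abs(cross) <= 1e-12 * pmax(1, abs(x2 - x1) + abs(y2 - y1)) &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    # even-odd crossing of a ray toward +x
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}
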