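#' Read a Lagrange-style geography file
#'
#' The format is the presence-absence text dialect used by Lagrange-family
#' range estimation software: a header line `"<ntaxa> <nareas> (<labels>)"`
#' followed by one line per taxon, `"<taxon> <binary string of length
#' nareas>"`.
#'
#' @param path Path to the geography file.
#' @return A tibble with a `taxon` column and one 0/1 integer column per
#'   area, classed `geog_tbl`, with the area order in attribute `"areas"`.
#' @seealso [write_geog()], [geog_matrix()]
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("2 3 (AN CA SA)", "t1 100", "t2 011"), f)
#' read_geog(f)
read_geog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty geography file")
  hdr <- regmatches(lines[1], regexec("^\\s*(\\d+)\\s+(\\d+)\\s+\\(([^)]*)\\)\\s*$", lines[1]))[[1]]
  if (length(hdr) != 4) abort("line 1: header must be '<ntaxa> <nareas> (<labels>)'")
  ntaxa <- as.integer(hdr[2]); nareas <- as.integer(hdr[3])
  areas <- strsplit(trimws(hdr[4]), "\\s+")[[1]]
  if (length(areas) != nareas) {
    abort(sprintf("line 1: header declares %d areas but lists %d labels", nareas, length(areas)))
  }
  body <- lines[-1]
  if (length(body) != ntaxa) {
    abort(sprintf("header declares %d taxa but the body has %d rows", ntaxa, length(body)))
  }
  taxa <- character(ntaxa)
  bits <- matrix(0L, ntaxa, nareas, dimnames = list(NULL, areas))
  for (i in seq_along(body)) {
    fields <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(fields) != 2) abort(sprintf("line %d: expected '<taxon> <bits>'", i + 1))
    if (grepl("[^01]", fields[2])) abort(sprintf("non-binary character at line %d", i + 1))
    if (nchar(fields[2]) != nareas) {
      abort(sprintf("line %d: %d bits given, %d areas declared", i + 1, nchar(fields[2]), nareas))
    }
    taxa[i] <- fields[1]
    bits[i, ] <- as.integer(strsplit(fields[2], "")[[1]])
  }
  if (anyDuplicated(taxa)) {
    abort(sprintf("duplicate taxon at line %d", which(duplicated(taxa))[1] + 1))
  }
  new_geog(bits, taxa, areas)
}

#' Construct a geography table from a presence-absence matrix
#'
#' @param bits Integer 0/1 matrix, rows = taxa, columns = areas.
#' @param taxa Taxon names.
#' @param areas Area labels (column order is the bit order).
#' @return A `geog_tbl` tibble.
#' @export
new_geog <- function(bits, taxa, areas) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (any(bits != 0L & bits != 1L)) abort("presence bits must be 0 or 1")
  out <- tibble::as_tibble(as.data.frame(bits, optional = TRUE), .name_repair = "minimal")
  names(out) <- areas
  out <- dplyr::bind_cols(tibble::tibble(taxon = taxa), out)
  structure(out, areas = areas, class = c("geog_tbl", class(out)))
}

#' Presence-absence matrix of a geography table
#'
#' @param geog A `geog_tbl`.
#' @return Integer matrix with taxa as rownames and areas as colnames.
#' @export
geog_matrix <- function(geog) {
  areas <- attr(geog, "areas") %||% setdiff(names(geog), "taxon")
  m <- as.matrix(geog[, areas, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- geog$taxon
  m
}

#' @rdname read_geog
#' @param geog A `geog_tbl`.
#' @return `write_geog()` writes the canonical single-space-separated format
#'   and returns `path` invisibly; `write_geog(read_geog(f))` is
#'   byte-identical for canonical files.
#' @export
write_geog <- function(geog, path) {
  m <- geog_matrix(geog)
  lines <- c(
    sprintf("%d %d (%s)", nrow(m), ncol(m), paste(colnames(m), collapse = " ")),
    sprintf("%s %s", rownames(m), apply(m, 1, paste, collapse = ""))
  )
  writeLines(lines, path)
  invisible(path)
}

# check a geography table against a tree: same taxa, no empty ranges
validate_geog <- function(geog, tree = NULL) {
  m <- geog_matrix(geog)
  empty <- rowSums(m) == 0
  if (any(empty)) {
    abort(sprintf("taxa with empty ranges: %s", paste(rownames(m)[empty], collapse = ", ")))
  }
  if (!is.null(tree)) {
    if (!setequal(tree$tip.label, rownames(m))) {
      only_tree <- setdiff(tree$tip.label, rownames(m))
      only_geog <- setdiff(rownames(m), tree$tip.label)
      abort(sprintf(
        "tree tips and geography taxa differ (tree-only: %s; geog-only: %s)",
        paste(head(only_tree, 3), collapse = ", "), paste(head(only_geog, 3), collapse = ", ")
      ))
    }
  }
  invisible(geog)
}
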