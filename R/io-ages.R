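#' Read a node-age table with 95% HPD bounds
#'
#' Expects a CSV with columns `genus, crown_mean, crown_lo, crown_hi,
#' stem_mean, stem_lo, stem_hi, top_area, top_prob` and optionally
#' `crown_node`, `stem_node`, `clade`. Each HPD interval must bracket its
#' mean (`lo <= mean <= hi`). A stem node younger than its crown node is
#' tolerated with a warning (published consensus-tree tables occasionally
#' contain such rows), never an error.
#'
#' @param path CSV path, UTF-8, `.` decimal separator, header row.
#' @return A tibble of validated age records, classed `age_tbl`.
#' @seealso [caribbean_node_ages()] for the packaged Caribbean table.
#' @export
read_age_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "", check.names = FALSE)
  required <- c("genus", "crown_mean", "crown_lo", "crown_hi", "stem_mean", "stem_lo", "stem_hi")
  optional <- c("crown_node", "stem_node", "top_area", "top_prob", "clade")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) abort(sprintf("age table is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  unknown <- setdiff(names(df), c(required, optional))
  if (length(unknown)) abort(sprintf("unknown column(s) in age table: %s", paste(unknown, collapse = ", ")))
  df <- tibble::as_tibble(df)
  for (node in c("crown", "stem")) {
    lo <- df[[paste0(node, "_lo")]]; mid <- df[[paste0(node, "_mean")]]; hi <- df[[paste0(node, "_hi")]]
    bad <- which(lo > mid | mid > hi)
    if (length(bad)) {
      abort(sprintf(
        "%s HPD does not bracket the mean for: %s (need lo <= mean <= hi)",
        node, paste(df$genus[bad], collapse = ", ")
      ))
    }
  }
  inverted <- which(df$stem_mean < df$crown_mean)
  if (length(inverted)) {
    warn(sprintf(
      "stem mean age younger than crown mean age for: %s (kept as given)",
      paste(df$genus[inverted], collapse = ", ")
    ))
  }
  if (!"clade" %in% names(df)) df$clade <- df$genus
  structure(df, class = c("age_tbl", class(df)))
}

#' Read a literature-age table
#'
#' Expects a CSV with columns `genus, crown, stem, area`; `crown` and
#' `stem` are ages in Ma and may be missing individually, but every row
#' must carry at least one age.
#'
#' @param path CSV path.
#' @return A tibble of literature records.
#' @seealso [caribbean_literature_ages()] for the packaged compilation.
#' @export
read_literature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "", check.names = FALSE)
  required <- c("genus", "crown", "stem")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) abort(sprintf("literature table is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  unknown <- setdiff(names(df), c(required, "area"))
  if (length(unknown)) abort(sprintf("unknown column(s) in literature table: %s", paste(unknown, collapse = ", ")))
  df <- tibble::as_tibble(df)
  df$crown <- as.numeric(df$crown)
  df$stem <- as.numeric(df$stem)
  no_age <- which(is.na(df$crown) & is.na(df$stem))
  if (length(no_age)) {
    abort(sprintf("rows without any age: %s", paste(df$genus[no_age], collapse = ", ")))
  }
  df
}

stratbiogeo_extdata <- function(file) {
  path <- system.file("extdata", file, package = "stratbiogeo")
  if (path == "") abort(sprintf("packaged data file '%s' not found", file))
  path
}

#' Packaged Caribbean reference tables
#'
#' `caribbean_node_ages()` returns the node-age table for the 32 seed-plant
#' genera endemic to the Caribbean analysed by the broad-scale dated
#' phylogeny this package models: per genus the crown and stem mean ages
#' with 95% HPD bounds (Ma), the highest-probability ancestral area at the
#' stem node under the best-fitting stratified founder-event model, and the
#' endemic-clade grouping used for origin summaries.
#' `caribbean_literature_ages()` returns the compilation of independently
#' published crown/stem ages (and, where reported, ancestral areas) for 24
#' of those genera. `caribbean_model_fits()` returns the archived 18-row
#' model-comparison table (3 dispersal scenarios x 6 models: lnL, parameter
#' estimates, AIC, Akaike weight) from the same analysis, useful as
#' reference input for AIC/weight arithmetic.
#'
#' @return A tibble; see each description.
#' @export
caribbean_node_ages <- function() {
  read_age_table(stratbiogeo_extdata("caribbean_node_ages.csv"))
}

#' @rdname caribbean_node_ages
#' @export
caribbean_literature_ages <- function() {
  read_literature_table(stratbiogeo_extdata("caribbean_literature_ages.csv"))
}

#' @rdname caribbean_node_ages
#' @export
caribbean_model_fits <- function() {
  tibble::as_tibble(read.csv(stratbiogeo_extdata("caribbean_model_fits.csv"),
    stringsAsFactors = FALSE, check.names = FALSE
  ))
}
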