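#' A geological age window
#'
#' Defaults to the hypothesized GAARlandia land-bridge span, 33-35 Ma.
#'
#' @param lower,upper Window bounds in Ma, `lower < upper`.
#' @return Numeric length-2 vector of class `age_window`.
#' @export
gaarlandia_window <- function(lower = 33, upper = 35) {
  if (!(lower < upper)) abort("window lower bound must be below its upper bound")
  structure(c(lower = lower, upper = upper), class = "age_window")
}

interval_overlaps <- function(lo, hi, window) {
  # closed intervals: boundary contact counts as overlap
  lo <= window[[2]] & hi >= window[[1]]
}

#' Classify divergence-time intervals against an age window
#'
#' A genus is `overlapping` if its crown or its stem 95% HPD intersects
#' the window (closed intervals, tested first); `younger` if both HPDs lie
#' entirely below the window; `older` if both lie entirely above. The rare
#' configuration where the crown HPD lies entirely below and the stem HPD
#' entirely above (the divergence brackets the window without either HPD
#' touching it) is classed `older`, since the lineage predates the window.
#'
#' @param ages An age table (see [read_age_table()]) or any data frame
#'   with columns `crown_lo`, `crown_hi`, `stem_lo`, `stem_hi`.
#' @param window An [gaarlandia_window()]-style window.
#' @return Character vector (`"younger"`, `"overlapping"`, `"older"`), one
#'   element per row.
#' @export
window_class <- function(ages, window = gaarlandia_window()) {
  need <- c("crown_lo", "crown_hi", "stem_lo", "stem_hi")
  miss <- setdiff(need, names(ages))
  if (length(miss)) abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyNA(ages[need])) abort("missing HPD bound(s); both intervals are required")
  overlap <- interval_overlaps(ages$crown_lo, ages$crown_hi, window) |
    interval_overlaps(ages$stem_lo, ages$stem_hi, window)
  younger <- ages$crown_hi < window[[1]] & ages$stem_hi < window[[1]]
  dplyr::case_when(overlap ~ "overlapping", younger ~ "younger", .default = "older")
}

#' Summarize an age table against a window
#'
#' Applies [window_class()] to every record and tabulates the three-way
#' partition.
#'
#' @inheritParams window_class
#' @return A list of class `window_summary` with `per_genus` (tibble:
#'   genus, class and the four HPD bounds), `counts` (tibble: class, n,
#'   always listing all three classes) and the `window`.
#' @export
#' @examples
#' window_summary(caribbean_node_ages())$counts
window_summary <- function(ages, window = gaarlandia_window()) {
  if (!nrow(ages)) abort("empty age table")
  per <- tibble::tibble(
    genus = ages$genus,
    class = window_class(ages, window),
    crown_lo = ages$crown_lo, crown_hi = ages$crown_hi,
    stem_lo = ages$stem_lo, stem_hi = ages$stem_hi
  )
  counts <- tibble::tibble(class = c("younger", "overlapping", "older")) |>
    dplyr::left_join(dplyr::count(per, .data$class), by = "class") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  structure(list(per_genus = per, counts = counts, window = window), class = "window_summary")
}

#' @export
print.window_summary <- function(x, ...) {
  cat(sprintf("<window_summary> window %g-%g Ma, %d genera\n", x$window[[1]], x$window[[2]], nrow(x$per_genus)))
  print(x$counts)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.window_summary <- function(x, ...) x$per_genus

#' Concordance of literature ages with estimated HPD intervals
#'
#' A genus is `discordant` iff every literature age available for it lies
#' outside the corresponding estimated 95% HPD (crown age vs crown HPD,
#' stem age vs stem HPD; closed intervals, so an age equal to a bound is
#' inside), and `concordant` if at least one lies inside. Genera present
#' in only one of the two tables are skipped with a note.
#'
#' @param lit Literature table (see [read_literature_table()]).
#' @param ages Age table with HPD bounds.
#' @return Tibble with one row per genus present in both tables: the
#'   literature ages, inside/outside flags (`NA` when that age is absent)
#'   and `status`; skipped genera in attribute `"skipped"`.
#' @export
#' @examples
#' dplyr::count(concordance(caribbean_literature_ages(), caribbean_node_ages()), status)
concordance <- function(lit, ages) {
  common <- intersect(lit$genus, ages$genus)
  skipped <- union(setdiff(lit$genus, ages$genus), setdiff(ages$genus, lit$genus))
  if (length(skipped)) {
    inform(sprintf(
      "%d genus/genera present in only one table skipped: %s",
      length(skipped), paste(head(sort(skipped), 8), collapse = ", ")
    ))
  }
  joined <- dplyr::inner_join(
    lit[c("genus", "crown", "stem")],
    ages[c("genus", "crown_lo", "crown_hi", "stem_lo", "stem_hi")],
    by = "genus"
  )
  out <- joined |>
    dplyr::mutate(
      crown_inside = dplyr::if_else(
        is.na(.data$crown), NA,
        .data$crown >= .data$crown_lo & .data$crown <= .data$crown_hi
      ),
      stem_inside = dplyr::if_else(
        is.na(.data$stem), NA,
        .data$stem >= .data$stem_lo & .data$stem <= .data$stem_hi
      ),
      status = dplyr::if_else(
        dplyr::coalesce(.data$crown_inside, FALSE) | dplyr::coalesce(.data$stem_inside, FALSE),
        "concordant", "discordant"
      )
    ) |>
    dplyr::select("genus", "crown", "crown_inside", "stem", "stem_inside", "status")
  attr(out, "skipped") <- skipped
  out
}

#' Ancestral-origin summary from stem-node areas
#'
#' Assigns each genus the highest-probability ancestral area of its stem
#' node; genera grouped into an endemic clade (sister endemic genera that
#' share one stem node) inherit the clade's shared assignment. Composite
#' labels (e.g. `"ANRW"`) are kept composite. Counts are reported at both
#' genus and clade granularity.
#'
#' @param ages Age table with `top_area`, `top_prob` and (optionally)
#'   `clade` columns; a missing `clade` column treats every genus as its
#'   own unit.
#' @return A list of class `origin_summary` with `per_genus`,
#'   `genus_counts`, `clade_counts` and `unassigned` (genera lacking a
#'   `top_area` label).
#' @export
#' @examples
#' origin_summary(caribbean_node_ages())$genus_counts
origin_summary <- function(ages) {
  if (!"top_area" %in% names(ages)) abort("age table has no 'top_area' column")
  df <- tibble::as_tibble(ages)
  if (!"clade" %in% names(df)) df$clade <- df$genus
  df$clade <- dplyr::coalesce(df$clade, df$genus)
  unassigned <- df$genus[is.na(df$top_area)]
  if (length(unassigned)) {
    inform(sprintf("unassigned genera (no top_area): %s", paste(unassigned, collapse = ", ")))
  }
  assigned <- df[!is.na(df$top_area), ]
  if (!"top_prob" %in% names(assigned)) assigned$top_prob <- NA_real_
  per_clade <- assigned |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(
      area = sort(unique(.data$top_area))[1],
      tie = dplyr::n_distinct(.data$top_area) > 1L,
      prob = suppressWarnings(max(.data$top_prob)),
      .groups = "drop"
    )
  ties <- per_clade$clade[per_clade$tie]
  if (length(ties)) {
    warn(sprintf("clade members disagree on top area (lexicographic tie-break): %s", paste(ties, collapse = ", ")))
  }
  per_genus <- assigned |>
    dplyr::select("genus", "clade") |>
    dplyr::left_join(per_clade[c("clade", "area", "prob")], by = "clade")
  structure(
    list(
      per_genus = per_genus,
      genus_counts = dplyr::count(per_genus, .data$area, name = "n_genera"),
      clade_counts = dplyr::count(per_clade, .data$area, name = "n_clades"),
      unassigned = unassigned
    ),
    class = "origin_summary"
  )
}

#' @export
print.origin_summary <- function(x, ...) {
  cat(sprintf("<origin_summary> %d genera in %d clades\n", nrow(x$per_genus), sum(x$clade_counts$n_clades)))
  print(dplyr::full_join(x$genus_counts, x$clade_counts, by = "area"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.origin_summary <- function(x, ...) x$per_genus
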