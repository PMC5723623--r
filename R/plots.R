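#' Plot a model comparison
#'
#' Bar chart of Akaike weights per model, faceted by scenario when the
#' comparison spans several scenarios.
#'
#' @param object A `biogeo_model_comparison` (from [model_selection()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.biogeo_model_comparison <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$model, y = .data$aic_wt)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "Akaike weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (dplyr::n_distinct(object$scenario) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$scenario))
  }
  p
}

#' Plot divergence-time intervals against an age window
#'
#' Horizontal crown/stem 95% HPD bars per genus ordered by crown age, with
#' the window shaded — the standard way to eyeball which lineages could
#' have used a hypothesized land bridge.
#'
#' @param object A `window_summary` (from [window_summary()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.window_summary <- function(object, ...) {
  per <- object$per_genus |>
    tidyr::pivot_longer(
      cols = c("crown_lo", "crown_hi", "stem_lo", "stem_hi"),
      names_to = c("node", ".value"), names_sep = "_"
    ) |>
    dplyr::mutate(genus = stats::reorder(.data$genus, .data$lo))
  ggplot2::ggplot(per) +
    ggplot2::annotate("rect",
      xmin = object$window[[1]], xmax = object$window[[2]],
      ymin = -Inf, ymax = Inf, alpha = 0.25, fill = "grey40"
    ) +
    ggplot2::geom_linerange(
      ggplot2::aes(y = .data$genus, xmin = .data$lo, xmax = .data$hi, colour = .data$node),
      position = ggplot2::position_dodge(width = 0.6)
    ) +
    ggplot2::scale_colour_manual(values = c(crown = "#2166ac", stem = "#b2182b")) +
    ggplot2::labs(x = "Age (Ma)", y = NULL, colour = "node") +
    ggplot2::theme_minimal()
}

#' Plot ancestral range probabilities
#'
#' Stacked per-node state probabilities for the internal nodes of a
#' marginal ancestral-range reconstruction (states below `min_prob`
#' everywhere are pooled as "other").
#'
#' @param object A `node_range_probs` (from [ancestral_marginals()]).
#' @param min_prob States never reaching this probability are pooled.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.node_range_probs <- function(object, min_prob = 0.1, ...) {
  df <- tidy(object)
  keep <- df |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(mx = max(.data$prob), .groups = "drop") |>
    dplyr::filter(.data$mx >= min_prob) |>
    dplyr::pull(.data$state)
  df <- df |>
    dplyr::mutate(state = ifelse(.data$state %in% keep, .data$state, "other")) |>
    dplyr::group_by(.data$node, .data$state) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$node), y = .data$prob, fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "internal node", y = "marginal probability", fill = "range") +
    ggplot2::theme_minimal()
}
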