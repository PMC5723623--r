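#' Simulate one tree-plus-ranges dataset
#'
#' Draws a Yule tree and evolves ranges on it. Occasionally a drawn tree
#' cannot yield extant-only data at the requested rates (every range
#' replicate contains an extinct tip, e.g. when deep branches are long);
#' the tree and ranges are then redrawn together, deterministically in the
#' seed, up to `max_dataset_tries` times.
#'
#' @inheritParams recovery_experiment
#' @param model Model to simulate under.
#' @param seed Integer seed.
#' @param max_dataset_tries Cap on whole-dataset redraws.
#' @return List with `tree`, `geog`, `sim` (the [simulate_ranges()]
#'   output) and `dataset_tries`.
#' @export
simulate_biogeo_dataset <- function(truth, model, config, n_tips = 200,
                                    lambda = 0.25, target_height = 20,
                                    seed = 1, max_range_size = NULL,
                                    max_dataset_tries = 20) {
  for (a in seq_len(max_dataset_tries)) {
    tr <- simulate_yule_tree(n_tips, lambda,
      seed = seed + (a - 1L) * 1000003L, target_height = target_height
    )
    sim <- tryCatch(
      simulate_ranges(tr, config, model, truth,
        seed = seed + 1L + (a - 1L) * 1000003L, max_range_size = max_range_size
      ),
      error = function(err) NULL
    )
    if (!is.null(sim)) {
      return(list(tree = tr, geog = sim$geog, sim = sim, dataset_tries = a))
    }
  }
  abort(sprintf(
    "no extant-only dataset in %d tree draws; lower e relative to d or shrink the tree",
    max_dataset_tries
  ))
}

#' Simulation-based parameter and model recovery
#'
#' Simulates replicate datasets (Yule tree + range evolution) under known
#' parameters, refits one or more models to each, and summarizes how well
#' the truth is recovered: bias, relative RMSE and a model-selection table
#' when several models are fitted. This is the standard validation harness
#' for the fitting machinery; see the methods vignette for the problem
#' sizes used in the packaged tests.
#'
#' @param truth Named vector `c(d=, e=, j=)` used to simulate.
#' @param sim_model Model the data is simulated under.
#' @param fit_models Character vector of models fitted to each replicate.
#' @param config Epoch configuration (areas + multipliers) shared by
#'   simulation and fitting.
#' @param n_tips Tips per simulated tree.
#' @param lambda Yule birth rate per Ma.
#' @param replicates Number of replicates.
#' @param seed Integer seed; replicate r uses `seed + r` internally.
#' @param target_height Fixed tree height (Ma); `NULL` leaves the Yule
#'   height random. The default 20-Ma, 200-tip radiation gives the
#'   simulated ranges enough events to carry signal while keeping the
#'   extinct-tip rejection step of [simulate_ranges()] tractable.
#' @param starts Optional start list forwarded to [fit_model()] (a single
#'   start speeds large grids considerably).
#' @param max_range_size Passed through to simulation and fitting.
#' @return A list of class `recovery_report`: `per_replicate` (one row per
#'   replicate x fitted model), `estimates` (summary of bias/RMSE for the
#'   simulated model's own fit) and `selection` (AIC winner counts, when
#'   more than one model was fitted).
#' @export
recovery_experiment <- function(truth, sim_model, fit_models = sim_model, config,
                                n_tips = 200, lambda = 0.25, replicates = 20,
                                seed = 1, target_height = 20, max_range_size = NULL,
                                starts = NULL) {
  rows <- list()
  for (r in seq_len(replicates)) {
    ds <- simulate_biogeo_dataset(truth, sim_model, config,
      n_tips = n_tips, lambda = lambda, target_height = target_height,
      seed = seed + 10000 * r, max_range_size = max_range_size
    )
    tr <- ds$tree
    sim <- ds$sim
    fits <- list()
    for (m in fit_models) {
      sp <- model_spec(m)
      base <- if (sp$founder) fits[[sp$family]] else NULL
      fits[[sp$name]] <- fit_model(tr, sim$geog, config, m,
        base_fit = base, max_range_size = max_range_size, starts = starts
      )
    }
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    winner <- names(fits)[order(aics, vapply(fits, function(f) f$k, numeric(1)), names(fits))[1]]
    for (f in fits) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = r, model = f$model,
        d = unname(f$params["d"]), e = unname(f$params["e"]), j = unname(f$params["j"]),
        loglik = f$loglik, aic = f$aic, selected = f$model == winner
      )
    }
  }
  per <- dplyr::bind_rows(rows)
  own <- per[per$model == model_spec(sim_model)$name, ]
  summarize_par <- function(est, tru) {
    tibble::tibble(
      truth = tru, mean_estimate = mean(est), bias = mean(est) - tru,
      rel_rmse = if (tru > 0) sqrt(mean((est - tru)^2)) / tru else NA_real_
    )
  }
  estimates <- dplyr::bind_rows(
    d = summarize_par(own$d, truth[["d"]]),
    e = summarize_par(own$e, truth[["e"]]),
    j = summarize_par(own$j, if ("j" %in% names(truth)) truth[["j"]] else 0),
    .id = "param"
  )
  selection <- if (length(fit_models) > 1) {
    dplyr::count(per[per$selected, ], .data$model, name = "n_selected")
  } else NULL
  structure(
    list(per_replicate = per, estimates = estimates, selection = selection,
         truth = truth, sim_model = model_spec(sim_model)$name),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> simulated under %s, %d replicates\n",
    x$sim_model, max(x$per_replicate$replicate)
  ))
  print(x$estimates)
  if (!is.null(x$selection)) print(x$selection)
  invisible(x)
}
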