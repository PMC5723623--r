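#' Akaike information criterion from log-likelihood
#'
#' `AIC = 2k - 2 lnL`, with `k` the number of free parameters (2 for base
#' models, 3 for `+J` models).
#'
#' @param lnl Log-likelihood (natural log).
#' @param k Number of free parameters.
#' @return AIC value(s).
#' @export
#' @examples
#' aic_from_loglik(-1221.16, 3)
aic_from_loglik <- function(lnl, k) {
  2 * k - 2 * lnl
}

#' Akaike weights of a model set
#'
#' `w_i = exp(-dAIC_i / 2) / sum(exp(-dAIC / 2))`, with `dAIC` relative to
#' the smallest AIC in the set; weights sum to 1.
#'
#' @param aic Numeric vector of AIC values fitted to the same data.
#' @return Numeric vector of weights.
#' @export
akaike_weights <- function(aic) {
  rel <- exp(-(aic - min(aic)) / 2)
  rel / sum(rel)
}

default_starts <- function(founder) {
  de <- list(c(0.01, 0.01), c(0.1, 0.01), c(0.001, 0.001))
  js <- if (founder) c(0, 0.01, 0.1) else 0
  out <- list()
  for (s in de) for (j in js) out[[length(out) + 1L]] <- c(d = s[1], e = s[2], j = j)
  out
}

#' Fit a range-evolution model by maximum likelihood
#'
#' Maximizes [stratified_loglik()] over `d`, `e` (and `j` for `+J` models)
#' with bounded multi-start local optimization (`L-BFGS-B` on log10-rate
#' scale; `d, e` in `[1e-12, 5]` per Ma, `j` in `[0, 3]`). For `+J` models
#' the optimizer is additionally started from the corresponding base
#' model's optimum (computed on the fly or passed via `base_fit`), which
#' guarantees the nested-model property `lnL(+J) >= lnL(base)` up to
#' optimizer tolerance.
#'
#' @inheritParams stratified_loglik
#' @param starts List of named start vectors `c(d=, e=, j=)`; defaults to a
#'   small grid.
#' @param base_fit Optional `biogeo_fit` of the base (no-`J`) model on the
#'   same data, used as an extra start for `+J` fits.
#' @param seed Optional integer seed (kept for interface symmetry; the
#'   default optimization is deterministic).
#' @param scenario Optional label recorded in the result (e.g. a preset
#'   configuration name).
#' @return A `biogeo_fit` object: model spec, MLE `params`, `loglik`, `k`,
#'   `aic`, convergence diagnostics and a data fingerprint. Supports
#'   [tidy()] and [glance()].
#' @export
fit_model <- function(tree, geog, config, model, starts = NULL, base_fit = NULL,
                      max_range_size = NULL, root_prior = "uniform",
                      seed = NULL, scenario = config$name) {
  spec <- model_spec(model)
  if (!is.null(seed)) set.seed(seed)
  if (spec$founder && is.null(base_fit)) {
    base_fit <- fit_model(tree, geog, config, spec$family,
      starts = starts, max_range_size = max_range_size,
      root_prior = root_prior, scenario = scenario
    )
  }
  starts <- starts %||% default_starts(spec$founder)
  if (spec$founder && !is.null(base_fit)) {
    starts <- c(starts, list(c(base_fit$params[c("d", "e")], j = 0)))
  }

  lb <- c(log10(1e-12), log10(1e-12), 0)
  ub <- c(log10(5), log10(5), 3)
  npar <- if (spec$founder) 3L else 2L
  machine <- biogeo_machine(tree, geog, config, spec$name,
    root_prior = root_prior, max_range_size = max_range_size
  )
  obj <- function(theta) {
    par <- c(d = 10^theta[1], e = 10^theta[2], j = if (npar == 3L) theta[3] else 0)
    ll <- machine$eval(par)
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  diagnostics <- list(n_starts = length(starts), convergence = integer(0), evals = 0L)
  for (si in seq_along(starts)) {
    st <- starts[[si]]
    theta0 <- c(log10(max(st[["d"]], 1e-12)), log10(max(st[["e"]], 1e-12)),
                if (npar == 3L) min(max(st[["j"]], 0), 3))
    theta0 <- theta0[seq_len(npar)]
    res <- tryCatch(
      optim(theta0, obj, method = "L-BFGS-B",
            lower = lb[seq_len(npar)], upper = ub[seq_len(npar)],
            control = list(factr = 1e8, maxit = 200)),
      error = function(err) NULL
    )
    if (is.null(res)) next
    diagnostics$convergence <- c(diagnostics$convergence, res$convergence)
    diagnostics$evals <- diagnostics$evals + res$counts[1]
    if (is.null(best) || res$value < best$value) {
      best <- res
      diagnostics$best_start <- si
    }
  }
  if (is.null(best)) abort("all optimizer starts failed")
  diagnostics$converged <- any(diagnostics$convergence == 0)
  if (!diagnostics$converged) {
    warn(sprintf("no optimizer start reported clean convergence for %s; best point returned", spec$name))
  }
  params <- c(
    d = 10^best$par[1], e = 10^best$par[2],
    j = if (npar == 3L) unname(best$par[3]) else 0
  )
  lnl <- -best$value
  structure(
    list(
      model = spec$name, family = spec$family, founder = spec$founder,
      scenario = scenario, params = params, loglik = lnl, k = npar,
      aic = aic_from_loglik(lnl, npar), diagnostics = diagnostics,
      fingerprint = data_fingerprint(tree, geog, config)
    ),
    class = "biogeo_fit"
  )
}

data_fingerprint <- function(tree, geog, config) {
  hash(list(
    sort(tree$tip.label), round(sort(tree$edge.length), 12),
    geog_matrix(geog)[sort(geog$taxon), , drop = FALSE],
    config$boundaries, config$matrices
  ))
}

#' @export
print.biogeo_fit <- function(x, ...) {
  cat(sprintf(
    "<biogeo_fit> %s (%s scenario): lnL = %.4f, AIC = %.4f\n  d = %.6g, e = %.6g, j = %.6g\n",
    x$model, x$scenario, x$loglik, x$aic, x$params["d"], x$params["e"], x$params["j"]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.biogeo_fit <- function(x, ...) {
  keep <- if (x$founder) c("d", "e", "j") else c("d", "e")
  tibble::tibble(term = keep, estimate = unname(x$params[keep]))
}

#' @exportS3Method generics::glance
glance.biogeo_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, scenario = x$scenario, logLik = x$loglik,
    k = x$k, AIC = x$aic, converged = x$diagnostics$converged
  )
}

#' Compare fitted models by AIC
#'
#' Ranks a set of fits of the same data, reporting delta-AIC and Akaike
#' weights. Ties in AIC are broken by fewer parameters, then by model
#' name. Fits whose data fingerprints differ are rejected.
#'
#' @param fits List of `biogeo_fit` objects (>= 2) on identical data.
#' @return A tibble of class `biogeo_model_comparison` with one row per
#'   fit: `scenario`, `model`, `lnl`, `k`, `d`, `e`, `j`, `aic`,
#'   `delta_aic`, `aic_wt` and `best`.
#' @export
model_selection <- function(fits) {
  if (length(fits) < 2) abort("need at least two fits to compare")
  fp <- vapply(fits, function(f) f$fingerprint, character(1))
  if (length(unique(fp)) > 1) abort("fits were computed on different data; refusing to compare")
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      scenario = f$scenario, model = f$model, lnl = f$loglik, k = f$k,
      d = unname(f$params["d"]), e = unname(f$params["e"]), j = unname(f$params["j"]),
      aic = f$aic
    )
  })
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$aic_wt <- akaike_weights(tab$aic)
  ord <- order(tab$aic, tab$k, tab$model)
  tab$best <- seq_len(nrow(tab)) == ord[1]
  class(tab) <- c("biogeo_model_comparison", class(tab))
  tab
}
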