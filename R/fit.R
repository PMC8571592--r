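#' Default optimizer configuration for Mk model fitting
#'
#' Rates are optimized on the log scale within `[lower, upper]` (1/Myr),
#' with multiple restarts: one moderate deterministic start scaled to the
#' tree height plus `restarts - 1` log-uniform random starts. Restarts guard
#' against the multimodality typical of hidden-rate-class likelihoods.
#'
#' @param lower,upper rate bounds in 1/Myr.
#' @param restarts total number of optimizer starts (>= 1).
#' @param tol relative convergence tolerance passed to [stats::nlminb()].
#' @param seed optional integer seed for the random restarts.
#' @return a list usable as `config` in [fit_ml()].
#' @export
optimizer_config <- function(lower = 1e-8, upper = 1e2, restarts = 10,
                             tol = 1e-8, seed = NULL) {
  stopifnot(lower > 0, upper > lower, restarts >= 1)
  list(lower = lower, upper = upper, restarts = as.integer(restarts),
       tol = tol, seed = seed)
}

#' Maximum-likelihood fit of a structured Mk model
#'
#' Maximizes [pruning_loglik()] over the model's rate parameters on the log
#' scale using [stats::nlminb()] with multiple restarts. The fit is flagged
#' unconverged when fewer than two successful restarts agree with the best
#' log-likelihood within 0.01 log-units (with a single restart, the
#' optimizer's own convergence code is used).
#'
#' @inheritParams pruning_loglik
#' @param config optimizer settings from [optimizer_config()].
#' @return an object of class `"mk_fit"`: list with `spec`, `params` (MLE,
#'   1/Myr), `Q` (rate matrix at the MLE), `logLik`, `AIC`, `converged`,
#'   `restarts`, `restart_logLik`, `root_prior`.
#' @examples
#' \donttest{
#' fx <- make_study_fixture(seed = 1, n_tips = 40, n_posterior = 0)
#' fit <- fit_ml(fx$tree, fx$characters, build_model_spec("four_rate"),
#'               config = optimizer_config(restarts = 2, seed = 1))
#' fit$AIC
#' }
#' @export
fit_ml <- function(tree, data, spec, root_prior = "equal",
                   config = optimizer_config()) {
  stopifnot(inherits(spec, "mk_model_spec"))
  cache <- .pruning_cache(tree, data, spec$n_class)
  m <- spec$n_expanded

  negll <- function(logp) {
    p <- exp(logp)
    ll <- tryCatch({
      pr <- .mk_pruning(cache, assemble_q(spec, p))
      root_cond <- pr$L[cache$root, ]
      w <- .root_weights(root_prior, root_cond, m)
      log(sum(w * root_cond)) + pr$logsc[cache$root]
    }, error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  height <- max(ape::node.depth.edgelength(tree))
  if (height <= 0) height <- 1
  starts <- matrix(NA_real_, config$restarts, spec$k)
  starts[1, ] <- rep(log(1 / height), spec$k)
  if (config$restarts > 1) {
    if (!is.null(config$seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(config$seed)
    }
    for (r in 2:config$restarts)
      starts[r, ] <- log(10^stats::runif(spec$k, -2.5, 0.5) / height)
  }
  lo <- log(config$lower); hi <- log(config$upper)
  starts <- pmin(pmax(starts, lo), hi)

  fits <- vector("list", config$restarts)
  for (r in seq_len(config$restarts)) {
    fits[[r]] <- tryCatch(
      stats::nlminb(starts[r, ], negll, lower = lo, upper = hi,
                    control = list(rel.tol = config$tol, iter.max = 500)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("optimizer failed on all ", config$restarts, " restarts for model '",
         spec$name, "'", call. = FALSE)
  lls <- vapply(fits, function(f) if (is.null(f)) -Inf else -f$objective,
                numeric(1))
  best <- which.max(lls)
  if (config$restarts == 1L) {
    converged <- fits[[best]]$convergence == 0
  } else {
    converged <- sum(lls >= lls[best] - 0.01) >= 2
  }
  params <- exp(fits[[best]]$par)
  logL <- lls[best]
  structure(list(spec = spec, params = params,
                 Q = assemble_q(spec, params),
                 logLik = logL, AIC = aic_score(logL, spec$k),
                 converged = converged, restarts = config$restarts,
                 restart_logLik = lls, root_prior = root_prior),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit '", x$spec$name, "': logL = ", format(x$logLik, digits = 8),
      ", k = ", x$spec$k, ", AIC = ", format(x$AIC, digits = 8),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("rates (1/Myr):", format(x$params, digits = 4), "\n")
  invisible(x)
}

#' AIC model-selection table over a set of model specifications
#'
#' Fits each model by [fit_ml()] and ranks them by AIC. Per-model failures
#' are reported as flagged rows (NA scores), not as errors.
#'
#' @inheritParams fit_ml
#' @param specs list of `"mk_model_spec"` objects or model-name strings;
#'   defaults to all six models of the family.
#' @return data.frame with columns `model`, `k`, `logLik`, `AIC`, `dAIC`,
#'   `converged`, `error`, sorted by AIC (failed rows last); the full
#'   `"mk_fit"` objects are attached as attribute `"fits"`.
#' @export
model_selection_table <- function(tree, data, specs = mk_model_names(),
                                  root_prior = "equal",
                                  config = optimizer_config()) {
  if (length(specs) < 2) stop("need at least two models", call. = FALSE)
  specs <- lapply(specs, function(s)
    if (inherits(s, "mk_model_spec")) s else build_model_spec(s))
  fits <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    fit <- tryCatch(fit_ml(tree, data, specs[[i]], root_prior, config),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(model = specs[[i]]$name, k = specs[[i]]$k,
                              logLik = NA_real_, AIC = NA_real_,
                              converged = FALSE,
                              error = conditionMessage(fit),
                              stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- fit
      rows[[i]] <- data.frame(model = specs[[i]]$name, k = specs[[i]]$k,
                              logLik = fit$logLik, AIC = fit$AIC,
                              converged = fit$converged, error = "",
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  tab <- tab[order(tab$AIC), c("model", "k", "logLik", "AIC", "dAIC",
                               "converged", "error")]
  rownames(tab) <- NULL
  attr(tab, "fits") <- stats::setNames(fits, vapply(specs, `[[`, "", "name"))
  tab
}

#' Names of the six models in the family
#'
#' @return character vector of valid [build_model_spec()] names.
#' @export
mk_model_names <- function() {
  c("two_rate", "four_rate", "ard",
    "hmm_ard_plus_four_rate_2class", "hmm_ard_2class", "hmm_ard_3class")
}
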