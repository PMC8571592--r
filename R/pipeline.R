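# ---- Config-driven end-to-end runs -----------------------------------------

#' Analysis configuration
#'
#' Collects every knob of an end-to-end run. Inputs may be file paths
#' (Newick/NEXUS trees, TSV/CSV character table) or in-memory objects.
#'
#' @param tree consensus tree: path or `"phylo"`.
#' @param characters character table: path or data.frame.
#' @param posterior optional posterior tree set: path or `"multiPhylo"`.
#' @param rename_map optional taxon rename map: path or data.frame.
#' @param models model names to fit (default: all six).
#' @param root_prior `"fitzjohn"` (default) or `"equal"`. FitzJohn
#'   (conditionals-proportional) weighting avoids placing root mass on
#'   states the data rule out, which under equal weighting produces spurious
#'   transition mass on the short root-adjacent edges of stochastic maps.
#' @param n_maps stochastic maps on the consensus tree.
#' @param n_maps_posterior maps per posterior tree.
#' @param n_posterior posterior trees to use (subsampled from the head).
#' @param bins time bins for the rate-through-time series.
#' @param boundary K-Pg age cut in Myr before present.
#' @param modal_threshold minimum modal probability for origin counting.
#' @param seed master seed.
#' @param outdir optional output directory for TSV/JSON artifacts.
#' @param optimizer optimizer settings, see [optimizer_config()].
#' @return a list of class `"analysis_config"`.
#' @export
analysis_config <- function(tree, characters, posterior = NULL,
                            rename_map = NULL, models = mk_model_names(),
                            root_prior = "fitzjohn", n_maps = 5000,
                            n_maps_posterior = 500, n_posterior = 1000,
                            bins = 50, boundary = 66.02,
                            modal_threshold = 0.5, seed = 1, outdir = NULL,
                            optimizer = optimizer_config()) {
  stopifnot(n_maps >= 1, bins >= 1, boundary > 0)
  structure(list(tree = tree, characters = characters, posterior = posterior,
                 rename_map = rename_map, models = models,
                 root_prior = root_prior, n_maps = n_maps,
                 n_maps_posterior = n_maps_posterior,
                 n_posterior = n_posterior, bins = bins, boundary = boundary,
                 modal_threshold = modal_threshold, seed = seed,
                 outdir = outdir, optimizer = optimizer),
            class = "analysis_config")
}

.load_inputs <- function(config) {
  tree <- if (is.character(config$tree)) read_trees(config$tree) else config$tree
  validate_tree(tree)
  chars <- if (is.character(config$characters))
    read_character_table(config$characters, rename_map = config$rename_map)
  else config$characters
  if (config$boundary >= root_age(tree))
    stop("boundary age must lie inside (0, root age)", call. = FALSE)
  posterior <- config$posterior
  if (!is.null(posterior) && is.character(posterior)) {
    if (!file.exists(posterior)) posterior <- NULL else
      posterior <- read_trees(posterior)
  }
  if (!is.null(posterior)) {
    if (inherits(posterior, "phylo")) posterior <- list(posterior)
    posterior <- posterior[seq_len(min(length(posterior), config$n_posterior))]
  }
  list(tree = tree, chars = chars, posterior = posterior)
}

.maybe_write <- function(df, config, name) {
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(df, file.path(config$outdir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}

#' Run AIC model selection on the consensus tree
#'
#' Fits the configured model list on the consensus tree and ranks by AIC;
#' writes `model_selection.tsv` when an output directory is set.
#'
#' @param config an [analysis_config()].
#' @return the [model_selection_table()] result (best model attached as
#'   attribute `"best"`).
#' @export
run_model_selection <- function(config) {
  inp <- .load_inputs(config)
  cfg <- config$optimizer
  cfg$seed <- config$seed
  tab <- model_selection_table(inp$tree, inp$chars, config$models,
                               config$root_prior, cfg)
  ok <- !is.na(tab$AIC) & tab$converged
  best <- if (any(ok)) tab$model[which(ok)[1]] else tab$model[1]
  attr(tab, "best") <- best
  .maybe_write(tab[, setdiff(names(tab), "error")], config,
               "model_selection.tsv")
  tab
}

#' Run ancestral reconstructions and stochastic mapping
#'
#' Fits (or accepts) a model on the consensus tree and emits: marginal ASR,
#' Sankoff parsimony ASR, and a stochastic-map summary from `n_maps`
#' consensus maps. When a posterior tree set is configured, maps are also
#' generated on each posterior tree (`n_maps_posterior` each, Q refit per
#' tree) and summarized onto the consensus tree by clade matching.
#'
#' @param config an [analysis_config()].
#' @param model model name to use; default: the first configured model.
#' @param fit optional precomputed `"mk_fit"` (skips refitting).
#' @return list with `fit`, `marginal` (node probability matrix),
#'   `parsimony` (`"mpr_recon"`), `consensus_summary` and
#'   `posterior_summary` (`"simmap_summary"` or NULL).
#' @export
run_asr <- function(config, model = config$models[[1]], fit = NULL) {
  inp <- .load_inputs(config)
  spec <- if (inherits(model, "mk_model_spec")) model else build_model_spec(model)
  if (is.null(fit)) {
    cfg <- config$optimizer
    cfg$seed <- config$seed
    fit <- fit_ml(inp$tree, inp$chars, spec, config$root_prior, cfg)
  }
  marginal <- marginal_asr(inp$tree, inp$chars, spec, fit$params,
                           config$root_prior)
  pars <- parsimony_asr(inp$tree, inp$chars)
  cons_maps <- generate_maps(inp$tree, inp$chars, spec,
                             n_maps = config$n_maps,
                             root_prior = config$root_prior,
                             q_source = "fixed", Q = fit$Q,
                             seed = config$seed)
  cons_sum <- summarize_maps(cons_maps, ref_tree = inp$tree)
  post_sum <- NULL
  post_maps <- NULL
  if (!is.null(inp$posterior)) {
    cfg <- config$optimizer
    cfg$restarts <- min(cfg$restarts, 3L)
    post_maps <- generate_maps(inp$posterior, inp$chars, spec,
                               n_maps = config$n_maps_posterior,
                               root_prior = config$root_prior,
                               q_source = "refit", config = cfg,
                               seed = config$seed + 1L)
    post_sum <- summarize_maps(post_maps, ref_tree = inp$tree)
  }
  .maybe_write(data.frame(node = rownames(marginal), round(marginal, 6)),
               config, "marginal_asr.tsv")
  .maybe_write(data.frame(node = seq_len(nrow(cons_sum$node_probs)),
                          round(cons_sum$node_probs, 6)),
               config, "simmap_consensus.tsv")
  list(fit = fit, marginal = marginal, parsimony = pars,
       consensus_maps = cons_maps, consensus_summary = cons_sum,
       posterior_maps = post_maps, posterior_summary = post_sum)
}

#' Count post-boundary origins of arboreality
#'
#' Audit-style counting rule over modal node states: an origin is an edge
#' whose child node is modally arboreal (probability above the threshold),
#' whose parent is determinately modal in a non-arboreal state, and whose
#' child age is younger than the boundary. Once an origin is counted,
#' further origins nested inside that arboreal subtree are skipped, so
#' repeated gains within an already-arboreal clade are not double-counted.
#' Nodes with modal ties or sub-threshold modes are indeterminate: they are
#' never origins themselves and never serve as the non-arboreal parent of
#' one.
#'
#' @param node_probs matrix of per-node observed-state probabilities over
#'   all nodes (tips degenerate), as returned by [marginal_asr()] or in a
#'   `"simmap_summary"`.
#' @param tree the reference tree (for ages and edges).
#' @param boundary age cut in Myr (default 66.02, the K-Pg boundary).
#' @param modal_threshold minimum probability for a modal call.
#' @return list with `count` and `edges` (audit data.frame: parent, child,
#'   child age, modal probabilities).
#' @export
count_post_boundary_arboreal_origins <- function(node_probs, tree,
                                                 boundary = 66.02,
                                                 modal_threshold = 0.5) {
  ages <- node_ages(tree)
  if (anyNA(ages)) stop("missing node ages", call. = FALSE)
  ntot <- ape::Ntip(tree) + tree$Nnode
  stopifnot(nrow(node_probs) == ntot)
  modal <- apply(node_probs, 1, function(p) {
    if (anyNA(p)) return(NA_integer_)
    mx <- max(p)
    if (mx < modal_threshold || sum(p == mx) > 1L) NA_integer_ else
      which.max(p)
  })
  arb <- !is.na(modal) & modal == 1L
  nonarb <- !is.na(modal) & modal != 1L  # determinate, not arboreal
  # preorder walk, skipping subtrees below a counted origin
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  blocked <- logical(ntot)
  hits <- list()
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1]; ch <- pre[e, 2]
    if (blocked[p]) { blocked[ch] <- TRUE; next }
    if (arb[ch] && nonarb[p] && ages[ch] < boundary) {
      hits[[length(hits) + 1L]] <- data.frame(
        parent = p, child = ch, child_age = unname(ages[ch]),
        p_arboreal_child = node_probs[ch, 1],
        p_arboreal_parent = node_probs[p, 1])
      blocked[ch] <- TRUE
    }
  }
  edges <- if (length(hits)) do.call(rbind, hits) else
    data.frame(parent = integer(0), child = integer(0),
               child_age = numeric(0), p_arboreal_child = numeric(0),
               p_arboreal_parent = numeric(0))
  list(count = nrow(edges), edges = edges)
}

#' Run the transition-rate-through-time stage
#'
#' Computes the branch-length-normalized per-type transition series for the
#' consensus maps, and per-tree curves over the posterior maps when
#' supplied; writes `rtt_consensus.tsv` (and `rtt_posterior.tsv`) when an
#' output directory is set.
#'
#' @param config an [analysis_config()].
#' @param consensus_maps a `"simmap_set"` on the consensus tree (e.g. from
#'   [run_asr()]).
#' @param posterior_maps optional `"simmap_set"` over posterior trees.
#' @return list with `consensus` (`"rtt_series"`) and `posterior`
#'   (`"rtt_bundle"` or NULL).
#' @export
run_rtt <- function(config, consensus_maps, posterior_maps = NULL) {
  inp <- .load_inputs(config)
  cons <- normalized_transition_series(consensus_maps, inp$tree,
                                       B = config$bins)
  post <- NULL
  if (!is.null(posterior_maps)) {
    live <- setdiff(seq_along(posterior_maps$trees), posterior_maps$skipped)
    series <- lapply(live, function(i)
      normalized_transition_series(posterior_maps$maps[[i]],
                                   posterior_maps$trees[[i]],
                                   B = config$bins))
    post <- aggregate_over_posterior(series)
  }
  .maybe_write(as.data.frame(cons), config, "rtt_consensus.tsv")
  if (!is.null(post)) .maybe_write(post$curves, config, "rtt_posterior.tsv")
  list(consensus = cons, posterior = post)
}

#' Assemble and write the machine-readable analysis report
#'
#' Collects the stage outputs into one JSON-serializable report with a run
#' manifest (seed, package version, configuration echo). Stages not run are
#' flagged as skipped and the report marked incomplete.
#'
#' @param config an [analysis_config()].
#' @param selection output of [run_model_selection()] (or NULL).
#' @param asr output of [run_asr()] (or NULL).
#' @param rtt output of [run_rtt()] (or NULL).
#' @param origins output of [count_post_boundary_arboreal_origins()] (or NULL).
#' @return the report list, invisibly; written to `report.json` under
#'   `config$outdir` when set.
#' @export
write_report <- function(config, selection = NULL, asr = NULL, rtt = NULL,
                         origins = NULL) {
  stages <- c(model_selection = !is.null(selection), asr = !is.null(asr),
              rtt = !is.null(rtt), origins = !is.null(origins))
  report <- list(
    manifest = list(
      package = "arbormk",
      version = as.character(utils::packageVersion("arbormk")),
      seed = config$seed, boundary = config$boundary,
      bins = config$bins, n_maps = config$n_maps,
      root_prior = config$root_prior, models = unlist(config$models)),
    stages_run = as.list(stages),
    complete = all(stages))
  if (!is.null(selection)) {
    report$model_selection <- selection[, c("model", "k", "logLik", "AIC",
                                            "dAIC", "converged")]
    report$best_model <- attr(selection, "best")
  }
  if (!is.null(asr)) {
    report$chosen_model <- asr$fit$spec$name
    report$logLik <- asr$fit$logLik
    report$AIC <- asr$fit$AIC
    report$mle_rates <- as.list(stats::setNames(asr$fit$params,
                                                paste0("rate", seq_along(asr$fit$params))))
    report$mean_transitions_per_map <- asr$consensus_summary$mean_counts
  }
  if (!is.null(origins)) {
    report$post_boundary_arboreal_origins <- origins$count
    report$origin_edges <- origins$edges
  }
  if (!is.null(rtt)) {
    peak <- .series_peak(rtt$consensus, "semi-arboreal->nonarboreal")
    report$sn_peak_bin_age <- peak
  }
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(report)
}

# Midpoint age of the bin where a type's normalized series peaks.
.series_peak <- function(series, type) {
  s <- series[series$type == type & !is.na(series$value), ]
  if (!nrow(s)) return(NA_real_)
  i <- which.max(s$value)
  (s$older[i] + s$younger[i]) / 2
}
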