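# ---- Bayesian stochastic character mapping ---------------------------------
#
# A map is sampled in two stages: (1) joint node states drawn backward from
# the pruning conditionals (root from the prior-weighted conditionals, then
# each child given its sampled parent), (2) an endpoint-conditioned CTMC
# path on every edge, sampled exactly by uniformization (Poisson number of
# candidate jumps at the dominating rate, bridge over the candidate chain,
# virtual jumps thinned).

.observed_state <- function(expanded) ((expanded - 1L) %% 3L) + 1L

#' Sample joint node states conditional on tip data
#'
#' Draws one joint assignment of (expanded) states to all nodes from the
#' exact conditional distribution given the tip data: the root from the
#' prior-weighted root conditionals, then each child from its conditional
#' given the sampled parent state. Uses R's current RNG stream.
#'
#' @inheritParams pruning_loglik
#' @param Q rate matrix over the expanded space (its dimension determines
#'   the number of hidden classes).
#' @return integer vector of expanded-state indices, one per node (ape ids).
#' @export
sample_joint_node_states <- function(tree, data, Q, root_prior = "equal") {
  n_class <- nrow(Q) %/% 3L
  cache <- .pruning_cache(tree, data, n_class)
  pr <- .mk_pruning(cache, Q)
  .draw_node_states(cache, pr, root_prior)
}

.draw_node_states <- function(cache, pr, root_prior) {
  m <- pr$m
  states <- integer(cache$ntot)
  w <- .root_weights(root_prior, pr$L[cache$root, ], m)
  probs <- w * pr$L[cache$root, ]
  states[cache$root] <- sample.int(m, 1L, prob = probs)
  for (e in rev(seq_len(nrow(cache$edges)))) {
    p <- cache$edges[e, 1]; ch <- cache$edges[e, 2]
    pc <- pr$P[[e]][states[p], ] * pr$L[ch, ]
    states[ch] <- sample.int(m, 1L, prob = pc)
  }
  states
}

# Growable cache of powers of the uniformized jump matrix R = I + Q/mu.
.bridge_env <- function(Q) {
  mu <- max(-diag(Q))
  m <- nrow(Q)
  env <- new.env(parent = emptyenv())
  env$Q <- Q; env$mu <- mu; env$m <- m
  env$R <- if (mu > 0) diag(m) + Q / mu else diag(m)
  env$pow <- list(diag(m))    # pow[[n+1]] = R^n
  env
}

.R_power <- function(env, n) {
  while (length(env$pow) < n + 1L)
    env$pow[[length(env$pow) + 1L]] <- env$pow[[length(env$pow)]] %*% env$R
  env$pow[[n + 1L]]
}

.sample_bridge <- function(env, start, end, t, Pab) {
  mu <- env$mu
  if (t == 0 || mu == 0) {
    if (start != end)
      stop("impossible endpoint pair: no probability mass from state ",
           start, " to ", end, " over duration ", t, call. = FALSE)
    return(list(state = start, duration = t))
  }
  if (Pab <= 0)
    stop("impossible endpoint pair (", start, " -> ", end,
         "): transition probability is 0 under this Q (structural zero)",
         call. = FALSE)
  # number of candidate jumps: P(N = n | a, b, t) ~ Pois(mu t)(n) R^n[a, b]
  u <- stats::runif(1) * Pab
  lam <- mu * t
  n <- -1L
  acc <- 0
  while (acc < u && n < 100000L) {
    n <- n + 1L
    acc <- acc + stats::dpois(n, lam) * .R_power(env, n)[start, end]
  }
  if (n <= 0L) return(list(state = start, duration = t))
  # bridge over the candidate jump chain
  chain <- integer(n + 1L)
  chain[1L] <- start; chain[n + 1L] <- end
  if (n > 1L) for (k in 2:n) {
    remaining <- .R_power(env, n + 1L - k)
    pv <- env$R[chain[k - 1L], ] * remaining[, end]
    chain[k] <- sample.int(env$m, 1L, prob = pv)
  }
  times <- sort(stats::runif(n)) * t
  keep <- c(TRUE, chain[-1L] != chain[-(n + 1L)])
  states <- chain[keep]
  bounds <- c(0, times[keep[-1L]], t)
  list(state = states, duration = diff(bounds))
}

#' Endpoint-conditioned CTMC path on a single branch
#'
#' Samples one realization of the CTMC bridge from `start_state` to
#' `end_state` over duration `t` under rate matrix `Q`, by uniformization.
#'
#' @param start_state,end_state expanded-state indices.
#' @param t branch duration (Myr).
#' @param Q rate matrix.
#' @return list with `state` (integer vector of visited states) and
#'   `duration` (matching segment durations summing to `t`).
#' @export
sample_branch_history <- function(start_state, end_state, t, Q) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  env <- .bridge_env(Q)
  Pab <- transition_probabilities(Q, t)[start_state, end_state]
  .sample_bridge(env, start_state, end_state, t, Pab)
}

# One-tree mapping engine: precomputes pruning conditionals, per-edge P and
# the bridge cache, then samples maps cheaply.
.map_engine <- function(tree, data, Q, root_prior) {
  n_class <- nrow(Q) %/% 3L
  cache <- .pruning_cache(tree, data, n_class)
  pr <- .mk_pruning(cache, Q)
  env <- .bridge_env(Q)
  ne <- nrow(cache$edges)
  sample_one <- function() {
    states <- .draw_node_states(cache, pr, root_prior)
    segs <- vector("list", ne)
    for (e in seq_len(ne)) {
      p <- cache$edges[e, 1]; ch <- cache$edges[e, 2]
      segs[[e]] <- .sample_bridge(env, states[p], states[ch], cache$elen[e],
                                  pr$P[[e]][states[p], states[ch]])
    }
    structure(list(tree = tree, edge = cache$edges,
                   edge_length = cache$elen, segments = segs,
                   node_states = states, n_class = n_class),
              class = "stoch_map")
  }
  list(sample_one = sample_one, cache = cache, pr = pr)
}

#' @export
print.stoch_map <- function(x, ...) {
  cm <- count_transitions(x)
  cat("Stochastic map on", ape::Ntip(x$tree), "tips:",
      sum(cm), "observed-state transitions",
      if (x$n_class > 1) paste0("(+", attr(cm, "class_switches"),
                                " hidden-class switches)"), "\n")
  invisible(x)
}

#' Count state transitions on a stochastic map
#'
#' Tallies observed-state changes (3x3, diagonal zero). Under hidden-class
#' models, class switches that leave the observed state unchanged are
#' excluded from the matrix and reported via attribute `"class_switches"`.
#'
#' @param map a `"stoch_map"`.
#' @return 3x3 integer matrix of i -> j event counts.
#' @export
count_transitions <- function(map) {
  counts <- matrix(0L, 3L, 3L, dimnames = list(arb_states(), arb_states()))
  switches <- 0L
  for (seg in map$segments) {
    if (length(seg$state) < 2L) next
    a <- .observed_state(seg$state[-length(seg$state)])
    b <- .observed_state(seg$state[-1L])
    ch <- a != b
    switches <- switches + sum(!ch)
    if (any(ch)) for (i in which(ch))
      counts[a[i], b[i]] <- counts[a[i], b[i]] + 1L
  }
  attr(counts, "class_switches") <- switches
  counts
}

#' Generate stochastic character maps, optionally across a tree set
#'
#' Workhorse for Bayesian stochastic mapping: for each input tree, a Q
#' matrix is either refit by maximum likelihood (`q_source = "refit"`) or
#' taken as supplied (`Q`), and `n_maps` full character histories are then
#' sampled conditional on the tip data. Per-(tree, map) RNG seeds are drawn
#' upfront from `seed`, so results are reproducible and independent of how
#' the work is scheduled. Trees whose fit fails are flagged and skipped.
#'
#' @param trees a `"phylo"`, `"multiPhylo"` or list of trees.
#' @param data character table covering the shared tip set.
#' @param spec model specification (required when refitting).
#' @param n_maps maps per tree.
#' @param root_prior `"equal"`, `"fitzjohn"` or a fixed vector.
#' @param q_source `"refit"` (ML fit per tree) or `"fixed"` (use `Q`).
#' @param Q rate matrix used for every tree when `q_source = "fixed"`.
#' @param config optimizer settings for per-tree refits.
#' @param seed integer master seed.
#' @return object of class `"simmap_set"`: list with `maps` (list per tree
#'   of `"stoch_map"`s), `trees`, `Q` (per-tree rate matrices), `skipped`
#'   (indices of trees whose fit failed), `n_maps`, `seed`.
#' @export
generate_maps <- function(trees, data, spec = NULL, n_maps = 100,
                          root_prior = "equal",
                          q_source = c("refit", "fixed"), Q = NULL,
                          config = optimizer_config(restarts = 3),
                          seed = NULL) {
  q_source <- match.arg(q_source)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (q_source == "refit" && is.null(spec))
    stop("spec is required when q_source = \"refit\"", call. = FALSE)
  if (q_source == "fixed" && is.null(Q))
    stop("Q is required when q_source = \"fixed\"", call. = FALSE)
  if (n_maps < 0) stop("n_maps must be >= 0", call. = FALSE)
  nt <- length(trees)
  if (!is.null(seed)) set.seed(seed)
  fit_seeds <- sample.int(.Machine$integer.max, nt)
  map_seeds <- matrix(sample.int(.Machine$integer.max, nt * max(n_maps, 1L)),
                      nrow = nt)
  maps <- vector("list", nt)
  Qs <- vector("list", nt)
  skipped <- integer(0)
  for (i in seq_len(nt)) {
    Qi <- if (q_source == "fixed") Q else {
      cfg <- config; cfg$seed <- fit_seeds[i]
      f <- tryCatch(fit_ml(trees[[i]], data, spec, root_prior, cfg),
                    error = function(e) NULL)
      if (is.null(f)) NULL else f$Q
    }
    if (is.null(Qi)) { skipped <- c(skipped, i); next }
    Qs[[i]] <- Qi
    engine <- .map_engine(trees[[i]], data, Qi, root_prior)
    maps[[i]] <- vector("list", n_maps)
    for (j in seq_len(n_maps)) {
      set.seed(map_seeds[i, j])
      maps[[i]][[j]] <- engine$sample_one()
    }
  }
  if (length(skipped) == nt && nt > 0)
    stop("per-tree fit failed on every tree", call. = FALSE)
  structure(list(maps = maps, trees = trees, Q = Qs, skipped = skipped,
                 n_maps = n_maps, seed = seed, root_prior = root_prior),
            class = "simmap_set")
}

#' @export
print.simmap_set <- function(x, ...) {
  cat("simmap_set:", length(x$trees), "tree(s) x", x$n_maps, "map(s)",
      if (length(x$skipped)) paste0("(", length(x$skipped), " skipped)"), "\n")
  invisible(x)
}

#' Summarize stochastic maps onto a reference tree
#'
#' Per reference internal node, the frequency of each observed state across
#' all (map, phylogenetically equivalent node) pairs; pairs are restricted
#' to trees containing the clade, and the clade frequency is reported
#' alongside so downstream consumers can filter. Also reports the mean
#' observed-state transition-count matrix over all maps and, when Q was
#' refit per tree, the element-wise mean of the per-tree MLE Q matrices
#' (`q_average = "geometric"` switches to a geometric mean).
#'
#' @param maps a `"simmap_set"`.
#' @param ref_tree reference tree (defaults to the first mapped tree).
#' @param q_average `"arithmetic"` (default) or `"geometric"`.
#' @return object of class `"simmap_summary"`: list with `node_probs`
#'   (matrix, all reference nodes x 3 observed states; tips degenerate),
#'   `clade_freq` (per internal node), `mean_counts` (3x3),
#'   `mean_class_switches`, `mean_Q`, `n_maps_total`, `ref_tree`.
#' @export
summarize_maps <- function(maps, ref_tree = NULL,
                           q_average = c("arithmetic", "geometric")) {
  stopifnot(inherits(maps, "simmap_set"))
  q_average <- match.arg(q_average)
  live <- setdiff(seq_along(maps$trees), maps$skipped)
  if (length(live) == 0 || maps$n_maps == 0 ||
      sum(lengths(maps$maps[live])) == 0)
    stop("empty map list", call. = FALSE)
  if (is.null(ref_tree)) ref_tree <- maps$trees[[live[1]]]
  nm <- match_nodes(ref_tree, maps$trees[live])

  ntip <- ape::Ntip(ref_tree)
  ntot <- ntip + ref_tree$Nnode
  probs <- matrix(0, ntot, 3L, dimnames = list(seq_len(ntot), arb_states()))
  denom <- numeric(ntot)
  counts <- matrix(0, 3L, 3L, dimnames = list(arb_states(), arb_states()))
  switches <- 0
  total_maps <- 0L
  for (jj in seq_along(live)) {
    i <- live[jj]
    for (mp in maps$maps[[i]]) {
      total_maps <- total_maps + 1L
      obs <- .observed_state(mp$node_states)
      # internal nodes via clade matching
      matched <- nm$matches[, jj]
      ok <- !is.na(matched)
      rows <- nm$ref_nodes[ok]
      idx <- cbind(rows, obs[matched[ok]])
      probs[idx] <- probs[idx] + 1
      denom[rows] <- denom[rows] + 1
      cm <- count_transitions(mp)
      counts <- counts + cm
      switches <- switches + attr(cm, "class_switches")
    }
  }
  # tips: degenerate on the observed data state
  tipst <- as_tip_states(ref_tree, .first_map_data(maps, ref_tree))
  probs[cbind(seq_len(ntip), tipst)] <- 1
  denom[seq_len(ntip)] <- 1
  denom[denom == 0] <- NA
  probs <- probs / denom

  mean_Q <- NULL
  qs <- Filter(Negate(is.null), maps$Q)
  if (length(qs)) {
    if (q_average == "arithmetic") {
      mean_Q <- Reduce(`+`, qs) / length(qs)
    } else {
      lg <- lapply(qs, function(q) { q2 <- q; q2[q2 <= 0] <- NA; log(q2) })
      mean_Q <- exp(Reduce(function(a, b) a + b, lg) / length(qs))
      mean_Q[is.na(mean_Q)] <- 0
      diag(mean_Q) <- 0
      diag(mean_Q) <- -rowSums(mean_Q)
    }
  }
  structure(list(node_probs = probs,
                 clade_freq = stats::setNames(nm$clade_freq, nm$ref_nodes),
                 mean_counts = counts / total_maps,
                 mean_class_switches = switches / total_maps,
                 mean_Q = mean_Q, n_maps_total = total_maps,
                 ref_tree = ref_tree),
            class = "simmap_summary")
}

# Tip data implied by the maps themselves (tip-end states of the first map
# on a tree with the reference tip set).
.first_map_data <- function(maps, ref_tree) {
  live <- setdiff(seq_along(maps$trees), maps$skipped)
  mp <- maps$maps[[live[1]]][[1]]
  tr <- maps$trees[[live[1]]]
  obs <- .observed_state(mp$node_states[seq_len(ape::Ntip(tr))])
  stats::setNames(arb_states()[obs], tr$tip.label)
}

#' @export
print.simmap_summary <- function(x, ...) {
  cat("simmap_summary over", x$n_maps_total, "maps;",
      "mean transitions per map:\n")
  print(round(x$mean_counts, 3))
  invisible(x)
}
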