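# ---- Synthetic data: trees, characters with known histories, posteriors ----

#' Simulate a taxon-conditioned, time-scaled birth-death tree
#'
#' Wraps [phytools::pbtree()] with a retry loop (extinction can leave fewer
#' survivors than requested) and rescales the result to the requested root
#' age, yielding an ultrametric chronogram with exactly `n_tips` extant tips.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param root_age tree height in Myr.
#' @param birth,death per-lineage rates (shape only; the tree is rescaled).
#' @param retries retry budget for the conditioned simulation.
#' @return an ultrametric `"phylo"` tree.
#' @export
simulate_birth_death_tree <- function(n_tips, root_age, birth = 0.2,
                                      death = 0.05, retries = 10000) {
  stopifnot(n_tips >= 2, root_age > 0, birth > 0, death >= 0)
  for (i in seq_len(retries)) {
    tr <- tryCatch(
      suppressWarnings(phytools::pbtree(b = birth, d = death, n = n_tips,
                                        extant.only = TRUE, quiet = TRUE)),
      error = function(e) NULL)
    if (!is.null(tr) && ape::Ntip(tr) == n_tips) {
      h <- max(ape::node.depth.edgelength(tr))
      tr$edge.length <- tr$edge.length * root_age / h
      return(tr)
    }
  }
  stop("retry budget exhausted simulating a ", n_tips, "-tip tree",
       call. = FALSE)
}

#' Simulate a chronogram with a post-boundary radiation profile
#'
#' Emulates the diversification structure of the mammalian timetree: a set
#' of "ordinal" stem lineages that diverge before the K-Pg boundary, each
#' crossing it and then radiating shortly afterwards (crown ages drawn just
#' below the boundary). The resulting tree is ultrametric with the requested
#' root age and concentrates many short internal edges in the first ~10 Myr
#' after the boundary, as the empirical mammal trees do.
#'
#' @param n_tips total number of extant tips.
#' @param root_age tree height (Myr), must exceed `boundary`.
#' @param boundary the age below which the radiations start (Myr).
#' @param n_backbone number of boundary-crossing stem lineages.
#' @param crown_offset crown ages are drawn uniformly in
#'   `boundary - crown_offset` ... `boundary - 2` Myr.
#' @param stub_offset how long before the boundary the backbone stops
#'   diverging (Myr); radiating stems depart from `boundary + stub_offset`.
#' @return an ultrametric `"phylo"` tree with `n_tips` tips.
#' @export
simulate_kpg_radiation_tree <- function(n_tips, root_age, boundary = 66.02,
                                        n_backbone = 30,
                                        crown_offset = 8, stub_offset = 1) {
  stopifnot(root_age > boundary + 4, n_backbone >= 2,
            n_tips >= n_backbone)
  stub_age <- boundary + stub_offset
  backbone <- simulate_birth_death_tree(n_backbone, root_age - stub_age,
                                        birth = 0.2, death = 0)
  backbone$tip.label <- paste0("bb", seq_len(n_backbone))
  # subtree sizes: at least 1 tip each, remainder spread at random
  extra <- n_tips - n_backbone
  sizes <- rep(1L, n_backbone) +
    tabulate(sample.int(n_backbone, extra, replace = TRUE), n_backbone)
  crowns <- stats::runif(n_backbone, boundary - crown_offset, boundary - 2)
  out <- backbone
  for (i in seq_len(n_backbone)) {
    lab <- paste0("bb", i)
    at <- which(out$tip.label == lab)
    if (sizes[i] == 1L) {
      # lone boundary-crossing lineage: extend its pendant edge to the present
      e <- which(out$edge[, 2] == at)
      out$edge.length[e] <- out$edge.length[e] + stub_age
      out$tip.label[at] <- paste0("t", i, "_1")
    } else {
      st <- simulate_birth_death_tree(sizes[i], crowns[i], birth = 0.3,
                                      death = 0)
      st$tip.label <- paste0("t", i, "_", seq_len(sizes[i]))
      st$root.edge <- stub_age - crowns[i]
      out <- ape::bind.tree(out, st, where = at, position = 0)
    }
  }
  validate_tree(out)
}

#' Forward simulation of a character history on a tree
#'
#' Exact Gillespie simulation of the CTMC down the tree, recording the full
#' history as a stochastic map. An optional epoch schedule switches the rate
#' parameters at fixed ages (mid-edge if needed), which deliberately creates
#' a time-heterogeneous truth that the time-homogeneous inference models do
#' not match.
#'
#' @param tree `"phylo"` tree with branch lengths in Myr.
#' @param spec an `"mk_model_spec"` for the generating model.
#' @param params rate vector (used for the whole tree when no schedule).
#' @param root_state canonical state label, expanded-state index, or `NULL`
#'   to draw uniformly over observed states (class 1 for hidden-class specs).
#' @param schedule optional list with `boundaries` (interior epoch ages,
#'   decreasing, Myr) and `params` (list of rate vectors, one per epoch,
#'   oldest first; length = `length(boundaries) + 1`).
#' @return object of class `"simulation_truth"`: list with `tree`,
#'   `characters` (taxon/state data.frame), `map` (`"stoch_map"` of the true
#'   history), `counts` (true 3x3 transition counts) and `events`
#'   (data.frame of true event ages and types).
#' @export
simulate_character_history <- function(tree, spec, params, root_state = NULL,
                                       schedule = NULL) {
  validate_tree(tree)
  stopifnot(inherits(spec, "mk_model_spec"))
  if (is.null(schedule)) {
    Qs <- list(assemble_q(spec, params))
    bounds <- numeric(0)
  } else {
    stopifnot(length(schedule$params) == length(schedule$boundaries) + 1)
    Qs <- lapply(schedule$params, function(p) assemble_q(spec, p))
    bounds <- as.numeric(schedule$boundaries)
    if (is.unsorted(rev(bounds)))
      stop("schedule boundaries must be decreasing ages", call. = FALSE)
  }
  ages <- node_ages(tree)
  epoch_of <- function(age) {
    # epoch 1 is the oldest; boundaries are ages where the next epoch starts
    1L + sum(age < bounds + 1e-12 * max(ages))
  }
  m <- spec$n_expanded
  root <- ape::Ntip(tree) + 1L
  states <- integer(ape::Ntip(tree) + tree$Nnode)
  if (is.null(root_state)) {
    states[root] <- sample.int(3L, 1L)
  } else if (is.character(root_state)) {
    states[root] <- state_index(root_state)
  } else {
    states[root] <- as.integer(root_state)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE] # preorder
  elen <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  segs <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    age <- ages[p]; target <- ages[p] - elen[e]
    st <- states[p]
    seg_states <- st
    seg_bounds <- age
    while (TRUE) {
      ep <- epoch_of(age)
      rate <- -Qs[[ep]][st, st]
      # age of the next epoch switch below the current age, if any
      nxt <- c(bounds[bounds < age - 1e-12], -Inf)[1]
      wait <- if (rate > 0) stats::rexp(1, rate) else Inf
      cand <- age - wait
      if (cand > max(target, nxt)) {
        # a real jump inside this epoch segment
        q <- Qs[[ep]][st, ]; q[st] <- 0
        st <- sample.int(m, 1L, prob = q)
        age <- cand
        seg_states <- c(seg_states, st)
        seg_bounds <- c(seg_bounds, age)
      } else if (nxt > target) {
        age <- nxt      # cross the epoch boundary, resample (memoryless)
      } else {
        break
      }
    }
    states[ch] <- st
    segs[[e]] <- list(state = seg_states,
                      duration = diff(-c(seg_bounds, target)))
  }
  map <- structure(list(tree = tree, edge = edges, edge_length = elen,
                        segments = segs, node_states = states,
                        n_class = spec$n_class),
                   class = "stoch_map")
  tipobs <- arb_states()[.observed_state(states[seq_len(ape::Ntip(tree))])]
  chars <- data.frame(taxon = tree$tip.label, state = tipobs,
                      stringsAsFactors = FALSE)
  counts <- count_transitions(map)
  structure(list(tree = tree, characters = chars, map = map,
                 counts = counts, events = .map_events(map)),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth:", ape::Ntip(x$tree), "tips,",
      sum(x$counts), "true transitions; tip mix:",
      paste(names(table(x$characters$state)),
            as.integer(table(x$characters$state)), collapse = ", "), "\n")
  invisible(x)
}

# Parent vector + children lists for a phylo tree.
.tree_family <- function(tree) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  par <- integer(ntot)
  for (e in seq_len(nrow(tree$edge))) par[tree$edge[e, 2]] <- tree$edge[e, 1]
  list(par = par, ntip = ape::Ntip(tree), root = ape::Ntip(tree) + 1L)
}

# Rebuild a phylo tree from children lists + node ages via a Newick string.
.family_to_tree <- function(children, ages, labels, root) {
  rec <- function(v) {
    kids <- children[[v]]
    if (!length(kids))
      return(labels[v])
    paste0("(", paste(vapply(kids, function(k)
      paste0(rec(k), ":", format(ages[v] - ages[k], digits = 15)),
      character(1)), collapse = ","), ")")
  }
  parse_tree(paste0(rec(root), ";"))
}

#' Pseudo-posterior tree set by age jitter and rooted NNI moves
#'
#' Emulates a Bayesian posterior tree sample around a reference chronogram:
#' internal-node ages are jittered multiplicatively (each node's age, as a
#' fraction of its parent's age, is scaled by a log-normal factor and kept
#' inside the valid interval), preserving ultrametricity, the root age and
#' the tip set; `n_nni` random rooted nearest-neighbor interchanges per tree
#' then perturb the topology.
#'
#' @param ref ultrametric reference `"phylo"` tree.
#' @param n number of trees.
#' @param branch_jitter_sd log-scale SD of the age jitter (0 = none).
#' @param n_nni NNI moves per tree (0 = none).
#' @param seed optional integer seed.
#' @return a `"multiPhylo"` list of `n` trees.
#' @export
perturb_tree_set <- function(ref, n, branch_jitter_sd = 0.05, n_nni = 0,
                             seed = NULL) {
  stopifnot(branch_jitter_sd >= 0, n_nni >= 0)
  if (!is.null(seed)) set.seed(seed)
  ages0 <- unname(node_ages(ref))
  fam <- .tree_family(ref)
  ntip <- fam$ntip; root <- fam$root
  ntot <- length(ages0)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    par <- fam$par
    ages <- ages0
    if (branch_jitter_sd > 0) {
      # preorder by decreasing original age so parents are updated first
      ord <- setdiff(order(ages0, decreasing = TRUE), c(root, seq_len(ntip)))
      for (v in ord) {
        f <- ages0[v] / ages0[par[v]]
        f <- min(max(f * exp(stats::rnorm(1, 0, branch_jitter_sd)), 1e-3),
                 1 - 1e-3)
        ages[v] <- f * ages[par[v]]
      }
      ages[seq_len(ntip)] <- 0
      ages[root] <- ages0[root]
      # enforce parent-older-than-child after jitter
      for (v in ord) ages[v] <- min(ages[v], ages[par[v]] * (1 - 1e-6))
    }
    children <- split(seq_len(ntot)[-root], par[-root])
    chl <- vector("list", ntot)
    chl[as.integer(names(children))] <- children
    for (k in seq_len(n_nni)) {
      # internal, non-root nodes with an internal parent
      cand <- which(seq_len(ntot) > ntip & par > 0 & par != 0)
      cand <- setdiff(cand, c(root, seq_len(ntip)))
      cand <- cand[vapply(cand, function(v) length(chl[[par[v]]]) >= 2,
                          logical(1))]
      if (!length(cand)) break
      v <- if (length(cand) == 1L) cand else sample(cand, 1L)
      p <- par[v]
      sibs <- setdiff(chl[[p]], v)
      y <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
      x <- chl[[v]][[if (length(chl[[v]]) == 1L) 1L else
        sample(length(chl[[v]]), 1L)]]
      # swap: x moves up to p, y moves down under v
      chl[[v]] <- c(setdiff(chl[[v]], x), y)
      chl[[p]] <- c(setdiff(chl[[p]], c(y)), x)
      par[x] <- p; par[y] <- v
      # keep v strictly older than its new children, younger than p
      lo <- max(ages[chl[[v]]])
      if (ages[v] <= lo) ages[v] <- lo + stats::runif(1) * (ages[p] - lo)
    }
    out[[i]] <- .family_to_tree(chl, ages, c(ref$tip.label, rep("", ntot - ntip)),
                                root)
  }
  class(out) <- "multiPhylo"
  out
}

#' Self-contained study-scale fixture
#'
#' Generates, deterministically from a seed, a complete synthetic study
#' bundle emulating the scale and structure of the real analysis: a
#' radiation-structured chronogram (default 164 tips, root age 90 Myr, with
#' stem lineages crossing the 66.02 Ma boundary and radiating just after
#' it), a three-state character evolved under the ordered four-rate model
#' in three ecological epochs, and a pseudo-posterior set of perturbed
#' trees. The epochs encode the study scenario: semi-arboreality is
#' essentially absent early (nonarboreal root, negligible N->S rate), a
#' nonarboreal -> semi-arboreal inflow opens in the Late Cretaceous (from
#' `inflow_start`), and the semi-arboreal -> nonarboreal rate jumps after
#' the boundary (the K-Pg crash), with a milder N->S inflow continuing to
#' the present. The full true history is retained.
#'
#' @param seed integer seed (the bundle is a deterministic function of it).
#' @param n_tips,root_age tree scale.
#' @param n_posterior number of pseudo-posterior trees (0 to skip).
#' @param boundary age of the S->N rate shift (Myr).
#' @param inflow_start age at which the N->S inflow epoch begins (Myr).
#' @param params_base four-rate generator rates in index order
#'   (A->S, S->A, S->N, N->S), 1/Myr, used in the earliest epoch.
#' @param inflow_ns N->S rate during the inflow epoch.
#' @param post_sn,post_ns S->N and N->S rates after the boundary.
#' @param jitter_sd,n_nni posterior-set perturbation scale.
#' @return list with `tree`, `posterior` (`"multiPhylo"` or NULL),
#'   `characters`, `truth` (`"simulation_truth"`) and `manifest`.
#' @export
make_study_fixture <- function(seed, n_tips = 164, root_age = 90,
                               n_posterior = 1000, boundary = 66.02,
                               inflow_start = 82,
                               params_base = c(0.004, 0.01, 0.003, 0.002),
                               inflow_ns = 0.02, post_sn = 0.03,
                               post_ns = 0.008,
                               jitter_sd = 0.05, n_nni = 2) {
  set.seed(seed)
  tree <- simulate_kpg_radiation_tree(n_tips, root_age, boundary)
  spec <- build_model_spec("four_rate")
  e1 <- params_base
  e2 <- params_base; e2[4] <- inflow_ns
  e3 <- params_base; e3[3] <- post_sn; e3[4] <- post_ns
  truth <- simulate_character_history(
    tree, spec, e1, root_state = "nonarboreal",
    schedule = list(boundaries = c(inflow_start, boundary),
                    params = list(e1, e2, e3)))
  posterior <- if (n_posterior > 0)
    perturb_tree_set(tree, n_posterior, jitter_sd, n_nni) else NULL
  list(tree = tree, posterior = posterior, characters = truth$characters,
       truth = truth,
       manifest = list(seed = seed, n_tips = n_tips, root_age = root_age,
                       n_posterior = n_posterior, boundary = boundary,
                       inflow_start = inflow_start, model = "four_rate",
                       params_epochs = list(e1, e2, e3),
                       jitter_sd = jitter_sd, n_nni = n_nni))
}

#' Write a fixture bundle to a directory
#'
#' Writes `tree.nwk`, `posterior.nwk` (multi-tree Newick), `characters.tsv`,
#' `truth_segments.tsv` (one row per true history segment) and
#' `manifest.json`.
#'
#' @param bundle output of [make_study_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(write_newick(bundle$tree), file.path(dir, "tree.nwk"))
  if (!is.null(bundle$posterior))
    ape::write.tree(bundle$posterior, file.path(dir, "posterior.nwk"))
  utils::write.table(bundle$characters, file.path(dir, "characters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  mp <- bundle$truth$map
  rows <- list()
  for (e in seq_len(nrow(mp$edge))) {
    seg <- mp$segments[[e]]
    rows[[e]] <- data.frame(parent = mp$edge[e, 1], child = mp$edge[e, 2],
                            segment = seq_along(seg$state),
                            state = arb_states()[.observed_state(seg$state)],
                            duration = seg$duration)
  }
  utils::write.table(do.call(rbind, rows),
                     file.path(dir, "truth_segments.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
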