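# Independent oracles used across the suite. These deliberately avoid the
# package's pruning/mapping code paths: enumeration over internal-state
# assignments, closed forms for the symmetric 3-state chain, and exact
# recursions, so the implementation can be checked against them.

# Brute-force Mk likelihood: sum over all assignments of expanded states to
# internal nodes of prod(root prior x edge transition probabilities x tip
# conditionals). Vectorized over assignments; feasible for <= 6 tips.
enum_loglik <- function(tree, data, spec, params, root_prior = "equal") {
  Q <- assemble_q(spec, params)
  m <- nrow(Q)
  ntip <- ape::Ntip(tree)
  internal <- ntip + seq_len(tree$Nnode)
  tipst <- arbormk:::as_tip_states(tree, data)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_probabilities(Q, tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), length(internal))))
  colnames(grid) <- internal
  root_col <- match(ntip + 1L, internal)
  w <- if (identical(root_prior, "equal")) rep(1 / m, m) else root_prior
  lik <- w[grid[, root_col]]
  n_class <- m %/% 3L
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    ps <- grid[, match(p, internal)]
    if (ch <= ntip) {
      # tip: sum transition probability over the hidden classes of the
      # observed state
      cols <- (seq_len(n_class) - 1L) * 3L + tipst[ch]
      contrib <- rowSums(P[[e]][ps, cols, drop = FALSE])
    } else {
      contrib <- P[[e]][cbind(ps, grid[, match(ch, internal)])]
    }
    lik <- lik * contrib
  }
  log(sum(lik))
}

# Brute-force marginal node probabilities by the same enumeration, collapsed
# to observed states.
enum_marginals <- function(tree, data, spec, params, root_prior = "equal") {
  Q <- assemble_q(spec, params)
  m <- nrow(Q)
  ntip <- ape::Ntip(tree)
  internal <- ntip + seq_len(tree$Nnode)
  tipst <- arbormk:::as_tip_states(tree, data)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_probabilities(Q, tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), length(internal))))
  root_col <- match(ntip + 1L, internal)
  w <- if (identical(root_prior, "equal")) rep(1 / m, m) else root_prior
  lik <- w[grid[, root_col]]
  n_class <- m %/% 3L
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    ps <- grid[, match(p, internal)]
    if (ch <= ntip) {
      cols <- (seq_len(n_class) - 1L) * 3L + tipst[ch]
      lik <- lik * rowSums(P[[e]][ps, cols, drop = FALSE])
    } else {
      lik <- lik * P[[e]][cbind(ps, grid[, match(ch, internal)])]
    }
  }
  out <- matrix(0, length(internal), 3L)
  obs <- ((grid - 1L) %% 3L) + 1L
  for (i in seq_along(internal)) for (s in 1:3)
    out[i, s] <- sum(lik[obs[, i] == s])
  out / rowSums(out)
}

# Closed-form transition probabilities for the symmetric 3-state chain with
# every off-diagonal rate q.
closed_form_equal_rates <- function(q, t) {
  pii <- 1 / 3 + (2 / 3) * exp(-3 * q * t)
  pij <- (1 / 3) * (1 - exp(-3 * q * t))
  matrix(c(pii, pij, pij,
           pij, pii, pij,
           pij, pij, pii), 3, 3, byrow = TRUE)
}

# Exhaustive-minimum parsimony score over all internal-state assignments.
enum_parsimony <- function(tree, data, cost) {
  ntip <- ape::Ntip(tree)
  internal <- ntip + seq_len(tree$Nnode)
  tipst <- arbormk:::as_tip_states(tree, data)
  grid <- as.matrix(expand.grid(rep(list(1:3), length(internal))))
  tot <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    ps <- grid[, match(p, internal)]
    cs <- if (ch <= ntip) rep(tipst[ch], nrow(grid)) else
      grid[, match(ch, internal)]
    tot <- tot + cost[cbind(ps, cs)]
  }
  list(score = min(tot),
       root_set = sort(unique(grid[tot <= min(tot) + 1e-9,
                                   match(ntip + 1L, internal)])))
}

# Exact expected Colless imbalance of a Yule tree with n tips, by the
# uniform-split recursion E[I_n] = mean_k(|n - 2k| + E[I_k] + E[I_{n-k}]).
yule_expected_colless <- function(n) {
  E <- numeric(n)
  for (nn in 3:n) {
    ks <- 1:(nn - 1)
    E[nn] <- mean(abs(nn - 2 * ks) + E[ks] + E[nn - ks])
  }
  E[n]
}

colless_index <- function(tree) {
  keys <- clade_keys(tree)
  sizes <- lengths(strsplit(keys, "|", fixed = TRUE))
  ntip <- ape::Ntip(tree)
  tot <- 0
  for (v in ntip + seq_len(tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    if (length(kids) == 2) tot <- tot + abs(sizes[kids[1]] - sizes[kids[2]])
  }
  tot
}

# Random character table over the three states for a tree's tips.
random_characters <- function(tree) {
  data.frame(taxon = tree$tip.label,
             state = sample(arb_states(), ape::Ntip(tree), replace = TRUE),
             stringsAsFactors = FALSE)
}

# Random rate vector for a spec, bounded away from 0 for identifiability.
random_params <- function(spec) stats::runif(spec$k, 0.02, 0.5)

# A fixed 20-tip mapping fixture shared by the consistency checks.
mapping_fixture <- function(seed = 404) {
  set.seed(seed)
  tree <- simulate_birth_death_tree(20, 60, birth = 0.15, death = 0.02)
  spec <- build_model_spec("ard")
  params <- c(0.03, 0.01, 0.02, 0.04, 0.01, 0.03)
  truth <- simulate_character_history(tree, spec, params,
                                      root_state = "semi-arboreal")
  list(tree = tree, data = truth$characters, spec = spec, params = params,
       Q = assemble_q(spec, params))
}
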