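#' Marginal ancestral state reconstruction under an Mk model
#'
#' Computes, for every node, the marginal probability of each observed state
#' given all tip data, by the standard inside-outside computation: downward
#' conditionals from Felsenstein pruning combined with an upward pass that
#' carries the likelihood of the rest of the tree. Hidden rate classes are
#' marginalized into the three observed states (per-class probabilities are
#' available via `per_class = TRUE`).
#'
#' @inheritParams pruning_loglik
#' @param per_class if `TRUE`, return probabilities over the expanded
#'   (state, class) space instead of observed states.
#' @return matrix of probabilities, one row per node (ape node ids; tips
#'   first), rows summing to 1. Tip rows are unit vectors on the observed
#'   state. Attribute `"logLik"` carries the tree log-likelihood.
#' @export
marginal_asr <- function(tree, data, spec, params, root_prior = "equal",
                         per_class = FALSE) {
  cache <- .pruning_cache(tree, data, spec$n_class)
  pr <- .mk_pruning(cache, assemble_q(spec, params))
  m <- pr$m
  root <- cache$root
  w <- .root_weights(root_prior, pr$L[root, ], m)

  ne <- nrow(cache$edges)
  # downward contribution of each (postorder) edge to its parent's partial
  D <- vector("list", ne)
  for (e in seq_len(ne))
    D[[e]] <- as.vector(pr$P[[e]] %*% pr$L[cache$edges[e, 2], ])

  # exclude-one-child products per parent, via grouped prefix/suffix products
  H <- matrix(0, cache$ntot, m)
  H[root, ] <- w
  edges_by_parent <- split(seq_len(ne), cache$edges[, 1])
  # preorder: reverse postorder guarantees H[parent] is ready before children
  for (e in rev(seq_len(ne))) {
    p <- cache$edges[e, 1]; ch <- cache$edges[e, 2]
    sibs <- edges_by_parent[[as.character(p)]]
    excl <- rep(1, m)
    for (e2 in sibs) if (e2 != e) excl <- excl * D[[e2]]
    up <- as.vector(crossprod(pr$P[[e]], H[p, ] * excl))
    s <- sum(up)
    H[ch, ] <- if (s > 0) up / s else up
  }

  marg <- pr$L * H
  rs <- rowSums(marg)
  rs[rs == 0] <- 1
  marg <- marg / rs
  if (!per_class && spec$n_class > 1L) {
    obs <- matrix(0, cache$ntot, 3L)
    for (cl in seq_len(spec$n_class))
      obs <- obs + marg[, (cl - 1L) * 3L + 1:3, drop = FALSE]
    marg <- obs
  }
  colnames(marg) <- if (per_class && spec$n_class > 1L) spec$states else arb_states()
  rownames(marg) <- seq_len(cache$ntot)
  attr(marg, "logLik") <- log(sum(w * pr$L[root, ])) + pr$logsc[root]
  marg
}

# Cost matrices for parsimony: unordered (Fitch) or ordered along the
# arboreal - semi-arboreal - nonarboreal axis.
parsimony_cost <- function(kind = c("unordered", "ordered")) {
  kind <- match.arg(kind)
  s <- arb_states()
  if (kind == "unordered") {
    cm <- 1 - diag(3)
  } else {
    cm <- abs(outer(1:3, 1:3, "-"))
  }
  dimnames(cm) <- list(s, s)
  cm
}

#' Maximum-parsimony ancestral reconstruction (Sankoff MPR)
#'
#' Two-pass Sankoff dynamic program returning, for every node, the set of
#' states attained by at least one globally most-parsimonious assignment,
#' plus the parsimony length (minimum total cost). Ties are retained as
#' sets, never broken. The default cost is unordered (any change costs 1);
#' `cost = "ordered"` charges 2 for a direct arboreal <-> nonarboreal change,
#' mirroring the ordered four-rate likelihood structure.
#'
#' @param tree rooted `"phylo"` tree (multifurcations allowed).
#' @param data character table or named state vector covering every tip.
#' @param cost `"unordered"` (default), `"ordered"`, or a 3x3 numeric cost
#'   matrix in the canonical state order.
#' @return object of class `"mpr_recon"`: list with `sets` (logical matrix,
#'   nodes x states; `TRUE` = state is in the MPR set), `score` (parsimony
#'   length) and `cost` (the cost matrix used).
#' @export
parsimony_asr <- function(tree, data, cost = "unordered") {
  validate_tree(tree)
  if (is.character(cost)) cost <- parsimony_cost(cost)
  stopifnot(is.matrix(cost), all(dim(cost) == 3L))
  tipstates <- as_tip_states(tree, data)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  ne <- nrow(edges)

  BIG <- 1e12
  g <- matrix(0, ntot, 3)
  g[seq_len(ntip), ] <- BIG
  g[cbind(seq_len(ntip), tipstates)] <- 0
  # g[v, s]: minimal cost of the subtree below v given state s at v
  for (e in seq_len(ne)) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    add <- apply(cost + rep(g[ch, ], each = 3), 1, min)
    g[p, ] <- g[p, ] + add
  }
  root <- ntip + 1L
  score <- min(g[root, ])

  # h[v, s]: minimal cost of everything outside the subtree of v, given s at v
  h <- matrix(0, ntot, 3)
  for (e in rev(seq_len(ne))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    contrib <- apply(cost + rep(g[ch, ], each = 3), 1, min) # child's term in g[p,]
    rest <- h[p, ] + g[p, ] - contrib
    h[ch, ] <- apply(cost + rep(rest, times = 3), 2, min)
  }

  total <- g + h
  sets <- total <= apply(total, 1, min) + 1e-9
  dimnames(sets) <- list(seq_len(ntot), arb_states())
  structure(list(sets = sets, score = score, cost = cost),
            class = "mpr_recon")
}

#' @export
print.mpr_recon <- function(x, ...) {
  cat("Sankoff MPR: parsimony length", x$score, "over",
      nrow(x$sets), "nodes\n")
  invisible(x)
}
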