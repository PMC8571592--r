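# Dense matrix exponential for small CTMC generators (expanded space <= 9
# states). Primary path: eigendecomposition, reused across all edge lengths
# of a tree; fallback for ill-conditioned or defective generators:
# scaling-and-squaring with a machine-precision Taylor series.

.expm_eig <- function(Q) {
  e <- tryCatch(eigen(Q), error = function(err) NULL)
  if (is.null(e)) return(list(ok = FALSE, Q = Q))
  V <- e$vectors
  Vinv <- tryCatch(solve(V), error = function(err) NULL)
  if (is.null(Vinv)) return(list(ok = FALSE, Q = Q))
  cond <- norm(as.matrix(Mod(V)), "1") * norm(as.matrix(Mod(Vinv)), "1")
  list(ok = is.finite(cond) && cond < 1e10,
       V = V, Vinv = Vinv, lambda = e$values, Q = Q)
}

.expm_taylor <- function(A) {
  # ||A/2^s|| < 0.25, then Taylor to machine precision and repeated squaring
  nrm <- norm(A, "1")
  s <- max(0L, ceiling(log2(max(nrm, 1e-300) / 0.25)))
  As <- A / 2^s
  m <- nrow(A)
  P <- diag(m)
  term <- diag(m)
  for (i in 1:30) {
    term <- term %*% As / i
    P <- P + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

.pmat <- function(eig, t) {
  if (t == 0) return(diag(nrow(eig$Q)))
  if (eig$ok) {
    P <- Re(eig$V %*% (exp(eig$lambda * t) * eig$Vinv))
  } else {
    P <- .expm_taylor(eig$Q * t)
  }
  if (min(P) < -1e-8) P <- .expm_taylor(eig$Q * t)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' CTMC transition probabilities over a time interval
#'
#' Computes `expm(Q t)` for a rate matrix over the (possibly expanded) state
#' space. Rows sum to 1; `t = 0` returns the identity.
#'
#' @param Q square rate matrix (rows sum to 0, off-diagonals >= 0).
#' @param t duration in Myr, `t >= 0`.
#' @return stochastic matrix of the same dimension as `Q`.
#' @examples
#' Q <- assemble_q(build_model_spec("two_rate"), c(0.1, 0.1))
#' transition_probabilities(Q, 1)
#' @export
transition_probabilities <- function(Q, t) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("t must be a single finite duration >= 0", call. = FALSE)
  P <- .pmat(.expm_eig(Q), t)
  dimnames(P) <- dimnames(Q)
  P
}

#' FitzJohn root-state weights
#'
#' Root-state prior proportional to the root conditional likelihoods: each
#' state is weighted by its ability to explain the observed tip data.
#'
#' @param root_conditionals non-negative vector, not all zero.
#' @return probability vector of the same length.
#' @export
fitzjohn_root_weights <- function(root_conditionals) {
  if (any(root_conditionals < 0) || all(root_conditionals == 0))
    stop("root conditionals must be non-negative and not all zero",
         call. = FALSE)
  root_conditionals / sum(root_conditionals)
}

# Map a character table (data.frame taxon/state or named vector) onto the
# tree's tips; returns integer observed-state index (1..3) in tip order.
as_tip_states <- function(tree, data) {
  if (is.data.frame(data)) {
    states <- stats::setNames(data$state, data$taxon)
  } else {
    states <- data
  }
  idx <- match(tree$tip.label, names(states))
  if (anyNA(idx))
    stop("missing character state for tip(s): ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  state_index(states[idx])
}

# Tip conditional likelihoods over the expanded space: a tip observed in
# state X has likelihood 1 for (X, class j) for every hidden class j.
.tip_conditionals <- function(tipstates, n_class) {
  m <- 3L * n_class
  out <- matrix(0, length(tipstates), m)
  for (cl in seq_len(n_class))
    out[cbind(seq_along(tipstates), (cl - 1L) * 3L + tipstates)] <- 1
  out
}

# Reusable pruning cache: postorder edge list and tip conditionals.
.pruning_cache <- function(tree, data, n_class = 1L) {
  validate_tree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  tipstates <- as_tip_states(tree, data)
  list(tree = tree, edges = po$edge, elen = po$edge.length,
       ntip = ape::Ntip(tree), ntot = ape::Ntip(tree) + tree$Nnode,
       root = ape::Ntip(tree) + 1L,
       n_children = tabulate(po$edge[, 1], ape::Ntip(tree) + tree$Nnode),
       tipstates = tipstates, n_class = as.integer(n_class),
       tipcond = .tip_conditionals(tipstates, n_class))
}

# Felsenstein pruning with per-node rescaling. Returns scaled downward
# conditionals L (ntot x m), per-node accumulated log scale factors, and the
# per-edge transition matrices (postorder edge order).
.mk_pruning <- function(cache, Q) {
  eig <- .expm_eig(Q)
  m <- nrow(Q)
  ne <- nrow(cache$edges)
  P <- vector("list", ne)
  for (e in seq_len(ne)) P[[e]] <- .pmat(eig, cache$elen[e])

  L <- matrix(1, cache$ntot, m)
  L[seq_len(cache$ntip), ] <- cache$tipcond
  logsc <- numeric(cache$ntot)
  done <- integer(cache$ntot)
  for (e in seq_len(ne)) {
    p <- cache$edges[e, 1]; ch <- cache$edges[e, 2]
    L[p, ] <- L[p, ] * (P[[e]] %*% L[ch, ])
    logsc[p] <- logsc[p] + logsc[ch]
    done[p] <- done[p] + 1L
    if (done[p] == cache$n_children[p]) {
      s <- sum(L[p, ])
      if (s <= 0 || !is.finite(s))
        stop("likelihood identically zero at the clade below node ", p,
             " (tips: ",
             paste(utils::head(ape::extract.clade(cache$tree, p)$tip.label, 5),
                   collapse = ", "), " ...)", call. = FALSE)
      L[p, ] <- L[p, ] / s
      logsc[p] <- logsc[p] + log(s)
    }
  }
  list(L = L, logsc = logsc, P = P, Q = Q, eig = eig, m = m)
}

.root_weights <- function(root_prior, root_cond, m) {
  if (is.numeric(root_prior)) {
    if (length(root_prior) != m || any(root_prior < 0) ||
        abs(sum(root_prior) - 1) > 1e-8)
      stop("fixed root prior must be a probability vector of length ", m,
           call. = FALSE)
    return(root_prior)
  }
  switch(match.arg(root_prior, c("equal", "fitzjohn")),
         equal = rep(1 / m, m),
         fitzjohn = fitzjohn_root_weights(root_cond))
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of the tip character data given a tree, a
#' model specification and its rate parameters, marginalizing any hidden
#' rate classes. Tips observed in state X are ambiguous over the hidden
#' classes of X. The root is collapsed with either equal weights over the
#' expanded states or FitzJohn (conditionals-proportional) weights.
#'
#' @param tree `"phylo"` tree with branch lengths in Myr.
#' @param data character table (data.frame with `taxon`, `state`) or a named
#'   state vector covering every tip.
#' @param spec an `"mk_model_spec"`.
#' @param params rate vector of length `spec$k` (1/Myr).
#' @param root_prior `"equal"` (default), `"fitzjohn"`, or a fixed
#'   probability vector over the expanded states.
#' @return log-likelihood (scalar).
#' @export
pruning_loglik <- function(tree, data, spec, params, root_prior = "equal") {
  cache <- .pruning_cache(tree, data, spec$n_class)
  pr <- .mk_pruning(cache, assemble_q(spec, params))
  root_cond <- pr$L[cache$root, ]
  w <- .root_weights(root_prior, root_cond, pr$m)
  log(sum(w * root_cond)) + pr$logsc[cache$root]
}
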