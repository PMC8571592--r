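test_that("model specs encode the intended sharing and structural zeros", {
  tw <- build_model_spec("two_rate")
  expect_equal(tw$k, 2L)
  # transitions touching semi-arboreal share parameter 1, direct A<->N is 2
  expect_equal(unname(tw$index[1, 2]), 1L)
  expect_equal(unname(tw$index[2, 1]), 1L)
  expect_equal(unname(tw$index[2, 3]), 1L)
  expect_equal(unname(tw$index[3, 2]), 1L)
  expect_equal(unname(tw$index[1, 3]), 2L)
  expect_equal(unname(tw$index[3, 1]), 2L)

  fr <- build_model_spec("four_rate")
  expect_equal(fr$k, 4L)
  expect_equal(unname(fr$index[1, 3]), 0L)  # A -> N forbidden
  expect_equal(unname(fr$index[3, 1]), 0L)  # N -> A forbidden
  expect_equal(sum(fr$index == 0) - 3L, 2L) # exactly 2 off-diagonal zeros

  expect_equal(build_model_spec("ard")$k, 6L)

  h2 <- build_model_spec("hmm_ard_2class")
  expect_equal(h2$n_expanded, 6L)
  expect_equal(h2$k, 13L)
  # class switches are symmetric and connect identical observed states only
  sw <- h2$index[1:3, 4:6]
  expect_equal(sw, t(h2$index[4:6, 1:3]))
  expect_true(all(diag(sw) == 13L) && all(sw[row(sw) != col(sw)] == 0L))

  expect_equal(build_model_spec("hmm_ard_plus_four_rate_2class")$k, 11L)
  expect_equal(build_model_spec("hmm_ard_3class")$k, 19L)
  expect_error(build_model_spec("five_rate"), "valid names")
})

test_that("assemble_q fills rates by index and keeps rows at zero", {
  fr <- build_model_spec("four_rate")
  expect_equal(unname(assemble_q(fr, rep(0, 4))), matrix(0, 3, 3))

  ar <- build_model_spec("ard")
  Q <- assemble_q(ar, 1:6)
  expect_equal(sort(Q[row(Q) != col(Q)]), as.numeric(1:6))
  expect_equal(unname(rowSums(Q)), rep(0, 3), tolerance = 1e-12)

  tw <- build_model_spec("two_rate")
  Q2 <- assemble_q(tw, c(0.3, 0.7))
  expect_equal(Q2["arboreal", "nonarboreal"], 0.7)
  expect_equal(Q2["arboreal", "semi-arboreal"], 0.3)

  expect_error(assemble_q(fr, c(1, 2)), "expected 4")
  expect_error(assemble_q(fr, c(1, -1, 1, 1)), ">= 0")

  # property: for every spec, random rates give zero row sums and exact
  # structural zeros
  set.seed(1)
  for (nm in mk_model_names()) {
    sp <- build_model_spec(nm)
    Q <- assemble_q(sp, random_params(sp))
    expect_equal(unname(rowSums(Q)), rep(0, sp$n_expanded), tolerance = 1e-12)
    expect_true(all(Q[sp$index == 0 & row(sp$index) != col(sp$index)] == 0))
  }
})

test_that("transition probabilities match the symmetric-chain closed form", {
  tw <- build_model_spec("two_rate")
  Q <- assemble_q(tw, c(0.1, 0.1))
  expect_equal(unname(transition_probabilities(Q, 0)), diag(3))
  expect_error(transition_probabilities(Q, -1), ">= 0")

  for (q in c(0.01, 0.1, 0.5, 2)) for (t in c(0.1, 1, 10)) {
    P <- transition_probabilities(assemble_q(tw, c(q, q)), t)
    expect_equal(unname(P), closed_form_equal_rates(q, t), tolerance = 1e-10)
  }
  # stationary limit of the symmetric chain
  P <- transition_probabilities(assemble_q(tw, c(0.1, 0.1)), 1e6)
  expect_equal(unname(P), matrix(1 / 3, 3, 3), tolerance = 1e-8)

  # rows sum to one for random generators (incl. expanded spaces)
  set.seed(2)
  for (nm in c("ard", "hmm_ard_3class")) {
    sp <- build_model_spec(nm)
    P <- transition_probabilities(assemble_q(sp, random_params(sp)), 3.7)
    expect_equal(unname(rowSums(P)), rep(1, sp$n_expanded), tolerance = 1e-10)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("pruning log-likelihood agrees with closed forms and enumeration", {
  tw <- build_model_spec("two_rate")
  # single tip under a symmetric model: all prior mass routes to the tip
  tip <- parse_tree("(A:1);")
  d1 <- data.frame(taxon = "A", state = "arboreal")
  expect_equal(pruning_loglik(tip, d1, tw, c(0.1, 0.1)), log(1 / 3),
               tolerance = 1e-12)

  # cherry with both tips arboreal: 3-term closed-form sum
  ch <- parse_tree("(A:1,B:1);")
  dd <- data.frame(taxon = c("A", "B"), state = c("arboreal", "arboreal"))
  P <- closed_form_equal_rates(0.1, 1)
  expect_equal(exp(pruning_loglik(ch, dd, tw, c(0.1, 0.1))),
               sum(P[, 1]^2) / 3, tolerance = 1e-10)

  # enumeration oracle across all six specs on random small trees
  set.seed(3)
  for (nm in mk_model_names()) {
    sp <- build_model_spec(nm)
    for (r in 1:3) {
      n <- sample(3:6, 1)
      tr <- ape::rtree(n)
      dat <- random_characters(tr)
      par <- random_params(sp)
      expect_equal(pruning_loglik(tr, dat, sp, par),
                   enum_loglik(tr, dat, sp, par), tolerance = 1e-8,
                   label = paste("pruning", nm, "rep", r))
    }
  }

  # invariance to child order (ladderized representation)
  set.seed(4)
  tr <- ape::rtree(8)
  dat <- random_characters(tr)
  sp <- build_model_spec("ard")
  par <- random_params(sp)
  ll1 <- pruning_loglik(tr, dat, sp, par)
  ll2 <- pruning_loglik(ape::ladderize(tr), dat, sp, par)
  expect_equal(ll1, ll2, tolerance = 1e-10)

  # a dormant hidden class (switch rate 0, duplicated template) changes
  # nothing: the observed process is identical
  h2 <- build_model_spec("hmm_ard_2class")
  par6 <- random_params(sp)
  ll_flat <- pruning_loglik(tr, dat, sp, par6)
  ll_hmm <- pruning_loglik(tr, dat, h2, c(par6, par6, 0))
  expect_equal(ll_hmm, ll_flat, tolerance = 1e-8)

  expect_error(pruning_loglik(tr, dat[-1, ], sp, par6), "missing")
})

test_that("FitzJohn weights renormalize root conditionals", {
  expect_equal(fitzjohn_root_weights(c(0.2, 0.2, 0.6)), c(0.2, 0.2, 0.6))
  expect_equal(fitzjohn_root_weights(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(fitzjohn_root_weights(c(0, 0.5, 0)), c(0, 1, 0))
  expect_error(fitzjohn_root_weights(c(0, 0, 0)), "not all zero")
})

test_that("AIC arithmetic and table ranking are correct", {
  expect_equal(aic_score(-100, 2), 204)
  expect_equal(aic_score(0, 4), 8)
  expect_error(aic_score(-10, 0))
  # with equal fit, fewer parameters rank first
  expect_true(aic_score(-50, 2) < aic_score(-50, 4))

  set.seed(8)
  tr <- simulate_birth_death_tree(60, 80)
  truth <- simulate_character_history(tr, build_model_spec("two_rate"),
                                      c(0.01, 0.005),
                                      root_state = "nonarboreal")
  tab <- model_selection_table(tr, truth$characters,
                               specs = c("two_rate", "ard"),
                               config = optimizer_config(restarts = 2,
                                                         seed = 1))
  expect_equal(nrow(tab), 2)
  expect_false(is.unsorted(tab$AIC))
  expect_equal(tab$dAIC[1], 0)
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$logLik, tolerance = 1e-9)
  fits <- attr(tab, "fits")
  expect_s3_class(fits[["two_rate"]], "mk_fit")
})

test_that("ML fitting recovers a degenerate all-one-state dataset", {
  set.seed(9)
  tr <- simulate_birth_death_tree(30, 50)
  dat <- data.frame(taxon = tr$tip.label, state = "nonarboreal")
  fit <- fit_ml(tr, dat, build_model_spec("two_rate"),
                config = optimizer_config(restarts = 2, seed = 1))
  expect_true(all(fit$params <= 1e-6))
  expect_equal(fit$logLik, log(1 / 3), tolerance = 1e-4)
})

test_that("likelihood cross-checks against an independent implementation", {
  set.seed(10)
  tr <- simulate_birth_death_tree(25, 40)
  spec <- build_model_spec("ard")
  truth <- simulate_character_history(tr, spec,
                                      c(0.05, 0.02, 0.03, 0.06, 0.02, 0.04),
                                      root_state = "semi-arboreal")
  x <- stats::setNames(truth$characters$state, truth$characters$taxon)
  par <- c(0.04, 0.01, 0.02, 0.05, 0.03, 0.02)
  Q <- assemble_q(spec, par)
  # phytools orders states alphabetically: arboreal, nonarboreal, semi-
  ord <- c(1, 3, 2)
  Qp <- Q[ord, ord]
  dimnames(Qp) <- list(sort(arb_states()), sort(arb_states()))
  ref <- phytools::fitMk(tr, as.factor(x[tr$tip.label]), fixedQ = Qp,
                         pi = "equal")
  expect_equal(pruning_loglik(tr, truth$characters, spec, par),
               as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})
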