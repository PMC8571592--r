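test_that("conditioned birth-death trees meet their contract", {
  set.seed(61)
  tr <- simulate_birth_death_tree(164, 90)
  expect_equal(ape::Ntip(tr), 164)
  expect_equal(unname(root_age(tr)), 90, tolerance = 1e-9)
  expect_true(is_ultrametric_tree(tr))

  ch <- simulate_birth_death_tree(2, 10, birth = 1, death = 0)
  expect_equal(ape::Ntip(ch), 2)

  # Yule balance oracle: mean Colless imbalance over replicates sits inside
  # the band around the exact uniform-split recursion expectation
  set.seed(62)
  n <- 15
  reps <- 200
  idx <- replicate(reps, colless_index(
    simulate_birth_death_tree(n, 1, birth = 1, death = 0)))
  exact <- yule_expected_colless(n)
  se <- stats::sd(idx) / sqrt(reps)
  expect_lt(abs(mean(idx) - exact), 4 * se)
})

test_that("the radiation tree concentrates divergences after the boundary", {
  set.seed(63)
  tr <- simulate_kpg_radiation_tree(164, 90)
  expect_equal(ape::Ntip(tr), 164)
  expect_equal(unname(root_age(tr)), 90, tolerance = 1e-6)
  expect_true(is_ultrametric_tree(tr))
  ages <- node_ages(tr)[164 + seq_len(tr$Nnode)]
  # crown radiations start below the boundary; the post-boundary decade is
  # far denser in divergences than the pre-boundary interval
  expect_gt(sum(ages <= 66.02 & ages > 56), sum(ages > 66.02 & ages <= 76))
})

test_that("forward character simulation is exact and self-consistent", {
  set.seed(64)
  tr <- simulate_birth_death_tree(30, 50)
  fr <- build_model_spec("four_rate")

  frozen <- simulate_character_history(tr, fr, rep(0, 4),
                                       root_state = "semi-arboreal")
  expect_true(all(frozen$characters$state == "semi-arboreal"))
  expect_equal(sum(frozen$counts), 0)

  # structural zeros are never crossed in the truth
  truth <- simulate_character_history(tr, fr, c(0.05, 0.03, 0.05, 0.04),
                                      root_state = "nonarboreal")
  expect_equal(truth$counts["arboreal", "nonarboreal"], 0L,
               ignore_attr = TRUE)
  expect_equal(truth$counts["nonarboreal", "arboreal"], 0L,
               ignore_attr = TRUE)

  # the recorded history, the tip table and the counts agree exactly
  ntip <- ape::Ntip(tr)
  tip_end <- arb_states()[arbormk:::.observed_state(
    truth$map$node_states[seq_len(ntip)])]
  expect_equal(stats::setNames(tip_end, tr$tip.label)[truth$characters$taxon],
               stats::setNames(truth$characters$state, truth$characters$taxon))
  expect_equal(sum(truth$counts), nrow(truth$events))
  expect_equal(unname(count_transitions(truth$map)),
               unname(truth$counts))

  # fast symmetric chain reaches its uniform stationary mix at the tips
  set.seed(65)
  big <- simulate_birth_death_tree(300, 50)
  st <- simulate_character_history(big, build_model_spec("two_rate"),
                                   c(2, 2), root_state = "arboreal")
  freqs <- table(factor(st$characters$state, levels = arb_states())) / 300
  expect_true(all(abs(as.numeric(freqs) - 1 / 3) < 0.09))
})

test_that("epoch schedules switch the generator mid-edge", {
  one <- parse_tree("(A:100,B:100);")
  fr <- build_model_spec("four_rate")
  pre <- c(0, 0, 0, 0)          # frozen before the boundary
  post <- c(0, 0, 5, 0)         # immediate S -> N crash after it
  set.seed(66)
  truth <- simulate_character_history(
    one, fr, pre, root_state = "semi-arboreal",
    schedule = list(boundaries = 40, params = list(pre, post)))
  ev <- truth$events
  expect_true(nrow(ev) >= 1)
  expect_true(all(ev$age <= 40))
  expect_true(all(truth$characters$state == "nonarboreal"))
})

test_that("pseudo-posterior perturbation preserves the contracts", {
  set.seed(67)
  ref <- simulate_birth_death_tree(24, 70)

  copies <- perturb_tree_set(ref, 3, branch_jitter_sd = 0, n_nni = 0)
  for (cp in copies) {
    expect_setequal(unname(clade_keys(cp)), unname(clade_keys(ref)))
    expect_equal(sort(unname(node_ages(cp))), sort(unname(node_ages(ref))),
                 tolerance = 1e-9)
  }

  jit <- perturb_tree_set(ref, 10, branch_jitter_sd = 0.1, n_nni = 0)
  for (tp in jit) {
    expect_true(is_ultrametric_tree(tp))
    expect_equal(unname(root_age(tp)), 70, tolerance = 1e-6)
    expect_setequal(tp$tip.label, ref$tip.label)
    expect_setequal(unname(clade_keys(tp)), unname(clade_keys(ref)))
  }

  # a single NNI changes at most one clade key (exactly one when
  # non-degenerate)
  nni <- perturb_tree_set(ref, 10, branch_jitter_sd = 0, n_nni = 1)
  delta <- vapply(nni, function(tp)
    length(setdiff(clade_keys(ref), clade_keys(tp))), integer(1))
  expect_true(all(delta <= 1))
  expect_true(any(delta == 1))

  # clade frequency decreases with perturbation intensity
  freqs <- vapply(c(0, 1, 5), function(k) {
    set.seed(68)
    mean(match_nodes(ref, perturb_tree_set(ref, 20, 0, n_nni = k))$clade_freq)
  }, numeric(1))
  expect_true(all(diff(freqs) < 0))
})

test_that("the study fixture is deterministic and well-mixed", {
  fx1 <- make_study_fixture(seed = 1, n_posterior = 3)
  fx2 <- make_study_fixture(seed = 1, n_posterior = 3)
  expect_identical(serialize(fx1, NULL), serialize(fx2, NULL))

  fx <- make_study_fixture(seed = 1, n_posterior = 0)
  mix <- table(factor(fx$characters$state, levels = arb_states())) / 164
  expect_true(all(mix >= 0.10))
  sn_post <- with(fx$truth$events, sum(from == 2 & to == 3 & age < 66.02))
  expect_gte(sn_post, 1)
  # the crash is post-boundary by construction: no pre-boundary S->N burst
  sn_pre <- with(fx$truth$events, sum(from == 2 & to == 3 & age >= 66.02))
  expect_lt(sn_pre, sn_post)
})

test_that("rate recovery sharpens with taxon sampling", {
  fr <- build_model_spec("four_rate")
  true_par <- c(0.02, 0.01, 0.03, 0.01)
  rel_err <- function(n_tips, seed) {
    set.seed(seed)
    tr <- simulate_birth_death_tree(n_tips, 90)
    truth <- simulate_character_history(tr, fr, true_par,
                                        root_state = "semi-arboreal")
    fit <- fit_ml(tr, truth$characters, fr,
                  config = optimizer_config(restarts = 2, seed = seed))
    abs(fit$params - true_par) / true_par
  }
  errs_small <- unlist(lapply(1:10, function(s) rel_err(100, s)))
  errs_large <- unlist(lapply(1:10, function(s) rel_err(800, s + 100)))
  expect_lt(stats::median(errs_large), stats::median(errs_small))
})

test_that("fixture bundles round-trip through the directory format", {
  fx <- make_study_fixture(seed = 2, n_tips = 30, n_posterior = 2)
  dir <- withr::local_tempdir()
  write_fixture_bundle(fx, dir)
  expect_true(all(file.exists(file.path(dir,
    c("tree.nwk", "posterior.nwk", "characters.tsv", "truth_segments.tsv",
      "manifest.json")))))
  re_tree <- read_trees(file.path(dir, "tree.nwk"))
  expect_setequal(unname(clade_keys(re_tree)), unname(clade_keys(fx$tree)))
  re_chars <- read_character_table(file.path(dir, "characters.tsv"))
  expect_equal(re_chars$state, fx$characters$state)
  segs <- utils::read.table(file.path(dir, "truth_segments.tsv"),
                            header = TRUE, sep = "\t")
  expect_equal(sum(segs$duration), total_tree_length(fx$tree),
               tolerance = 1e-6)
})
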