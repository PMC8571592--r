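test_that("time-bin grids partition the tree depth", {
  tr <- parse_tree("((A:50,B:50):50,C:100);")
  g <- make_time_bins(tr, 50)
  expect_equal(g$width, 2)
  expect_equal(length(g$edges), 51)
  expect_equal(g$edges[1], 100)
  expect_equal(g$edges[51], 0)
  expect_true(all(diff(g$edges) < 0))
  expect_equal(g$width * g$B, unname(root_age(tr)), tolerance = 1e-9)

  g1 <- make_time_bins(tr, 1)
  expect_equal(g1$edges, c(100, 0))

  expect_error(make_time_bins(tr, 0), ">= 1")
  expect_error(make_time_bins(parse_tree("((A:1,B:2):1,C:2);"), 10),
               "ultrametric")

  # the boundary cut lands in the expected bin on an 80-Myr tree
  set.seed(51)
  t80 <- simulate_birth_death_tree(10, 80)
  g80 <- make_time_bins(t80, 50)
  expect_equal(g80$width, 1.6)
  expect_equal(arbormk:::.bin_of(66.02, g80), 9)  # floor((80-66.02)/1.6) + 1
})

test_that("branch length per bin conserves total tree length", {
  one <- parse_tree("(A:10);")
  expect_equal(branch_length_per_bin(one, make_time_bins(one, 2)), c(5, 5))

  tr <- parse_tree("((A:1,B:1):1,C:2);")
  expect_equal(branch_length_per_bin(tr, make_time_bins(tr, 2)), c(2, 3))

  set.seed(52)
  for (r in 1:3) {
    bd <- simulate_birth_death_tree(sample(10:60, 1), 70)
    bl <- branch_length_per_bin(bd, make_time_bins(bd, 17))
    expect_equal(sum(bl), total_tree_length(bd), tolerance = 1e-9)
  }
})

test_that("events are binned older-inclusive and averaged over maps", {
  tr <- parse_tree("(A:10,B:10);")
  g <- make_time_bins(tr, 2)
  mk_map <- function(durA) {
    structure(list(tree = tr, edge = tr$edge, edge_length = c(10, 10),
                   segments = list(list(state = c(2L, 3L), duration = durA),
                                   list(state = 2L, duration = 10)),
                   node_states = c(3L, 2L, 2L), n_class = 1L),
              class = "stoch_map")
  }
  # event at age 7 (parent age 10, first segment 3 Myr)
  counts <- transitions_per_bin(list(mk_map(c(3, 7))), g, by_type = FALSE)
  expect_equal(counts, c(1, 0))
  # event exactly on the interior bin edge (age 5) goes to the older bin
  counts2 <- transitions_per_bin(list(mk_map(c(5, 5))), g, by_type = FALSE)
  expect_equal(counts2, c(1, 0))
  # averaging over maps
  counts3 <- transitions_per_bin(list(mk_map(c(3, 7)), mk_map(c(8, 2))), g,
                                 by_type = FALSE)
  expect_equal(counts3, c(0.5, 0.5))
  by_type <- transitions_per_bin(list(mk_map(c(3, 7))), g)
  expect_equal(by_type["semi-arboreal->nonarboreal", ], c(1, 0),
               ignore_attr = TRUE)
  expect_equal(sum(by_type), 1)

  # a corrupt map with an event beyond the root age errors
  bad <- mk_map(c(3, 7))
  bad$segments[[1]]$duration <- c(-2, 12)
  expect_error(transitions_per_bin(list(bad), g), "corrupt")
})

test_that("unconditional equal-rates events match the Poisson intensity", {
  # symmetric chain: exit rate 2q from every state, so the expected count in
  # a bin is 2q x branch length, independent of state occupancy
  set.seed(53)
  tr <- simulate_birth_death_tree(25, 40)
  tw <- build_model_spec("two_rate")
  q <- 0.04
  nrep <- 150
  maps <- lapply(seq_len(nrep), function(i)
    simulate_character_history(tr, tw, c(q, q))$map)
  g <- make_time_bins(tr, 8)
  bl <- branch_length_per_bin(tr, g)
  counts <- transitions_per_bin(maps, g, by_type = FALSE)
  expected <- 2 * q * bl
  # 3 standard errors of the per-bin mean (Poisson variance)
  se <- sqrt(expected / nrep)
  expect_true(all(abs(counts - expected) <= 3 * se + 1e-9))
})

test_that("normalized series divide by lineage-time and conserve counts", {
  tr <- parse_tree("(A:10,B:10);")
  mp <- structure(list(tree = tr, edge = tr$edge, edge_length = c(10, 10),
                       segments = list(list(state = c(2L, 3L),
                                            duration = c(3, 7)),
                                       list(state = 2L, duration = 10)),
                       node_states = c(3L, 2L, 2L), n_class = 1L),
                  class = "stoch_map")
  s <- normalized_transition_series(list(mp), tr, B = 2)
  sn <- s[s$type == "semi-arboreal->nonarboreal", ]
  expect_equal(sn$value, c(1 / 10, 0))  # one event over 10 Myr of lineage
  expect_equal(s$value[s$type == "total"], sn$value, tolerance = 1e-12)

  # zero events everywhere: all-zero series
  frozen <- structure(list(tree = tr, edge = tr$edge, edge_length = c(10, 10),
                           segments = list(list(state = 1L, duration = 10),
                                           list(state = 1L, duration = 10)),
                           node_states = c(1L, 1L, 1L), n_class = 1L),
                      class = "stoch_map")
  s0 <- normalized_transition_series(list(frozen), tr, B = 4)
  expect_true(all(s0$value == 0))

  # conservation identity on simulated maps
  set.seed(54)
  bd <- simulate_birth_death_tree(18, 60)
  sp <- build_model_spec("four_rate")
  maps <- lapply(1:20, function(i)
    simulate_character_history(bd, sp, c(0.02, 0.01, 0.03, 0.02),
                               root_state = "semi-arboreal")$map)
  s2 <- normalized_transition_series(maps, bd, B = 12)
  for (ty in transition_types()) {
    sl <- s2[s2$type == ty, ]
    recovered <- sum(sl$value * sl$branch_length_myr, na.rm = TRUE)
    direct <- mean(vapply(maps, function(m) {
      cm <- count_transitions(m)
      cm[t(matrix(unlist(strsplit(ty, "->", fixed = TRUE)), 2))]
    }, numeric(1)))
    expect_equal(recovered, direct, tolerance = 1e-9, label = ty)
  }
})

test_that("posterior curves align on a common absolute-age axis", {
  set.seed(55)
  tr <- simulate_birth_death_tree(12, 80)
  sp <- build_model_spec("two_rate")
  mk_series <- function(tree) {
    maps <- lapply(1:5, function(i)
      simulate_character_history(tree, sp, c(0.03, 0.01))$map)
    normalized_transition_series(maps, tree, B = 10)
  }
  s1 <- mk_series(tr)
  agg <- aggregate_over_posterior(list(s1, s1))
  c1 <- agg$curves[agg$curves$tree == 1, "value"]
  c2 <- agg$curves[agg$curves$tree == 2, "value"]
  expect_identical(c1, c2)

  # shallower trees are undefined in the bins older than their root
  short <- tr; short$edge.length <- short$edge.length * 0.8  # root age 64
  s2 <- mk_series(short)
  agg2 <- aggregate_over_posterior(list(s1, s2))
  expect_equal(max(agg2$edges), 80)
  old_bins <- agg2$curves$tree == 2 & agg2$curves$younger >= 64
  expect_true(all(is.na(agg2$curves$value[old_bins])))
  expect_false(anyNA(agg2$curves$value[agg2$curves$tree == 1]))

  expect_error(aggregate_over_posterior(
    list(s1, normalized_transition_series(
      lapply(1:2, function(i)
        simulate_character_history(tr, sp, c(0.03, 0.01))$map), tr, B = 5))),
    "mixed bin counts")
  # median curve exists for every type
  expect_equal(sort(unique(agg$median$type)),
               sort(c(transition_types(), "total")))
})
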