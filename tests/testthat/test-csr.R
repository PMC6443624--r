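test_that("reconstruction returns exactly the states of tied optimal assignments", {
  tr <- read_newick("(A,B);")
  m0 <- coded_matrix(matrix(c(0L, 0L), 2, 1, dimnames = list(c("A", "B"), "c")),
                     n_states = 6)
  r0 <- reconstruct_states(tr, m0, ordered_stepmatrix(6))
  expect_equal(which(r0$state_sets[[1]][, 3]) - 1L, 0L)

  m04 <- coded_matrix(matrix(c(0L, 4L), 2, 1, dimnames = list(c("A", "B"), "c")),
                      n_states = 6)
  r04 <- reconstruct_states(tr, m04, ordered_stepmatrix(6))
  expect_equal(which(r04$state_sets[[1]][, 3]) - 1L, 0:4) # every median ties

  m05 <- coded_matrix(matrix(c(0L, 5L), 2, 1, dimnames = list(c("A", "B"), "c")),
                      n_states = 32)
  r05 <- reconstruct_states(tr, m05, hk_stepmatrix(32, "abundance"))
  expect_equal(which(r05$state_sets[[1]][, 3]) - 1L, 5L) # loss-only optimum
  expect_equal(r05$total_length, 1)
  expect_error(reconstruct_states(rand_topology(5, seed = 1), m0, "ordered"), "rooted")
})

test_that("reconstruction cost vectors reproduce the tree length and leaf singletons", {
  for (seed in 1:10) {
    n <- sample(4:8, 1)
    tr <- rand_topology(n, seed = seed, rooted = TRUE)
    m <- rand_coded(n, 3, 6, seed = seed + 60)
    s <- ordered_stepmatrix(6)
    rec <- reconstruct_states(tr, m, s)
    expect_equal(rec$total_length, as.numeric(sankoff_length(tr, m, s)))
    X <- unclass(m)[rec$tree$tip.label, ]
    for (j in seq_len(ncol(X))) {
      for (i in seq_len(n)) {
        expect_equal(which(rec$state_sets[[j]][, i]) - 1L, unname(X[i, j]))
      }
      expect_true(all(colSums(rec$state_sets[[j]]) >= 1)) # non-empty sets
    }
  }
})

test_that("unambiguous change counting follows the singleton rule", {
  # chain tree with forced direction: anchor 0, leaves 0 and 3
  rt <- read_newick("((A,B),C);")
  m <- coded_matrix(matrix(c(3L, 3L, 0L), 3, 1,
                           dimnames = list(c("A", "B", "C"), "c")), n_states = 6)
  rec <- reconstruct_states(rt, m, ordered_stepmatrix(6))
  cf <- change_frequencies(rec, exclude_leaves = character())
  # ambiguous branches (root set {0..3}) are tallied, not counted
  expect_equal(sum(cf$counts), cf$total)
  expect_true(cf$ambiguous > 0)

  # with an unambiguous anchor the 0 -> 3 gain lands in one cell
  rt2 <- read_newick("(((A,B),C),Z);")
  m2 <- coded_matrix(matrix(c(3L, 3L, 0L, 0L), 4, 1,
                            dimnames = list(c("A", "B", "C", "Z"), "c")), n_states = 6)
  rec2 <- reconstruct_states(rt2, m2, ordered_stepmatrix(6))
  cf2 <- change_frequencies(rec2, exclude_leaves = character())
  expect_equal(cf2$counts["0", "3"], 1)
  expect_equal(sum(cf2$counts), 1)
  expect_equal(sum(cf2$counts[lower.tri(cf2$counts)]), 0)
})

test_that("tied trees are averaged, not pooled", {
  rt2 <- read_newick("(((A,B),C),Z);")
  m2 <- coded_matrix(matrix(c(3L, 3L, 0L, 0L), 4, 1,
                            dimnames = list(c("A", "B", "C", "Z"), "c")), n_states = 6)
  rec <- reconstruct_states(rt2, m2, ordered_stepmatrix(6))
  cf_avg <- change_frequencies(list(rec, rec), exclude_leaves = character())
  cf_one <- change_frequencies(rec, exclude_leaves = character())
  expect_equal(cf_avg$counts, cf_one$counts)
  expect_equal(cf_avg$n_trees, 2L)
})

test_that("pure-gain occurrence data yields a strictly gain-only frequency matrix", {
  for (sd in c(21L, 22L)) {
    cfg <- sim_config(n_taxa = 10, n_fsf_initial = 12, mu = 0, a = 0.05, seed = sd)
    sim <- simulate_proteomes(cfg)
    mb <- to_binary_occurrence(sim$abundance)
    sr <- heuristic_search(mb, "unordered", n_replicates = 2, seed = sd + 100L)
    rr <- lundberg_root(sr$best_trees[[1]], mb, "unordered", ancestor = "0")
    aug <- domtol:::.augmented_matrix(mb, rr$ancestor_states)
    rec <- reconstruct_states(rr$rooted_tree_with_ancestor, aug, "unordered")
    cf <- change_frequencies(rec)
    expect_equal(sum(cf$counts[lower.tri(cf$counts)]), 0)
    expect_gt(sum(cf$counts[upper.tri(cf$counts)]), 0)
  }
})

test_that("gain-biased abundance data reconstructs more gains than losses", {
  cfg <- sim_config(n_taxa = 10, n_fsf_initial = 12, seed = 31)
  sim <- simulate_proteomes(cfg)
  m <- encode_abundance(sim$abundance, n_states = 32)
  sr <- heuristic_search(m, "unordered", n_replicates = 2, seed = 32)
  rr <- lundberg_root(sr$best_trees[[1]], m, "unordered", ancestor = "0")
  aug <- domtol:::.augmented_matrix(m, rr$ancestor_states)
  rec <- reconstruct_states(rr$rooted_tree_with_ancestor, aug, "unordered")
  cf <- change_frequencies(rec)
  expect_gt(sum(cf$counts[upper.tri(cf$counts)]),
            sum(cf$counts[lower.tri(cf$counts)]))
})

test_that("one dynamic-weighting round is stable on homoplasy-free ordered data", {
  pd <- perfect_dataset(8)
  it <- dynamic_weighting_iterate(pd$m, "ordered",
                                  search_opts = list(seed = 5, n_replicates = 3))
  g <- glance(it)
  expect_equal(nrow(g), 1L) # rounds = 1 yields exactly one (T0, T1) pair
  expect_equal(g$cluster_distance, 0L)
  expect_equal(g$verdict, "stable")
  expect_equal(g$hybridization_distance, 0L)
})

test_that("refinement reverses the gain penalty when seeded with the penalized model", {
  cfg <- sim_config(n_taxa = 8, n_fsf_initial = 10, seed = 31)
  sim <- simulate_proteomes(cfg)
  m <- encode_abundance(sim$abundance, n_states = 32)
  it <- dynamic_weighting_iterate(m, hk_stepmatrix(32, "abundance"),
                                  search_opts = list(seed = 77, n_replicates = 2))
  r <- it$rounds[[1]]
  obs <- which(r$frequency_matrix$counts[1, -1] > 0)
  expect_gt(length(obs), 0)
  # reconstructed first-gain transformations come out cheaper than the
  # penalty they were given
  expect_lt(mean(r$derived_stepmatrix$cost[1, 1 + obs]), 3)
})

test_that("refinement refuses data with no unambiguous changes", {
  tr <- ape::stree(4, "balanced"); tr$tip.label <- paste0("t", 1:4)
  mc <- coded_matrix(matrix(2L, 4, 2, dimnames = list(tr$tip.label, c("a", "b"))),
                     n_states = 8)
  expect_error(dynamic_weighting_iterate(mc, "ordered",
                                         search_opts = list(seed = 1, n_replicates = 1)),
               "unambiguous")
})
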