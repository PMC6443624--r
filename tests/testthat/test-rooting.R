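quartet_fix <- function() {
  list(tree = read_newick("(A,B,(C,D));"),
       m = coded_matrix(matrix(c(0L, 1L, 4L, 5L), 4, 1,
                               dimnames = list(c("A", "B", "C", "D"), "c")),
                        n_states = 6))
}

test_that("lundberg attaches an all-0 ancestor on the low-state pendant edge", {
  fx <- quartet_fix()
  rr <- lundberg_root(fx$tree, fx$m, ordered_stepmatrix(6), ancestor = "0")
  # enumerate all five attachment edges independently: score tree + pendant ANC
  lens <- vapply(seq_len(nrow(rr$scoring_tree$edge)), function(e) {
    aug <- domtol:::.attach_leaf_on_edge(rr$scoring_tree, e, ".ANC")
    maug <- coded_matrix(rbind(unclass(fx$m), .ANC = 0L), n_states = 6)
    as.numeric(sankoff_length(aug, maug, ordered_stepmatrix(6)))
  }, numeric(1))
  expect_equal(rr$rooted_length, min(lens))
  expect_equal(rr$rooted_length, rr$unrooted_length) # zero added cost
  # the root split isolates A (the taxon closest to the ancestor)
  key <- domtol:::.root_split_key(rr$rooted_tree)
  expect_equal(key, "A")
})

test_that("the all-missing (standard) ancestor ties on every edge at zero added cost", {
  fx <- quartet_fix()
  rr <- lundberg_root(fx$tree, fx$m, "ordered", ancestor = "?")
  expect_equal(length(rr$ties), nrow(rr$scoring_tree$edge))
  expect_equal(rr$rooted_length, rr$unrooted_length)
  rr2 <- lundberg_root(fx$tree, fx$m, "ordered", ancestor = "standard")
  expect_equal(rr2$ties, rr$ties)
  # rooted input and bad ancestor strings are refused
  expect_error(lundberg_root(read_newick("((A,B),(C,D));"), fx$m, "ordered"), "unrooted")
  expect_error(lundberg_root(fx$tree, fx$m, "ordered", ancestor = "01"), "characters")
})

test_that("a real taxon's state vector as ancestor reproduces outgroup rooting", {
  for (seed in 1:8) {
    n <- sample(5:8, 1)
    un <- rand_topology(n, seed = seed)
    m <- rand_coded(n, 4, 8, seed = seed + 30)
    tx <- sample(un$tip.label, 1)
    anc <- paste(state_to_symbol(unclass(m)[tx, ]), collapse = "")
    rr <- lundberg_root(un, m, "ordered", ancestor = anc)
    # the taxon's own pendant edge adds zero cost, so it must be optimal
    pend <- which(rr$scoring_tree$edge[, 2] == match(tx, rr$scoring_tree$tip.label))
    expect_true(pend %in% rr$ties)
    expect_equal(rr$rooted_length, rr$unrooted_length)
  }
})

test_that("the ancestor sweep emits one row per scheme and a fitted regression", {
  cfg <- sim_config(n_taxa = 8, n_fsf_initial = 10, seed = 101)
  sim <- simulate_proteomes(cfg)
  m <- encode_abundance(sim$abundance, n_states = 16)
  sr <- heuristic_search(m, "ordered", n_replicates = 2, seed = 102)
  sw <- ancestor_sweep(sr$best_trees[[1]], m, "ordered", groups = taxon_groups(m))
  expect_equal(nrow(sw), 17L) # standard + 16 constant ancestors
  expect_setequal(sw$ancestor, c("standard", state_alphabet(16)$symbols))
  reg <- attr(sw, "regression")
  expect_equal(nrow(reg), 2L)
  expect_true(all(is.finite(reg$slope)))
  # gain-dominated data: the all-0 rooting is no longer than the all-top one
  expect_lte(sw$length[sw$ancestor == "0"], sw$length[sw$ancestor == "F"])
  expect_error(ancestor_sweep(sr$best_trees[[1]], m, hk_stepmatrix(32, "abundance")),
               "ordered or unordered")
})

test_that("a constant matrix degenerates the sweep to all-edge ties", {
  un <- rand_topology(5, seed = 4)
  mc <- coded_matrix(matrix(2L, 5, 3, dimnames = list(un$tip.label, c("a", "b", "c"))),
                     n_states = 8)
  for (anc in c("0", "2", "7")) {
    rr <- lundberg_root(un, mc, "ordered", ancestor = anc)
    expect_equal(length(rr$ties), nrow(rr$scoring_tree$edge))
    # added cost is exactly nchar * |anc - 2| wherever the ancestor lands
    expect_equal(rr$rooted_length, 3 * abs(symbol_to_state(anc) - 2L))
  }
})

test_that("basal classification distinguishes mono-, para-phyly and mixtures", {
  groups <- c(A1 = "Archaea", A2 = "Archaea", B1 = "Bacteria", B2 = "Bacteria",
              E1 = "Eukarya")
  mono <- classify_basal(read_newick("((A1,A2),(B1,(B2,E1)));"), groups)
  expect_equal(mono$group, "Archaea")
  expect_equal(mono$structure, "monophyletic")
  para <- classify_basal(read_newick("(A1,(A2,(B1,E1)));"), groups)
  expect_equal(para$group, "Archaea")
  expect_equal(para$structure, "paraphyletic")
  mixed <- classify_basal(read_newick("((A1,B1),(A2,E1));"), groups)
  expect_equal(mixed$structure, "unresolved")
  expect_error(classify_basal(read_newick("(A1,A2,B1);"), groups), "rooted")
})
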