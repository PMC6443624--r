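two_leaf <- function(a, b, ns) {
  list(tree = read_newick("(A,B);"),
       m = coded_matrix(matrix(c(a, b), 2, 1, dimnames = list(c("A", "B"), "c1")),
                        n_states = ns))
}

test_that("sankoff scoring matches hand-worked cases", {
  tl <- two_leaf(0L, 5L, 32L)
  expect_equal(as.numeric(sankoff_length(tl$tree, tl$m, ordered_stepmatrix(32))), 5)
  # gain-penalty model prefers a high ancestor and one loss
  expect_equal(as.numeric(sankoff_length(tl$tree, tl$m, hk_stepmatrix(32, "abundance"))), 1)
  # constant character costs nothing on any tree
  tr <- rand_topology(8, seed = 1)
  mc <- coded_matrix(matrix(4L, 8, 2, dimnames = list(tr$tip.label, c("a", "b"))),
                     n_states = 8)
  expect_equal(as.numeric(sankoff_length(tr, mc, ordered_stepmatrix(8))), 0)
  # asymmetric model on an unrooted tree is refused
  expect_error(sankoff_length(tr, coded_matrix(matrix(0L, 8, 1, dimnames = list(tr$tip.label, "c")), n_states = 32),
                              hk_stepmatrix(32, "abundance")),
               "rooted")
})

test_that("fitch and wagner match their textbook examples", {
  q <- read_newick("((A,B),(C,D));")
  m <- coded_matrix(matrix(c(0L, 1L, 0L, 1L), 4, 1,
                           dimnames = list(c("A", "B", "C", "D"), "c")),
                    n_states = 2)
  expect_equal(as.numeric(fitch_length(q, m)), 2)
  expect_equal(as.numeric(fitch_length(q, coded_matrix(matrix(3L, 4, 1, dimnames = list(c("A", "B", "C", "D"), "c")), n_states = 8))), 0)
  expect_equal(as.numeric(wagner_length(two_leaf(0L, 4L, 5L)$tree, two_leaf(0L, 4L, 5L)$m)), 4)
  expect_equal(as.numeric(wagner_length(two_leaf(0L, 2L, 5L)$tree, two_leaf(0L, 2L, 5L)$m)), 2)
})

test_that("fold algorithms equal generalized sankoff on random instances", {
  for (seed in 1:40) {
    n <- sample(4:9, 1)
    tr <- rand_topology(n, seed = seed, rooted = seed %% 2 == 0)
    m <- rand_coded(n, sample(1:4, 1), sample(c(2L, 4L, 8L), 1), seed = seed + 100,
                    p_missing = ifelse(seed %% 3 == 0, 0.15, 0))
    ns <- attr(m, "n_states")
    expect_equal(as.numeric(fitch_length(tr, m)),
                 as.numeric(sankoff_length(tr, m, unordered_stepmatrix(ns))))
    expect_equal(as.numeric(wagner_length(tr, m)),
                 as.numeric(sankoff_length(tr, m, ordered_stepmatrix(ns))))
  }
})

test_that("dynamic program equals brute-force enumeration, including asymmetric costs", {
  set.seed(77)
  asym <- stepmatrix(matrix(c(0, 3, 1,
                              1, 0, 1,
                              2, 2, 0), 3, 3, byrow = TRUE), "asym")
  for (seed in 1:30) {
    n <- sample(3:6, 1)
    tr <- rand_topology(n, seed = seed, rooted = TRUE)
    m <- rand_coded(n, sample(1:3, 1), 3L, seed = seed + 500,
                    p_missing = ifelse(seed %% 4 == 0, 0.2, 0))
    X <- unclass(m)
    for (s in list(ordered_stepmatrix(3), unordered_stepmatrix(3), asym)) {
      expect_equal(as.numeric(sankoff_length(tr, m, s)),
                   brute_tree_length(tr, X, s$cost),
                   info = paste("seed", seed, s$name))
    }
  }
})

test_that("length is root-invariant for symmetric models but not asymmetric ones", {
  m <- rand_coded(6, 3, 4, seed = 12)
  un <- rand_topology(6, seed = 12)
  base <- as.numeric(sankoff_length(un, m, ordered_stepmatrix(4)))
  for (e in seq_len(nrow(un$edge))) {
    rt <- domtol:::.root_on_edge(un, e)
    expect_equal(as.numeric(sankoff_length(rt, m, ordered_stepmatrix(4))), base)
  }
  # an instance where the asymmetric length depends on the root
  asym <- hk_stepmatrix(32, "abundance")
  m32 <- coded_matrix(matrix(c(0L, 0L, 5L, 5L, 6L, 7L), 6, 1,
                             dimnames = list(un$tip.label, "c")), n_states = 32)
  lens <- vapply(seq_len(nrow(un$edge)), function(e) {
    as.numeric(sankoff_length(domtol:::.root_on_edge(un, e), m32, asym))
  }, numeric(1))
  expect_true(length(unique(lens)) > 1)
})

test_that("per-character bounds match brute force and the worked cases", {
  expect_equal(char_bounds(c(0, 0, 0, 4, 4, 8), "ordered"), c(M = 8, G = 16))
  expect_equal(char_bounds(c(0, 0, 0, 4, 4, 8), "unordered"), c(M = 2, G = 3))
  expect_equal(char_bounds(c(3, 3, 3), "ordered"), c(M = 0, G = 0))
  expect_equal(char_bounds(c(3, 3, 3), "unordered"), c(M = 0, G = 0))
  for (seed in 1:20) {
    set.seed(seed)
    ns <- sample(c(4L, 8L), 1)
    vals <- sample(0:(ns - 1), sample(3:8, 1), replace = TRUE)
    expect_equal(unname(char_bounds(vals, "ordered", ns)["G"]),
                 brute_star_length(vals, ordered_stepmatrix(ns)$cost))
    expect_equal(unname(char_bounds(vals, "unordered", ns)["G"]),
                 brute_star_length(vals, unordered_stepmatrix(ns)$cost))
  }
})

test_that("retention index hits its defining endpoints", {
  q_match <- read_newick("((A,B),(C,D));")
  m <- coded_matrix(matrix(c(0L, 0L, 1L, 1L), 4, 1,
                           dimnames = list(c("A", "B", "C", "D"), "c")),
                    n_states = 2)
  fi <- ensemble_indices(q_match, m, "unordered")
  expect_equal(fi$RI, 1) # S = M: perfect fit
  q_cross <- read_newick("((A,C),(B,D));")
  fi0 <- ensemble_indices(q_cross, m, "unordered")
  expect_equal(fi0$RI, 0) # S = G: worst fit
  # constant matrix: RI undefined
  fic <- ensemble_indices(q_match,
                          coded_matrix(matrix(2L, 4, 2, dimnames = list(c("A", "B", "C", "D"), c("x", "y"))), n_states = 8),
                          "ordered")
  expect_true(is.na(fic$RI))
  # bounds on random instances
  for (seed in 1:15) {
    n <- sample(4:8, 1)
    tr <- rand_topology(n, seed = seed)
    m <- rand_coded(n, 5, 6, seed = seed + 50)
    for (ct in c("ordered", "unordered")) {
      fi <- ensemble_indices(tr, m, ct)
      expect_true(all(fi$M <= fi$S + 1e-9 & fi$S <= fi$G + 1e-9))
      if (!is.na(fi$RI)) expect_true(fi$RI >= 0 && fi$RI <= 1)
    }
  }
})
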