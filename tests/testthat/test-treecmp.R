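test_that("hardwired cluster distance matches hand enumeration", {
  t1 <- read_newick("((A,B),(C,D));")
  t2 <- read_newick("((A,C),(B,D));")
  expect_equal(cluster_distance(t1, t1), 0L)
  expect_equal(cluster_distance(t1, t2), 4L) # {AB},{CD} vs {AC},{BD}
  expect_equal(cluster_distance(t1, t2, halved = TRUE), 2)
  # one NNI deep inside a 6-leaf tree changes exactly one cluster on each side
  s1 <- read_newick("(((A,B),C),((D,E),F));")
  s2 <- read_newick("(((A,C),B),((D,E),F));")
  expect_equal(cluster_distance(s1, s2), 2L)
  expect_error(cluster_distance(ape::unroot(t1), t2), "rooted")
  # non-shared leaves pruned with a warning
  t3 <- read_newick("(((A,B),(C,D)),X);")
  expect_warning(d <- cluster_distance(t1, t3), "X")
  expect_equal(d, 0L)
})

test_that("cluster distance is symmetric and zero iff topologies agree", {
  for (seed in 1:10) {
    a <- rand_topology(7, seed = seed, rooted = TRUE)
    b <- rand_topology(7, seed = seed + 99, rooted = TRUE)
    expect_equal(cluster_distance(a, b), cluster_distance(b, a))
    expect_equal(cluster_distance(a, a), 0L)
    if (cluster_distance(a, b) == 0L) {
      expect_equal(domtol:::.topo_key(a), domtol:::.topo_key(b))
    }
  }
})

test_that("hybridization distance solves the worked cases exactly", {
  t1 <- read_newick("((A,B),(C,D));")
  t2 <- read_newick("((A,C),(B,D));")
  expect_equal(hybridization_distance(t1, t1)$distance, 0L)
  hd <- hybridization_distance(t1, t2)
  expect_equal(hd$method, "exact")
  # exhaustive agreement-forest search over all leaf partitions agrees
  expect_equal(hd$distance, brute_hybridization(t1, t2))
  expect_equal(hd$distance, 2L)
  # one reticulation suffices when the trees differ by one rSPR move
  t4 <- read_newick("((A,B),((C,D),E));")
  t5 <- read_newick("((A,(B,E)),(C,D));")
  h2 <- hybridization_distance(t4, t5)
  expect_equal(h2$distance, brute_hybridization(t4, t5))
  expect_equal(h2$distance, 1L)
  expect_error(hybridization_distance(read_newick("((A,B,C),D);"), t1), "binary")
})

test_that("hybridization matches the exhaustive partition oracle on random pairs", {
  for (seed in 1:8) {
    n <- sample(4:6, 1)
    a <- rand_topology(n, seed = seed * 3, rooted = TRUE)
    b <- rand_topology(n, seed = seed * 3 + 1, rooted = TRUE)
    b$tip.label <- a$tip.label[match(b$tip.label, sort(b$tip.label))]
    got <- hybridization_distance(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$distance, brute_hybridization(a, b),
                 info = paste("seed", seed))
    # symmetry
    expect_equal(hybridization_distance(b, a)$distance, got$distance)
  }
  # a larger instance against the partition oracle
  a <- rand_topology(7, seed = 71, rooted = TRUE)
  b <- rand_topology(7, seed = 72, rooted = TRUE)
  expect_equal(hybridization_distance(a, b)$distance, brute_hybridization(a, b))
})

test_that("beyond the exact limit certified bounds are returned", {
  a <- rand_topology(20, seed = 5, rooted = TRUE)
  b <- rand_topology(20, seed = 6, rooted = TRUE)
  hd <- hybridization_distance(a, b, exact_leaf_limit = 8)
  expect_equal(hd$method, "heuristic")
  expect_true(hd$lower <= hd$upper)
  expect_true(hd$lower >= 1) # topologies differ
})

test_that("tanglegram orderings report crossings consistent with brute counting", {
  t1 <- read_newick("((A,B),(C,D));")
  tg0 <- tanglegram_export(t1, t1)
  expect_equal(attr(tg0, "crossings"), 0L)
  expect_equal(tg0$position_t1, tg0$position_t2)
  t2 <- read_newick("((A,C),(B,D));")
  tg1 <- tanglegram_export(t1, t2)
  expect_gte(attr(tg1, "crossings"), 1L)
  # reported crossings equal the inversion count of the emitted orderings
  for (seed in 1:6) {
    a <- rand_topology(8, seed = seed, rooted = TRUE)
    b <- rand_topology(8, seed = seed + 50, rooted = TRUE)
    b$tip.label <- a$tip.label[match(b$tip.label, sort(b$tip.label))]
    tg <- tanglegram_export(a, b)
    ord1 <- tg$leaf[order(tg$position_t1)]
    ord2 <- tg$leaf[order(tg$position_t2)]
    expect_equal(attr(tg, "crossings"), brute_crossings(ord1, ord2))
    # barycenter passes never leave more crossings than the raw ladderized layout
    raw <- brute_crossings(domtol:::.ladder_order(a), domtol:::.ladder_order(b))
    expect_lte(attr(tg, "crossings"), raw)
  }
})
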