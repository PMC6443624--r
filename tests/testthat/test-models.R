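test_that("ordered stepmatrix is the additive |i-j| model", {
  s <- ordered_stepmatrix(5)
  expect_equal(s$cost[1, 3], 2) # states 0 and 2: two steps
  expect_equal(s$cost[3, 1], 2)
  expect_equal(s$cost[1, 5], 4) # states 0 and 4: four steps
  expect_equal(s$cost[5, 1], 4)
  expect_true(s$symmetric)
  s32 <- ordered_stepmatrix(32)
  expect_true(all(diag(s32$cost) == 0))
  expect_equal(s32$cost, abs(outer(0:31, 0:31, `-`)), ignore_attr = TRUE)
})

test_that("unordered stepmatrix has unit costs and 992 directed transformations", {
  u <- unordered_stepmatrix(32)
  expect_equal(u$cost[1, 32], 1)
  expect_equal(sum(u$cost != 0), 992)
  expect_true(u$symmetric)
  expect_equal(unordered_stepmatrix(2)$cost, ordered_stepmatrix(2)$cost,
               ignore_attr = TRUE)
})

test_that("gain-penalty stepmatrices tax gains per the occurrence/abundance rules", {
  occ <- hk_stepmatrix(2, "occurrence")
  expect_equal(occ$cost[1, 2], 2) # gain 0 -> 1 taxed twice
  expect_equal(occ$cost[2, 1], 1) # loss unpenalized
  expect_false(occ$symmetric)

  ab <- hk_stepmatrix(32, "abundance")
  expect_false(ab$symmetric)
  expect_equal(sum(ab$cost == 3), 31) # all first-gain 0 -> j cells
  expect_equal(sum(ab$cost == 3) / 992, 0.031, tolerance = 0.01) # ~3%
  expect_true(all(ab$cost[1, -1] == 3))
  expect_equal(ab$cost[6, 1], 1) # loss 5 -> 0 stays baseline
  expect_true(all(ab$cost[-1, ][ab$cost[-1, ] != 0] == 1))

  ab1 <- hk_stepmatrix(32, "abundance", first_gain_only = TRUE)
  expect_equal(sum(ab1$cost == 3), 1)
  expect_error(hk_stepmatrix(3, "abundance"), "n = 32")
  expect_error(hk_stepmatrix(32, "occurrence"), "n = 2")
})

test_that("wheeler stepmatrix inverts frequency into cost with cap and pseudocount", {
  f <- matrix(0, 4, 4)
  f[1, 2] <- 40; f[1, 3] <- 40; f[2, 3] <- 5
  w <- wheeler_stepmatrix(f)
  expect_equal(w$cost[1, 2], 1) # most frequent change costs one step
  expect_equal(w$cost[1, 3], 1)
  expect_true(w$cost[2, 3] > 1 && w$cost[2, 3] < w$cost[3, 2])
  expect_true(all(diag(w$cost) == 0))
  # unobserved cell with astronomically dominant maximum hits the cap
  f2 <- matrix(0, 3, 3); f2[1, 2] <- 1e15
  expect_equal(wheeler_stepmatrix(f2)$cost[2, 1], 32)
  # antitone in frequency
  costs <- vapply(c(0, 1, 5, 20, 40), function(v) {
    f3 <- f; f3[3, 1] <- v
    wheeler_stepmatrix(f3)$cost[3, 1]
  }, numeric(1))
  expect_true(all(diff(costs) <= 0))
  expect_error(wheeler_stepmatrix(matrix(0, 3, 3)), "zero")
})

test_that("a uniform frequency matrix yields a model Sankoff-equivalent to unordered", {
  f <- matrix(7, 5, 5); diag(f) <- 0
  w <- wheeler_stepmatrix(f)
  off <- w$cost[row(w$cost) != col(w$cost)]
  expect_true(all(off == off[1]))
  tr <- rand_topology(6, seed = 2)
  m <- rand_coded(6, 4, 5, seed = 3)
  expect_equal(as.numeric(sankoff_length(tr, m, w)),
               off[1] * as.numeric(sankoff_length(tr, m, unordered_stepmatrix(5))))
})

test_that("triangle-inequality audit is exhaustive and correct", {
  expect_equal(nrow(audit_triangle_inequality(ordered_stepmatrix(32))), 0)
  expect_equal(nrow(audit_triangle_inequality(unordered_stepmatrix(32))), 0)
  expect_true(ordered_stepmatrix(32)$satisfies_triangle_inequality)
  s <- stepmatrix(matrix(c(0, 1, 5, 1, 0, 1, 5, 1, 0), 3, 3), "bad")
  v <- audit_triangle_inequality(s)
  expect_true(nrow(v) > 0)
  expect_true(any(v$i == 0 & v$k == 1 & v$j == 2 & v$direct == 5 & v$via == 2))
  expect_false(s$satisfies_triangle_inequality)
  # brute-force cross-check on a random asymmetric matrix
  set.seed(9)
  cm <- matrix(sample(1:6, 25, TRUE), 5, 5); diag(cm) <- 0
  sa <- stepmatrix(cm, "rand")
  au <- audit_triangle_inequality(sa)
  brute <- 0L
  for (i in 1:5) for (k in 1:5) for (j in 1:5) {
    if (cm[i, j] > cm[i, k] + cm[k, j] + 1e-12) brute <- brute + 1L
  }
  expect_equal(nrow(au), brute)
  # the 31-cell first-gain penalty itself is metric-consistent: every detour
  # out of state 0 also pays the penalty (3 <= 3 + 1); the audit exists so
  # that alternative published penalty variants can be tested the same way
  expect_true(hk_stepmatrix(32, "abundance")$satisfies_triangle_inequality)
})

test_that("stepmatrix TSV round-trips", {
  s <- hk_stepmatrix(32, "abundance")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stepmatrix_tsv(s, path)
  back <- read_stepmatrix_tsv(path, name = "hk")
  expect_equal(back$cost, s$cost, ignore_attr = TRUE)
})
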