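test_that("the event log reconciles exactly with parent/child counts", {
  cfg <- sim_config(n_taxa = 8, n_fsf_initial = 10, seed = 7)
  sim <- simulate_proteomes(cfg)
  ev <- sim$events[!grepl("new", sim$events$fsf), ]
  expect_true(all(ev$child_count == ev$parent_count + ev$births - ev$deaths))
  expect_true(all(unclass(sim$abundance) >= 0))
})

test_that("degenerate rate settings behave as contracted", {
  # no events at all: leaves equal the root profile
  cfg0 <- sim_config(n_taxa = 6, n_fsf_initial = 8, lambda = 0, mu = 0, a = 0,
                     seed = 3)
  sim0 <- simulate_proteomes(cfg0)
  root_counts <- sim0$node_profiles[[domtol:::.root_node(sim0$tree)]]
  for (i in seq_len(nrow(sim0$abundance))) {
    expect_identical(unname(unclass(sim0$abundance)[i, names(root_counts)]),
                     as.integer(unname(root_counts)))
  }
  # pure birth: abundance non-decreasing from root to every leaf
  cfgb <- sim_config(n_taxa = 8, n_fsf_initial = 10, mu = 0, a = 0, seed = 4)
  simb <- simulate_proteomes(cfgb)
  rootb <- simb$node_profiles[[domtol:::.root_node(simb$tree)]]
  for (i in seq_len(nrow(simb$abundance))) {
    expect_true(all(unclass(simb$abundance)[i, names(rootb)] >= unname(rootb)))
  }
})

test_that("growth-dominated rates inflate proteomes beyond the root total", {
  totals <- vapply(1:30, function(r) {
    cfg <- sim_config(n_taxa = 5, n_fsf_initial = 8, depth = 3, seed = 100 + r)
    sim <- simulate_proteomes(cfg)
    root <- sim$node_profiles[[domtol:::.root_node(sim$tree)]]
    mean(rowSums(unclass(sim$abundance))) - sum(root)
  }, numeric(1))
  se <- stats::sd(totals) / sqrt(length(totals))
  expect_gt(mean(totals), 2 * se)
})

test_that("innovation volume scales roughly linearly with the innovation rate", {
  a_grid <- c(0.005, 0.01, 0.02, 0.05)
  mean_innov <- vapply(a_grid, function(a) {
    mean(vapply(1:6, function(r) {
      cfg <- sim_config(n_taxa = 6, n_fsf_initial = 10, a = a, seed = 1000 + r)
      sim <- simulate_proteomes(cfg)
      as.numeric(ncol(sim$abundance) - 10L)
    }, numeric(1)))
  }, numeric(1))
  fit <- lm(mean_innov ~ a_grid)
  expect_gt(coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.8)
})

test_that("simulation is deterministic given the seed and labels three groups", {
  cfg <- sim_config(n_taxa = 9, n_fsf_initial = 8, rogue_fraction = 0.2, seed = 12)
  s1 <- simulate_proteomes(cfg)
  s2 <- simulate_proteomes(cfg)
  expect_identical(unclass(s1$abundance)[, ], unclass(s2$abundance)[, ])
  expect_identical(s1$events, s2$events)
  expect_equal(sort(unique(unname(taxon_groups(s1$abundance)))),
               c("Archaea", "Bacteria", "Eukarya"))
  expect_length(s1$rogues, 2L)
})

test_that("rogue leaves lose domain copies relative to their peers", {
  diffs <- vapply(1:12, function(r) {
    cfg <- sim_config(n_taxa = 10, n_fsf_initial = 12, mu = 0.15,
                      rogue_fraction = 0.2, rogue_mu_factor = 10, seed = 2000 + r)
    sim <- simulate_proteomes(cfg)
    tot <- rowSums(unclass(sim$abundance))
    mean(tot[!(names(tot) %in% sim$rogues)]) - mean(tot[sim$rogues])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("gain-biased simulations root significantly above chance under all-0 Lundberg", {
  cfg <- sim_config(n_taxa = 8, n_fsf_initial = 10, seed = 41)
  b <- suppressWarnings(rooting_recovery_benchmark(cfg, reps = 10, n_states = 16))
  row <- b[b$method == "lundberg-all0", ]
  expect_gt(row$fraction, row$chance)
  expect_lt(row$p_value, 0.05)
  expect_equal(b$reps, rep(10L, nrow(b)))
})

test_that("symmetric drift leaves rooting methods near chance", {
  cfg <- sim_config(n_taxa = 8, n_fsf_initial = 10, lambda = 0.3, mu = 0.3,
                    a = 0.005, seed = 61)
  b <- suppressWarnings(rooting_recovery_benchmark(cfg, reps = 10, n_states = 16))
  # no method should look overwhelmingly better than chance on drifty data
  expect_true(all(b$p_value > 1e-4))
})

test_that("clade indicator characters are perfect by construction", {
  pd <- perfect_dataset(8)
  fi <- ensemble_indices(ape::unroot(pd$tree), pd$m, "ordered")
  expect_equal(fi$RI, 1)
})
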