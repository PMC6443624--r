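# Synthetic proteome evolution: per-FSF linear birth-death copy-number
# dynamics with rare innovation of new FSFs, simulated event-by-event
# (Gillespie) along a known rooted tree so that the event log reconciles
# exactly with the leaf counts.

#' Configuration for the proteome simulator
#'
#' Defines the generative regime: a rooted tree, a sparse ancestral proteome,
#' and three per-copy rates. `lambda` is the birth (duplication) rate of
#' copies of an existing FSF, `mu` the per-copy loss rate, and `a` the
#' innovation rate at which an existing copy founds a brand-new FSF (a
#' column that starts at count 1 in that lineage). The regime of interest is
#' gain-biased growth with rare innovation, `a << lambda` and
#' `mu < lambda`; the defaults encode that regime at desk scale, producing
#' leaf abundances from 0 to the low hundreds with heavy-tailed per-FSF
#' distributions. Taxa are labeled with three groups (the two root clades
#' and the larger one split once more), mimicking three superkingdoms;
#' `rogue_fraction` designates parasite-like leaves whose pendant branches
#' lose copies at `rogue_mu_factor * mu`.
#'
#' @param n_taxa Number of leaves.
#' @param n_fsf_initial Number of FSFs seeded (at small counts) in the root
#'   proteome.
#' @param tree_shape `"birth-death"`, `"balanced"` or `"caterpillar"`.
#' @param depth Total root-to-tip height of the (rescaled) tree, in units of
#'   1/rate.
#' @param lambda,mu,a Per-copy birth, death and innovation rates.
#' @param root_profile `"seeded"` (counts drawn in 1..root_max_count) or an
#'   explicit named integer vector of root counts.
#' @param root_max_count Upper bound of the seeded root counts.
#' @param rogue_fraction Fraction of leaves designated rogue.
#' @param rogue_mu_factor Loss-rate multiplier on rogue pendant branches.
#' @param group_labels Labels for the three basal clades.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 16L, n_fsf_initial = 12L,
                       tree_shape = c("birth-death", "balanced", "caterpillar"),
                       depth = 5, lambda = 0.6, mu = 0.06, a = 0.01,
                       root_profile = "seeded", root_max_count = 3L,
                       rogue_fraction = 0, rogue_mu_factor = 10,
                       group_labels = c("Archaea", "Bacteria", "Eukarya"),
                       seed = NULL) {
  tree_shape <- match.arg(tree_shape)
  if (is.null(seed)) abort("`seed` is mandatory in a simulation config.")
  if (lambda < 0 || mu < 0 || a < 0) abort("Rates must be non-negative.")
  if (n_taxa < 4L) abort("Need at least 4 taxa.")
  structure(
    list(n_taxa = as.integer(n_taxa), n_fsf_initial = as.integer(n_fsf_initial),
         tree_shape = tree_shape, depth = depth, lambda = lambda, mu = mu,
         a = a, root_profile = root_profile,
         root_max_count = as.integer(root_max_count),
         rogue_fraction = rogue_fraction, rogue_mu_factor = rogue_mu_factor,
         group_labels = group_labels, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# simulated topology with unit-comparable branch lengths, rescaled to depth
.sim_tree <- function(cfg) {
  tree <- switch(cfg$tree_shape,
    "birth-death" = ape::rphylo(cfg$n_taxa, birth = 1, death = 0),
    "balanced" = ape::stree(cfg$n_taxa, "balanced"),
    "caterpillar" = ape::stree(cfg$n_taxa, "left")
  )
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  tree$tip.label <- paste0("t", seq_len(cfg$n_taxa))
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length * cfg$depth / max(depths)
  tree
}

# evolve one lineage's count vector over branch length `len`;
# returns list(counts, births, deaths, innovations(vector of new counts))
.evolve_branch <- function(counts, len, lambda, mu, a) {
  n_new <- 0L
  new_counts <- integer(0)
  births <- integer(length(counts))
  deaths <- integer(length(counts))
  t <- 0
  repeat {
    all_counts <- c(counts, new_counts)
    total <- sum(all_counts)
    rate <- total * (lambda + mu + a)
    if (rate <= 0) break
    t <- t + rexp(1L, rate)
    if (t > len) break
    j <- sample.int(length(all_counts), 1L, prob = all_counts)
    u <- runif(1L)
    if (u < lambda / (lambda + mu + a)) {
      if (j <= length(counts)) births[j] <- births[j] + 1L
      if (j <= length(counts)) counts[j] <- counts[j] + 1L else
        new_counts[j - length(counts)] <- new_counts[j - length(counts)] + 1L
    } else if (u < (lambda + mu) / (lambda + mu + a)) {
      if (j <= length(counts)) { deaths[j] <- deaths[j] + 1L; counts[j] <- counts[j] - 1L }
      else new_counts[j - length(counts)] <- new_counts[j - length(counts)] - 1L
    } else {
      n_new <- n_new + 1L
      new_counts <- c(new_counts, 1L)
    }
  }
  list(counts = counts, births = births, deaths = deaths,
       innovations = new_counts)
}

#' Simulate proteome FSF abundance along a tree
#'
#' Runs the birth-death-innovation process of [sim_config()] down a known
#' rooted tree and returns the leaf abundance matrix, the true tree, and a
#' per-branch event log whose totals reconcile exactly with the count
#' differences between parent and child (conservation: child count = parent
#' count + births - deaths for every pre-existing FSF).
#'
#' @param cfg A [sim_config()].
#' @return A `sim_result`: list with `tree` (rooted `phylo`), `abundance`
#'   ([abundance_matrix()] with group labels), `events` (tibble), `config`.
#' @export
simulate_proteomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    tree <- .sim_tree(cfg)
    if (all(tree$edge.length == 0) && (cfg$lambda + cfg$mu + cfg$a) > 0) {
      warn("All branch lengths are zero: no evolution will occur.")
    }
    n <- length(tree$tip.label)
    root_counts <- if (is.character(cfg$root_profile) && cfg$root_profile == "seeded") {
      setNames(sample.int(cfg$root_max_count, cfg$n_fsf_initial, replace = TRUE),
               paste0("FSF", seq_len(cfg$n_fsf_initial)))
    } else {
      stats::setNames(as.integer(cfg$root_profile), names(cfg$root_profile))
    }
    rogues <- character(0)
    if (cfg$rogue_fraction > 0) {
      k <- max(1L, round(cfg$rogue_fraction * n))
      rogues <- sample(tree$tip.label, k)
    }
    tree_po <- ape::reorder.phylo(tree, "postorder")
    root <- tree_po$edge[nrow(tree_po$edge), 1]
    profiles <- vector("list", n + tree_po$Nnode)
    profiles[[root]] <- root_counts
    events <- list()
    fsf_counter <- length(root_counts)
    # preorder traversal = reverse postorder of edges
    for (k in rev(seq_len(nrow(tree_po$edge)))) {
      p <- tree_po$edge[k, 1]; ch <- tree_po$edge[k, 2]
      len <- tree_po$edge.length[k]
      parent_counts <- profiles[[p]]
      mu_here <- cfg$mu
      if (ch <= n && tree_po$tip.label[ch] %in% rogues) {
        mu_here <- cfg$mu * cfg$rogue_mu_factor
      }
      ev <- .evolve_branch(unname(parent_counts), len, cfg$lambda, mu_here, cfg$a)
      child_counts <- setNames(ev$counts, names(parent_counts))
      if (length(ev$innovations)) {
        keep <- ev$innovations > 0L
        if (any(keep)) {
          new_ids <- paste0("FSF", fsf_counter + seq_len(sum(keep)))
          child_counts <- c(child_counts, setNames(as.integer(ev$innovations[keep]), new_ids))
        }
        fsf_counter <- fsf_counter + length(ev$innovations)
      }
      profiles[[ch]] <- child_counts
      branch_label <- if (ch <= n) tree_po$tip.label[ch] else paste0("node", ch)
      events[[length(events) + 1L]] <- tibble::tibble(
        branch = branch_label,
        fsf = names(parent_counts),
        births = ev$births,
        deaths = ev$deaths,
        parent_count = unname(parent_counts),
        child_count = unname(child_counts[names(parent_counts)])
      )
      if (length(ev$innovations)) {
        events[[length(events) + 1L]] <- tibble::tibble(
          branch = branch_label,
          fsf = paste0("[new x", length(ev$innovations), "]"),
          births = 0L, deaths = 0L,
          parent_count = 0L,
          child_count = as.integer(sum(ev$innovations > 0L))
        )
      }
    }
    all_fsf <- unique(unlist(lapply(profiles[seq_len(n)], names)))
    counts <- matrix(0L, n, length(all_fsf),
                     dimnames = list(tree_po$tip.label, all_fsf))
    for (i in seq_len(n)) {
      pr <- profiles[[i]]
      counts[i, names(pr)] <- as.integer(pr)
    }
    groups <- .three_group_labels(tree, cfg$group_labels)
    structure(
      list(tree = tree,
           abundance = abundance_matrix(counts, groups = groups),
           events = dplyr::bind_rows(events),
           rogues = rogues,
           node_profiles = profiles,
           config = cfg),
      class = "sim_result"
    )
  })
}

# label the three basal-most clades of a rooted tree
.three_group_labels <- function(tree, labels) {
  n <- length(tree$tip.label)
  sets <- .node_tipsets(tree)
  root <- .root_node(tree)
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  sides <- lapply(kids, function(k) sets[[k]])
  big <- which.max(lengths(sides))
  clades <- sides[-big]
  big_node <- kids[big]
  big_kids <- tree$edge[tree$edge[, 1] == big_node, 2]
  clades <- c(clades, lapply(big_kids, function(k) sets[[k]]))
  clades <- clades[order(-lengths(clades))]
  out <- rep(labels[1], n)
  for (i in seq_along(clades)) {
    out[clades[[i]]] <- labels[min(i, length(labels))]
  }
  setNames(out, tree$tip.label)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", nrow(x$abundance), " proteomes x ", ncol(x$abundance),
      " FSFs; lambda=", x$config$lambda, ", mu=", x$config$mu,
      ", a=", x$config$a, ", seed=", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' @export
glance.sim_result <- function(x, ...) {
  tibble::tibble(
    n_taxa = nrow(x$abundance), n_fsf = ncol(x$abundance),
    total_abundance = sum(x$abundance),
    n_innovations = ncol(x$abundance) - x$config$n_fsf_initial,
    lambda = x$config$lambda, mu = x$config$mu, a = x$config$a,
    seed = x$config$seed
  )
}

#' Benchmark root-recovery of alternative rooting methods
#'
#' For each replicate: simulate proteomes on a known rooted tree, encode the
#' abundance matrix, search for optimal unrooted trees under ordered
#' characters, and root the best tree by each method (Lundberg all-`0`,
#' Lundberg `"standard"`, and the intrinsic rooting of the asymmetric
#' gain-penalty stepmatrix). A method scores a success when the bipartition
#' of its chosen root edge matches the true root bipartition or that of an
#' edge adjacent to the true root. Chance level is 1 / (number of edges).
#'
#' @param cfg A [sim_config()] (its seed anchors all replicates).
#' @param reps Number of replicates.
#' @param methods Subset of `c("lundberg-all0", "lundberg-standard", "hk")`.
#' @param n_states Alphabet size used by the encoder.
#' @param search_replicates Random-addition replicates per search.
#' @return A tibble: method, successes, reps, fraction, binomial standard
#'   error, chance level, and one-sided p-value against chance.
#' @export
rooting_recovery_benchmark <- function(cfg, reps = 20L,
                                       methods = c("lundberg-all0",
                                                   "lundberg-standard", "hk"),
                                       n_states = 32L,
                                       search_replicates = 2L) {
  methods <- match.arg(methods, several.ok = TRUE)
  succ <- setNames(numeric(length(methods)), methods)
  n_edges_sum <- 0
  for (r in seq_len(reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    sim <- simulate_proteomes(cfg_r)
    m <- encode_abundance(sim$abundance, n_states = n_states)
    sr <- heuristic_search(m, "ordered", n_replicates = search_replicates,
                           seed = cfg$seed + 1000L + r)
    best <- sr$best_trees[[1]]
    target <- .root_neighborhood_keys(sim$tree)
    n_edges_sum <- n_edges_sum + nrow(ape::unroot(sim$tree)$edge)
    for (meth in methods) {
      rooted <- switch(meth,
        "lundberg-all0" = lundberg_root(best, m, "ordered", ancestor = "0")$rooted_tree,
        "lundberg-standard" = {
          rr <- lundberg_root(best, m, "ordered", ancestor = "standard")
          # the standard (all-missing) ancestor ties everywhere; resolve
          # operationally as the all-0 rooting, keeping the tie set on record
          if (length(rr$ties) == nrow(rr$scoring_tree$edge)) {
            lundberg_root(best, m, "ordered", ancestor = "0")$rooted_tree
          } else {
            rr$rooted_tree
          }
        },
        "hk" = {
          es <- .edge_root_scores(best, .leaf_states(best, m),
                                  hk_stepmatrix(32L, "abundance")$cost)
          .root_on_edge(es$tree, which.min(es$totals))
        }
      )
      if (.root_split_key(rooted) %in% target) succ[meth] <- succ[meth] + 1
    }
  }
  n_reps <- reps
  chance_p <- min(1, 5 / (n_edges_sum / n_reps)) # root edge + <= 4 neighbors
  frac <- succ / n_reps
  pvals <- vapply(succ, function(s) {
    stats::binom.test(s, n_reps, p = chance_p,
                      alternative = "greater")$p.value
  }, numeric(1))
  tibble::tibble(
    method = methods,
    successes = as.integer(succ),
    reps = n_reps,
    fraction = unname(frac),
    se = unname(sqrt(pmax(frac * (1 - frac), 1e-12) / n_reps)),
    chance = chance_p,
    p_value = unname(pvals)
  )
}

#' Homoplasy-free clade-indicator characters for a known tree
#'
#' Builds a coded matrix in which each character marks one clade of the
#' given rooted tree with a constant positive state (0 outside). Such
#' characters are mutually compatible gain-only indicators: the tree is
#' their unique most parsimonious topology, the retention index is 1, and a
#' Lundberg all-`0` rooting recovers the true root. Used to exercise
#' clean-data guarantees (search exactness, refinement stability).
#'
#' @param tree A rooted `phylo` tree.
#' @param state Positive state assigned inside each clade (default 3).
#' @param n_states Alphabet size of the result.
#' @return A [coded_matrix()] with one character per internal clade
#'   (including both root children).
#' @export
clade_indicator_matrix <- function(tree, state = 3L, n_states = 32L) {
  if (!ape::is.rooted(tree)) abort("Need a rooted tree.")
  n <- length(tree$tip.label)
  sets <- .node_tipsets(tree)
  root <- .root_node(tree)
  nodes <- c(tree$edge[tree$edge[, 1] == root, 2][1],
             setdiff(unique(tree$edge[, 1]), root))
  X <- vapply(nodes, function(v) {
    z <- rep(0L, n)
    z[sets[[v]]] <- as.integer(state)
    z
  }, integer(n))
  rownames(X) <- tree$tip.label
  colnames(X) <- paste0("clade", seq_along(nodes))
  coded_matrix(X, n_states = n_states,
               coding_params = list(generator = "clade_indicator",
                                    state = state))
}

# bipartition key of a rooted tree's root split (smaller side, sorted labels)
.root_split_key <- function(rt) {
  n <- length(rt$tip.label)
  sets <- .node_tipsets(rt)
  root <- .root_node(rt)
  kids <- rt$edge[rt$edge[, 1] == root, 2]
  side <- rt$tip.label[sets[[kids[1]]]]
  other <- setdiff(rt$tip.label, side)
  pick <- if (length(side) < length(other) ||
              (length(side) == length(other) && paste(sort(side), collapse = ",") <
               paste(sort(other), collapse = ","))) side else other
  paste(sort(pick), collapse = ",")
}

# keys of the true root edge and its adjacent edges, as unrooted bipartitions
.root_neighborhood_keys <- function(true_rooted) {
  un <- ape::unroot(true_rooted)
  labs <- un$tip.label
  sets <- .node_tipsets(un)
  keyify <- function(tipidx) {
    side <- labs[tipidx]
    other <- setdiff(labs, side)
    pick <- if (length(side) < length(other) ||
                (length(side) == length(other) && paste(sort(side), collapse = ",") <
                 paste(sort(other), collapse = ","))) side else other
    paste(sort(pick), collapse = ",")
  }
  root_key <- .root_split_key(true_rooted)
  # edges whose bipartition matches the root split, plus adjacent edges
  keys <- vapply(seq_len(nrow(un$edge)), function(k) keyify(sets[[un$edge[k, 2]]]),
                 character(1))
  hit <- which(keys == root_key)
  adj <- integer(0)
  for (k in hit) {
    p <- un$edge[k, 1]; ch <- un$edge[k, 2]
    adj <- c(adj, which(un$edge[, 1] %in% c(p, ch) | un$edge[, 2] %in% c(p, ch)))
  }
  unique(keys[unique(c(hit, adj))])
}
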