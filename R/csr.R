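# Character-state reconstruction (CSR): most-parsimonious-reconstruction
# state sets per node, unambiguous change counting, and the one-round
# dynamic-weighting refinement loop.

#' Ancestral state sets under generalized parsimony
#'
#' For every node and character, computes the set of states assigned by at
#' least one most-parsimonious reconstruction (MPR) under the stepmatrix:
#' bottom-up Sankoff cost vectors are combined with a top-down pass carrying
#' the cost of the rest of the tree, and a state is in the set iff its total
#' equals the tree length. Leaf sets are singletons (the full state set when
#' missing). Requires a rooted tree; with asymmetric models the root's state
#' is the free minimum.
#'
#' @param rt A rooted `phylo` tree.
#' @inheritParams sankoff_length
#' @param model A [stepmatrix()] or model name.
#' @return A `reconstruction_result`: postorder tree, per-character logical
#'   state-set matrices (`state` x `node`), per-character lengths.
#' @export
reconstruct_states <- function(rt, m, model = "ordered") {
  if (!ape::is.rooted(rt)) abort("Character-state reconstruction needs a rooted tree.")
  ns <- attr(m, "n_states")
  mod <- .resolve_model(model, ns)
  cost <- mod$step$cost
  X <- .leaf_states(rt, m)
  dp <- .sankoff_down(rt, X, cost, keep_contrib = TRUE)
  tree <- dp$tree
  total_nodes <- dp$n_tip + tree$Nnode
  ne <- nrow(tree$edge)
  tcost <- t(cost)
  # U[state, node, char]: minimal cost of everything outside the node's
  # subtree, conditional on the node's state
  U <- array(0, dim = c(dp$ns, total_nodes, dp$C))
  for (k in rev(seq_len(ne))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    A <- matrix(U[, p, ], nrow = dp$ns) + matrix(dp$D[, p, ], nrow = dp$ns) -
      matrix(dp$contrib[, k, ], nrow = dp$ns)
    U[, ch, ] <- .minplus(tcost, A)
  }
  per_char <- .root_char_lengths(dp)
  sets <- vector("list", dp$C)
  for (j in seq_len(dp$C)) {
    tot <- matrix(U[, , j], nrow = dp$ns) + matrix(dp$D[, , j], nrow = dp$ns)
    sets[[j]] <- sweep(tot, 2L, per_char[j] + .domtol_tol, `<=`)
  }
  names(sets) <- colnames(m)
  structure(
    list(tree = tree, state_sets = sets,
         per_character_length = setNames(per_char, colnames(m)),
         total_length = sum(per_char), model = mod$name, n_states = dp$ns),
    class = "reconstruction_result"
  )
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat("<reconstruction_result> model '", x$model, "', ",
      length(x$state_sets), " characters, total length ",
      format(x$total_length, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Count unambiguous state changes along branches
#'
#' Tallies reconstructed character-state transformations: a branch
#' contributes one event to cell (i, j) of the change-frequency matrix iff
#' its parent and child MPR state sets are the singletons \{i\} and \{j\}
#' with i != j — the change is then identical across every
#' most-parsimonious reconstruction ("unambiguous"). Branches with any
#' ambiguous endpoint are tallied separately. A transformation under an
#' ordered model counts as one i -> j event (not |i - j| unit steps): the
#' frequencies describe state pairs, not steps. When several tied optimal
#' trees are supplied, counts are averaged over trees so datasets with
#' different numbers of optima stay comparable.
#'
#' @param r A `reconstruction_result`, or a list of them (tied trees).
#' @param exclude_leaves Leaf labels whose pendant branches are not counted
#'   (default `".ANC"`, the hypothetical ancestor attached by
#'   [lundberg_root()]).
#' @return A `change_frequency_matrix`: `counts` (n x n), `relative`
#'   frequencies, the `ambiguous` branch-character tally, and `n_trees`.
#' @export
change_frequencies <- function(r, exclude_leaves = ".ANC") {
  rs <- if (inherits(r, "reconstruction_result")) list(r) else r
  ns <- rs[[1]]$n_states
  acc <- matrix(0, ns, ns)
  ambiguous <- 0
  for (rec in rs) {
    tree <- rec$tree
    n <- length(tree$tip.label)
    skip <- match(intersect(exclude_leaves, tree$tip.label), tree$tip.label)
    counts <- matrix(0, ns, ns)
    amb <- 0
    for (sets in rec$state_sets) {
      sizes <- colSums(sets)
      for (k in seq_len(nrow(tree$edge))) {
        p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
        if (ch %in% skip) next
        if (sizes[p] == 1L && sizes[ch] == 1L) {
          i <- which(sets[, p]); j <- which(sets[, ch])
          if (i != j) counts[i, j] <- counts[i, j] + 1
        } else {
          amb <- amb + 1
        }
      }
    }
    acc <- acc + counts
    ambiguous <- ambiguous + amb
  }
  acc <- acc / length(rs)
  ambiguous <- ambiguous / length(rs)
  dimnames(acc) <- rep(list(state_alphabet(max(2L, ns))$symbols[seq_len(ns)]), 2L)
  total <- sum(acc)
  structure(
    list(counts = acc, relative = if (total > 0) acc / total else acc,
         total = total, ambiguous = ambiguous, n_trees = length(rs),
         n_states = ns),
    class = "change_frequency_matrix"
  )
}

#' @export
print.change_frequency_matrix <- function(x, ...) {
  cat("<change_frequency_matrix> ", x$n_states, " states, ",
      format(x$total, digits = 6), " unambiguous change(s) (averaged over ",
      x$n_trees, " tree(s)), ", format(x$ambiguous, digits = 6),
      " ambiguous branch-characters\n", sep = "")
  up <- sum(x$counts[upper.tri(x$counts)])
  lo <- sum(x$counts[lower.tri(x$counts)])
  cat("gains (upper triangle): ", format(up, digits = 6),
      "; losses (lower triangle): ", format(lo, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.change_frequency_matrix <- function(x, ...) {
  syms <- rownames(x$counts)
  out <- tidyr::expand_grid(from = factor(syms, levels = syms),
                            to = factor(syms, levels = syms))
  out$count <- as.vector(t(x$counts))
  out$relative_frequency <- as.vector(t(x$relative))
  dplyr::filter(out, .data$from != .data$to)
}

#' @export
autoplot.change_frequency_matrix <- function(object, ...) {
  df <- dplyr::filter(tidy.change_frequency_matrix(object), .data$count > 0)
  ggplot(df, aes(x = .data$to, y = .data$from, size = .data$relative_frequency)) +
    geom_point(alpha = 0.7) +
    scale_size_area(max_size = 8) +
    labs(title = "Reconstructed change frequencies",
         x = "derived state", y = "ancestral state",
         size = "relative frequency") +
    theme_minimal()
}

#' Export a change-frequency matrix as TSV (wide or long)
#' @param x A `change_frequency_matrix`.
#' @param path Output path.
#' @param long Write the long (from, to, count, relative_frequency) format.
#' @export
write_change_frequencies <- function(x, path, long = FALSE) {
  if (long) {
    utils::write.table(as.data.frame(tidy.change_frequency_matrix(x)), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(x$counts, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  }
  invisible(path)
}

#' One-round dynamic weighting: derive a model from the data and refit
#'
#' Implements the iterative refinement loop used to audit character models:
#' search for optimal trees under an initial model, root them (intrinsically
#' for asymmetric models, by Lundberg all-`0` otherwise), reconstruct
#' ancestral states, count unambiguous change frequencies, convert the
#' frequencies into a Wheeler stepmatrix, and re-search under the derived
#' model. The topological distance between the initial tree T0 and the
#' refined tree T1 (hardwired cluster and hybridization distances)
#' quantifies how well the initial model matches the data: a stable topology
#' (cluster distance 0) indicates data-model fit.
#'
#' @param m A [coded_matrix()].
#' @param init_model Initial model ([stepmatrix()] or name).
#' @param search_opts List of options for [heuristic_search()] (`seed` is
#'   required; `n_replicates`, `swap`, `maxtrees` optional).
#' @param rounds Number of refinement rounds (the audit uses 1).
#' @param pseudocount,cap Passed to [wheeler_stepmatrix()].
#' @param max_reconstruct Cap on the number of tied trees used for
#'   frequency counting.
#' @return An `iteration_report`; see [glance.iteration_report()].
#' @export
dynamic_weighting_iterate <- function(m, init_model = "ordered",
                                      search_opts = list(), rounds = 1L,
                                      pseudocount = 0.5, cap = 32,
                                      max_reconstruct = 8L) {
  if (rounds < 1L) abort("`rounds` must be >= 1.")
  ns <- attr(m, "n_states")
  seed <- search_opts$seed
  if (is.null(seed)) abort("search_opts$seed is required.")
  do_search <- function(model, seed_offset) {
    heuristic_search(
      m, model,
      n_replicates = search_opts$n_replicates %||% 5L,
      seed = seed + seed_offset,
      swap = search_opts$swap %||% "NNI",
      maxtrees = search_opts$maxtrees %||% 20L
    )
  }
  rooted_rep <- function(sr, model) {
    mod <- .resolve_model(model, ns)
    if (!mod$step$symmetric) {
      list(rooted = sr$best_trees, with_anc = sr$best_trees, anc = FALSE)
    } else {
      rr <- lapply(sr$best_trees, function(t) lundberg_root(t, m, mod$step, ancestor = "0"))
      list(rooted = lapply(rr, `[[`, "rooted_tree"),
           with_anc = lapply(rr, `[[`, "rooted_tree_with_ancestor"),
           anc = TRUE)
    }
  }
  model <- init_model
  out_rounds <- vector("list", rounds)
  for (rd in seq_len(rounds)) {
    s0 <- do_search(model, seed_offset = rd - 1L)
    r0 <- rooted_rep(s0, model)
    trees_for_csr <- utils::head(r0$with_anc, max_reconstruct)
    m_csr <- if (r0$anc) .augmented_matrix(m, rep(0L, ncol(m))) else m
    recs <- lapply(trees_for_csr, function(t) reconstruct_states(t, m_csr, model))
    freq <- change_frequencies(recs)
    if (freq$total == 0) {
      abort(paste0("No unambiguous changes to derive a model from (",
                   format(freq$ambiguous, digits = 6),
                   " ambiguous branch-characters)."))
    }
    derived <- wheeler_stepmatrix(freq, pseudocount = pseudocount, cap = cap)
    s1 <- do_search(derived, seed_offset = 100L + rd - 1L)
    t0 <- r0$rooted[[1]]
    t1 <- s1$best_trees[[1]]
    cd <- cluster_distance(t0, t1)
    hd <- hybridization_distance(t0, t1)
    out_rounds[[rd]] <- list(
      init_model = .resolve_model(model, ns)$name,
      T0 = r0$rooted, T0_length = s0$length, T0_search = s0,
      frequency_matrix = freq, derived_stepmatrix = derived,
      T1 = s1$best_trees, T1_length = s1$length, T1_search = s1,
      cluster_distance = cd,
      hybridization_distance = hd,
      verdict = if (cd == 0) "stable" else "unstable"
    )
    model <- derived
  }
  structure(list(rounds = out_rounds, n_rounds = rounds, seed = seed),
            class = "iteration_report")
}

#' @export
print.iteration_report <- function(x, ...) {
  for (rd in seq_along(x$rounds)) {
    r <- x$rounds[[rd]]
    hd <- r$hybridization_distance
    hd_txt <- if (hd$method == "exact") as.character(hd$distance) else
      paste0("[", hd$lower, ", ", hd$upper, "]")
    cat("round ", rd, ": init '", r$init_model, "' T0 length ",
        format(r$T0_length, digits = 8), " -> refined T1 length ",
        format(r$T1_length, digits = 8), "; cluster distance ",
        r$cluster_distance, ", hybridization ", hd_txt, " => ", r$verdict,
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @rdname dynamic_weighting_iterate
#' @param x An `iteration_report`.
#' @param ... Unused.
glance.iteration_report <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$rounds), function(rd) {
    r <- x$rounds[[rd]]
    hd <- r$hybridization_distance
    tibble::tibble(
      round = rd, init_model = r$init_model,
      T0_length = r$T0_length, T1_length = r$T1_length,
      n_T0 = length(r$T0), n_T1 = length(r$T1),
      cluster_distance = r$cluster_distance,
      hybridization_distance = if (hd$method == "exact") hd$distance else NA_integer_,
      hybridization_lower = hd$lower, hybridization_upper = hd$upper,
      verdict = r$verdict
    )
  }))
}
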