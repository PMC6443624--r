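# Tree search under a parsimony model: random-addition starting trees with
# hill-climbing branch swapping, plus an exhaustive searcher used as oracle.

# normalize a model argument into a stepmatrix + scoring metadata
.resolve_model <- function(model, n_states) {
  if (is.character(model)) {
    model <- switch(model,
      ordered = ordered_stepmatrix(n_states),
      unordered = unordered_stepmatrix(n_states),
      hk = hk_stepmatrix(32L, "abundance"),
      `hk-abundance` = hk_stepmatrix(32L, "abundance"),
      `hk-occurrence` = hk_stepmatrix(2L, "occurrence"),
      abort(paste0("Unknown model name: ", model))
    )
  }
  if (!inherits(model, "stepmatrix")) abort("`model` must be a stepmatrix or model name.")
  idx <- seq_len(model$n) - 1L
  engine <- if (!model$symmetric) {
    "sankoff-rooted"
  } else if (isTRUE(all.equal(model$cost, abs(outer(idx, idx, `-`)) + 0,
                              check.attributes = FALSE))) {
    "wagner"
  } else if (all(model$cost[row(model$cost) != col(model$cost)] == 1)) {
    "fitch"
  } else {
    "sankoff"
  }
  char_type <- switch(engine, wagner = "ordered", fitch = "unordered", NA_character_)
  list(step = model, engine = engine, char_type = char_type, name = model$name)
}

# total-length scoring closure for unrooted topologies; asymmetric models
# score a topology at its best intrinsic rooting (min over root edges)
.score_fun <- function(mod, X, ns) {
  cost <- mod$step$cost
  # leaf rows must follow each candidate tree's own tip ordering
  switch(mod$engine,
    wagner = function(tree) {
      sum(.wagner_perchar(tree, X[tree$tip.label, , drop = FALSE], ns))
    },
    fitch = function(tree) {
      sum(.fitch_perchar(tree, X[tree$tip.label, , drop = FALSE], ns))
    },
    sankoff = function(tree) {
      dp <- .sankoff_down(tree, X[tree$tip.label, , drop = FALSE], cost)
      sum(.root_char_lengths(dp))
    },
    `sankoff-rooted` = function(tree) {
      min(.edge_root_scores(tree, X[tree$tip.label, , drop = FALSE], cost)$totals)
    }
  )
}

# unrooted starting tree by random stepwise addition
.random_addition_tree <- function(taxa, score) {
  ord <- sample(taxa)
  tree <- ape::read.tree(text = paste0("(", ord[1], ",", ord[2], ",", ord[3], ");"))
  for (tx in ord[-(1:3)]) {
    cands <- lapply(seq_len(nrow(tree$edge)), function(e) {
      .attach_leaf_on_edge(tree, e, tx)
    })
    lens <- vapply(cands, score, numeric(1))
    tree <- cands[[which.min(lens)]]
  }
  tree
}

# all NNI neighbors plus, optionally, subtree-prune-regraft neighbors;
# returned as a plain list of uncompressed phylo objects
.neighbors <- function(tree, swap) {
  nbs <- phangorn::nni(tree)
  out <- lapply(seq_along(nbs), function(i) nbs[[i]])
  if (swap == "SPR") out <- c(out, .spr_neighbors(tree))
  out
}

.spr_neighbors <- function(tree) {
  n <- length(tree$tip.label)
  sets <- .node_tipsets(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    tips_sub <- sets[[ch]]
    if (length(tips_sub) > n - 3L) next
    sub_labels <- tree$tip.label[tips_sub]
    remaining <- ape::drop.tip(tree, sub_labels)
    if (is.null(remaining) || length(remaining$tip.label) < 3L) next
    sub <- if (length(tips_sub) == 1L) NULL else ape::extract.clade(tree, ch)
    for (f in seq_len(nrow(remaining$edge))) {
      cand <- if (is.null(sub)) {
        .attach_leaf_on_edge(remaining, f, sub_labels)
      } else {
        .bind_on_edge(remaining, sub, f)
      }
      out <- c(out, list(cand))
    }
  }
  out
}

# graft rooted subtree `sub` onto the middle of edge `e` of `base`
.bind_on_edge <- function(base, sub, e) {
  nb <- length(base$tip.label); mb <- base$Nnode
  nsub <- length(sub$tip.label); msub <- sub$Nnode
  N <- nb + nsub
  map_base <- function(x) ifelse(x <= nb, x, x + nsub)
  w <- N + mb + 1L
  map_sub <- function(x) ifelse(x <= nsub, x + nb, x + nb + mb + 1L)
  edges <- cbind(map_base(base$edge[, 1]), map_base(base$edge[, 2]))
  p <- edges[e, 1]; ch <- edges[e, 2]
  edges <- edges[-e, , drop = FALSE]
  sub_root <- map_sub(nsub + 1L)
  edges <- rbind(edges, c(p, w), c(w, ch), c(w, sub_root),
                 cbind(map_sub(sub$edge[, 1]), map_sub(sub$edge[, 2])))
  out <- list(edge = edges, tip.label = c(base$tip.label, sub$tip.label),
              Nnode = mb + msub + 1L)
  class(out) <- "phylo"
  .normalize_phylo(out)
}

.new_search_result <- function(trees, length, mod, log, opts) {
  structure(
    list(best_trees = trees, length = length, model = mod$name,
         char_type = mod$char_type, log = log, opts = opts),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> model '", x$model, "': ", length(x$best_trees),
      " optimal tree(s), length ", format(x$length, digits = 8), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.search_result <- function(x, ...) {
  tibble::tibble(
    tree = seq_along(x$best_trees),
    length = x$length,
    rooted = vapply(x$best_trees, ape::is.rooted, logical(1)),
    newick = vapply(x$best_trees, function(t) ape::write.tree(t), character(1))
  )
}

#' @export
glance.search_result <- function(x, ...) {
  tibble::tibble(model = x$model, length = x$length,
                 n_trees = length(x$best_trees),
                 n_replicates = nrow(x$log),
                 seed = x$opts$seed %||% NA_integer_)
}

#' Heuristic maximum-parsimony tree search
#'
#' Searches tree space for most parsimonious trees by random-addition
#' starting trees followed by hill-climbing branch swapping. Symmetric
#' models (ordered/unordered/symmetric stepmatrices) are optimized over
#' unrooted topologies; asymmetric stepmatrices root trees intrinsically, so
#' each candidate topology is scored at its best root edge and the returned
#' optima are rooted. The search is deterministic given `seed`.
#'
#' @param m A [coded_matrix()].
#' @param model A [stepmatrix()] or one of `"ordered"`, `"unordered"`,
#'   `"hk"`, `"hk-occurrence"`.
#' @param n_replicates Number of random-addition replicates.
#' @param seed Integer seed (mandatory).
#' @param swap Branch-swapping neighborhood: `"NNI"` or `"SPR"`. (TBR is not
#'   provided; equal-optimum recovery, not a particular swap schedule, is the
#'   contract.)
#' @param maxtrees Retain at most this many tied optimal topologies.
#' @return A `search_result`: tied best trees, their length, and a search log.
#' @export
heuristic_search <- function(m, model = "ordered", n_replicates = 10L,
                             seed = NULL, swap = c("NNI", "SPR"),
                             maxtrees = 100L) {
  swap <- match.arg(swap)
  taxa_ids <- rownames(m)
  if (length(taxa_ids) < 4L) abort("Need at least 4 taxa to search.")
  ns <- attr(m, "n_states")
  mod <- .resolve_model(model, ns)
  X <- unclass(m)
  score <- .score_fun(mod, X, ns)
  .with_seed(seed, {
    finals <- vector("list", n_replicates)
    log <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      tree <- .random_addition_tree(taxa_ids, score)
      len <- score(tree)
      start_len <- len
      swaps <- 0L
      repeat {
        nb <- .neighbors(tree, swap)
        lens <- vapply(nb, score, numeric(1))
        if (min(lens) < len - .domtol_tol) {
          k <- which.min(lens)
          tree <- nb[[k]]; len <- lens[k]
          swaps <- swaps + 1L
        } else break
      }
      finals[[r]] <- list(tree = tree, length = len)
      log[[r]] <- tibble::tibble(replicate = r, start_length = start_len,
                                 final_length = len, n_swaps = swaps)
    }
    lens <- vapply(finals, function(f) f$length, numeric(1))
    best <- min(lens)
    seeds <- lapply(finals[lens <= best + .domtol_tol], function(f) f$tree)
    # breadth-first walk over the equal-length plateau to collect ties
    pool <- list()
    seen <- character(0)
    queue <- seeds
    while (length(queue) && length(pool) < maxtrees) {
      t0 <- queue[[1]]
      queue <- queue[-1]
      k0 <- .topo_key(t0)
      if (k0 %in% seen) next
      seen <- c(seen, k0)
      pool <- c(pool, list(t0))
      nb <- .neighbors(t0, swap)
      lens_nb <- vapply(nb, score, numeric(1))
      queue <- c(queue, nb[lens_nb <= best + .domtol_tol])
    }
    if (mod$engine == "sankoff-rooted") {
      pool <- lapply(pool, function(t) {
        es <- .edge_root_scores(t, X[t$tip.label, , drop = FALSE], mod$step$cost)
        .root_on_edge(es$tree, which.min(es$totals))
      })
    }
    .new_search_result(pool, best, mod, dplyr::bind_rows(log),
                       list(seed = seed, swap = swap,
                            n_replicates = n_replicates, maxtrees = maxtrees))
  })
}

#' Exhaustive maximum-parsimony search (oracle)
#'
#' Enumerates every unrooted binary topology on the taxa of `m` and scores
#' each under the model, guaranteeing the global optimum. Intended as a
#' desk-scale oracle: the number of topologies is (2n-5)!!, so the default
#' cap is 10 taxa.
#'
#' @inheritParams heuristic_search
#' @param max_taxa Refuse to enumerate beyond this many taxa.
#' @return A `search_result` containing all tied global optima.
#' @export
exact_search <- function(m, model = "ordered", max_taxa = 10L) {
  taxa_ids <- rownames(m)
  n <- length(taxa_ids)
  if (n < 4L) abort("Need at least 4 taxa.")
  if (n > max_taxa) abort(sprintf("Exhaustive search capped at %d taxa.", max_taxa))
  ns <- attr(m, "n_states")
  mod <- .resolve_model(model, ns)
  X <- unclass(m)
  score <- .score_fun(mod, X, ns)
  all_trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa_ids)
  lens <- vapply(all_trees, score, numeric(1))
  best <- min(lens)
  pool <- all_trees[lens <= best + .domtol_tol]
  pool <- lapply(pool, identity)
  if (mod$engine == "sankoff-rooted") {
    pool <- lapply(pool, function(t) {
      es <- .edge_root_scores(t, X[t$tip.label, , drop = FALSE], mod$step$cost)
      .root_on_edge(es$tree, which.min(es$totals))
    })
  }
  .new_search_result(pool, best, mod,
                     tibble::tibble(replicate = 1L, start_length = NA_real_,
                                    final_length = best,
                                    n_swaps = NA_integer_),
                     list(n_topologies = length(all_trees)))
}
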