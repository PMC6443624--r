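# Generalized (Sankoff) stepmatrix parsimony: dynamic programming over a
# tree, vectorized across characters. States are 0-based everywhere; rows of
# a cost matrix are parent states, columns are child states.

# min-plus product: out[i, c] = min_j (S[i, j] + V[j, c])
.minplus <- function(S, V) {
  n <- nrow(S)
  V <- matrix(V, nrow = n)
  out <- matrix(Inf, n, ncol(V))
  for (j in seq_len(n)) {
    v <- V[j, ]
    if (all(v == Inf)) next
    out <- pmin(out, outer(S[, j], v, `+`))
  }
  out
}

# leaf state matrix in tip order: taxa x characters, NA = missing
.leaf_states <- function(tree, m) {
  .check_leaves(tree, m)
  unclass(m)[tree$tip.label, , drop = FALSE]
}

# bottom-up cost vectors; returns list(D = array[state, node, char], tree
# (postorder), root, contrib = array of per-edge child contributions)
.sankoff_down <- function(tree, X, cost, keep_contrib = FALSE) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  ns <- nrow(cost)
  C <- ncol(X)
  if (max(X, na.rm = TRUE) >= ns) {
    abort("Observed state exceeds the stepmatrix dimension.")
  }
  D <- array(0, dim = c(ns, total, C))
  D[, seq_len(n), ] <- Inf
  for (i in seq_len(n)) {
    x <- X[i, ]
    miss <- is.na(x)
    if (any(miss)) D[, i, miss] <- 0
    if (any(!miss)) D[cbind(x[!miss] + 1L, i, which(!miss))] <- 0
  }
  ne <- nrow(tree$edge)
  contrib <- if (keep_contrib) array(NA_real_, dim = c(ns, ne, C)) else NULL
  for (k in seq_len(ne)) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    ct <- .minplus(cost, matrix(D[, ch, ], nrow = ns))
    if (keep_contrib) contrib[, k, ] <- ct
    D[, p, ] <- matrix(D[, p, ], nrow = ns) + ct
  }
  root <- tree$edge[ne, 1]
  list(D = D, tree = tree, root = root, contrib = contrib, n_tip = n, C = C, ns = ns)
}

.root_char_lengths <- function(dp) {
  rootm <- matrix(dp$D[, dp$root, ], nrow = dp$ns)
  apply(rootm, 2L, min)
}

#' Generalized parsimony tree length under a stepmatrix
#'
#' Scores a tree against a coded character matrix under an arbitrary
#' stepmatrix by the Sankoff dynamic program: each node carries, per
#' character, the minimal cost of its subtree conditional on each possible
#' state; a leaf costs 0 at its observed state (0 at every state when
#' missing) and infinity elsewhere; the tree length is the minimum over root
#' states, summed over characters. Asymmetric (directed) stepmatrices impose
#' a direction of time and therefore require a rooted tree: the cost
#' `cost[i, j]` is charged for a parent in state `i` begetting a child in
#' state `j`.
#'
#' @param tree A `phylo` tree whose tips are taxa of `m`.
#' @param m A [coded_matrix()].
#' @param s A [stepmatrix()].
#' @param keep_vectors Retain the per-node optimal-cost vectors as the
#'   `"vectors"` attribute (state x node x character array, postorder tree in
#'   `"dp_tree"`).
#' @return Total tree length (numeric) with a `"per_character"` attribute.
#' @examples
#' tr <- read_newick("(A,B);")
#' m <- coded_matrix(matrix(c(0L, 5L), 2, 1, dimnames = list(c("A", "B"), "c1")))
#' sankoff_length(tr, m, ordered_stepmatrix(6))
#' @export
sankoff_length <- function(tree, m, s, keep_vectors = FALSE) {
  if (!s$symmetric && !ape::is.rooted(tree)) {
    abort("directed model requires rooted tree")
  }
  X <- .leaf_states(tree, m)
  dp <- .sankoff_down(tree, X, s$cost)
  per_char <- .root_char_lengths(dp)
  names(per_char) <- colnames(m)
  out <- sum(per_char)
  attr(out, "per_character") <- per_char
  if (keep_vectors) {
    attr(out, "vectors") <- dp$D
    attr(out, "dp_tree") <- dp$tree
  }
  out
}

# ---- Fitch (unordered) fold ------------------------------------------------

# per-character Fitch lengths via the set intersection/union up-pass;
# exact for binary trees with at most a basal trifurcation
.fitch_perchar <- function(tree, X, ns) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  C <- ncol(X)
  sets <- vector("list", total)
  for (i in seq_len(n)) {
    s <- matrix(FALSE, ns, C)
    x <- X[i, ]
    miss <- is.na(x)
    s[, miss] <- TRUE
    if (any(!miss)) s[cbind(x[!miss] + 1L, which(!miss))] <- TRUE
    sets[[i]] <- s
  }
  steps <- numeric(C)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    if (is.null(sets[[p]])) {
      sets[[p]] <- sets[[ch]]
    } else {
      inter <- sets[[p]] & sets[[ch]]
      empty <- colSums(inter) == 0L
      if (any(empty)) {
        inter[, empty] <- sets[[p]][, empty] | sets[[ch]][, empty]
        steps[empty] <- steps[empty] + 1
      }
      sets[[p]] <- inter
    }
  }
  steps
}

#' Fitch (unordered-character) tree length
#'
#' Equivalent to [sankoff_length()] with a unit-cost [unordered_stepmatrix()]
#' but computed by the classical set intersection/union up-pass. Any change
#' between distinct states costs one step.
#'
#' @inheritParams sankoff_length
#' @return Integer total length with a `"per_character"` attribute.
#' @export
fitch_length <- function(tree, m) {
  X <- .leaf_states(tree, m)
  per_char <- .fitch_perchar(tree, X, attr(m, "n_states"))
  names(per_char) <- colnames(m)
  out <- sum(per_char)
  attr(out, "per_character") <- per_char
  out
}

# ---- Wagner (ordered) Farris interval fold ---------------------------------

.wagner_perchar <- function(tree, X, ns) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  C <- ncol(X)
  lo <- matrix(NA_real_, total, C)
  hi <- matrix(NA_real_, total, C)
  for (i in seq_len(n)) {
    x <- X[i, ]
    lo[i, ] <- ifelse(is.na(x), 0, x)
    hi[i, ] <- ifelse(is.na(x), ns - 1, x)
  }
  steps <- numeric(C)
  seen <- logical(total)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    if (!seen[p]) {
      lo[p, ] <- lo[ch, ]; hi[p, ] <- hi[ch, ]
      seen[p] <- TRUE
    } else {
      mlo <- pmax(lo[p, ], lo[ch, ])
      mhi <- pmin(hi[p, ], hi[ch, ])
      gap <- pmax(0, mlo - mhi)
      steps <- steps + gap
      lo[p, ] <- pmin(mlo, mhi)
      hi[p, ] <- pmax(mlo, mhi)
    }
  }
  steps
}

#' Wagner (ordered-character) tree length
#'
#' Equivalent to [sankoff_length()] with the additive [ordered_stepmatrix()]
#' (`cost[i, j] = |i - j|`) but computed by the Farris interval up-pass.
#'
#' @inheritParams sankoff_length
#' @return Numeric total length with a `"per_character"` attribute.
#' @export
wagner_length <- function(tree, m) {
  X <- .leaf_states(tree, m)
  per_char <- .wagner_perchar(tree, X, attr(m, "n_states"))
  names(per_char) <- colnames(m)
  out <- sum(per_char)
  attr(out, "per_character") <- per_char
  out
}

# ---- Farris bounds and ensemble indices ------------------------------------

#' Per-character minimum and maximum conceivable steps
#'
#' `M` is the smallest number of steps any tree can require for the observed
#' state multiset; `G` is the largest (the star-tree length). For ordered
#' characters `M = max - min` and `G = min_m sum(|x_i - m|)` over candidate
#' median states `m`; for unordered characters `M = (#distinct) - 1` and
#' `G = n - (count of the most frequent state)`.
#'
#' @param values Integer vector of observed states (`NA` dropped).
#' @param char_type `"ordered"` or `"unordered"`.
#' @param n_states Alphabet size (bounds the median search).
#' @return Named numeric vector `c(M = , G = )`.
#' @export
char_bounds <- function(values, char_type = c("ordered", "unordered"),
                        n_states = 32L) {
  char_type <- match.arg(char_type)
  values <- values[!is.na(values)]
  if (!length(values)) abort("Need at least one non-missing value.")
  if (char_type == "ordered") {
    M <- max(values) - min(values)
    G <- min(vapply(seq.int(min(values), max(values)), function(mid) {
      sum(abs(values - mid))
    }, numeric(1)))
  } else {
    M <- length(unique(values)) - 1L
    G <- length(values) - max(table(values))
  }
  c(M = as.numeric(M), G = as.numeric(G))
}

#' Ensemble fit indices (retention and consistency index)
#'
#' Scores the tree per character (Wagner or Fitch according to `char_type`),
#' computes the Farris bounds, and reports the ensemble retention index
#' `RI = (sum(G) - sum(S)) / (sum(G) - sum(M))` and consistency index
#' `CI = sum(M) / sum(S)`. RI = 1 means a perfect, homoplasy-free fit of the
#' characters to the tree; RI = 0 the worst possible fit. When every
#' character is uninformative (`sum(G) = sum(M)`) the RI is undefined and
#' reported as `NA`.
#'
#' @inheritParams sankoff_length
#' @param char_type `"ordered"` or `"unordered"`.
#' @return A `fit_indices` object (list with `S`, `M`, `G` per character and
#'   totals, `RI`, `CI`).
#' @export
ensemble_indices <- function(tree, m, char_type = c("ordered", "unordered")) {
  char_type <- match.arg(char_type)
  X <- .leaf_states(tree, m)
  ns <- attr(m, "n_states")
  S <- if (char_type == "ordered") .wagner_perchar(tree, X, ns) else .fitch_perchar(tree, X, ns)
  MG <- vapply(seq_len(ncol(X)), function(j) {
    char_bounds(X[, j], char_type, n_states = ns)
  }, numeric(2))
  M <- MG[1, ]; G <- MG[2, ]
  sS <- sum(S); sM <- sum(M); sG <- sum(G)
  RI <- if (sG > sM) (sG - sS) / (sG - sM) else NA_real_
  CI <- if (sS > 0) sM / sS else NA_real_
  structure(
    list(S = setNames(S, colnames(m)), M = setNames(M, colnames(m)),
         G = setNames(G, colnames(m)),
         total_S = sS, total_M = sM, total_G = sG,
         RI = RI, CI = CI, char_type = char_type),
    class = "fit_indices"
  )
}

#' @export
print.fit_indices <- function(x, ...) {
  cat("<fit_indices> ", length(x$S), " ", x$char_type, " characters\n",
      "length S = ", x$total_S, ", min M = ", x$total_M, ", max G = ", x$total_G, "\n",
      "RI = ", format(x$RI, digits = 4), ", CI = ", format(x$CI, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.fit_indices <- function(x, ...) {
  tibble::tibble(character = names(x$S), S = unname(x$S), M = unname(x$M),
                 G = unname(x$G))
}

#' @export
glance.fit_indices <- function(x, ...) {
  tibble::tibble(length = x$total_S, min_steps = x$total_M,
                 max_steps = x$total_G, RI = x$RI, CI = x$CI,
                 char_type = x$char_type)
}

# ---- all-edge rooted scoring (re-rooting dynamic program) ------------------

# For every edge e = (p, child) of the stored (possibly unrooted) tree,
# computes the tree length when a root is inserted on e, with an optional
# pendant hypothetical-ancestor leaf at the root. Complement vectors CE give
# the cost of everything outside subtree(child), rooted at p and oriented
# away from it, so asymmetric costs are handled exactly.
# anc: NULL, or integer vector (0-based states, NA = missing) per character.
.edge_root_scores <- function(tree, X, cost, anc = NULL) {
  dp <- .sankoff_down(tree, X, cost, keep_contrib = TRUE)
  tree <- dp$tree
  ns <- dp$ns; C <- dp$C
  ne <- nrow(tree$edge)
  edge_parent_edge <- integer(ne) # index of the edge above parent node, 0 = root
  parent_of <- integer(dp$n_tip + tree$Nnode)
  for (k in seq_len(ne)) parent_of[tree$edge[k, 2]] <- k
  for (k in seq_len(ne)) edge_parent_edge[k] <- parent_of[tree$edge[k, 1]]
  # sum of child contributions per node
  sumAll <- array(0, dim = c(ns, dp$n_tip + tree$Nnode, C))
  for (k in seq_len(ne)) {
    p <- tree$edge[k, 1]
    sumAll[, p, ] <- matrix(sumAll[, p, ], nrow = ns) + matrix(dp$contrib[, k, ], nrow = ns)
  }
  CE <- array(NA_real_, dim = c(ns, ne, C))
  # preorder = reverse postorder
  for (k in rev(seq_len(ne))) {
    p <- tree$edge[k, 1]
    base <- matrix(sumAll[, p, ], nrow = ns) - matrix(dp$contrib[, k, ], nrow = ns)
    if (p != dp$root) {
      f <- edge_parent_edge[k]
      base <- base + .minplus(cost, matrix(CE[, f, ], nrow = ns))
    }
    CE[, k, ] <- base
  }
  anc_term <- NULL
  if (!is.null(anc)) {
    anc_term <- matrix(0, ns, C)
    obs <- which(!is.na(anc))
    if (length(obs)) anc_term[, obs] <- cost[, anc[obs] + 1L, drop = FALSE]
  }
  totals <- numeric(ne)
  per_edge_char <- matrix(NA_real_, ne, C)
  for (k in seq_len(ne)) {
    at_root <- matrix(dp$contrib[, k, ], nrow = ns) +
      .minplus(cost, matrix(CE[, k, ], nrow = ns))
    if (!is.null(anc_term)) at_root <- at_root + anc_term
    per_edge_char[k, ] <- apply(at_root, 2L, min)
    totals[k] <- sum(per_edge_char[k, ])
  }
  list(tree = tree, totals = totals, per_edge_char = per_edge_char)
}
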