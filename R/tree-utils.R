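# Internal tree helpers shared by the parsimony, rooting and comparison code.
# Trees are ape `phylo` objects; tips 1..n, internal nodes n+1..n+Nnode.

# tip-index sets of every node (list indexed by node id)
.node_tipsets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  total <- n + tree$Nnode
  sets <- vector("list", total)
  for (i in seq_len(n)) sets[[i]] <- i
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  lapply(sets, sort)
}

# root node id, without assuming ape's numbering convention
.root_node <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
}

# nontrivial rooted clusters as sorted label strings
.cluster_keys <- function(tree) {
  n <- length(tree$tip.label)
  sets <- .node_tipsets(tree)
  root <- .root_node(tree)
  keys <- character(0)
  for (v in setdiff(seq.int(n + 1L, n + tree$Nnode), root)) {
    tipset <- sets[[v]]
    if (length(tipset) >= 2L && length(tipset) < n) {
      keys <- c(keys, paste(sort(tree$tip.label[tipset]), collapse = "\r"))
    }
  }
  unique(keys)
}

# canonical key of a topology; rooted -> cluster set, unrooted -> split set
.topo_key <- function(tree) {
  n <- length(tree$tip.label)
  if (ape::is.rooted(tree)) {
    return(paste(sort(.cluster_keys(tree)), collapse = "\n"))
  }
  sets <- .node_tipsets(tree)
  labs <- tree$tip.label
  anchor <- min(labs)
  keys <- character(0)
  for (k in seq_len(nrow(tree$edge))) {
    c <- tree$edge[k, 2]
    tipset <- sets[[c]]
    if (length(tipset) < 2L || length(tipset) > n - 2L) next
    side <- sort(labs[tipset])
    if (anchor %in% side) side <- sort(setdiff(labs, side))
    keys <- c(keys, paste(side, collapse = "\r"))
  }
  paste(sort(unique(keys)), collapse = "\n")
}

# rebuild a phylo with ape's canonical node numbering (tips 1..n in
# traversal order of the Newick text, root = n+1); tolerant of edge-surgery
# objects whose numbering no longer follows ape's conventions
.normalize_phylo <- function(tree) {
  n <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  root <- .root_node(tree)
  rec <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    paste0("(", paste(vapply(children[[as.character(v)]], rec, character(1)),
                      collapse = ","), ")")
  }
  ape::read.tree(text = paste0(rec(root), ";"))
}

# attach a new pendant leaf in the middle of edge `e` (row of tree$edge);
# returns an unrooted-style phylo with one more tip and internal node
.attach_leaf_on_edge <- function(tree, e, label) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  map <- function(x) ifelse(x > n, x + 1L, x)
  new_tip <- n + 1L
  new_node <- n + 1L + m + 1L
  edges <- cbind(map(tree$edge[, 1]), map(tree$edge[, 2]))
  p <- edges[e, 1]; ch <- edges[e, 2]
  edges <- edges[-e, , drop = FALSE]
  edges <- rbind(edges, c(p, new_node), c(new_node, ch), c(new_node, new_tip))
  out <- list(edge = edges, tip.label = c(tree$tip.label, label),
              Nnode = m + 1L)
  class(out) <- "phylo"
  .normalize_phylo(out)
}

# root an unrooted tree on edge `e` (row index of tree$edge); the new root is
# a bifurcation separating the two sides of that edge
.root_on_edge <- function(tree, e) {
  aug <- .attach_leaf_on_edge(tree, e, ".__dummy__")
  rooted <- ape::root(aug, outgroup = ".__dummy__", resolve.root = TRUE)
  out <- ape::drop.tip(rooted, ".__dummy__")
  out
}

# assert leaves of tree are scored by matrix m; returns taxa in tree order
.check_leaves <- function(tree, m) {
  missing <- setdiff(tree$tip.label, rownames(m))
  if (length(missing)) {
    abort(paste0("Tree leaves missing from the character matrix: ",
                 paste(missing, collapse = ", ")))
  }
  tree$tip.label
}

# groups attribute lookup with validation
.check_groups <- function(tree, groups) {
  if (is.null(groups)) abort("Taxon group labels are required.")
  missing <- setdiff(tree$tip.label, names(groups))
  if (length(missing)) {
    abort(paste0("No group label for: ", paste(missing, collapse = ", ")))
  }
  groups[tree$tip.label]
}

# deterministic local RNG scope: evaluates expr with the given seed and
# restores the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) abort("A seed is required for reproducibility.")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}
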