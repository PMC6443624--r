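# Rooted tree comparison: hardwired cluster distance, hybridization number
# via (acyclic) agreement forests, and tanglegram leaf orderings.

# prune both trees to their shared leaves, warning if any are dropped
.shared_pair <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) == 0L) abort("The trees share no leaves.")
  drop1 <- setdiff(t1$tip.label, shared)
  drop2 <- setdiff(t2$tip.label, shared)
  if (length(drop1) || length(drop2)) {
    warn(paste0("Pruning non-shared leaves: ",
                paste(c(drop1, drop2), collapse = ", ")))
    if (length(drop1)) t1 <- ape::drop.tip(t1, drop1)
    if (length(drop2)) t2 <- ape::drop.tip(t2, drop2)
  }
  list(t1 = t1, t2 = t2, shared = shared)
}

#' Hardwired cluster distance between rooted trees
#'
#' The size of the symmetric difference between the two trees' sets of
#' nontrivial clusters (descendant leaf sets of internal nodes, proper
#' subsets with at least 2 leaves). Identical topologies give 0; for binary
#' trees this equals twice the rooted Robinson-Foulds partition count.
#' Non-shared leaves are pruned first with a warning.
#'
#' @param t1,t2 Rooted `phylo` trees.
#' @param halved Divide the symmetric difference by two.
#' @return Integer distance.
#' @export
cluster_distance <- function(t1, t2, halved = FALSE) {
  if (!ape::is.rooted(t1) || !ape::is.rooted(t2)) {
    abort("Cluster distance is defined for rooted trees.")
  }
  pr <- .shared_pair(t1, t2)
  k1 <- .cluster_keys(pr$t1)
  k2 <- .cluster_keys(pr$t2)
  d <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  if (halved) d / 2 else as.integer(d)
}

# ---- hybridization number via agreement forests ----------------------------

# per-tree precomputation on a fixed leaf label ordering
.af_tree_info <- function(tree, labels) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntot <- length(tree$tip.label) + tree$Nnode
  parent <- integer(ntot)
  for (k in seq_len(nrow(tree$edge))) parent[tree$edge[k, 2]] <- tree$edge[k, 1]
  tip_id <- match(labels, tree$tip.label)
  root <- tree$edge[nrow(tree$edge), 1]
  # ancestor chains for each node (node first, root last)
  chains <- vector("list", ntot)
  for (v in seq_len(ntot)) {
    ch <- v
    cur <- v
    while (cur != root) {
      cur <- parent[cur]
      ch <- c(ch, cur)
    }
    chains[[v]] <- ch
  }
  sets <- .node_tipsets(tree)
  clusters <- lapply(sets, function(s) sort(match(tree$tip.label[s], labels)))
  list(tree = tree, parent = parent, root = root, tip_id = tip_id,
       chains = chains, clusters = clusters, ntot = ntot)
}

# MRCA of a set of leaf ids (in `labels` numbering): deepest node common to
# all root-ward chains
.af_mrca <- function(info, block) {
  nodes <- info$tip_id[block]
  if (length(nodes) == 1L) return(nodes)
  anc <- info$chains[[nodes[1]]]
  for (v in nodes[-1]) anc <- anc[anc %in% info$chains[[v]]]
  anc[1]
}

# embedded (Steiner) vertex set of a block: union of paths from each leaf to
# the block MRCA
.af_embedded <- function(info, block) {
  r <- .af_mrca(info, block)
  rchain <- info$chains[[r]]
  out <- r
  for (v in info$tip_id[block]) {
    ch <- info$chains[[v]]
    stop_at <- match(r, ch)
    out <- c(out, ch[seq_len(stop_at)])
  }
  unique(out)
}

# restricted rooted topology of a block, as a canonical cluster-set key
.af_restriction_key <- function(info, block) {
  bl <- sort(block)
  keys <- character(0)
  for (cl in info$clusters) {
    inter <- cl[cl %in% bl]
    if (length(inter) >= 2L && length(inter) < length(bl)) {
      keys <- c(keys, paste(inter, collapse = ","))
    }
  }
  paste(sort(unique(keys)), collapse = ";")
}

# validity of a candidate forest (list of blocks over shared labels + rho):
# per-block topological agreement, vertex-disjoint embeddings in both trees,
# and acyclicity of the component ancestry digraph
.af_valid <- function(blocks, info1, info2) {
  for (b in blocks) {
    if (.af_restriction_key(info1, b) != .af_restriction_key(info2, b)) return(FALSE)
  }
  k <- length(blocks)
  roots1 <- integer(k)
  roots2 <- integer(k)
  for (t in 1:2) {
    info <- if (t == 1L) info1 else info2
    used <- integer(0)
    roots <- integer(k)
    for (i in seq_len(k)) {
      emb <- .af_embedded(info, blocks[[i]])
      if (any(emb %in% used)) return(FALSE)
      used <- c(used, emb)
      roots[i] <- .af_mrca(info, blocks[[i]])
    }
    if (t == 1L) roots1 <- roots else roots2 <- roots
  }
  if (k > 1L) {
    # edge i -> j when the root of block i is a proper ancestor of the root
    # of block j in either tree
    adj <- matrix(FALSE, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      if (roots1[i] %in% info1$chains[[roots1[j]]][-1]) adj[i, j] <- TRUE
      if (roots2[i] %in% info2$chains[[roots2[j]]][-1]) adj[i, j] <- TRUE
    }
    # cycle detection (DFS)
    color <- integer(k)
    has_cycle <- FALSE
    visit <- function(v) {
      if (has_cycle) return()
      color[v] <<- 1L
      for (w in which(adj[v, ])) {
        if (color[w] == 1L) { has_cycle <<- TRUE; return() }
        if (color[w] == 0L) visit(w)
      }
      color[v] <<- 2L
    }
    for (v in seq_len(k)) if (color[v] == 0L) visit(v)
    if (has_cycle) return(FALSE)
  }
  TRUE
}

# attach the formal root leaf rho above the root of a rooted tree
.af_add_rho <- function(tree) {
  txt <- sub(";\\s*$", "", ape::write.tree(tree))
  ape::read.tree(text = paste0("(", txt, ",.rho);"))
}

# blocks induced by cutting edge subset `cut` in tree1-with-rho
.af_blocks_from_cut <- function(info1, cut) {
  tree <- info1$tree
  comp <- seq_len(info1$ntot)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (k in seq_len(nrow(tree$edge))) {
    if (k %in% cut) next
    a <- find(tree$edge[k, 1]); b <- find(tree$edge[k, 2])
    if (a != b) comp[a] <- b
  }
  leaf_comp <- vapply(info1$tip_id, find, integer(1))
  split(seq_along(info1$tip_id), leaf_comp)
}

#' Hybridization distance between rooted binary trees
#'
#' The minimum number of reticulation events a hybridization network needs
#' to display both trees, computed through maximum acyclic agreement
#' forests: the distance is the smallest k such that the leaf set (plus a
#' formal root) can be partitioned into k + 1 blocks whose restricted
#' subtrees agree between the trees, embed vertex-disjointly in both, and
#' admit an acyclic ancestry order. Candidate forests are enumerated as
#' edge-cut sets of the first tree in increasing size, so the first feasible
#' size is exact. Beyond `exact_leaf_limit` leaves (or when the enumeration
#' budget is exceeded) the function returns certified bounds instead: the
#' lower bound from the exhausted cut sizes, the upper bound from a greedy
#' agreement forest, tagged `method = "heuristic"`.
#'
#' @param t1,t2 Rooted binary `phylo` trees on the same leaves (non-shared
#'   leaves are pruned with a warning).
#' @param exact_leaf_limit Leaf count above which only bounds are reported.
#' @param max_candidates Enumeration budget (number of cut sets per size
#'   level).
#' @return A `tree_distance` list: `distance` (NA when not exact), `lower`,
#'   `upper`, `method` (`"exact"` or `"heuristic"`), `n_leaves`.
#' @export
hybridization_distance <- function(t1, t2, exact_leaf_limit = 16L,
                                   max_candidates = 2e5) {
  if (!ape::is.rooted(t1) || !ape::is.rooted(t2)) {
    abort("Hybridization distance is defined for rooted trees.")
  }
  if (!ape::is.binary(t1) || !ape::is.binary(t2)) {
    abort("Hybridization distance needs binary trees; resolve polytomies first.")
  }
  pr <- .shared_pair(t1, t2)
  labels <- c(sort(pr$t1$tip.label), ".rho")
  r1 <- .af_add_rho(pr$t1)
  r2 <- .af_add_rho(pr$t2)
  info1 <- .af_tree_info(r1, labels)
  info2 <- .af_tree_info(r2, labels)
  n_leaves <- length(pr$t1$tip.label)
  upper <- .af_greedy_upper(info1, info2, labels)
  exact_ok <- n_leaves <= exact_leaf_limit
  ne <- nrow(info1$tree$edge)
  if (exact_ok) {
    for (s in 0:min(upper, ne)) {
      n_cand <- choose(ne, s)
      if (n_cand > max_candidates) { exact_ok <- FALSE; lower_reached <- s; break }
      cuts <- if (s == 0L) list(integer(0)) else
        asplit(utils::combn(ne, s), 2L)
      found <- FALSE
      for (cut in cuts) {
        blocks <- .af_blocks_from_cut(info1, as.integer(cut))
        if (length(blocks) != s + 1L) next
        if (.af_valid(blocks, info1, info2)) { found <- TRUE; break }
      }
      if (found) {
        return(structure(list(distance = s, lower = s, upper = s,
                              method = "exact", n_leaves = n_leaves),
                         class = "tree_distance"))
      }
    }
    if (exact_ok) lower_reached <- min(upper, ne) + 1L
  } else {
    lower_reached <- if (cluster_distance(pr$t1, pr$t2) > 0) 1L else 0L
  }
  structure(list(distance = NA_integer_, lower = as.integer(lower_reached),
                 upper = as.integer(upper), method = "heuristic",
                 n_leaves = n_leaves),
            class = "tree_distance")
}

# greedy upper bound: remove leaves (as singleton blocks) until the
# restrictions of the remaining leaf set agree; rho stays with the core
.af_greedy_upper <- function(info1, info2, labels) {
  live <- seq_len(length(labels)) # includes rho (last)
  removed <- 0L
  repeat {
    core <- live
    if (.af_restriction_key(info1, core) == .af_restriction_key(info2, core)) break
    # drop the leaf whose removal best reduces disagreement
    cands <- setdiff(live, length(labels))
    scores <- vapply(cands, function(v) {
      rest <- setdiff(live, v)
      k1 <- strsplit(.af_restriction_key(info1, rest), ";")[[1]]
      k2 <- strsplit(.af_restriction_key(info2, rest), ";")[[1]]
      length(setdiff(k1, k2)) + length(setdiff(k2, k1))
    }, numeric(1))
    drop_v <- cands[which.min(scores)]
    live <- setdiff(live, drop_v)
    removed <- removed + 1L
    if (length(live) <= 2L) break
  }
  removed
}

#' @export
print.tree_distance <- function(x, ...) {
  if (x$method == "exact") {
    cat("<tree_distance> hybridization number ", x$distance,
        " (exact, ", x$n_leaves, " leaves)\n", sep = "")
  } else {
    cat("<tree_distance> hybridization number in [", x$lower, ", ", x$upper,
        "] (heuristic, ", x$n_leaves, " leaves)\n", sep = "")
  }
  invisible(x)
}

#' Tanglegram leaf orderings and crossing count
#'
#' Produces the side-by-side leaf orderings used to draw a tanglegram of two
#' rooted trees. Leaf orders start from each tree's own ladderized order and
#' are then improved by barycenter passes (reordering the children of each
#' internal node of one tree by the mean position of the matched leaves in
#' the other tree's current order); a pass is only accepted when it does not
#' increase the number of connector crossings, so crossings are
#' non-increasing over passes. The crossing count of the final layout is the
#' number of leaf pairs ordered oppositely in the two columns.
#'
#' @param t1,t2 Rooted `phylo` trees sharing at least 2 leaves.
#' @param groups Optional named group labels added to the output.
#' @param passes Number of barycenter sweeps.
#' @return A tibble (leaf, position_t1, position_t2, group) with the
#'   crossing count in attribute `"crossings"`.
#' @export
tanglegram_export <- function(t1, t2, groups = NULL, passes = 4L) {
  pr <- .shared_pair(t1, t2)
  if (length(pr$t1$tip.label) < 2L) abort("Need at least 2 shared leaves.")
  ord1 <- .ladder_order(pr$t1)
  ord2 <- .ladder_order(pr$t2)
  cross <- function(o1, o2) {
    pos2 <- match(o1, o2)
    sum(vapply(seq_along(pos2), function(i) sum(pos2[seq_len(i - 1)] > pos2[i]), numeric(1)))
  }
  best <- cross(ord1, ord2)
  for (p in seq_len(passes)) {
    cand2 <- .barycenter_order(pr$t2, match(pr$t2$tip.label, ord1))
    if (cross(ord1, cand2) <= best) { ord2 <- cand2; best <- cross(ord1, ord2) }
    cand1 <- .barycenter_order(pr$t1, match(pr$t1$tip.label, ord2))
    if (cross(cand1, ord2) <= best) { ord1 <- cand1; best <- cross(ord1, ord2) }
  }
  out <- tibble::tibble(
    leaf = ord1,
    position_t1 = seq_along(ord1),
    position_t2 = match(ord1, ord2)
  )
  if (!is.null(groups)) out$group <- unname(groups[out$leaf])
  attr(out, "crossings") <- as.integer(best)
  class(out) <- c("tanglegram", class(out))
  out
}

# leaf order after ladderizing (deterministic)
.ladder_order <- function(tree) {
  lt <- ape::ladderize(tree)
  lt <- ape::reorder.phylo(lt, "cladewise")
  lt$tip.label[lt$edge[lt$edge[, 2] <= length(lt$tip.label), 2]]
}

# reorder children of every internal node by mean matched position
.barycenter_order <- function(tree, tip_pos) {
  n <- length(tree$tip.label)
  sets <- .node_tipsets(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  score <- function(v) mean(tip_pos[sets[[v]]], na.rm = TRUE)
  order_node <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    kids <- kids[order(vapply(kids, score, numeric(1)))]
    unlist(lapply(kids, order_node))
  }
  root <- tree$edge[nrow(tree$edge), 1]
  order_node(root)
}

#' @export
autoplot.tanglegram <- function(object, ...) {
  ggplot(object) +
    geom_segment(aes(x = 0, xend = 1, y = .data$position_t1,
                     yend = .data$position_t2)) +
    labs(title = paste0("Tanglegram (",
                        attr(object, "crossings"), " crossings)"),
         x = NULL, y = "leaf position") +
    theme_minimal()
}
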