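# Independent oracles and fixture builders. Everything here is deliberately
# naive (enumeration, brute force) and shares no code with the package's
# dynamic programs.

# minimum stepmatrix cost of a tree by enumerating every complete internal
# state assignment
brute_tree_length <- function(tree, X, cost) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  internals <- sort(unique(tree$edge[, 1]))
  ns <- nrow(cost)
  total <- 0
  for (ch in seq_len(ncol(X))) {
    leaf_states <- X[tree$tip.label, ch]
    grid <- expand.grid(rep(list(seq_len(ns)), length(internals)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      st <- integer(n + tree$Nnode)
      st[internals] <- as.integer(unlist(grid[g, ]))
      miss <- is.na(leaf_states)
      st[seq_len(n)] <- ifelse(miss, NA_integer_, leaf_states + 1L)
      cst <- 0
      ok <- TRUE
      for (k in seq_len(nrow(tree$edge))) {
        p <- st[tree$edge[k, 1]]; c2 <- st[tree$edge[k, 2]]
        if (is.na(c2)) next # missing leaf contributes its best state
        cst <- cst + cost[p, c2]
      }
      # missing leaves: choose their cheapest state given the parent
      for (i in which(miss)) {
        p <- st[tree$edge[tree$edge[, 2] == i, 1]]
        cst <- cst + min(cost[p, ])
      }
      best <- min(best, cst)
    }
    total <- total + best
  }
  total
}

# star-tree (maximum conceivable) steps by scoring every center state
brute_star_length <- function(values, cost) {
  values <- values[!is.na(values)]
  ns <- nrow(cost)
  min(vapply(seq_len(ns), function(center) {
    sum(cost[center, values + 1L])
  }, numeric(1)))
}

rand_coded <- function(n_taxa, n_char, n_states, seed, p_missing = 0) {
  set.seed(seed)
  X <- matrix(sample(0:(n_states - 1L), n_taxa * n_char, replace = TRUE),
              n_taxa, n_char,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("c", seq_len(n_char))))
  if (p_missing > 0) {
    nmiss <- ceiling(p_missing * length(X))
    # keep at least one observed value per character
    idx <- sample(seq_along(X), nmiss)
    X[idx] <- NA_integer_
    for (j in seq_len(ncol(X))) {
      if (all(is.na(X[, j]))) X[1, j] <- 0L
    }
  }
  coded_matrix(X, n_states = n_states)
}

rand_topology <- function(n, seed, rooted = FALSE) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = rooted)
  tr$edge.length <- NULL
  tr
}

# ---- exhaustive agreement-forest oracle for the hybridization number ------

# all set partitions of 1..n (restricted-growth strings)
all_partitions <- function(n) {
  out <- list()
  rg <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      out[[length(out) + 1L]] <<- split(seq_len(n), rg)
      return()
    }
    for (v in seq_len(maxv + 1L)) {
      rg[i] <<- v
      recurse(i + 1L, max(maxv, v))
    }
  }
  recurse(1L, 0L)
  out
}

# --- fully independent agreement-forest machinery built on ape utilities ---

oracle_add_rho <- function(tree) {
  txt <- sub(";\\s*$", "", ape::write.tree(tree))
  ape::read.tree(text = paste0("(", txt, ",.rho);"))
}

oracle_rooted_key <- function(tree) {
  if (length(tree$tip.label) <= 2L) return(paste(sort(tree$tip.label), collapse = "|"))
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    paste(sort(attr(pp, "labels")[idx]), collapse = ",")
  }, character(1))
  paste(sort(keys), collapse = "|")
}

oracle_restrict <- function(tree, labs) {
  if (length(labs) == 1L) return(labs)
  ape::keep.tip(tree, labs)
}

oracle_restriction_key <- function(tree, labs) {
  r <- oracle_restrict(tree, labs)
  if (is.character(r)) r else oracle_rooted_key(r)
}

oracle_embedded_nodes <- function(tree, labs) {
  tips <- match(labs, tree$tip.label)
  if (length(tips) == 1L) return(tips)
  mrca <- ape::getMRCA(tree, tips)
  nodes <- mrca
  for (tp in tips) nodes <- c(nodes, ape::nodepath(tree, tp, mrca))
  unique(nodes)
}

oracle_block_root <- function(tree, labs) {
  tips <- match(labs, tree$tip.label)
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(tree, tips)
}

oracle_is_ancestor <- function(tree, a, b) {
  if (a == b) return(FALSE)
  root <- length(tree$tip.label) + 1L
  if (a == root) return(TRUE)
  if (b == root) return(FALSE)
  a %in% ape::nodepath(tree, root, b)
}

oracle_af_valid <- function(blocks_labs, t1, t2) {
  for (b in blocks_labs) {
    if (oracle_restriction_key(t1, b) != oracle_restriction_key(t2, b)) return(FALSE)
  }
  k <- length(blocks_labs)
  roots1 <- integer(k); roots2 <- integer(k)
  for (tset in 1:2) {
    tree <- if (tset == 1L) t1 else t2
    used <- integer(0)
    for (i in seq_len(k)) {
      emb <- oracle_embedded_nodes(tree, blocks_labs[[i]])
      if (any(emb %in% used)) return(FALSE)
      used <- c(used, emb)
      if (tset == 1L) roots1[i] <- oracle_block_root(tree, blocks_labs[[i]])
      else roots2[i] <- oracle_block_root(tree, blocks_labs[[i]])
    }
  }
  if (k > 1L) {
    adj <- matrix(FALSE, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      if (oracle_is_ancestor(t1, roots1[i], roots1[j])) adj[i, j] <- TRUE
      if (oracle_is_ancestor(t2, roots2[i], roots2[j])) adj[i, j] <- TRUE
    }
    # Kahn cycle check
    indeg <- colSums(adj)
    left <- rep(TRUE, k)
    repeat {
      free <- which(left & indeg == 0)
      if (!length(free)) break
      for (v in free) {
        left[v] <- FALSE
        indeg <- indeg - adj[v, ]
      }
    }
    if (any(left)) return(FALSE)
  }
  TRUE
}

# brute-force hybridization number: minimum (blocks - 1) over ALL partitions
# of leaves + rho forming a valid acyclic agreement forest
brute_hybridization <- function(t1, t2) {
  r1 <- oracle_add_rho(t1)
  r2 <- oracle_add_rho(t2)
  labels <- c(sort(t1$tip.label), ".rho")
  n <- length(labels)
  best <- n - 1L
  for (part in all_partitions(n)) {
    k <- length(part)
    if (k - 1L >= best) next
    blocks_labs <- lapply(part, function(idx) labels[idx])
    if (oracle_af_valid(blocks_labs, r1, r2)) best <- k - 1L
  }
  best
}

# crossing count of two leaf orderings (inversion count, quadratic)
brute_crossings <- function(ord1, ord2) {
  pos2 <- match(ord1, ord2)
  total <- 0L
  for (i in seq_along(pos2)) {
    for (j in seq_len(i - 1L)) if (pos2[j] > pos2[i]) total <- total + 1L
  }
  total
}

# homoplasy-free dataset + its generating tree
perfect_dataset <- function(n_taxa = 8L, state = 3L, n_states = 32L) {
  tree <- ape::stree(n_taxa, "balanced")
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  list(tree = tree, m = clade_indicator_matrix(tree, state, n_states))
}
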