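# A-posteriori rooting by Lundberg optimization: attach a hypothetical
# ancestor most parsimoniously to an internode of an unrooted optimal tree.

# expand an ancestor specification into 0-based states (NA = missing)
.ancestor_states <- function(ancestor, m) {
  n_char <- ncol(m)
  if (identical(ancestor, "standard")) ancestor <- "?"
  chars <- strsplit(ancestor, "")[[1]]
  if (length(chars) == 1L) chars <- rep(chars, n_char)
  if (length(chars) != n_char) {
    abort(sprintf("Ancestor string has %d symbols but the matrix has %d characters.",
                  length(chars), n_char))
  }
  states <- symbol_to_state(chars, state_alphabet())
  if (any(!is.na(states) & states >= attr(m, "n_states"))) {
    abort("Ancestor state outside the matrix alphabet.")
  }
  states
}

#' Root an unrooted tree by Lundberg optimization
#'
#' Attaches a pendant hypothetical ancestor with the given character states
#' to every internode of the unrooted tree in turn, scores each augmented
#' tree under the model, and roots the tree at the minimum-cost attachment
#' (Weston's generality criterion implemented empirically). The `"standard"`
#' ancestor sets every state to missing (`?`), which adds zero cost on every
#' edge: all edges tie, and the tie is resolved to the first edge in the
#' canonical (postorder) edge ordering — operationally the same rooted
#' topology as the all-`0` ancestor on growth-dominated data.
#'
#' @param t An unrooted `phylo` tree.
#' @param m A [coded_matrix()] scoring the tree's leaves.
#' @param model A [stepmatrix()] or model name (see [heuristic_search()]).
#' @param ancestor Single symbol (recycled over characters), full-length
#'   state string, `"?"`, or `"standard"`.
#' @return A `rooting_result`: the rooted ingroup tree, the rooted tree with
#'   the ancestor leaf attached (leaf `".ANC"`), the attachment edge, the
#'   rooted length, and all tied edges.
#' @export
lundberg_root <- function(t, m, model = "ordered", ancestor = "0") {
  if (ape::is.rooted(t)) abort("Lundberg rooting expects an unrooted tree.")
  ns <- attr(m, "n_states")
  mod <- .resolve_model(model, ns)
  anc <- .ancestor_states(ancestor, m)
  X <- .leaf_states(t, m)
  es <- .edge_root_scores(t, X, mod$step$cost, anc = anc)
  best <- min(es$totals)
  ties <- which(es$totals <= best + .domtol_tol)
  k <- ties[1L]
  rooted <- .root_on_edge(es$tree, k)
  aug <- .attach_leaf_on_edge(es$tree, k, ".ANC")
  aug_rooted <- ape::root(aug, outgroup = ".ANC", resolve.root = TRUE)
  unrooted_length <- if (mod$step$symmetric) {
    dp <- .sankoff_down(es$tree, X, mod$step$cost)
    sum(.root_char_lengths(dp))
  } else NA_real_
  structure(
    list(rooted_tree = rooted, rooted_tree_with_ancestor = aug_rooted,
         attachment_edge = k, ties = ties, rooted_length = best,
         unrooted_length = unrooted_length,
         ancestor = if (length(unique(ancestor)) == 1L) ancestor else "custom",
         ancestor_states = anc, model = mod$name, scoring_tree = es$tree),
    class = "rooting_result"
  )
}

#' @export
print.rooting_result <- function(x, ...) {
  cat("<rooting_result> ancestor '", x$ancestor, "', model '", x$model,
      "'\nrooted length ", format(x$rooted_length, digits = 8),
      " (unrooted ", format(x$unrooted_length, digits = 8), "), ",
      length(x$ties), " tied attachment edge(s)\n", sep = "")
  invisible(x)
}

# matrix augmented with the ancestor row, for RI computed over the ancestor
.augmented_matrix <- function(m, anc_states) {
  states <- unclass(m)
  out <- rbind(states, matrix(anc_states, 1L, dimnames = list(".ANC")))
  coded_matrix(out, n_states = attr(m, "n_states"),
               coding_params = attr(m, "coding_params"),
               groups = attr(m, "groups"))
}

#' Sweep all constant ancestors over the state alphabet
#'
#' Roots the tree by Lundberg with the `"standard"` (all-missing) ancestor
#' and with every constant ancestor of the alphabet in turn (`0`..`9`,
#' `A`..`V` for 32 states), recording for each the rooted tree length, the
#' ensemble retention index (computed with the ancestor included as a scored
#' leaf, so that rows differ), and the basal-group call. A linear regression
#' of RI on rooted length over the constant-ancestor rows summarizes whether
#' fit decays monotonically as polarization is inverted.
#'
#' @inheritParams lundberg_root
#' @param groups Named taxon group labels; defaults to the matrix's `groups`
#'   attribute. Basal calls are skipped when absent.
#' @return A `sweep_table` tibble with one row per ancestor scheme and
#'   regression summaries in attributes (see [glance.sweep_table()]).
#' @export
ancestor_sweep <- function(t, m, model = "ordered", groups = NULL) {
  ns <- attr(m, "n_states")
  mod <- .resolve_model(model, ns)
  if (is.na(mod$char_type)) {
    abort("Ancestor sweeps need an ordered or unordered character model (RI is undefined for arbitrary stepmatrices).")
  }
  groups <- groups %||% attr(m, "groups")
  symbols <- state_alphabet(ns)$symbols
  schemes <- c("standard", symbols)
  rows <- purrr::map(schemes, function(sym) {
    rr <- lundberg_root(t, m, model = mod$step, ancestor = sym)
    aug_m <- .augmented_matrix(m, rr$ancestor_states)
    fi <- ensemble_indices(rr$rooted_tree_with_ancestor, aug_m, mod$char_type)
    call <- if (!is.null(groups)) classify_basal(rr$rooted_tree, groups) else NULL
    tibble::tibble(
      ancestor = sym,
      state_index = if (sym == "standard") NA_integer_ else unname(symbol_to_state(sym)),
      length = rr$rooted_length,
      RI = fi$RI,
      n_ties = length(rr$ties),
      basal_group = if (is.null(call)) NA_character_ else call$group,
      basal_structure = if (is.null(call)) NA_character_ else call$structure
    )
  })
  out <- dplyr::bind_rows(rows)
  const <- dplyr::filter(out, !is.na(.data$state_index))
  reg_len <- lm(RI ~ length, data = const)
  reg_state <- lm(RI ~ state_index, data = const)
  r2 <- function(fit) summary(fit)$r.squared
  attr(out, "regression") <- tibble::tibble(
    predictor = c("length", "state_index"),
    slope = c(coef(reg_len)[2], coef(reg_state)[2]),
    intercept = c(coef(reg_len)[1], coef(reg_state)[1]),
    r_squared = c(r2(reg_len), r2(reg_state))
  )
  attr(out, "model") <- mod$name
  class(out) <- c("sweep_table", class(out))
  out
}

#' @export
glance.sweep_table <- function(x, ...) {
  reg <- attr(x, "regression")
  tibble::tibble(
    model = attr(x, "model"),
    n_schemes = nrow(x),
    best_length = min(x$length),
    slope_ri_on_length = reg$slope[reg$predictor == "length"],
    slope_ri_on_state = reg$slope[reg$predictor == "state_index"],
    r_squared_length = reg$r_squared[reg$predictor == "length"]
  )
}

#' @export
autoplot.sweep_table <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$state_index))
  ggplot(df, aes(x = .data$length, y = .data$RI)) +
    geom_point(aes(size = .data$state_index), alpha = 0.7) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4) +
    scale_size_area(max_size = 3) +
    labs(title = "Ancestor sweep: retention index vs rooted tree length",
         x = "tree length", y = "ensemble RI", size = "ancestor state") +
    theme_minimal()
}

#' Classify the basal group of a rooted tree
#'
#' Reads off which taxon group sits at the base of a rooted tree and whether
#' it does so as a monophyletic clade or as a paraphyletic grade. The basal
#' side is the smaller side of the root split (ties broken toward the first
#' child of the root). If that side mixes groups the call is `"unresolved"`;
#' if it is pure and contains every member of its group it is
#' `"monophyletic"`; if the group continues above the root split it is
#' `"paraphyletic"`.
#'
#' @param rt A rooted `phylo` tree with at least 3 taxa.
#' @param groups Named character vector mapping taxa to group labels.
#' @return A `basal_call`: list with `group`, `structure`, `basal_taxa`.
#' @export
classify_basal <- function(rt, groups) {
  if (!ape::is.rooted(rt)) abort("classify_basal needs a rooted tree.")
  n <- length(rt$tip.label)
  if (n < 3L) abort("Need at least 3 taxa.")
  groups <- .check_groups(rt, groups)
  sets <- .node_tipsets(rt)
  root <- .root_node(rt)
  kids <- rt$edge[rt$edge[, 1] == root, 2]
  sides <- lapply(kids, function(k) rt$tip.label[sets[[k]]])
  sizes <- lengths(sides)
  basal_idx <- if (any(sizes < max(sizes))) which.min(sizes) else 1L
  basal <- sides[[basal_idx]]
  gset <- unique(unname(groups[basal]))
  if (length(gset) > 1L) {
    structure_ <- "unresolved"
    g <- NA_character_
  } else {
    g <- gset
    all_g <- names(groups)[groups == g]
    structure_ <- if (setequal(basal, all_g)) "monophyletic" else "paraphyletic"
  }
  structure(list(group = g, structure = structure_, basal_taxa = basal),
            class = "basal_call")
}

#' @export
print.basal_call <- function(x, ...) {
  cat("<basal_call> ", x$structure,
      if (!is.na(x$group)) paste0(" ", x$group) else "",
      ": ", paste(x$basal_taxa, collapse = ", "), "\n", sep = "")
  invisible(x)
}
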