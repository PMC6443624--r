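#' Character-transformation stepmatrices
#'
#' A stepmatrix makes the cost of every state-to-state transformation explicit
#' for generalized (Sankoff) parsimony. `stepmatrix()` is the low-level
#' constructor; the `ordered_stepmatrix()`, `unordered_stepmatrix()`,
#' `hk_stepmatrix()` and `wheeler_stepmatrix()` helpers build the specific
#' character models compared in this package.
#'
#' @param cost Square numeric matrix of non-negative costs with zero diagonal;
#'   `cost[i, j]` is the cost of transforming state `i-1` into state `j-1`.
#' @param name Model name used in printing and Nexus USERTYPE blocks.
#' @return An object of class `stepmatrix` with fields `cost`, `n`, `name`,
#'   `symmetric` and `satisfies_triangle_inequality`.
#' @export
stepmatrix <- function(cost, name = "usertype") {
  cost <- as.matrix(cost)
  if (nrow(cost) != ncol(cost)) abort("Stepmatrix must be square.")
  if (any(cost < 0)) abort("Stepmatrix costs must be non-negative.")
  if (any(abs(diag(cost)) > 0)) abort("Stepmatrix diagonal must be zero.")
  n <- nrow(cost)
  dimnames(cost) <- rep(list(state_alphabet(max(2L, n))$symbols[seq_len(n)]), 2L)
  s <- structure(
    list(cost = cost, n = n, name = name,
         symmetric = isTRUE(all.equal(cost, t(cost), tolerance = 1e-12)),
         satisfies_triangle_inequality = NA),
    class = "stepmatrix"
  )
  s$satisfies_triangle_inequality <- nrow(audit_triangle_inequality(s)) == 0L
  s
}

#' @export
print.stepmatrix <- function(x, ...) {
  cat("<stepmatrix> '", x$name, "', ", x$n, " states, ",
      if (x$symmetric) "symmetric" else "asymmetric",
      if (x$satisfies_triangle_inequality) ", metric-consistent" else ", violates triangle inequality",
      "\n", sep = "")
  if (x$n <= 10L) print(x$cost)
  invisible(x)
}

#' @export
tidy.stepmatrix <- function(x, ...) {
  syms <- rownames(x$cost)
  tidyr::expand_grid(from = syms, to = syms) |>
    dplyr::mutate(cost = as.vector(t(x$cost))) |>
    dplyr::filter(.data$from != .data$to)
}

#' @rdname stepmatrix
#' @details
#' `ordered_stepmatrix(n)` builds the Wagner (linearly ordered, additive)
#' model: transforming between states `i` and `j` costs `|i - j|`, the number
#' of edges separating them on the linear character-state graph. On a 5-state
#' graph, states 0 and 2 are 2 steps apart and states 0 and 4 are 4 steps
#' apart, in either direction.
#' @param n Number of states.
#' @export
ordered_stepmatrix <- function(n = 32L) {
  if (n < 2L) abort("Need at least 2 states.")
  idx <- seq_len(n) - 1L
  stepmatrix(abs(outer(idx, idx, `-`)), name = "ordered")
}

#' @rdname stepmatrix
#' @details
#' `unordered_stepmatrix(n)` builds the Fitch (maximally connected) model:
#' any change between distinct states costs one step. Among 32 states there
#' are `32 * 31 = 992` possible directed transformations.
#' @export
unordered_stepmatrix <- function(n = 32L) {
  if (n < 2L) abort("Need at least 2 states.")
  cost <- matrix(1, n, n)
  diag(cost) <- 0
  stepmatrix(cost, name = "unordered")
}

#' The asymmetric gain-penalty (HK) stepmatrix
#'
#' Builds the asymmetric stepmatrix that taxes domain gains more than losses
#' and thereby roots trees intrinsically during Sankoff optimization. For
#' binary occurrence data (`mode = "occurrence"`, n = 2) the single gain
#' 0 -> 1 costs 2 while the loss 1 -> 0 costs 1. For multistate abundance
#' data (`mode = "abundance"`, n = 32) the "first gain" transformations out of
#' state 0 cost 3 while every other change costs 1; by default all 31 cells
#' `0 -> j` are penalized (31 of the 992 possible transformations, ~3%).
#' `first_gain_only = TRUE` restricts the penalty to the single cell 0 -> 1.
#'
#' @param n Number of states: must be 2 for occurrence, 32 for abundance.
#' @param mode `"occurrence"` or `"abundance"`.
#' @param first_gain_only Penalize only 0 -> 1 in abundance mode.
#' @return An asymmetric `stepmatrix`.
#' @export
hk_stepmatrix <- function(n = 32L, mode = c("abundance", "occurrence"),
                          first_gain_only = FALSE) {
  mode <- match.arg(mode)
  if (mode == "occurrence" && n != 2L) abort("Occurrence mode requires n = 2.")
  if (mode == "abundance" && n != 32L) abort("Abundance mode requires n = 32.")
  cost <- matrix(1, n, n)
  diag(cost) <- 0
  if (mode == "occurrence") {
    cost[1L, 2L] <- 2
  } else if (first_gain_only) {
    cost[1L, 2L] <- 3
  } else {
    cost[1L, -1L] <- 3
  }
  stepmatrix(cost, name = paste0("hk-", mode))
}

#' Frequency-derived (Wheeler) stepmatrix
#'
#' Converts a matrix of reconstructed change frequencies into transformation
#' costs, implementing the inverse relation between cost and probability of
#' change: frequent transformations become cheap, unobserved ones expensive.
#' The cost of `i -> j` (i != j) is
#' `min(cap, 1 + round(-log((f_ij + pseudocount) / (f_max + pseudocount))))`
#' with `f_max` the largest off-diagonal frequency, so the most frequent
#' change costs exactly 1 step and costs are capped for Sankoff-friendliness.
#'
#' @param f A [change_frequencies()] result or a plain non-negative square
#'   matrix of counts.
#' @param pseudocount Additive smoothing constant (default 0.5).
#' @param cap Maximum cost (default 32).
#' @return A `stepmatrix` (asymmetric whenever the frequencies are).
#' @export
wheeler_stepmatrix <- function(f, pseudocount = 0.5, cap = 32) {
  fm <- if (inherits(f, "change_frequency_matrix")) f$counts else as.matrix(f)
  if (nrow(fm) != ncol(fm)) abort("Frequency matrix must be square.")
  off <- fm
  diag(off) <- NA
  fmax <- max(off, na.rm = TRUE)
  if (fmax <= 0) abort("All off-diagonal change frequencies are zero; no model can be derived.")
  cost <- 1 + floor(-log((fm + pseudocount) / (fmax + pseudocount)) + 0.5)
  cost <- pmin(pmax(cost, 1), cap) # scalar first in pmin/pmax would drop dim
  diag(cost) <- 0
  stepmatrix(cost, name = "wheeler")
}

#' Audit a stepmatrix for triangle-inequality violations
#'
#' Exhaustively checks all ordered state triples (i, k, j): a violation is a
#' pair whose direct cost exceeds the cost of passing through an intermediate
#' state, `cost[i, j] > cost[i, k] + cost[k, j]`. A model that violates the
#' triangle inequality assigns a "straight line" between two states a higher
#' cost than a detour, an internally inconsistent notion of distance.
#'
#' @param s A `stepmatrix`.
#' @return A tibble with columns `i`, `k`, `j` (0-based states), `direct` and
#'   `via`; zero rows when the matrix is consistent.
#' @export
audit_triangle_inequality <- function(s) {
  cost <- s$cost
  n <- nrow(cost)
  viol <- vector("list", n)
  for (k in seq_len(n)) {
    via <- outer(cost[, k], cost[k, ], `+`)
    bad <- which(cost > via + 1e-12, arr.ind = TRUE)
    if (nrow(bad)) {
      viol[[k]] <- tibble::tibble(
        i = bad[, 1] - 1L, k = k - 1L, j = bad[, 2] - 1L,
        direct = cost[bad], via = via[bad]
      )
    }
  }
  out <- dplyr::bind_rows(viol)
  if (!nrow(out)) {
    out <- tibble::tibble(i = integer(), k = integer(), j = integer(),
                          direct = numeric(), via = numeric())
  }
  dplyr::arrange(out, .data$i, .data$k, .data$j)
}

#' @export
autoplot.stepmatrix <- function(object, ...) {
  df <- tidy.stepmatrix(object)
  ggplot(df, aes(x = .data$to, y = .data$from, fill = .data$cost)) +
    geom_tile() +
    labs(title = paste0("Stepmatrix '", object$name, "'"),
         x = "to state", y = "from state") +
    theme_minimal()
}

#' Serialize / read a stepmatrix as TSV
#'
#' @param s A `stepmatrix`.
#' @param path File path.
#' @return `path` invisibly; `read_stepmatrix_tsv()` returns a `stepmatrix`.
#' @export
write_stepmatrix_tsv <- function(s, path) {
  utils::write.table(s$cost, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_stepmatrix_tsv
#' @param name Model name for the object read back.
#' @export
read_stepmatrix_tsv <- function(path, name = "usertype") {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  stepmatrix(m, name = name)
}
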