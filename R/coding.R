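#' Code raw abundance counts into multistate characters
#'
#' Transforms a proteome x FSF count matrix into phylogenetic characters on
#' the ordered 32-symbol alphabet. Counts are log-transformed (by default),
#' rescaled against the character's (or the matrix's) maximum, and rounded to
#' an integer state, so that a count of 0 always codes to state 0 and the
#' maximum count codes to the top state. The gradient of abundance across
#' proteomes is thereby preserved as an ordered series of serial homologies.
#'
#' The default, `scale = "log"` with `norm_scope = "per_character"`, codes
#' taxon t on character c as
#' `round((n_states - 1) * log(count + 1) / log(max_c + 1))`
#' where `max_c` is the largest count of that FSF over all proteomes.
#' `scale = "linear"` replaces `log(count + 1)` by `count`. With
#' `norm_scope = "global"` the maximum is taken over the whole matrix.
#' Rounding is deterministic half-up. Characters whose maximum is 0 carry no
#' signal and are dropped with a warning.
#'
#' @param a An [abundance_matrix()].
#' @param n_states Number of states (2..32, default 32).
#' @param scale `"log"` (default) or `"linear"`.
#' @param norm_scope `"per_character"` (default) or `"global"`.
#' @return A `coded_matrix`: integer matrix of 0-based states with attributes
#'   `alphabet`, `coding_params` and (if present) `groups`.
#' @examples
#' a <- abundance_matrix(matrix(c(0, 10, 1000), 3, 1,
#'   dimnames = list(c("x", "y", "z"), "f")))
#' unclass(encode_abundance(a))[, 1]
#' @export
encode_abundance <- function(a, n_states = 32L, scale = c("log", "linear"),
                             norm_scope = c("per_character", "global")) {
  scale <- match.arg(scale)
  norm_scope <- match.arg(norm_scope)
  n_states <- as.integer(n_states)
  if (n_states < 2L || n_states > 32L) abort("`n_states` must be in 2..32.")
  counts <- unclass(a)
  if (all(counts == 0L)) abort("no informative characters: all counts are zero")
  maxc <- apply(counts, 2L, max)
  drop <- maxc == 0L
  if (any(drop)) {
    warn(paste0("Dropping ", sum(drop), " character(s) with all-zero counts: ",
                paste(utils::head(colnames(counts)[drop], 5L), collapse = ", "),
                if (sum(drop) > 5L) ", ..." else ""))
    counts <- counts[, !drop, drop = FALSE]
    maxc <- maxc[!drop]
  }
  val <- if (scale == "log") log(counts + 1) else counts
  denom <- if (norm_scope == "per_character") {
    if (scale == "log") log(maxc + 1) else maxc
  } else {
    m <- max(counts)
    rep(if (scale == "log") log(m + 1) else m, ncol(counts))
  }
  states <- floor(sweep(val, 2L, (n_states - 1) / denom, `*`) + 0.5)
  storage.mode(states) <- "integer"
  coded_matrix(states, n_states = n_states,
               coding_params = list(n_states = n_states, scale = scale,
                                    norm_scope = norm_scope),
               groups = attr(a, "groups"))
}

#' Binary occurrence coding of an abundance matrix
#'
#' Codes presence/absence of each FSF: state 1 iff the count is positive.
#' This is the coding used with two-state occurrence stepmatrices.
#'
#' @param a An [abundance_matrix()].
#' @return A `coded_matrix` with states in \{0, 1\}.
#' @export
to_binary_occurrence <- function(a) {
  counts <- unclass(a)
  states <- ifelse(counts > 0L, 1L, 0L)
  storage.mode(states) <- "integer"
  coded_matrix(states, n_states = 2L,
               coding_params = list(n_states = 2L, scale = "occurrence",
                                    norm_scope = "none"),
               groups = attr(a, "groups"))
}

#' Construct a coded character matrix
#'
#' @param states Integer matrix of 0-based states (`NA` = missing), row names
#'   taxa, column names character ids.
#' @param n_states Alphabet size in use (2..32).
#' @param coding_params Provenance record of the coding configuration.
#' @param groups Optional named taxon group labels.
#' @return A `coded_matrix` object.
#' @export
coded_matrix <- function(states, n_states = 32L, coding_params = list(),
                         groups = NULL) {
  states <- as.matrix(states)
  if (is.null(rownames(states))) rownames(states) <- paste0("t", seq_len(nrow(states)))
  if (is.null(colnames(states))) colnames(states) <- paste0("c", seq_len(ncol(states)))
  storage.mode(states) <- "integer"
  n_states <- as.integer(n_states)
  rng <- range(states, na.rm = TRUE)
  if (ncol(states) > 0 && any(!is.na(states)) && (rng[1] < 0L || rng[2] >= n_states)) {
    abort("States must lie in 0..(n_states-1) or be NA.")
  }
  allna <- apply(states, 2L, function(v) all(is.na(v)))
  if (any(allna)) abort("Every character needs at least one non-missing state.")
  structure(states,
            n_states = n_states,
            alphabet = state_alphabet(max(2L, n_states)),
            coding_params = coding_params,
            groups = groups,
            class = c("coded_matrix", "matrix", "array"))
}

#' @export
print.coded_matrix <- function(x, ...) {
  cat("<coded_matrix> ", nrow(x), " taxa x ", ncol(x), " characters, ",
      attr(x, "n_states"), " states\n", sep = "")
  a <- attr(x, "alphabet")
  show <- unclass(x)[seq_len(min(nrow(x), 6L)), seq_len(min(ncol(x), 20L)), drop = FALSE]
  txt <- apply(show, 1L, function(v) paste(state_to_symbol(v, a), collapse = ""))
  for (i in seq_along(txt)) cat(format(names(txt)[i], width = 12), txt[i], "\n")
  invisible(x)
}

#' @export
tidy.coded_matrix <- function(x, ...) {
  df <- as.data.frame(unclass(x), check.names = FALSE)
  df$taxon <- rownames(x)
  tidyr::pivot_longer(tibble::as_tibble(df), cols = -"taxon",
                      names_to = "character", values_to = "state")
}

# internal: subset a coded matrix to taxa, preserving attributes
.subset_coded <- function(m, taxa_keep) {
  coded_matrix(unclass(m)[taxa_keep, , drop = FALSE],
               n_states = attr(m, "n_states"),
               coding_params = attr(m, "coding_params"),
               groups = attr(m, "groups"))
}

#' Append a hypothetical-ancestor row to a coded matrix
#'
#' Adds one taxon row (named `".ANC"` by default) holding the given ancestor
#' states, so that trees carrying the ancestor leaf produced by
#' [lundberg_root()] can be scored and reconstructed against the matrix.
#'
#' @param m A [coded_matrix()].
#' @param ancestor Single symbol (recycled), full-length state string, `"?"`
#'   or `"standard"` (all-missing).
#' @param label Row name for the ancestor.
#' @return A [coded_matrix()] with one extra row.
#' @export
add_ancestor_row <- function(m, ancestor = "0", label = ".ANC") {
  anc <- .ancestor_states(ancestor, m)
  states <- rbind(unclass(m), matrix(anc, 1L, dimnames = list(label)))
  coded_matrix(states, n_states = attr(m, "n_states"),
               coding_params = attr(m, "coding_params"),
               groups = attr(m, "groups"))
}
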