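#' Read and write Newick trees with an explicit rootedness convention
#'
#' Newick text is ambiguous about rootedness; this package adopts the usual
#' convention that a basal bifurcation denotes a rooted tree and a basal
#' trifurcation (or higher polytomy) denotes an unrooted one. `read_newick()`
#' parses a file or a literal string and validates leaf labels;
#' `write_newick()` serializes a `phylo` tree, refusing to silently change
#' rootedness.
#'
#' @param x A file path or a Newick string (detected by the presence of
#'   parentheses/semicolon).
#' @return A `phylo` tree.
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' ape::is.rooted(tr)
#' @export
read_newick <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[();]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  if (!grepl(";\\s*$", txt)) txt <- paste0(txt, ";")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close) {
    abort(sprintf("Malformed Newick: %d '(' vs %d ')' (first imbalance near position %d).",
                  n_open, n_close, .newick_imbalance_pos(txt)))
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e))))
  if (is.null(tree)) abort("Newick parse error: no tree found.")
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("Duplicate leaf label(s): ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")))
  }
  tree
}

.newick_imbalance_pos <- function(txt) {
  ch <- strsplit(txt, "")[[1]]
  depth <- cumsum((ch == "(") - (ch == ")"))
  bad <- which(depth < 0)
  if (length(bad)) bad[1] else nchar(txt)
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) abort("Duplicate leaf labels.")
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
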