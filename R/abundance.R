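#' Construct a proteome x FSF abundance matrix
#'
#' The basic input of the pipeline: a census of how many copies of each fold
#' superfamily (FSF) structural domain occur in each proteome. Rows are
#' proteomes (taxa), columns are FSFs, cells are non-negative integer counts.
#' Each taxon can carry a superkingdom-style group label (e.g. Archaea,
#' Bacteria, Eukarya) used by rooting diagnostics.
#'
#' @param counts A numeric matrix (or data frame) of non-negative integers,
#'   with row names = taxon ids and column names = FSF ids.
#' @param groups Optional named character vector mapping each taxon to a group
#'   label.
#' @return An object of class `abundance_matrix` (an integer matrix with a
#'   `groups` attribute).
#' @examples
#' m <- abundance_matrix(matrix(c(0, 3, 1, 0), 2, 2,
#'   dimnames = list(c("t1", "t2"), c("f1", "f2"))))
#' taxa(m)
#' @export
abundance_matrix <- function(counts, groups = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("t", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("FSF", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) abort("Duplicate taxon ids.")
  if (anyDuplicated(colnames(counts))) abort("Duplicate FSF ids.")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(counts))
    abort(sprintf(
      "Abundance cell (%s, %s) is not a non-negative integer: %s",
      rownames(counts)[rc[1]], colnames(counts)[rc[2]],
      as.character(counts[bad[1]])
    ))
  }
  storage.mode(counts) <- "integer"
  if (!is.null(groups)) {
    if (is.null(names(groups))) {
      if (length(groups) != nrow(counts)) {
        abort("`groups` must be named by taxon or have one entry per taxon.")
      }
      names(groups) <- rownames(counts)
    }
    missing <- setdiff(rownames(counts), names(groups))
    if (length(missing)) {
      abort(paste0("No group label for taxa: ", paste(missing, collapse = ", ")))
    }
    groups <- groups[rownames(counts)]
  }
  structure(counts, groups = groups, class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("<abundance_matrix> ", nrow(x), " proteomes x ", ncol(x), " FSFs\n", sep = "")
  g <- attr(x, "groups")
  if (!is.null(g)) {
    tab <- table(g)
    cat("groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE]))
  invisible(x)
}

#' Taxa, FSF ids and group labels of pipeline objects
#' @param x An `abundance_matrix` or `coded_matrix`.
#' @return Character vector of taxon ids / FSF or character ids / group labels.
#' @export
taxa <- function(x) rownames(x)

#' @rdname taxa
#' @export
fsf_ids <- function(x) colnames(x)

#' @rdname taxa
#' @export
taxon_groups <- function(x) attr(x, "groups")

#' Read a proteome x FSF abundance table from disk
#'
#' Expects a tab- or comma-separated table whose first column holds taxon ids
#' and whose header row holds FSF ids. An optional `group` column (any
#' position, named `group`) carries taxon group labels. All remaining cells
#' must be non-negative integers.
#'
#' @param path File path.
#' @param sep Field separator; guessed from the file extension/first line when
#'   `NULL` (default).
#' @return An [abundance_matrix()].
#' @export
read_abundance_table <- function(path, sep = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) abort("Abundance table needs a taxon column and at least one FSF column.")
  taxa_ids <- as.character(df[[1L]])
  if (anyDuplicated(taxa_ids)) {
    abort(paste0("Duplicate taxon id(s): ",
                 paste(unique(taxa_ids[duplicated(taxa_ids)]), collapse = ", ")))
  }
  df <- df[-1L]
  groups <- NULL
  gcol <- which(tolower(names(df)) == "group")
  if (length(gcol)) {
    groups <- setNames(as.character(df[[gcol[1]]]), taxa_ids)
    df <- df[-gcol[1]]
  }
  if (anyDuplicated(names(df))) {
    abort(paste0("Duplicate FSF id(s): ",
                 paste(unique(names(df)[duplicated(names(df))]), collapse = ", ")))
  }
  counts <- as.matrix(df)
  suppressWarnings(storage.mode(counts) <- "numeric")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(counts))
    abort(sprintf("Cell (row '%s', column '%s') is not a non-negative integer.",
                  taxa_ids[rc[1]], colnames(counts)[rc[2]]))
  }
  rownames(counts) <- taxa_ids
  abundance_matrix(counts, groups = groups)
}

#' Write an abundance matrix as a tab-separated table
#'
#' Inverse of [read_abundance_table()]: first column `taxon`, then an optional
#' `group` column, then one column per FSF.
#'
#' @param x An [abundance_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  df <- data.frame(taxon = rownames(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  g <- attr(x, "groups")
  if (!is.null(g)) df$group <- unname(g[rownames(x)])
  df <- cbind(df, as.data.frame(unclass(x), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
as_tibble.abundance_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(unclass(x), check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(taxon = rownames(x)), out)
  g <- attr(x, "groups")
  if (!is.null(g)) out <- dplyr::bind_cols(out[1], tibble::tibble(group = unname(g[rownames(x)])), out[-1])
  out
}

#' @export
tidy.abundance_matrix <- function(x, ...) {
  long <- tidyr::pivot_longer(as_tibble.abundance_matrix(x),
                              cols = -dplyr::any_of(c("taxon", "group")),
                              names_to = "fsf", values_to = "count")
  long
}
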