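#' The 32-symbol ordered character-state alphabet
#'
#' Coded domain-abundance characters take states on an ordered alphanumeric
#' scale with up to 32 symbols: digits `0`-`9` followed by letters `A`-`V`.
#' State indices are 0-based (`0` -> 0, `V` -> 31) so that symbol order and
#' numeric order coincide, which is what makes the scale usable for ordered
#' (Wagner) characters.
#'
#' @param n_states Number of states to expose (2 to 32).
#' @return An object of class `state_alphabet`: a character vector of symbols
#'   with an index map attached.
#' @examples
#' a <- state_alphabet()
#' a$symbols[c(1, 32)] # "0" and "V"
#' symbol_to_state(c("0", "A", "V"))
#' @export
state_alphabet <- function(n_states = 32L) {
  n_states <- as.integer(n_states)
  if (is.na(n_states) || n_states < 2L || n_states > 32L) {
    abort("`n_states` must be an integer in 2..32.")
  }
  symbols <- c(as.character(0:9), LETTERS[1:22])[seq_len(n_states)]
  structure(
    list(
      symbols = symbols,
      index = setNames(seq_len(n_states) - 1L, symbols),
      n_states = n_states
    ),
    class = "state_alphabet"
  )
}

#' @export
print.state_alphabet <- function(x, ...) {
  cat("<state_alphabet> ", x$n_states, " symbols: ",
      paste(x$symbols, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Convert between state symbols and 0-based state indices
#'
#' `?` denotes missing data and maps to `NA`.
#'
#' @param symbols Character vector of single-character state symbols.
#' @param states Integer vector of 0-based states (or `NA`).
#' @param alphabet A [state_alphabet()].
#' @return An integer vector (`symbol_to_state`) or character vector
#'   (`state_to_symbol`).
#' @export
symbol_to_state <- function(symbols, alphabet = state_alphabet()) {
  out <- unname(alphabet$index[symbols])
  bad <- !is.na(symbols) & symbols != "?" & is.na(out)
  if (any(bad)) {
    abort(paste0("Symbol(s) outside the alphabet: ",
                 paste(unique(symbols[bad]), collapse = ", ")))
  }
  out[!is.na(symbols) & symbols == "?"] <- NA_integer_
  as.integer(out)
}

#' @rdname symbol_to_state
#' @export
state_to_symbol <- function(states, alphabet = state_alphabet()) {
  if (any(!is.na(states) & (states < 0L | states >= alphabet$n_states))) {
    abort("State index outside the alphabet range.")
  }
  out <- rep("?", length(states))
  ok <- !is.na(states)
  out[ok] <- alphabet$symbols[states[ok] + 1L]
  out
}
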