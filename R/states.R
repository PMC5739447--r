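#' State string / integer conversions
#'
#' Network states are fixed-width bit vectors aligned to the network's
#' node order. The canonical string form puts the FIRST node leftmost
#' (so the catalog state `"1001000"` reads
#' Activator/DegProtein/DegRNA/DNA/miRNA/mRNA/Protein); the canonical
#' integer form reads that string as a base-2 number, leftmost bit most
#' significant. Integers are 0-based (`0` is the all-OFF state).
#'
#' @param state Integer state code(s) in `0 .. 2^n - 1`.
#' @param n Number of nodes (bit width).
#' @return `stateToString()`: character vector of `n`-character bit
#'   strings. `stateFromString()`: integer vector of state codes.
#' @examples
#' stateToString(72L, 7)          # "1001000"
#' stateFromString("1001000")    # 72
#' @export
stateToString <- function(state, n) {
  state <- as.integer(state)
  stopifnot(all(state >= 0L), all(state < 2^n))
  vapply(state, function(s) {
    paste(bitwAnd(s %/% 2L^((n - 1L):0L), 1L), collapse = "")
  }, character(1))
}

#' @rdname stateToString
#' @param string State string(s) made of `0`/`1` characters.
#' @export
stateFromString <- function(string) {
  vapply(string, function(s) {
    if (!grepl("^[01]+$", s)) {
      stop(sprintf("malformed state string '%s'", s), call. = FALSE)
    }
    strtoi(s, base = 2L)
  }, integer(1), USE.NAMES = FALSE)
}

# number of set bits for each of 0..2^n-1 (internal lookup builder)
.popcountTable <- function(n) {
  states <- 0:(2L^n - 1L)
  counts <- integer(2L^n)
  for (i in seq_len(n)) counts <- counts + bitwAnd(states %/% 2L^(i - 1L), 1L)
  counts
}
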