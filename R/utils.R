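#' Canonical edge keys
#'
#' Edges are undirected: the canonical key of a pair is
#' `"<min>|<max>"` under lexicographic node order, so `(a,b)` and `(b,a)`
#' map to the same key.
#'
#' @param a,b character vectors of node identifiers (recycled).
#' @return character vector of canonical keys.
#' @export
edge_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Split canonical edge keys back into endpoints
#'
#' @param key character vector of `"a|b"` keys.
#' @return two-column character matrix (`a`, `b`).
#' @export
edge_endpoints <- function(key) {
  parts <- strsplit(as.character(key), "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed edge key(s): ", paste(key[bad], collapse = ", "))
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("a", "b")
  m
}

# round-half-up (round() is banker's rounding; 64865 * 0.001 must give 65)
round_half_up <- function(x) floor(x + 0.5)

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two partitions agree (both together or
#' both apart). Used to compare a recovered edge clustering with a planted one.
#'
#' @param x,y cluster label vectors of equal length (any atomic type).
#' @return the Rand index in `[0, 1]`; 1 for identical partitions.
#' @export
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  same_x <- outer(x, x, "==")
  same_y <- outer(y, y, "==")
  ut <- upper.tri(same_x)
  mean(same_x[ut] == same_y[ut])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
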