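#' Undirected protein interaction network
#'
#' A `ppi_network` is a simple (no self-loops, no multi-edges) undirected
#' graph stored as a canonical edge table: columns `a`, `b` with `a < b`
#' lexicographically, plus the key `"a|b"`. Rows are sorted by key, so two
#' networks with the same edge set are identical objects.
#'
#' @param a,b character vectors of endpoints (one edge per element).
#' @return a `ppi_network` object.
#' @export
ppi_network <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  keep <- a != b
  n_loops <- sum(!keep)
  a <- a[keep]; b <- b[keep]
  key <- edge_key(a, b)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  key <- key[!dup]
  ord <- order(key, method = "radix")
  key <- key[ord]
  ep <- edge_endpoints(key)
  net <- structure(
    list(
      edges = data.frame(a = ep[, "a"], b = ep[, "b"], key = key,
                         stringsAsFactors = FALSE),
      nodes = sort(unique(c(ep[, "a"], ep[, "b"])))
    ),
    class = "ppi_network"
  )
  attr(net, "dropped_self_loops") <- n_loops
  attr(net, "dropped_duplicates") <- n_dup
  net
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

#' Convert a `ppi_network` to an igraph graph
#'
#' @param net a `ppi_network`.
#' @param nodes optional extra (possibly isolated) vertices to include.
#' @return an undirected `igraph` graph with vertex names.
#' @export
as_igraph <- function(net, nodes = NULL) {
  vs <- sort(unique(c(net$nodes, nodes)))
  igraph::graph_from_data_frame(net$edges[, c("a", "b")], directed = FALSE,
                                vertices = vs)
}

# node -> incident edge keys, for the eDMS frontier
incidence_list <- function(net) {
  ab <- c(net$edges$a, net$edges$b)
  kk <- c(net$edges$key, net$edges$key)
  split(kk, ab)
}

header_like <- function(fields) {
  pat <- "protein|gene|node|source|target|interactor|symbol|entrez|^id$|_a$|_b$"
  any(grepl(pat, tolower(fields)))
}

#' Read an interaction network from an edge-list TSV or SIF file
#'
#' Accepts a two-column tab- or whitespace-separated edge list (extra columns
#' ignored), or a SIF file (`a <type> b`; chosen when the extension is
#' `.sif` or `format = "sif"`). A leading header line mentioning common
#' column names (protein/gene/source/target/...) is detected and skipped.
#' Self-loops and duplicate edges are removed; counts are reported via
#' `message()`.
#'
#' @param path file path.
#' @param format `"auto"` (default, by extension), `"tsv"` or `"sif"`.
#' @return a [ppi_network].
#' @export
read_network <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty network file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  fields <- strsplit(lines, "[\t ]+")
  if (header_like(fields[[1]])) fields <- fields[-1]
  if (length(fields) == 0L) stop("network file contains only a header: ", path)
  nf <- lengths(fields)
  if (format == "sif") {
    if (any(nf < 3L)) stop("SIF rows need >= 3 fields; offending row(s): ",
                           paste(which(nf < 3L), collapse = ", "))
    a <- vapply(fields, `[`, "", 1L)
    b <- vapply(fields, `[`, "", 3L)
  } else {
    if (any(nf < 2L)) stop("edge-list rows need >= 2 columns; offending row(s): ",
                           paste(which(nf < 2L), collapse = ", "))
    a <- vapply(fields, `[`, "", 1L)
    b <- vapply(fields, `[`, "", 2L)
  }
  net <- ppi_network(a, b)
  nl <- attr(net, "dropped_self_loops"); nd <- attr(net, "dropped_duplicates")
  if (nl + nd > 0L) {
    message(sprintf("read_network: dropped %d self-loop(s) and %d duplicate edge(s)",
                    nl, nd))
  }
  net
}

#' Restrict a network to the genes of an expression matrix
#'
#' Induced subgraph on the genes measured in `expr`; nodes that lose all
#' their edges are dropped.
#'
#' @param net a [ppi_network].
#' @param expr an expression matrix (genes in rows, see [read_expression]).
#' @return the restricted [ppi_network].
#' @export
restrict_network <- function(net, expr) {
  genes <- rownames(expr)
  keep <- net$edges$a %in% genes & net$edges$b %in% genes
  if (!any(keep)) stop("no network edge has both endpoints in the expression matrix")
  ppi_network(net$edges$a[keep], net$edges$b[keep])
}
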