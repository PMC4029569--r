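#' Union of transition subnetworks with full dC trajectories
#'
#' @param subs list of `subnetwork`s (>= 1).
#' @param profiles an [edge_profiles] frame covering every union edge.
#' @return `list(edges = <frame a,b,key>, dc = <edges x transitions matrix>,
#'   r = <edges x stages matrix>)`, class `union_subnetwork`; rows sorted by
#'   edge key.
#' @export
union_subnetworks <- function(subs, profiles) {
  stopifnot(length(subs) >= 1L)
  keys <- sort(unique(unlist(lapply(subs, function(s) s$edges$key))))
  idx <- match(keys, profiles$key)
  if (anyNA(idx)) stop("union edge(s) missing from profiles: ",
                       paste(keys[is.na(idx)], collapse = ", "))
  ep <- edge_endpoints(keys)
  structure(
    list(edges = data.frame(a = ep[, "a"], b = ep[, "b"], key = keys,
                            stringsAsFactors = FALSE),
         dc = profile_dc(profiles)[idx, , drop = FALSE],
         r = profile_r(profiles)[idx, , drop = FALSE]),
    class = "union_subnetwork")
}

#' @export
print.union_subnetwork <- function(x, ...) {
  cat(sprintf("union_subnetwork: %d edges, %d transitions\n",
              nrow(x$edges), ncol(x$dc)))
  invisible(x)
}

#' Cluster union edges by their dC trajectories
#'
#' Complete-linkage hierarchical clustering of the per-edge dC vectors under
#' Euclidean distance, cut into `k` clusters. Rows are sorted by canonical
#' edge key before clustering, so the result does not depend on input edge
#' order.
#'
#' @param x a `union_subnetwork` (from [union_subnetworks]) or a numeric
#'   matrix of dC vectors with edge keys as rownames.
#' @param k number of clusters (default 6), `1 <= k <=` number of edges.
#' @return a `cluster_assignment` data frame `key`, `cluster` with the
#'   `hclust` tree in `attr(, "tree")` and `k` in `attr(, "k")`.
#' @export
cluster_edges <- function(x, k = 6L) {
  dc <- if (inherits(x, "union_subnetwork")) x$dc else as.matrix(x)
  if (is.null(rownames(dc))) stop("dC matrix needs edge keys as rownames")
  ord <- order(rownames(dc), method = "radix")
  dc <- dc[ord, , drop = FALSE]
  n <- nrow(dc)
  if (k < 1L || k > n) stop("k must be between 1 and the number of edges (", n, ")")
  if (n == 1L) {
    cl <- 1L
    tree <- NULL
  } else {
    tree <- stats::hclust(stats::dist(dc, method = "euclidean"),
                          method = "complete")
    cl <- stats::cutree(tree, k = k)
  }
  out <- data.frame(key = rownames(dc), cluster = as.integer(cl),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  attr(out, "k") <- as.integer(k)
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Per-cluster component statistics
#'
#' For each cluster, the connected components of its edge-induced subgraph:
#' edge/node counts, number of components with >= `min_genes` genes, and
#' the largest component size.
#'
#' @param assignment a `cluster_assignment`.
#' @param min_genes component size threshold (default 5).
#' @return data frame `cluster`, `n_edges`, `n_nodes`,
#'   `n_components_min`, `largest_component`.
#' @export
cluster_components <- function(assignment, min_genes = 5L) {
  ks <- sort(unique(assignment$cluster))
  rows <- lapply(ks, function(cl) {
    edges <- assignment$key[assignment$cluster == cl]
    comps <- edge_components(edges)
    sizes <- vapply(comps, function(c) length(c$nodes), 0L)
    data.frame(cluster = cl,
               n_edges = length(edges),
               n_nodes = length(unique(unlist(lapply(comps, `[[`, "nodes")))),
               n_components_min = sum(sizes >= min_genes),
               largest_component = max(sizes))
  })
  do.call(rbind, rows)
}

#' Mean correlation / dC trajectory of each cluster
#'
#' @param assignment a `cluster_assignment`.
#' @param profiles an [edge_profiles] frame covering the assigned edges.
#' @return `list(r = <cluster x stage matrix of mean r>,
#'   dc = <cluster x transition matrix of mean dC>,
#'   n = <edges per cluster>)`.
#' @export
cluster_trajectory <- function(assignment, profiles) {
  idx <- match(assignment$key, profiles$key)
  if (anyNA(idx)) stop("assigned edge(s) missing from profiles")
  rmat <- profile_r(profiles)[idx, , drop = FALSE]
  dcmat <- profile_dc(profiles)[idx, , drop = FALSE]
  cl <- factor(assignment$cluster)
  agg <- function(m) {
    out <- apply(m, 2L, function(col) tapply(col, cl, mean))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                         dimnames = list(levels(cl), names(out)))
    out
  }
  list(r = agg(rmat), dc = agg(dcmat),
       n = as.integer(table(cl)))
}

#' Interfacing proteins between trajectory clusters
#'
#' Nodes whose incident union edges belong to at least two distinct
#' clusters; nodes touching every cluster are flagged.
#'
#' @param assignment a `cluster_assignment`.
#' @return data frame `node`, `degree` (within the union), `n_clusters`,
#'   `clusters` (comma-separated), `all_clusters` (logical), sorted by
#'   decreasing degree then name.
#' @export
interfacing_proteins <- function(assignment) {
  ep <- edge_endpoints(assignment$key)
  long <- data.frame(node = c(ep[, "a"], ep[, "b"]),
                     cluster = rep(assignment$cluster, 2L))
  k_total <- length(unique(assignment$cluster))
  by_node <- split(long$cluster, long$node)
  n_cl <- vapply(by_node, function(v) length(unique(v)), 0L)
  deg <- lengths(by_node)
  keep <- n_cl >= 2L
  nodes <- names(by_node)[keep]
  out <- data.frame(
    node = nodes,
    degree = unname(deg[keep]),
    n_clusters = unname(n_cl[keep]),
    clusters = vapply(by_node[keep],
                      function(v) paste(sort(unique(v)), collapse = ","), ""),
    all_clusters = unname(n_cl[keep] == k_total),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$degree, out$node), , drop = FALSE]
}

#' Betweenness centrality ranking of a network's nodes
#'
#' Exact unweighted shortest-path betweenness (unnormalised — only ranks
#' matter), descending; ties broken lexicographically.
#'
#' @param net a [ppi_network], `union_subnetwork`, or `subnetwork`.
#' @return data frame `node`, `betweenness`, best first.
#' @export
betweenness_ranking <- function(net) {
  edges <- if (inherits(net, "ppi_network")) net$edges else net$edges
  if (!nrow(edges)) stop("empty graph")
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  ord <- order(-b, names(b), method = "radix")
  data.frame(node = names(b)[ord], betweenness = unname(b[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}
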