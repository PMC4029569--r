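# Independent oracles used to cross-check the package implementations.
# Each is written naively (recompute everything from scratch each step) so
# it stays independent of the code path it validates.

# literal greedy expansion: recompute frontier and means with mean() each step
oracle_expand <- function(module, net, dc, delta, max_iter = 100L) {
  module <- unique(module)
  accepted <- 0L
  repeat {
    if (accepted >= max_iter) break
    ep <- edge_endpoints(module)
    nodes <- unique(c(ep[, "a"], ep[, "b"]))
    touching <- net$edges$a %in% nodes | net$edges$b %in% nodes
    cand <- setdiff(net$edges$key[touching], module)
    if (!length(cand)) break
    cand <- cand[order(-dc[cand], cand, method = "radix")]
    best <- cand[1L]
    s_old <- mean(dc[module])
    s_new <- mean(dc[c(module, best)])
    rate <- if (s_old > 0) (s_old - s_new) / s_old else 0
    if (rate > delta) break
    module <- c(module, best)
    accepted <- accepted + 1L
  }
  sort(module)
}

# hand-rolled BFS distances from one source over an adjacency list
oracle_bfs_dist <- function(adj, from) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

oracle_adj <- function(net) {
  adj <- lapply(stats::setNames(nm = net$nodes), function(x) character())
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$a[i]; b <- net$edges$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# all-pairs mean shortest path within a gene set, excluding disconnected pairs
oracle_mean_sp <- function(genes, net) {
  adj <- oracle_adj(net)
  lens <- c(); excluded <- 0L
  genes <- sort(unique(genes))
  for (i in seq_along(genes)) {
    if (i == length(genes)) break
    d <- oracle_bfs_dist(adj, genes[i])
    for (j in seq((i + 1L), length(genes))) {
      dd <- d[[genes[j]]]
      if (is.finite(dd)) lens <- c(lens, dd) else excluded <- excluded + 1L
    }
  }
  list(mean = mean(lens), sd = if (length(lens) > 1) sd(lens) else 0,
       n_pairs = length(lens), excluded = excluded)
}

# betweenness by explicit enumeration of all shortest paths (tiny graphs)
oracle_betweenness <- function(net) {
  g <- as_igraph(net)
  nodes <- net$nodes
  btw <- stats::setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = nodes[i], to = nodes[j]))$vpaths
      if (!length(paths)) next
      for (p in paths) {
        inner <- setdiff(names(p), c(nodes[i], nodes[j]))
        btw[inner] <- btw[inner] + 1 / length(paths)
      }
    }
  }
  btw
}

# upper-tail hypergeometric by exhaustive enumeration of all draws
oracle_hyper <- function(universe_size, annotated_size, fg_size, observed) {
  draws <- utils::combn(universe_size, fg_size)
  mean(apply(draws, 2L, function(d) sum(d <= annotated_size) >= observed))
}

# --- tiny fixture builders ------------------------------------------------

# expression matrix where gene rows are given explicitly; samples named by
# stage with >=3 samples each
toy_design <- function(sizes = c(s1 = 3L, s2 = 3L)) {
  stages <- names(sizes)
  samples <- unlist(lapply(stages, function(s)
    paste0(s, "_", seq_len(sizes[[s]]))))
  stage_design(stats::setNames(rep(stages, sizes), samples), stages = stages)
}

toy_net <- function(...) {
  pairs <- list(...)
  ppi_network(vapply(pairs, `[`, "", 1L), vapply(pairs, `[`, "", 2L))
}

random_toy_net <- function(n_nodes, n_edges) {
  all_pairs <- t(utils::combn(sprintf("n%02d", seq_len(n_nodes)), 2L))
  idx <- sample(nrow(all_pairs), min(n_edges, nrow(all_pairs)))
  ppi_network(all_pairs[idx, 1L], all_pairs[idx, 2L])
}
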