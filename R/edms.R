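#' Configuration for the edgewise dense module search
#'
#' @param delta relative module-score decrease tolerance; `NULL` means
#'   "choose by [scan_delta]".
#' @param delta_grid grid scanned by [scan_delta] (default 0 to 0.1 by 0.01).
#' @param max_iterations cap on accepted absorptions per initial module
#'   (default 100), controlling module size.
#' @param min_component_genes components with fewer genes are discarded from
#'   the final subnetwork (default 5).
#' @param seed_fraction top fraction of ranked DCPs used as seeds
#'   (default 0.001).
#' @return an `edms_config` list.
#' @export
edms_config <- function(delta = NULL, delta_grid = seq(0, 0.1, by = 0.01),
                        max_iterations = 100L, min_component_genes = 5L,
                        seed_fraction = 0.001) {
  stopifnot(is.null(delta) || delta >= 0, length(delta_grid) >= 1L,
            all(delta_grid >= 0), max_iterations >= 1L,
            min_component_genes >= 1L,
            seed_fraction > 0, seed_fraction <= 1)
  structure(list(delta = delta, delta_grid = delta_grid,
                 max_iterations = as.integer(max_iterations),
                 min_component_genes = as.integer(min_component_genes),
                 seed_fraction = seed_fraction),
            class = "edms_config")
}

#' Module score: mean absolute dC over the member edges
#'
#' @param edges canonical edge keys (non-empty).
#' @param dc_map named numeric vector of `|dC|` per edge key
#'   (see [dc_map]).
#' @return the mean `|dC|`.
#' @export
module_score <- function(edges, dc_map) {
  if (!length(edges)) stop("module score of an empty edge set")
  v <- dc_map[edges]
  if (anyNA(v)) stop("edge(s) missing from dc_map: ",
                     paste(edges[is.na(v)], collapse = ", "))
  mean(v)
}

#' Initial modules: connected components of the seed edges
#'
#' @param seed_edges canonical edge keys (or a frame with a `key` column).
#' @param net the reference [ppi_network] (seeds must belong to it).
#' @return list of character vectors of edge keys, one per component,
#'   ordered by their smallest edge key.
#' @export
seed_components <- function(seed_edges, net) {
  if (is.data.frame(seed_edges)) seed_edges <- seed_edges$key
  seed_edges <- unique(as.character(seed_edges))
  if (!all(seed_edges %in% net$edges$key))
    stop("seed edge(s) absent from the network: ",
         paste(utils::head(setdiff(seed_edges, net$edges$key)), collapse = ", "))
  ep <- edge_endpoints(seed_edges)
  g <- igraph::graph_from_data_frame(
    data.frame(ep, key = seed_edges, stringsAsFactors = FALSE),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[ep[, "a"]]
  comps <- unname(split(seed_edges, comp_of_edge))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, "", 1L))]
}

#' Greedy expansion of one module (eDMS inner loop)
#'
#' Repeatedly absorbs, among all network edges outside the module with at
#' least one endpoint in the module's node set, the edge with maximum
#' `|dC|` (ties by edge key). The absorption is kept iff the relative
#' decrease of the module score, `(S - S') / S`, is at most `delta`
#' (score increases are always kept); the first rejection stops the loop,
#' as does reaching `max_iterations` accepted absorptions.
#'
#' @param module character vector of member edge keys.
#' @param net the reference [ppi_network].
#' @param dc_map named `|dC|` vector over all network edges.
#' @param config an [edms_config] with a non-`NULL` `delta`.
#' @param incidence optional precomputed `incidence_list(net)` (internal
#'   speed-up for [scan_delta]).
#' @return the expanded edge-key vector (always a superset of `module`).
#' @export
expand_module <- function(module, net, dc_map, config, incidence = NULL) {
  delta <- config$delta
  if (is.null(delta)) stop("config$delta must be set for expand_module")
  if (is.null(incidence)) incidence <- incidence_list(net)
  module <- unique(as.character(module))
  in_module <- stats::setNames(rep(TRUE, length(module)), module)
  ep <- edge_endpoints(module)
  nodes <- unique(c(ep[, "a"], ep[, "b"]))
  score_sum <- sum(dc_map[module])
  n_member <- length(module)
  accepted <- 0L
  repeat {
    if (accepted >= config$max_iterations) break
    frontier <- unique(unlist(incidence[nodes], use.names = FALSE))
    frontier <- frontier[is.na(in_module[frontier])]
    if (!length(frontier)) break
    sc <- dc_map[frontier]
    best <- frontier[order(-sc, frontier, method = "radix")[1L]]
    s_old <- score_sum / n_member
    s_new <- (score_sum + dc_map[[best]]) / (n_member + 1L)
    # s_old == 0 can only happen when every member |dC| is 0; accept then
    rate <- if (s_old > 0) (s_old - s_new) / s_old else 0
    if (rate > delta) break
    in_module[[best]] <- TRUE
    score_sum <- score_sum + dc_map[[best]]
    n_member <- n_member + 1L
    accepted <- accepted + 1L
    nodes <- unique(c(nodes, edge_endpoints(best)))
  }
  sort(names(in_module))
}

# connected components of an edge-key set; list of list(edges, nodes)
edge_components <- function(edges) {
  ep <- edge_endpoints(edges)
  g <- igraph::graph_from_data_frame(as.data.frame(ep), directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- unname(memb[ep[, "a"]])
  lapply(split(seq_along(edges), comp_of_edge), function(idx) {
    e <- sort(edges[idx])
    epp <- edge_endpoints(e)
    list(edges = e, nodes = sort(unique(c(epp[, "a"], epp[, "b"]))))
  })
}

#' Edgewise dense module search (eDMS)
#'
#' Expands every seed component with [expand_module], unions the expanded
#' modules, and removes connected components with fewer than
#' `min_component_genes` genes. The result carries per-component edge sets
#' and module scores.
#'
#' @param net the reference [ppi_network].
#' @param dc_map named `|dC|` vector over network edges.
#' @param seed_edges seed DCP edge keys (or a frame with `key`).
#' @param config an [edms_config] with `delta` set.
#' @param transition optional transition index stored on the result.
#' @return a `subnetwork` object: `list(edges = <data frame a,b,key,score>,
#'   components = <list of list(edges, nodes, score)>, delta, transition)`.
#' @export
edms <- function(net, dc_map, seed_edges, config, transition = NA_integer_) {
  comps <- seed_components(seed_edges, net)
  incidence <- incidence_list(net)
  expanded <- lapply(comps, expand_module, net = net, dc_map = dc_map,
                     config = config, incidence = incidence)
  all_edges <- sort(unique(unlist(expanded, use.names = FALSE)))
  final <- edge_components(all_edges)
  final <- Filter(function(cmp) length(cmp$nodes) >= config$min_component_genes,
                  final)
  if (!length(final))
    stop(sprintf(paste0("eDMS: all components fall below %d genes ",
                        "(union had %d edges); consider a larger delta or ",
                        "more seeds"),
                 config$min_component_genes, length(all_edges)))
  final <- lapply(final, function(cmp) {
    cmp$score <- module_score(cmp$edges, dc_map)
    cmp
  })
  keys <- sort(unique(unlist(lapply(final, `[[`, "edges"), use.names = FALSE)))
  ep <- edge_endpoints(keys)
  structure(
    list(edges = data.frame(a = ep[, "a"], b = ep[, "b"], key = keys,
                            score = unname(dc_map[keys]),
                            stringsAsFactors = FALSE),
         components = final,
         delta = config$delta,
         transition = transition),
    class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  nodes <- unique(c(x$edges$a, x$edges$b))
  cat(sprintf("subnetwork: %d nodes, %d edges, %d component(s), delta = %s%s\n",
              length(nodes), nrow(x$edges), length(x$components),
              format(x$delta),
              if (is.na(x$transition)) "" else
                sprintf(", transition %d", x$transition)))
  invisible(x)
}

subnetwork_nodes <- function(sub) sort(unique(c(sub$edges$a, sub$edges$b)))

#' Overall module score of a subnetwork
#'
#' Unweighted mean of the module scores of the subnetwork's connected
#' components; the objective maximised by the delta scan.
#'
#' @param sub a `subnetwork` from [edms].
#' @return numeric scalar.
#' @export
overall_module_score <- function(sub) {
  stopifnot(length(sub$components) >= 1L)
  mean(vapply(sub$components, `[[`, 0, "score"))
}

#' Scan the delta grid and pick the best tolerance
#'
#' Runs [edms] at every grid value and selects the delta with the maximal
#' overall module score (ties: the smallest delta). Grid values at which
#' every component is filtered out are recorded as failed (`NA` score).
#'
#' @inheritParams edms
#' @return `list(best_delta, best = <subnetwork>, report = <data frame
#'   delta, overall_score, n_edges, n_nodes, n_components>)`.
#' @export
scan_delta <- function(net, dc_map, seed_edges, config,
                       transition = NA_integer_) {
  grid <- sort(unique(config$delta_grid))
  runs <- vector("list", length(grid))
  report <- data.frame(delta = grid, overall_score = NA_real_,
                       n_edges = NA_integer_, n_nodes = NA_integer_,
                       n_components = NA_integer_)
  for (i in seq_along(grid)) {
    cfg <- config
    cfg$delta <- grid[i]
    sub <- tryCatch(edms(net, dc_map, seed_edges, cfg, transition = transition),
                    error = function(e) NULL)
    if (!is.null(sub)) {
      runs[[i]] <- sub
      report$overall_score[i] <- overall_module_score(sub)
      report$n_edges[i] <- nrow(sub$edges)
      report$n_nodes[i] <- length(subnetwork_nodes(sub))
      report$n_components[i] <- length(sub$components)
    }
  }
  if (all(is.na(report$overall_score)))
    stop("delta scan failed at every grid value (all components filtered out)")
  best_i <- which(report$overall_score == max(report$overall_score,
                                              na.rm = TRUE))[1L]
  list(best_delta = grid[best_i], best = runs[[best_i]], report = report)
}
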