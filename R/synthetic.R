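#' Generate a random interactome
#'
#' Scale-free graphs come from preferential attachment (heavy-tailed
#' degrees, hubs guaranteed at moderate size); Erdos-Renyi is available as a
#' homogeneous control. The result is simple and connected (components of a
#' disconnected draw are chained together deterministically).
#'
#' @param n_nodes number of genes (>= 10).
#' @param model `"scale-free"` (default) or `"erdos-renyi"`.
#' @param seed RNG seed.
#' @param pa_m edges added per new node under preferential attachment
#'   (default 2).
#' @param er_p edge probability under Erdos-Renyi (default 0.02).
#' @return a [ppi_network] with node names `g0001`, `g0002`, ...
#' @export
generate_network <- function(n_nodes, model = c("scale-free", "erdos-renyi"),
                             seed = 1L, pa_m = 2L, er_p = 0.02) {
  model <- match.arg(model)
  if (n_nodes < 10L) stop("n_nodes must be >= 10")
  set.seed(seed)
  g <- switch(model,
    "scale-free" = igraph::sample_pa(n_nodes, m = pa_m, directed = FALSE),
    "erdos-renyi" = igraph::sample_gnp(n_nodes, p = er_p))
  g <- igraph::simplify(g)
  width <- max(4L, nchar(as.character(n_nodes)))
  igraph::V(g)$name <- sprintf(paste0("g%0", width, "d"), seq_len(n_nodes))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    anchors <- vapply(seq_len(comp$no), function(i)
      igraph::V(g)$name[which(comp$membership == i)[1L]], "")
    g <- igraph::add_edges(g, as.vector(rbind(anchors[-length(anchors)],
                                              anchors[-1L])))
  }
  el <- igraph::as_edgelist(g)
  ppi_network(el[, 1L], el[, 2L])
}

#' Plant edge groups with prescribed correlation trajectories
#'
#' Each group adds fresh genes wired as a random spanning tree (so a group
#' of `n_genes` genes contributes `n_genes - 1` planted edges) plus one
#' anchoring edge to a random background node (not part of the truth). The
#' group's expression will follow its per-stage target correlation
#' trajectory (see [generate_expression]).
#'
#' @param net background [ppi_network].
#' @param groups list of `list(n_genes, trajectory, name)`; `trajectory` is
#'   a length-K vector of target correlations in `(-0.99, 0.99)`.
#' @param seed RNG seed.
#' @return `list(net = <augmented network>, truth = <planted_truth>)`;
#'   the truth holds, per group, its genes, planted edge keys and
#'   trajectory.
#' @export
plant_modules <- function(net, groups, seed = 1L) {
  set.seed(seed)
  truth_groups <- list()
  a_all <- net$edges$a; b_all <- net$edges$b
  background_nodes <- net$nodes
  for (gi in seq_along(groups)) {
    gsp <- groups[[gi]]
    name <- gsp$name %||% sprintf("mod%d", gi)
    n_genes <- gsp$n_genes
    stopifnot(n_genes >= 2L)
    if (any(abs(gsp$trajectory) >= 0.99))
      stop("target correlations must lie in (-0.99, 0.99)")
    genes <- sprintf("%s_%03d", name, seq_len(n_genes))
    # random spanning tree: node i attaches to a uniform earlier node
    parent <- c(NA_integer_,
                vapply(2:n_genes, function(i) sample.int(i - 1L, 1L), 0L))
    ta <- genes[parent[-1L]]; tb <- genes[-1L]
    anchor <- sample(background_nodes, 1L)
    a_all <- c(a_all, ta, genes[1L]); b_all <- c(b_all, tb, anchor)
    truth_groups[[name]] <- list(
      name = name, genes = genes,
      edges = sort(edge_key(ta, tb)),
      trajectory = as.numeric(gsp$trajectory))
  }
  truth <- structure(list(groups = truth_groups), class = "planted_truth")
  list(net = ppi_network(a_all, b_all), truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  for (g in x$groups)
    cat(sprintf("group %s: %d genes, %d edges, trajectory (%s)\n",
                g$name, length(g$genes), length(g$edges),
                paste(format(g$trajectory), collapse = ", ")))
  invisible(x)
}

planted_edges <- function(truth)
  sort(unique(unlist(lapply(truth$groups, `[[`, "edges"), use.names = FALSE)))

# +/-1 signs from a 2-colouring of the group's spanning tree; every planted
# edge then links opposite colours, giving correlation -|r| under negative
# targets (trees are always bipartite)
bipartite_signs <- function(genes, edges) {
  g <- igraph::graph_from_data_frame(as.data.frame(edge_endpoints(edges)),
                                     directed = FALSE,
                                     vertices = genes)
  colour <- igraph::bfs(g, root = 1, dist = TRUE)$dist
  stats::setNames(ifelse(colour %% 2 == 0, 1, -1), genes)
}

#' Generate expression with planted per-stage correlations
#'
#' Background genes are independent Gaussian noise. Within each planted
#' group and stage with target correlation `r`, genes follow a shared
#' latent factor: `x = s * sqrt(|r|) * z + sqrt(1 - |r|) * e` with
#' `z, e ~ N(0, 1)`, so each planted edge's population correlation is
#' `s_i * s_j * |r|`; for negative targets the signs `s` come from a
#' 2-colouring of the group's tree, making every planted edge's correlation
#' `-|r|` exactly. Values are scaled by `noise_sd` and shifted by
#' `baseline` (log-scale intensities).
#'
#' @param net the (augmented) [ppi_network]; its nodes are the genes.
#' @param design a [stage_design].
#' @param truth a `planted_truth` from [plant_modules].
#' @param noise_sd marginal standard deviation (default 1).
#' @param baseline added mean (default 8, a typical log2 intensity).
#' @param seed RNG seed.
#' @return genes x samples numeric matrix.
#' @export
generate_expression <- function(net, design, truth, noise_sd = 1,
                                baseline = 8, seed = 1L) {
  set.seed(seed)
  genes <- net$nodes
  samples <- names(design$assignment)
  K <- n_stages(design)
  mat <- matrix(stats::rnorm(length(genes) * length(samples)),
                nrow = length(genes),
                dimnames = list(genes, samples))
  for (g in truth$groups) {
    if (length(g$trajectory) != K)
      stop("group ", g$name, ": trajectory length != number of stages")
    if (any(abs(g$trajectory) >= 0.99))
      stop("group ", g$name, ": |target| must be < 0.99")
    alt_signs <- if (any(g$trajectory < 0)) bipartite_signs(g$genes, g$edges)
                 else stats::setNames(rep(1, length(g$genes)), g$genes)
    for (k in seq_len(K)) {
      r_t <- g$trajectory[k]
      cols <- stage_samples(design, k)
      # alternating signs only where the target is negative; a positive
      # target needs a common-sign factor loading
      signs <- if (r_t < 0) alt_signs[g$genes] else rep(1, length(g$genes))
      w <- sqrt(abs(r_t))
      z <- stats::rnorm(length(cols))
      e <- matrix(stats::rnorm(length(g$genes) * length(cols)),
                  nrow = length(g$genes))
      x <- outer(signs * w, z) + sqrt(1 - abs(r_t)) * e
      mat[g$genes, cols] <- x
    }
  }
  baseline + noise_sd * mat
}

#' Mock marker gene sets enriched on planted genes
#'
#' Builds gene sets (mimicking disease marker lists) in which planted genes
#' are overrepresented by `enrichment_factor` relative to the background
#' inclusion rate, for direction tests of seed-quality diagnostics.
#'
#' @param net the augmented [ppi_network].
#' @param truth a `planted_truth`.
#' @param set_names names of the sets (default `c("markersA", "markersB")`).
#' @param background_rate inclusion probability for background genes
#'   (default 0.05).
#' @param enrichment_factor planted-gene inclusion multiplier (default 5).
#' @param seed RNG seed.
#' @return named list of gene sets.
#' @export
mock_gene_sets <- function(net, truth,
                           set_names = c("markersA", "markersB"),
                           background_rate = 0.05, enrichment_factor = 5,
                           seed = 1L) {
  set.seed(seed)
  planted <- sort(unique(unlist(lapply(truth$groups, `[[`, "genes"))))
  background <- setdiff(net$nodes, planted)
  p_planted <- min(1, background_rate * enrichment_factor)
  sets <- lapply(set_names, function(nm) {
    sel <- c(background[stats::runif(length(background)) < background_rate],
             planted[stats::runif(length(planted)) < p_planted])
    sort(sel)
  })
  stats::setNames(sets, set_names)
}

#' Simulate a complete multi-stage dataset with planted structure
#'
#' Defaults mirror a five-stage disease progression series: stages N, C, D,
#' E, A with 10, 10, 17, 18 and 17 samples. One planted group of 13 genes
#' (12 edges) rises to r = 0.9 in stages 2-3 against a near-zero
#' background.
#'
#' @param n_background_nodes background interactome size (default 500).
#' @param stage_sizes named integer vector: samples per stage, in stage
#'   order.
#' @param groups planted group specs for [plant_modules]; default one
#'   13-gene group with trajectory `(0, .9, .9, 0, 0)` (padded/truncated to
#'   K stages).
#' @param noise_sd,baseline see [generate_expression].
#' @param model,pa_m,er_p see [generate_network].
#' @param seed RNG seed (sub-seeds are derived deterministically).
#' @param out_dir optional directory: writes `expression.tsv`, `design.tsv`,
#'   `network.tsv`, `gene_sets.gmt` and `truth.json`.
#' @return `list(expr, design, net, truth, gene_sets, paths)`.
#' @export
simulate_dataset <- function(n_background_nodes = 500L,
                             stage_sizes = c(N = 10L, C = 10L, D = 17L,
                                             E = 18L, A = 17L),
                             groups = NULL,
                             noise_sd = 1, baseline = 8,
                             model = "scale-free", pa_m = 2L, er_p = 0.02,
                             seed = 1L, out_dir = NULL) {
  K <- length(stage_sizes)
  if (is.null(groups)) {
    traj <- rep(0, K); traj[seq(2L, min(3L, K))] <- 0.9
    groups <- list(list(n_genes = 13L, trajectory = traj, name = "mod1"))
  }
  stages <- names(stage_sizes) %||% paste0("S", seq_len(K))
  samples <- unlist(lapply(seq_len(K), function(k)
    sprintf("%s_s%02d", stages[k], seq_len(stage_sizes[k]))))
  assignment <- stats::setNames(rep(stages, stage_sizes), samples)
  design <- stage_design(assignment, stages = stages)

  base_net <- generate_network(n_background_nodes, model = model,
                               seed = seed, pa_m = pa_m, er_p = er_p)
  planted <- plant_modules(base_net, groups, seed = seed + 1L)
  expr <- generate_expression(planted$net, design, planted$truth,
                              noise_sd = noise_sd, baseline = baseline,
                              seed = seed + 2L)
  gene_sets <- mock_gene_sets(planted$net, planted$truth, seed = seed + 3L)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p_expr <- file.path(out_dir, "expression.tsv")
    p_des <- file.path(out_dir, "design.tsv")
    p_net <- file.path(out_dir, "network.tsv")
    p_gmt <- file.path(out_dir, "gene_sets.gmt")
    p_truth <- file.path(out_dir, "truth.json")
    write_expression(expr, design, p_expr, p_des)
    utils::write.table(planted$net$edges[, c("a", "b")], p_net, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = c("protein_a", "protein_b"))
    write_gene_sets(gene_sets, p_gmt)
    writeLines(jsonlite::toJSON(planted$truth$groups, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE), p_truth)
    paths <- list(expression = p_expr, design = p_des, network = p_net,
                  gene_sets = p_gmt, truth = p_truth)
  }
  list(expr = expr, design = design, net = planted$net,
       truth = planted$truth, gene_sets = gene_sets, paths = paths)
}

#' Edge-level recovery metrics against a planted truth
#'
#' Precision, recall and Jaccard of a found edge set versus the planted
#' edges; when a `cluster_assignment` and a multi-group truth are supplied,
#' also the Rand index between the recovered partition and the planted
#' grouping, restricted to planted edges.
#'
#' @param truth a `planted_truth`.
#' @param found a `subnetwork`, a `cluster_assignment`, or a character
#'   vector of edge keys.
#' @return `list(precision, recall, jaccard, rand)`; `rand` is `NA` unless
#'   `found` is a cluster assignment covering >= 2 planted edges.
#' @export
recovery_metrics <- function(truth, found) {
  tr <- planted_edges(truth)
  rand <- NA_real_
  if (inherits(found, "cluster_assignment")) {
    keys <- found$key
    planted_cl <- rep(names(truth$groups),
                      vapply(truth$groups, function(g) length(g$edges), 0L))
    names(planted_cl) <- unlist(lapply(truth$groups, `[[`, "edges"))
    shared <- intersect(keys, names(planted_cl))
    if (length(shared) >= 2L) {
      rand <- rand_index(planted_cl[shared],
                         found$cluster[match(shared, found$key)])
    }
  } else if (inherits(found, "subnetwork")) {
    keys <- found$edges$key
  } else {
    keys <- as.character(found)
  }
  keys <- unique(keys)
  tp <- length(intersect(keys, tr))
  list(precision = if (length(keys)) tp / length(keys) else 0,
       recall = tp / length(tr),
       jaccard = tp / length(union(keys, tr)),
       rand = rand)
}
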