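#' Build / read a pipeline run configuration
#'
#' A run config names the input files and the analysis parameters. It can
#' be given as an R list, or as a YAML / JSON file path. Unknown keys are
#' an error so typos fail fast.
#'
#' @param expression,design,network input file paths (required).
#' @param gene_sets optional GMT of marker sets for subnetwork summaries.
#' @param annotation optional GMT used for term enrichment of clusters.
#' @param hierarchy optional parent/child TSV for the leaf-term rule.
#' @param out_dir output directory (required).
#' @param seed_fraction,delta_grid,max_iterations,min_component_genes
#'   see [edms_config].
#' @param k_clusters clusters cut from the dC-trajectory dendrogram
#'   (default 6).
#' @param alpha adjusted-p cutoff for cluster enrichment (default 0.001).
#' @param min_foreground enrichment foreground-count filter (default 5).
#' @param pattern_fdr FDR for stage-pattern labels of recurrent edges
#'   (default 0.25).
#' @param seed RNG seed for any sampled background.
#' @return a validated `run_config` list.
#' @export
run_config <- function(expression, design, network, out_dir,
                       gene_sets = NULL, annotation = NULL, hierarchy = NULL,
                       seed_fraction = 0.001,
                       delta_grid = seq(0, 0.1, by = 0.01),
                       max_iterations = 100L, min_component_genes = 5L,
                       k_clusters = 6L, alpha = 0.001, min_foreground = 5L,
                       pattern_fdr = 0.25, seed = 1L) {
  cfg <- list(expression = expression, design = design, network = network,
              out_dir = out_dir, gene_sets = gene_sets,
              annotation = annotation, hierarchy = hierarchy,
              seed_fraction = seed_fraction, delta_grid = delta_grid,
              max_iterations = as.integer(max_iterations),
              min_component_genes = as.integer(min_component_genes),
              k_clusters = as.integer(k_clusters), alpha = alpha,
              min_foreground = as.integer(min_foreground),
              pattern_fdr = pattern_fdr, seed = as.integer(seed))
  for (f in c("expression", "design", "network")) {
    if (!file.exists(cfg[[f]]))
      stop("config: ", f, " file not found: ", cfg[[f]])
  }
  stopifnot(cfg$k_clusters >= 1L, cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

# profile caching: the correlation pass is the slow quadratic step, so its
# result is cached under a key derived from the input files' md5 sums
profile_cache_path <- function(cfg) {
  sums <- tools::md5sum(c(cfg$expression, cfg$design, cfg$network))
  key <- paste(substr(unname(sums), 1, 8), collapse = "")
  file.path(cfg$out_dir, "cache", paste0("profiles_", key, ".tsv"))
}

#' Run the full differential co-expression pipeline
#'
#' Executes the four analysis arrows in order: (1) per-edge stage
#' correlations, dC vectors and per-transition eDMS subnetworks from
#' top-fraction DCP seeds with delta selected by grid scan; (2) union of
#' the transition subnetworks; (3) complete-linkage clustering of union
#' edges by dC trajectory; (4) per-cluster modules, trajectories,
#' interfacing proteins, betweenness ranking, and (when an annotation is
#' supplied) term enrichment. All tables are written under
#' `config$out_dir`; a `run_log.txt` echoes the configuration.
#'
#' @param config a `run_config` (or a path accepted by [read_run_config]).
#' @return invisibly, a list with every intermediate object
#'   (`profiles`, `seeds`, `scans`, `subnetworks`, `union`, `clusters`,
#'   `summary`, ...).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  inp <- step("read_inputs", {
    ed <- read_expression(cfg$expression, cfg$design)
    net0 <- read_network(cfg$network)
    net <- restrict_network(net0, ed$expr)
    sets <- if (!is.null(cfg$gene_sets)) read_gene_sets(cfg$gene_sets) else list()
    ann <- if (!is.null(cfg$annotation)) read_gene_sets(cfg$annotation) else NULL
    hier <- if (!is.null(cfg$hierarchy))
      utils::read.delim(cfg$hierarchy, stringsAsFactors = FALSE) else NULL
    list(expr = ed$expr, design = ed$design, net = net, sets = sets,
         ann = ann, hier = hier)
  })
  K <- n_stages(inp$design)

  profiles <- step("edge_profiles", {
    cache <- profile_cache_path(cfg)
    if (file.exists(cache)) {
      read_edge_profiles(cache)
    } else {
      pr <- edge_profiles(inp$expr, inp$design, inp$net)
      dir.create(dirname(cache), recursive = TRUE, showWarnings = FALSE)
      write_edge_profiles(pr, cache)
      pr
    }
  })

  ecfg <- edms_config(delta_grid = cfg$delta_grid,
                      max_iterations = cfg$max_iterations,
                      min_component_genes = cfg$min_component_genes,
                      seed_fraction = cfg$seed_fraction)
  seeds <- list(); scans <- list(); subs <- list(); summaries <- list()
  for (k in seq_len(K - 1L)) {
    step(sprintf("transition_%d", k), {
      ranked <- rank_dcps(profiles, k)
      seed_set <- top_fraction(ranked, cfg$seed_fraction)
      scan <- scan_delta(inp$net, dc_map(profiles, k), seed_set$key, ecfg,
                         transition = k)
      seeds[[k]] <- seed_set
      scans[[k]] <- scan
      subs[[k]] <- scan$best
      prefix <- file.path(cfg$out_dir, sprintf("subnetwork_t%d", k))
      write_subnetwork(scan$best, prefix, profiles = profiles)
      utils::write.table(scan$report,
                         file.path(cfg$out_dir,
                                   sprintf("delta_scan_t%d.tsv", k)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(seed_set,
                         file.path(cfg$out_dir, sprintf("seeds_t%d.tsv", k)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summaries[[k]] <- subnetwork_summary(scan$best, inp$sets,
                                            universe = inp$net$nodes)
    })
  }
  summary_df <- do.call(rbind, summaries)
  utils::write.table(summary_df, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  recur <- if (length(subs) >= 2L) recurrent_edges(subs) else NULL
  patterns <- NULL
  if (!is.null(recur) && nrow(recur)) {
    patterns <- stage_pattern_labels(recur$key, profiles, fdr = cfg$pattern_fdr)
    utils::write.table(merge(recur, patterns, by = "key"),
                       file.path(cfg$out_dir, "recurrent_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  uni <- step("union", union_subnetworks(subs, profiles))
  k_cl <- min(cfg$k_clusters, nrow(uni$edges))
  clusters <- step("cluster", cluster_edges(uni, k = k_cl))
  comp_stats <- cluster_components(clusters,
                                   min_genes = cfg$min_component_genes)
  traj <- cluster_trajectory(clusters, profiles)
  interf <- interfacing_proteins(clusters)
  betw <- betweenness_ranking(uni)

  step("write_processwise", {
    write_subnetwork(structure(list(edges = uni$edges), class = "subnetwork"),
                     file.path(cfg$out_dir, "union"),
                     profiles = profiles, clusters = clusters)
    utils::write.table(as.data.frame(clusters),
                       file.path(cfg$out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(comp_stats,
                       file.path(cfg$out_dir, "cluster_components.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tr <- data.frame(cluster = rownames(traj$r), traj$r, check.names = FALSE)
    utils::write.table(tr, file.path(cfg$out_dir, "cluster_trajectories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(interf,
                       file.path(cfg$out_dir, "interfacing_proteins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(betw, file.path(cfg$out_dir, "betweenness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  enrich <- NULL
  if (!is.null(inp$ann)) {
    enrich <- step("enrichment", {
      per_cluster <- lapply(sort(unique(clusters$cluster)), function(cl) {
        genes <- dcgs_from_dcps(clusters$key[clusters$cluster == cl])
        res <- term_enrichment(intersect(genes, inp$net$nodes), inp$ann,
                               universe = inp$net$nodes)
        res <- adjust_and_filter(res, min_foreground = cfg$min_foreground,
                                 alpha = cfg$alpha, hierarchy = inp$hier)
        if (nrow(res)) cbind(cluster = cl, res) else NULL
      })
      out <- do.call(rbind, per_cluster)
      if (!is.null(out))
        utils::write.table(out,
                           file.path(cfg$out_dir, "cluster_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      out
    })
  }

  # config echo (deterministic: no timestamps, so reruns are hash-identical)
  log_lines <- c(
    sprintf("edmsnet %s", as.character(utils::packageVersion("edmsnet"))),
    sprintf("R %s.%s", R.version$major, R.version$minor),
    "config:",
    strsplit(yaml::as.yaml(unclass(cfg)), "\n")[[1]])
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(config = cfg, net = inp$net, design = inp$design,
                 profiles = profiles, seeds = seeds, scans = scans,
                 subnetworks = subs, summary = summary_df,
                 recurrent = recur, patterns = patterns, union = uni,
                 clusters = clusters, cluster_components = comp_stats,
                 trajectories = traj, interfacing = interf,
                 betweenness = betw, enrichment = enrich))
}
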