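#' Write a subnetwork as SIF + edge attributes + GraphML
#'
#' Emits `<prefix>.sif` (rows `a pp b`), `<prefix>_edges.tsv` (edge key,
#' per-stage r, per-transition dC, and cluster id when supplied), and
#' `<prefix>.graphml`.
#'
#' @param sub a `subnetwork` from [edms].
#' @param prefix output path prefix.
#' @param profiles optional [edge_profiles] supplying r / dC columns.
#' @param clusters optional cluster assignment (frame with `key`,
#'   `cluster`) merged into the attribute table.
#' @return invisibly, the vector of written paths.
#' @export
write_subnetwork <- function(sub, prefix, profiles = NULL, clusters = NULL) {
  sif <- paste0(prefix, ".sif")
  writeLines(paste(sub$edges$a, "pp", sub$edges$b, sep = "\t"), sif)

  attr_df <- sub$edges
  if (!is.null(profiles)) {
    keep <- c("key", grep("^(r_|dC_)", names(profiles), value = TRUE))
    attr_df <- merge(attr_df, as.data.frame(profiles)[, keep],
                     by = "key", all.x = TRUE, sort = FALSE)
  }
  if (!is.null(clusters)) {
    attr_df <- merge(attr_df, as.data.frame(clusters)[, c("key", "cluster")],
                     by = "key", all.x = TRUE, sort = FALSE)
  }
  attr_df <- attr_df[order(attr_df$key), , drop = FALSE]
  tsv <- paste0(prefix, "_edges.tsv")
  utils::write.table(attr_df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  g <- igraph::graph_from_data_frame(attr_df[, c("a", "b")], directed = FALSE)
  for (col in setdiff(names(attr_df), c("a", "b"))) {
    g <- igraph::set_edge_attr(g, col, value = attr_df[[col]])
  }
  gml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, gml, format = "graphml")
  invisible(c(sif, tsv, gml))
}
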