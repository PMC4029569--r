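#' Hub genes of a subnetwork
#'
#' Hubs are nodes with more than six connections (degree >= 7) within the
#' subnetwork itself (not the reference interactome).
#'
#' @param sub a `subnetwork`, or anything with an `edges` frame (`a`, `b`).
#' @param min_degree minimal hub degree (default 7).
#' @return sorted character vector of hub genes (possibly empty).
#' @export
find_hubs <- function(sub, min_degree = 7L) {
  deg <- table(c(sub$edges$a, sub$edges$b))
  sort(as.character(names(deg)[deg >= min_degree]))
}

#' Edges recurring in several transition subnetworks
#'
#' @param subs list of `subnetwork`s (>= 2), in transition order.
#' @return data frame `key`, `n`, `transitions` (comma-separated indices)
#'   for edges present in >= 2 subnetworks; zero rows when none recur.
#' @export
recurrent_edges <- function(subs) {
  stopifnot(length(subs) >= 2L)
  key_lists <- lapply(subs, function(s) unique(s$edges$key))
  long <- data.frame(
    key = unlist(key_lists, use.names = FALSE),
    transition = rep(seq_along(subs), lengths(key_lists)))
  tab <- table(long$key)
  keys <- sort(names(tab)[tab >= 2L])
  data.frame(
    key = keys,
    n = as.integer(tab[keys]),
    transitions = vapply(keys, function(k)
      paste(sort(long$transition[long$key == k]), collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-stage significance pattern labels for a set of edges
#'
#' For each stage, the correlation p-values of the given edges are BH
#' adjusted within the stage (the family is the edge set under scrutiny)
#' and each edge is labelled `HP` (significant, r > 0), `HN` (significant,
#' r < 0), or `NS` at the given FDR. An edge's pattern string joins its
#' per-stage labels, e.g. `"NS-HP-NS"`.
#'
#' @param edges canonical edge keys (must be in `profiles`).
#' @param profiles an [edge_profiles] frame.
#' @param fdr FDR level in (0, 1) (default 0.25).
#' @return data frame `key`, one label column per stage, `pattern`; the
#'   implied per-stage |r| cutoff (smallest significant |r|, `NA` when no
#'   edge is significant) is in `attr(, "r_cutoff")`.
#' @export
stage_pattern_labels <- function(edges, profiles, fdr = 0.25) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must be inside (0, 1)")
  edges <- unique(as.character(edges))
  idx <- match(edges, profiles$key)
  if (anyNA(idx)) stop("edge(s) missing from profiles: ",
                       paste(edges[is.na(idx)], collapse = ", "))
  stages <- profile_stages(profiles)
  nk <- attr(profiles, "n_per_stage")
  rmat <- profile_r(profiles)[idx, , drop = FALSE]
  labels <- matrix("NS", nrow = length(edges), ncol = length(stages),
                   dimnames = list(edges, stages))
  cutoff <- stats::setNames(rep(NA_real_, length(stages)), stages)
  for (k in seq_along(stages)) {
    p <- correlation_pvalue(rmat[, k], nk[k])
    padj <- stats::p.adjust(p, method = "BH")
    sig <- padj <= fdr & rmat[, k] != 0
    labels[sig & rmat[, k] > 0, k] <- "HP"
    labels[sig & rmat[, k] < 0, k] <- "HN"
    if (any(sig)) cutoff[k] <- min(abs(rmat[sig, k]))
  }
  out <- data.frame(key = edges, labels,
                    pattern = apply(labels, 1L, paste, collapse = "-"),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out) <- c("key", stages, "pattern")
  attr(out, "r_cutoff") <- cutoff
  out
}

#' Summary of a transition subnetwork (Table-style)
#'
#' Node/edge counts, hubs, and per-gene-set overlap with hypergeometric
#' enrichment against the reference network's genes.
#'
#' @param sub a `subnetwork`.
#' @param gene_sets named list of gene sets (may be empty).
#' @param universe character vector of background genes (e.g. the reference
#'   network's nodes).
#' @return one-row data frame: `transition`, `n_nodes`, `n_edges`, `hubs`
#'   (comma-separated), then `<set>_overlap` and `<set>_p` per gene set.
#' @export
subnetwork_summary <- function(sub, gene_sets = list(), universe) {
  nodes <- subnetwork_nodes(sub)
  out <- data.frame(transition = sub$transition,
                    n_nodes = length(nodes),
                    n_edges = nrow(sub$edges),
                    hubs = paste(find_hubs(sub), collapse = ","),
                    stringsAsFactors = FALSE)
  fg <- intersect(nodes, universe)
  for (nm in names(gene_sets)) {
    enr <- set_enrichment(fg, gene_sets[[nm]], universe)
    out[[paste0(nm, "_overlap")]] <- enr$observed
    out[[paste0(nm, "_p")]] <- enr$p.value
  }
  out
}
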