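#' Rank edges by absolute differential correlation (DCPs)
#'
#' Differentially co-expressed pairs (DCPs) for one transition, in
#' decreasing `|dC|`; ties broken by canonical edge key so rankings are
#' deterministic.
#'
#' @param profiles an [edge_profiles] frame.
#' @param transition 1-based transition index.
#' @return data frame `a`, `b`, `key`, `score` (`|dC|`), best first.
#' @export
rank_dcps <- function(profiles, transition) {
  score <- dc_map(profiles, transition, absolute = TRUE)
  ord <- order(-score, profiles$key, method = "radix")
  out <- data.frame(a = profiles$a[ord], b = profiles$b[ord],
                    key = profiles$key[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank genes by absolute log fold change (DEGs)
#'
#' Expression is assumed log-scale, so the difference of stage means is the
#' log fold change between the two stages of the transition.
#'
#' @param expr genes x samples matrix.
#' @param design a [stage_design].
#' @param transition 1-based transition index.
#' @return data frame `gene`, `score` (`|lfc|`), `lfc` (signed, later minus
#'   earlier stage), best first; ties broken by gene name.
#' @export
rank_degs <- function(expr, design, transition) {
  K <- n_stages(design)
  if (transition < 1L || transition > K - 1L)
    stop("transition out of range 1..", K - 1L)
  m1 <- rowMeans(expr[, stage_samples(design, transition), drop = FALSE])
  m2 <- rowMeans(expr[, stage_samples(design, transition + 1L), drop = FALSE])
  lfc <- m2 - m1
  ord <- order(-abs(lfc), rownames(expr), method = "radix")
  data.frame(gene = rownames(expr)[ord], score = abs(lfc)[ord],
             lfc = lfc[ord], row.names = NULL, stringsAsFactors = FALSE)
}

#' Take the top fraction of a ranked table
#'
#' Count is `round_half_up(fraction * N)`; e.g. the top 0.1% of 64,865
#' ranked edges is 65. Nested by construction: a smaller fraction's set is a
#' prefix of a larger one's.
#'
#' @param ranked data frame from [rank_dcps] / [rank_degs] (or any ranked
#'   frame).
#' @param fraction top proportion in `(0, 1]`.
#' @return the leading rows of `ranked`.
#' @export
top_fraction <- function(ranked, fraction) {
  stopifnot(is.data.frame(ranked))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- round_half_up(fraction * nrow(ranked))
  if (n < 1L) stop("top fraction selects 0 items (fraction too small)")
  utils::head(ranked, n)
}

#' Genes involved in a set of DCP edges
#'
#' @param seed_edges character vector of canonical edge keys, or a data
#'   frame with a `key` column.
#' @return sorted character vector of endpoint genes (DCGs).
#' @export
dcgs_from_dcps <- function(seed_edges) {
  if (is.data.frame(seed_edges)) seed_edges <- seed_edges$key
  ep <- edge_endpoints(seed_edges)
  sort(unique(c(ep[, "a"], ep[, "b"])))
}

#' Hypergeometric gene-set enrichment of a foreground
#'
#' Upper-tail hypergeometric probability of drawing at least the observed
#' number of annotated genes when `|foreground|` genes are drawn from the
#' universe without replacement.
#'
#' @param foreground character vector, a subset of `universe`.
#' @param annotated character vector of genes carrying the annotation.
#' @param universe character vector (e.g. all network genes).
#' @return `list(observed, expected, p.value, foreground_size,
#'   annotated_in_universe, universe_size)`.
#' @export
set_enrichment <- function(foreground, annotated, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  foreground <- unique(as.character(foreground))
  if (!all(foreground %in% universe))
    stop("foreground genes outside the universe: ",
         paste(utils::head(setdiff(foreground, universe)), collapse = ", "))
  ann <- intersect(unique(as.character(annotated)), universe)
  obs <- length(intersect(foreground, ann))
  U <- length(universe); A <- length(ann); F <- length(foreground)
  p <- stats::phyper(obs - 1, A, U - A, F, lower.tail = FALSE)
  list(observed = obs, expected = F * A / U, p.value = p,
       foreground_size = F, annotated_in_universe = A, universe_size = U)
}

#' Mean shortest-path length within a gene set
#'
#' Unweighted shortest paths between all unordered pairs of the set in the
#' reference network; pairs with no connecting path are excluded and
#' counted. The sample standard deviation of a single retained length is
#' reported as 0.
#'
#' @param genes character vector, `length >= 2`; genes absent from the
#'   network are dropped with a warning.
#' @param net a [ppi_network].
#' @return `list(mean, sd, n_pairs, excluded)`.
#' @export
mean_shortest_path <- function(genes, net) {
  genes <- unique(as.character(genes))
  absent <- setdiff(genes, net$nodes)
  if (length(absent)) {
    warning("dropping gene(s) not in the network: ",
            paste(absent, collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  if (length(genes) < 2L) stop("need >= 2 genes present in the network")
  g <- as_igraph(net)
  d <- igraph::distances(g, v = genes, to = genes)
  vals <- d[upper.tri(d)]
  finite <- is.finite(vals)
  if (!any(finite)) stop("all gene pairs are disconnected in the network")
  lens <- vals[finite]
  list(mean = mean(lens),
       sd = if (length(lens) > 1L) stats::sd(lens) else 0,
       n_pairs = length(lens),
       excluded = sum(!finite))
}

#' Welch t-test of differential expression between two stages
#'
#' Two-sided, unequal-variance. The direction is the sign of the later
#' (stageB) minus earlier (stageA) mean; the regulation label (`"up"` /
#' `"down"`) is set only when p < `alpha`. Groups that are both constant
#' and equal give p = 1.
#'
#' @param expr genes x samples matrix.
#' @param design a [stage_design].
#' @param gene gene identifier.
#' @param stageA,stageB stage labels or indices.
#' @param alpha labelling threshold (default 0.05).
#' @return `list(direction, p.value, label)`; `label` is `NA` when not
#'   significant.
#' @export
deg_ttest <- function(expr, design, gene, stageA, stageB, alpha = 0.05) {
  stopifnot(gene %in% rownames(expr))
  xa <- expr[gene, stage_samples(design, stageA)]
  xb <- expr[gene, stage_samples(design, stageB)]
  if (length(xa) < 2L || length(xb) < 2L) stop("both stages need >= 2 samples")
  diffmean <- mean(xb) - mean(xa)
  # both groups constant: t.test errors; equal means -> p = 1, else degenerate 0
  p <- tryCatch(stats::t.test(xb, xa)$p.value,
                error = function(e) if (diffmean == 0) 1 else 0)
  direction <- sign(diffmean)
  label <- if (p < alpha && direction != 0) {
    if (direction > 0) "up" else "down"
  } else NA_character_
  list(direction = direction, p.value = p, label = label)
}
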