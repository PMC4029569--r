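#' Term enrichment of a foreground gene set
#'
#' Upper-tail hypergeometric test per annotation term, with the expected
#' foreground count `|foreground| * |term in universe| / |universe|`.
#' Shares its probability model with [set_enrichment]. Terms with no genes
#' in the universe are skipped with a warning.
#'
#' @param foreground character vector, subset of `universe`.
#' @param annotation named list: term -> character vector of genes.
#' @param universe background genes (e.g. the interactome's gene set).
#' @return data frame `term`, `expected`, `observed`, `p.value`, sorted by
#'   raw p then term.
#' @export
term_enrichment <- function(foreground, annotation, universe) {
  stopifnot(is.list(annotation), !is.null(names(annotation)))
  universe <- unique(as.character(universe))
  rows <- lapply(names(annotation), function(term) {
    ann <- intersect(annotation[[term]], universe)
    if (!length(ann)) {
      warning("term with no genes in the universe skipped: ", term)
      return(NULL)
    }
    enr <- set_enrichment(foreground, ann, universe)
    data.frame(term = term, expected = enr$expected,
               observed = enr$observed, p.value = enr$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), expected = numeric(),
                      observed = integer(), p.value = numeric()))
  out <- out[order(out$p.value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all descendants per term under a parent -> child relation (transitive)
descendant_closure <- function(hierarchy) {
  stopifnot(all(c("parent", "child") %in% names(hierarchy)))
  kids <- split(as.character(hierarchy$child), as.character(hierarchy$parent))
  desc <- new.env(parent = emptyenv())
  get_desc <- function(term) {
    if (!is.null(desc[[term]])) return(desc[[term]])
    direct <- kids[[term]] %||% character()
    desc[[term]] <- character()  # guard against cycles
    all_d <- unique(c(direct, unlist(lapply(direct, get_desc))))
    desc[[term]] <- all_d
    all_d
  }
  terms <- unique(c(hierarchy$parent, hierarchy$child))
  stats::setNames(lapply(terms, get_desc), terms)
}

#' Filter and BH-adjust enrichment results
#'
#' Reproduces the reporting rule: drop terms with fewer than
#' `min_foreground` annotated foreground genes, BH-adjust the survivors'
#' p-values (the adjustment family is the post-filter term list), drop
#' adjusted p above `alpha`, and, when a term hierarchy is supplied, keep
#' only the most specific terms (those with no retained descendant).
#'
#' @param results frame from [term_enrichment].
#' @param min_foreground minimal observed foreground count (default 5,
#'   i.e. terms with four or fewer annotated foreground genes are removed).
#' @param alpha adjusted-p cutoff in (0, 1) (default 0.001).
#' @param hierarchy optional data frame with `parent`, `child` columns.
#' @return filtered frame with an added `p.adjust` column, sorted by
#'   adjusted p.
#' @export
adjust_and_filter <- function(results, min_foreground = 5L, alpha = 0.001,
                              hierarchy = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be inside (0, 1)")
  keep <- results$observed >= min_foreground
  out <- results[keep, , drop = FALSE]
  if (!nrow(out)) {
    out$p.adjust <- numeric()
    return(out)
  }
  out$p.adjust <- stats::p.adjust(out$p.value, method = "BH")
  out <- out[out$p.adjust <= alpha, , drop = FALSE]
  if (!is.null(hierarchy) && nrow(out)) {
    desc <- descendant_closure(hierarchy)
    retained <- out$term
    is_leaf <- vapply(retained, function(t) {
      d <- desc[[t]]
      is.null(d) || !any(d %in% retained)
    }, TRUE)
    out <- out[is_leaf, , drop = FALSE]
  }
  out <- out[order(out$p.adjust, out$p.value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
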