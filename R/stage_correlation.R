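#' Fisher z-transformation of a correlation coefficient
#'
#' `R = 0.5 * log((1 + r) / (1 - r))`. The transform is a soft thresholding
#' of r: strictly increasing, odd, and expanding (`|R| >= |r|`), so large
#' correlations are emphasised relative to small ones. Values within
#' `clamp_eps` of +/-1 are clamped to `+/-(1 - clamp_eps)` to keep R finite.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @param clamp_eps clamping distance from +/-1 (default `1e-7`).
#' @return transformed values, same length as `r`.
#' @export
fisher_transform <- function(r, clamp_eps = 1e-7) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("correlation outside [-1, 1]")
  r <- pmax(pmin(r, 1 - clamp_eps), -(1 - clamp_eps))
  0.5 * log((1 + r) / (1 - r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution under bivariate normality:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' `|r| = 1` gives p = 0.
#'
#' @param r numeric vector of correlations.
#' @param n sample size(s), `n >= 3` (recycled).
#' @return two-sided p-values.
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3)) stop("correlation p-value needs n >= 3")
  if (any(abs(r) > 1)) stop("correlation outside [-1, 1]")
  p <- numeric(length(r))
  exact1 <- abs(r) == 1
  p[exact1] <- 0
  ri <- r[!exact1]
  ni <- rep_len(n, length(r))[!exact1]
  tt <- ri * sqrt(ni - 2) / sqrt(1 - ri^2)
  p[!exact1] <- 2 * stats::pt(abs(tt), df = ni - 2, lower.tail = FALSE)
  p
}

# rows standardised so rowSums(Z[i,] * Z[j,]) is the Pearson r of genes i, j;
# zero-variance rows become all-zero and are reported in the "zeroed" attribute
standardise_rows <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  ss <- sqrt(rowSums(xc^2))
  zero <- ss == 0
  ss[zero] <- 1
  z <- xc / ss
  attr(z, "zeroed") <- rownames(x)[zero]
  z
}

#' Per-edge stage correlations, Fisher transforms, and dC vectors
#'
#' For every network edge, Pearson r is computed within each of the K stages,
#' Fisher-transformed to R, and differenced across the K - 1 consecutive
#' transitions: `dC(k) = R[k+1] - R[k]`. A positive dC means co-expression
#' strengthens (in the transformed scale) going into the later stage.
#'
#' Gene/stage combinations with zero variance get r = 0 for the affected
#' edges and a `zero_var` flag, so every edge carries a complete dC vector.
#'
#' @param expr genes x samples matrix (log scale).
#' @param design a [stage_design].
#' @param net a [ppi_network] restricted to genes of `expr`
#'   (see [restrict_network]).
#' @param clamp_eps clamp for [fisher_transform].
#' @return an `edge_profiles` data frame: `a`, `b`, `key`, `r_<stage>` per
#'   stage, `dC_<k>` per transition, `zero_var`; attributes `stages`,
#'   `n_per_stage`, and the R matrix in `attr(, "R")`.
#' @export
edge_profiles <- function(expr, design, net, clamp_eps = 1e-7) {
  if (!all(net$nodes %in% rownames(expr)))
    stop("network contains genes absent from the expression matrix; ",
         "call restrict_network() first")
  K <- n_stages(design)
  ia <- match(net$edges$a, rownames(expr))
  ib <- match(net$edges$b, rownames(expr))
  r <- matrix(NA_real_, nrow = n_edges(net), ncol = K)
  zero_var <- logical(n_edges(net))
  n_per_stage <- integer(K)
  for (k in seq_len(K)) {
    cols <- stage_samples(design, k)
    n_per_stage[k] <- length(cols)
    z <- standardise_rows(expr[, cols, drop = FALSE])
    zeroed <- attr(z, "zeroed")
    if (length(zeroed)) {
      zero_var <- zero_var | net$edges$a %in% zeroed | net$edges$b %in% zeroed
    }
    rk <- rowSums(z[ia, , drop = FALSE] * z[ib, , drop = FALSE])
    r[, k] <- pmax(pmin(rk, 1), -1)
  }
  R <- fisher_transform(r, clamp_eps = clamp_eps)
  dC <- R[, -1L, drop = FALSE] - R[, -K, drop = FALSE]
  out <- data.frame(net$edges, r, dC, zero_var = zero_var,
                    stringsAsFactors = FALSE)
  names(out) <- c("a", "b", "key",
                  paste0("r_", design$stages),
                  paste0("dC_", seq_len(K - 1L)),
                  "zero_var")
  attr(out, "stages") <- design$stages
  attr(out, "n_per_stage") <- n_per_stage
  attr(out, "R") <- R
  class(out) <- c("edge_profiles", "data.frame")
  out
}

profile_stages <- function(profiles) attr(profiles, "stages")

# r matrix (edges x stages) out of an edge_profiles frame
profile_r <- function(profiles) {
  cols <- paste0("r_", profile_stages(profiles))
  m <- as.matrix(profiles[, cols, drop = FALSE])
  rownames(m) <- profiles$key
  m
}

# dC matrix (edges x transitions)
profile_dc <- function(profiles) {
  K <- length(profile_stages(profiles))
  cols <- paste0("dC_", seq_len(K - 1L))
  m <- as.matrix(profiles[, cols, drop = FALSE])
  rownames(m) <- profiles$key
  m
}

#' Named |dC| (or signed dC) lookup for one transition
#'
#' @param profiles an [edge_profiles] frame.
#' @param transition 1-based transition index.
#' @param absolute return absolute values (default TRUE).
#' @return named numeric vector keyed by canonical edge key.
#' @export
dc_map <- function(profiles, transition, absolute = TRUE) {
  dc <- profile_dc(profiles)
  if (transition < 1L || transition > ncol(dc))
    stop("transition out of range 1..", ncol(dc))
  v <- dc[, transition]
  if (absolute) v <- abs(v)
  v
}

#' Write / read an edge-profile table
#'
#' Round-trips the per-edge r and dC values (TSV).
#' @param profiles an [edge_profiles] frame.
#' @param path TSV path.
#' @return `write_edge_profiles`: the path, invisibly;
#'   `read_edge_profiles`: the [edge_profiles] frame.
#' @export
write_edge_profiles <- function(profiles, path) {
  df <- as.data.frame(profiles)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(stages = profile_stages(profiles),
               n_per_stage = attr(profiles, "n_per_stage"))
  writeLines(jsonlite::toJSON(meta), paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_edge_profiles
#' @export
read_edge_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  attr(df, "stages") <- meta$stages
  attr(df, "n_per_stage") <- meta$n_per_stage
  rmat <- as.matrix(df[, paste0("r_", meta$stages), drop = FALSE])
  attr(df, "R") <- fisher_transform(rmat)
  class(df) <- c("edge_profiles", "data.frame")
  df
}

#' One-sided KS comparison of edge vs background |r|
#'
#' Two-sample Kolmogorov-Smirnov test of the alternative that the edge
#' absolute correlations are stochastically LARGER than the background ones
#' (the direction in which interacting pairs are expected to differ from
#' random gene pairs). `alternative = "two.sided"` is available.
#'
#' @param edge_abs_r,background_abs_r numeric samples of |r|.
#' @param alternative `"greater"` (edges larger; default) or `"two.sided"`.
#' @return `list(statistic, p.value, alternative)`.
#' @export
ks_background_test <- function(edge_abs_r, background_abs_r,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(edge_abs_r) || !length(background_abs_r))
    stop("both samples must be non-empty")
  # stats::ks.test's "greater"/"less" refer to the CDF, which is inverted
  # relative to stochastic ordering: x stochastically larger <=> CDF below.
  ks_alt <- if (alternative == "greater") "less" else "two.sided"
  res <- suppressWarnings(
    stats::ks.test(edge_abs_r, background_abs_r, alternative = ks_alt)
  )
  list(statistic = unname(res$statistic), p.value = res$p.value,
       alternative = alternative)
}

#' Sample background |r| from random non-edge gene pairs
#'
#' The all-pairs background is quadratic in gene count, so a seeded random
#' sample of non-interacting pairs is used instead.
#'
#' @param expr genes x samples matrix.
#' @param design a [stage_design].
#' @param net the reference [ppi_network] (pairs in it are excluded).
#' @param stage stage label or index.
#' @param n_pairs number of background pairs to draw (default `1e6`, capped
#'   at the number available).
#' @param seed RNG seed.
#' @return numeric vector of background |r| values.
#' @export
background_abs_r <- function(expr, design, net, stage, n_pairs = 1e6,
                             seed = 1L) {
  genes <- rownames(expr)
  ng <- length(genes)
  set.seed(seed)
  n_draw <- min(ceiling(n_pairs * 1.2), ng * (ng - 1) / 2)
  i <- sample.int(ng, n_draw, replace = TRUE)
  j <- sample.int(ng, n_draw, replace = TRUE)
  ok <- i != j
  i <- i[ok]; j <- j[ok]
  key <- edge_key(genes[i], genes[j])
  keep <- !duplicated(key) & !(key %in% net$edges$key)
  i <- i[keep][seq_len(min(n_pairs, sum(keep)))]
  j <- j[keep][seq_len(min(n_pairs, sum(keep)))]
  cols <- stage_samples(design, stage)
  z <- standardise_rows(expr[, cols, drop = FALSE])
  abs(pmax(pmin(rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE]), 1), -1))
}

#' Cross-dataset agreement of dC values
#'
#' Pearson correlation (with its two-sided p) between the dC values of the
#' same edges, same transition, computed in two independent datasets. Used
#' to verify that top differential co-expression signal replicates.
#'
#' @param profilesA,profilesB [edge_profiles] frames from the two datasets.
#' @param edges canonical keys of the edges to compare (must be >= 3 and
#'   present in both).
#' @param transition 1-based transition index.
#' @return `list(r, p.value, n)`.
#' @export
cross_dataset_dc_correlation <- function(profilesA, profilesB, edges,
                                         transition) {
  edges <- unique(as.character(edges))
  inA <- edges %in% profilesA$key
  inB <- edges %in% profilesB$key
  shared <- edges[inA & inB]
  if (length(shared) < 3L)
    stop("need >= 3 edges present in both profile sets; got ", length(shared))
  da <- dc_map(profilesA, transition, absolute = FALSE)[shared]
  db <- dc_map(profilesB, transition, absolute = FALSE)[shared]
  ct <- stats::cor.test(da, db, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(shared))
}
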