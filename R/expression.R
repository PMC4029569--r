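#' Ordered stage design
#'
#' Maps samples to an explicit, ordered sequence of disease stages. With K
#' stages there are K - 1 consecutive transitions; transition k compares
#' stage k with stage k + 1.
#'
#' @param assignment named character vector: `names()` are sample IDs,
#'   values are stage labels.
#' @param stages character vector giving the stage order; defaults to order
#'   of first appearance in `assignment`.
#' @return a `stage_design` object.
#' @export
stage_design <- function(assignment, stages = NULL) {
  assignment <- vapply(assignment, as.character, "")
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop("assignment must be named by unique sample IDs")
  if (is.null(stages)) stages <- unique(unname(assignment))
  stages <- as.character(stages)
  if (anyDuplicated(stages)) stop("duplicate stage labels")
  if (!all(assignment %in% stages))
    stop("samples assigned to stages missing from the stage order: ",
         paste(setdiff(assignment, stages), collapse = ", "))
  sizes <- table(factor(assignment, levels = stages))
  if (any(sizes < 3L))
    stop("each stage needs >= 3 samples for Pearson correlation; too small: ",
         paste(names(sizes)[sizes < 3L], collapse = ", "))
  structure(list(stages = stages, assignment = assignment),
            class = "stage_design")
}

#' @export
print.stage_design <- function(x, ...) {
  sizes <- table(factor(x$assignment, levels = x$stages))
  cat(sprintf("stage_design: %d stages (%s), %d samples\n",
              length(x$stages),
              paste(sprintf("%s=%d", x$stages, sizes), collapse = ", "),
              length(x$assignment)))
  invisible(x)
}

n_stages <- function(design) length(design$stages)

#' Samples belonging to one stage
#'
#' @param design a [stage_design].
#' @param stage stage label or 1-based stage index.
#' @return character vector of sample IDs, in design order.
#' @export
stage_samples <- function(design, stage) {
  if (is.numeric(stage)) stage <- design$stages[stage]
  stopifnot(stage %in% design$stages)
  names(design$assignment)[design$assignment == stage]
}

#' Read an expression matrix and its stage design
#'
#' The expression file is TSV: gene identifiers in column 1, a header row of
#' sample identifiers, log-scale intensities in the body. The design file is
#' TSV with columns `sample` and `stage` (header required); stage order is
#' the order of first appearance unless `stages` is given. Samples in the
#' design but missing from the matrix are an error; matrix samples not in
#' the design are dropped with a warning.
#'
#' @param path expression TSV path.
#' @param design_path design TSV path.
#' @param stages optional explicit stage order.
#' @return `list(expr = <genes x samples matrix>, design = <stage_design>)`.
#' @export
read_expression <- function(path, design_path, stages = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression TSV needs a gene column plus >= 1 sample")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in expression matrix: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric values in expression matrix")
  if (anyNA(mat)) stop("missing values in expression matrix are not supported")
  rownames(mat) <- genes
  if (anyDuplicated(colnames(mat))) stop("duplicate sample identifiers")

  des <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  names(des) <- tolower(names(des))
  if (!all(c("sample", "stage") %in% names(des)))
    stop("design TSV must have 'sample' and 'stage' columns")
  missing <- setdiff(des$sample, colnames(mat))
  if (length(missing))
    stop("design assigns sample(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  unassigned <- setdiff(colnames(mat), des$sample)
  if (length(unassigned)) {
    warning(sprintf("dropping %d unassigned sample(s): %s",
                    length(unassigned), paste(unassigned, collapse = ", ")))
    mat <- mat[, des$sample, drop = FALSE]
  } else {
    mat <- mat[, des$sample, drop = FALSE]
  }
  assignment <- stats::setNames(des$stage, des$sample)
  list(expr = mat, design = stage_design(assignment, stages = stages))
}

#' Write an expression matrix and design in the format [read_expression] reads
#'
#' @param expr genes x samples numeric matrix.
#' @param design a [stage_design].
#' @param path,design_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(expr, design, path, design_path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dd <- data.frame(sample = names(design$assignment),
                   stage = unname(design$assignment))
  utils::write.table(dd, design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, design_path))
}
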