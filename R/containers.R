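#' Single-cell count matrix with cell labels
#'
#' Lightweight container for a labeled single-cell reference: a sparse
#' gene-by-cell count matrix together with per-cell cell-type and region
#' labels. This is the input to marker selection and signature building.
#'
#' @param counts gene x cell matrix of non-negative integer counts (coerced to
#'   a sparse `dgCMatrix`). Row names are gene ids, or supply `gene_ids`.
#' @param cell_types character/factor vector of per-cell cell-type labels.
#' @param regions optional per-cell region labels (e.g. "macula",
#'   "periphery"). Defaults to `"all"`.
#' @param gene_ids,cell_ids optional identifier vectors overriding dimnames.
#' @return An object of class `single_cell_matrix`: a list with elements
#'   `counts`, `gene_ids`, `cell_ids`, `cell_types`, `regions`.
#' @export
single_cell_matrix <- function(counts, cell_types, regions = NULL,
                               gene_ids = NULL, cell_ids = NULL) {
  if (!inherits(counts, "CsparseMatrix"))
    counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                  "dMatrix"),
                                      "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != floor(counts@x))) stop("counts must be integers")
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(cell_ids)) cell_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%06d", seq_len(ncol(counts)))
  if (length(cell_types) != ncol(counts))
    stop("cell_types length must match number of cells")
  if (is.null(regions)) regions <- rep("all", ncol(counts))
  if (length(regions) != ncol(counts))
    stop("regions length must match number of cells")
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_types = as.character(cell_types),
                 regions = as.character(regions)),
            class = "single_cell_matrix")
}

#' @export
print.single_cell_matrix <- function(x, ...) {
  cat(sprintf("single_cell_matrix: %d genes x %d cells; %d cell types; regions: %s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_types)),
              paste(unique(x$regions), collapse = ", ")))
  invisible(x)
}

#' Bulk count matrix with condition labels
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @param condition per-sample condition labels; the first level of
#'   `factor(condition)` (or of `levels` if given) is treated as the
#'   control/reference condition downstream.
#' @param gene_ids,sample_ids optional identifier vectors overriding dimnames.
#' @param levels optional explicit condition level ordering.
#' @return An object of class `bulk_matrix`: list with `counts` (dense
#'   matrix), `gene_ids`, `sample_ids`, `condition` (factor).
#' @export
bulk_matrix <- function(counts, condition, gene_ids = NULL, sample_ids = NULL,
                        levels = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative and finite")
  if (length(condition) != ncol(counts))
    stop("condition length must match number of samples")
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(sample_ids)) sample_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%03d", seq_len(ncol(counts)))
  dimnames(counts) <- list(gene_ids, sample_ids)
  condition <- if (is.null(levels)) factor(condition) else
    factor(condition, levels = levels)
  structure(list(counts = counts, gene_ids = gene_ids,
                 sample_ids = sample_ids, condition = condition),
            class = "bulk_matrix")
}

#' @export
print.bulk_matrix <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("bulk_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Restrict a bulk matrix to two conditions
#'
#' Subsets samples to the two given conditions and relevels so that
#' `conditions[1]` is the reference. Fold changes and proportion-change
#' estimates are defined for exactly two groups.
#'
#' @param bulk a [bulk_matrix()].
#' @param conditions length-2 character vector, reference first.
#' @return A `bulk_matrix` with exactly two condition levels.
#' @export
subset_conditions <- function(bulk, conditions) {
  stopifnot(inherits(bulk, "bulk_matrix"), length(conditions) == 2)
  if (!all(conditions %in% levels(bulk$condition)))
    stop("unknown condition(s): ",
         paste(setdiff(conditions, levels(bulk$condition)), collapse = ", "))
  keep <- bulk$condition %in% conditions
  bulk_matrix(bulk$counts[, keep, drop = FALSE],
              as.character(bulk$condition[keep]),
              gene_ids = bulk$gene_ids,
              sample_ids = bulk$sample_ids[keep],
              levels = conditions)
}

# internal: the two group index sets of a two-condition bulk matrix
.two_groups <- function(bulk) {
  lev <- levels(droplevels(bulk$condition))
  if (length(lev) != 2)
    stop("exactly two conditions required; use subset_conditions()")
  g1 <- which(bulk$condition == lev[1])
  g2 <- which(bulk$condition == lev[2])
  if (length(g1) < 2 || length(g2) < 2)
    stop("each condition needs at least 2 samples")
  list(g1 = g1, g2 = g2, levels = lev)
}
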