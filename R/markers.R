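#' Two-sided Wilcoxon rank-sum p-value
#'
#' Mann-Whitney/Wilcoxon rank-sum test of two samples. For small tie-free
#' samples (both sizes <= `exact_max`) the exact null distribution of the
#' rank-sum statistic is used; otherwise the normal approximation with tie
#' correction and continuity correction. Zero-variance configurations (all
#' values tied) return p = 1.
#'
#' @param x,y non-empty numeric vectors.
#' @param exact_max largest group size for which the exact distribution is
#'   used (when there are no ties).
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 50) {
  if (length(x) == 0 || length(y) == 0) stop("x and y must be non-empty")
  n1 <- length(x); n2 <- length(y)
  v <- c(x, y)
  ties <- any(duplicated(v))
  r <- rank(v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    # exact two-sided: double the smaller tail of the exact U distribution
    p_lo <- pwilcox(U, n1, n2)
    p_hi <- 1 - pwilcox(U - 1, n1, n2)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  mu <- n1 * n2 / 2
  N <- n1 + n2
  tie_tab <- table(v)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  min(1, 2 * pnorm(-abs(z)))
}

# Vectorized tie-corrected normal-approximation rank-sum test across the rows
# of a dense matrix; returns the two-sided p-value per row for group `mask`
# (logical over columns) vs the rest.
.rank_sum_rows <- function(X, mask) {
  n1 <- sum(mask); n2 <- sum(!mask); N <- n1 + n2
  ord <- c(which(mask), which(!mask))
  apply(X[, ord, drop = FALSE], 1, function(v) {
    r <- rank(v)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    tie_tab <- tabulate(match(v, unique(v)))
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    z <- U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment (clipped to 1, input order preserved), with input
#' validation.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p_values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Fraction of cells expressing a gene
#'
#' @param counts numeric vector of one gene's counts across cells (or a
#'   1-row matrix slice).
#' @param cell_mask logical or integer index selecting at least one cell.
#' @return fraction of selected cells with count > 0.
#' @export
expressed_fraction <- function(counts, cell_mask) {
  sel <- as.numeric(counts)[cell_mask]
  if (length(sel) == 0) stop("cell_mask selects no cells")
  mean(sel > 0)
}

# per-cell normalization to `scale` total counts, log1p-transformed;
# returns list(norm = counts/colsum*scale sparse, logn not materialized)
.normalize_cells <- function(counts, scale = 1e4) {
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  counts %*% Matrix::Diagonal(x = scale / cs)
}

#' Select cell-type-specific marker genes
#'
#' Two-stage selection per cell type j: (1) a Wilcoxon rank-sum test of each
#' gene in type-j cells against all other cells, on log-normalized expression
#' (counts scaled to 10,000 per cell, natural-log1p), BH-adjusted within the
#' comparison, with fold change (ratio of normalized group means, plus
#' pseudocount) required > `fc_min`; (2) expressed-fraction gates: the gene
#' must be detected in more than `pct_target_min` of type-j cells and in less
#' than `pct_other_max` of the cells of every other type. A gene may qualify
#' for more than one cell type.
#'
#' @param sc a [single_cell_matrix()].
#' @param scope `"all"`, or one of the region labels to restrict cells to
#'   that region before selection.
#' @param p_adj_max,fc_min,pct_target_min,pct_other_max selection thresholds.
#' @param pseudocount added to both group means before forming the fold
#'   change.
#' @return data.frame with one row per (cell_type, gene) marker:
#'   `cell_type`, `gene`, `fold_change`, `p_raw`, `p_adj`, `pct_target`,
#'   `pct_other_max`.
#' @export
select_markers <- function(sc, scope = "all",
                           p_adj_max = 0.05, fc_min = 2,
                           pct_target_min = 0.5, pct_other_max = 0.3,
                           pseudocount = 1e-9) {
  stopifnot(inherits(sc, "single_cell_matrix"))
  keep <- if (identical(scope, "all")) rep(TRUE, length(sc$regions))
          else sc$regions == scope
  if (!any(keep)) stop("scope '", scope, "' selects no cells")
  counts <- sc$counts[, keep, drop = FALSE]
  types <- sc$cell_types[keep]
  utypes <- sort(unique(types))
  if (length(utypes) < 2) stop("marker selection needs >= 2 cell types in scope")

  norm <- .normalize_cells(counts)
  # expressed fraction per gene per type
  pct <- sapply(utypes, function(tp)
    Matrix::rowMeans(counts[, types == tp, drop = FALSE] > 0))
  out <- vector("list", length(utypes))
  for (ji in seq_along(utypes)) {
    tp <- utypes[ji]
    mask <- types == tp
    pct_t <- pct[, ji]
    pct_o <- apply(pct[, -ji, drop = FALSE], 1, max)
    mean_t <- Matrix::rowMeans(norm[, mask, drop = FALSE])
    mean_o <- Matrix::rowMeans(norm[, !mask, drop = FALSE])
    fc <- (mean_t + pseudocount) / (mean_o + pseudocount)
    # expressed-fraction gates are cheap hard filters; the rank test is only
    # evaluated for genes that could still qualify
    gate <- pct_t > pct_target_min & pct_o < pct_other_max & fc > fc_min
    if (!any(gate)) next
    # BH family = all genes tested in this one-vs-rest comparison: test every
    # gene with any detectable expression, then adjust jointly
    tested <- which(mean_t + mean_o > 0)
    p_raw <- rep(NA_real_, nrow(counts))
    X <- as.matrix(log1p(norm[tested, , drop = FALSE]))
    p_raw[tested] <- .rank_sum_rows(X, mask)
    p_adj <- rep(NA_real_, nrow(counts))
    p_adj[tested] <- bh_adjust(p_raw[tested])
    sel <- which(gate & !is.na(p_adj) & p_adj < p_adj_max)
    if (!length(sel)) next
    out[[ji]] <- data.frame(cell_type = tp,
                            gene = rownames(counts)[sel],
                            fold_change = fc[sel],
                            p_raw = p_raw[sel],
                            p_adj = p_adj[sel],
                            pct_target = pct_t[sel],
                            pct_other_max = pct_o[sel],
                            row.names = NULL)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(cell_type = character(0), gene = character(0),
                      fold_change = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), pct_target = numeric(0),
                      pct_other_max = numeric(0))
  res
}

#' Split a marker data.frame into per-cell-type gene sets
#'
#' @param markers output of [select_markers()] (or any data.frame with
#'   `cell_type` and `gene` columns).
#' @return named list of gene-id vectors, one per cell type.
#' @export
marker_sets <- function(markers) {
  split(markers$gene, markers$cell_type)
}
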