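#' Build a cell-type signature matrix from a single-cell reference
#'
#' Retains genes expressed in at least `min_pct` of cells and in more than
#' `min_cells` cells in at least one cell type, averages library-normalized
#' expression per type, and renormalizes each cell type's column to sum to 1
#' (relative expression).
#'
#' @param sc a [single_cell_matrix()].
#' @param min_pct minimum expressed-cell fraction within a type.
#' @param min_cells minimum expressed-cell count within a type (strict >).
#' @param genes optional gene subset to intersect with the filtered set
#'   (e.g. marker genes only).
#' @return object of class `signature_matrix`: list with `profiles` (gene x
#'   cell-type matrix, columns sum to 1), `genes`, `celltypes`.
#' @export
build_signature <- function(sc, min_pct = 0.05, min_cells = 10, genes = NULL) {
  stopifnot(inherits(sc, "single_cell_matrix"))
  utypes <- sort(unique(sc$cell_types))
  counts <- sc$counts
  n_expr <- sapply(utypes, function(tp)
    Matrix::rowSums(counts[, sc$cell_types == tp, drop = FALSE] > 0))
  n_type <- table(sc$cell_types)[utypes]
  pass <- sweep(n_expr, 2, as.numeric(n_type), "/") >= min_pct &
    n_expr > min_cells
  if (any(colSums(pass) == 0))
    stop("cell type(s) with zero genes passing the signature filter: ",
         paste(utypes[colSums(pass) == 0], collapse = ", "))
  keep <- rowSums(pass) > 0
  if (!is.null(genes)) keep <- keep & rownames(counts) %in% genes
  rel <- .normalize_cells(counts, scale = 1)  # per-cell relative expression
  prof <- sapply(utypes, function(tp)
    Matrix::rowMeans(rel[keep, sc$cell_types == tp, drop = FALSE]))
  prof <- as.matrix(prof)
  prof <- sweep(prof, 2, colSums(prof), "/")
  rownames(prof) <- rownames(counts)[keep]
  structure(list(profiles = prof, genes = rownames(prof), celltypes = utypes),
            class = "signature_matrix")
}

#' Estimate cell-type proportions by non-negative least squares
#'
#' Each bulk sample's counts are restricted to the signature genes and
#' normalized to relative abundance; proportions solve
#' `min || y - S p ||^2, p >= 0` and are renormalized to sum to 1.
#' Library-size differences therefore cannot influence the estimates.
#'
#' @param bulk a [bulk_matrix()].
#' @param sig a [build_signature()] result.
#' @return data.frame with `sample_id`, `condition`, one proportion column
#'   per cell type, and `residual_norm`; attribute `rank_deficient` flags a
#'   rank-deficient signature (a warning is also raised).
#' @export
estimate_proportions <- function(bulk, sig) {
  stopifnot(inherits(bulk, "bulk_matrix"), inherits(sig, "signature_matrix"))
  shared <- intersect(bulk$gene_ids, sig$genes)
  C <- length(sig$celltypes)
  if (length(shared) < C)
    stop("need at least ", C, " signature genes shared with the bulk matrix")
  S <- sig$profiles[shared, , drop = FALSE]
  S <- sweep(S, 2, colSums(S), "/")
  rank_deficient <- qr(S)$rank < C
  if (rank_deficient)
    warning("signature matrix is rank-deficient; proportions may be unstable")
  Y <- bulk$counts[shared, , drop = FALSE]
  res <- t(apply(Y, 2, function(y) {
    tot <- sum(y)
    y <- if (tot > 0) y / tot else y
    fit <- pracma::lsqnonneg(S, y)
    p <- fit$x
    s <- sum(p)
    p <- if (s > 0) p / s else rep(1 / C, C)
    c(p, sqrt(max(fit$resid.norm, 0)))
  }))
  out <- data.frame(sample_id = bulk$sample_ids,
                    condition = as.character(bulk$condition),
                    res[, seq_len(C), drop = FALSE],
                    residual_norm = res[, C + 1],
                    row.names = NULL)
  names(out)[2 + seq_len(C)] <- sig$celltypes
  attr(out, "rank_deficient") <- rank_deficient
  out
}

#' Test cell-type proportion differences between conditions
#'
#' Welch two-sample t-test per cell type between two condition groups, with
#' BH adjustment across cell types. The second group may pool several
#' conditions (e.g. all disease stages against control).
#'
#' @param props output of [estimate_proportions()] (or any data.frame with
#'   `condition` and one column per cell type).
#' @param group1 condition label(s) of the first (reference) group.
#' @param group2 condition label(s) of the second group; several labels are
#'   pooled.
#' @param celltypes columns to test; defaults to all non-metadata columns.
#' @return data.frame with `cell_type`, `mean1`, `mean2`, `t_stat`, `p_raw`,
#'   `p_adj`, `degenerate` (TRUE when both groups had zero variance and p was
#'   set to 1).
#' @export
test_proportion_difference <- function(props, group1, group2,
                                       celltypes = NULL) {
  if (is.null(celltypes))
    celltypes <- setdiff(names(props),
                         c("sample_id", "condition", "residual_norm"))
  i1 <- props$condition %in% group1
  i2 <- props$condition %in% group2
  if (sum(i1) < 2 || sum(i2) < 2) stop("each group needs >= 2 samples")
  rows <- lapply(celltypes, function(ct) {
    x <- props[[ct]][i1]; y <- props[[ct]][i2]
    if (var(x) == 0 && var(y) == 0) {
      data.frame(cell_type = ct, mean1 = mean(x), mean2 = mean(y),
                 t_stat = 0, p_raw = 1, degenerate = TRUE)
    } else {
      tt <- t.test(y, x)
      data.frame(cell_type = ct, mean1 = mean(x), mean2 = mean(y),
                 t_stat = unname(tt$statistic), p_raw = tt$p.value,
                 degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out[, c("cell_type", "mean1", "mean2", "t_stat", "p_raw", "p_adj",
          "degenerate")]
}
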