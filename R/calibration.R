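#' Bulk fold changes between two conditions
#'
#' For each gene, the ratio of mean normalized expression in the second
#' (disease) condition to the first (control): `FC_g = mean_2 / mean_1` on
#' size-factor-normalized counts. Genes with a zero mean in either group get
#' `defined = FALSE` and are excluded from downstream proportion-change
#' averaging.
#'
#' @param bulk a [bulk_matrix()] with exactly two condition levels
#'   (reference first; see [subset_conditions()]).
#' @param genes optional gene subset (e.g. one cell type's markers).
#' @param sf per-sample size factors; [size_factors()] of the full matrix
#'   when NULL.
#' @param pseudocount optional value added to both group means before the
#'   ratio (default 0, i.e. undefined fold changes are flagged rather than
#'   patched).
#' @return data.frame with `gene`, `mean_1`, `mean_2`, `FC`, `log_FC`,
#'   `defined`.
#' @export
bulk_fold_change <- function(bulk, genes = NULL, sf = NULL, pseudocount = 0) {
  gr <- .two_groups(bulk)
  if (is.null(sf)) sf <- size_factors(bulk)
  counts <- bulk$counts
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(counts))
    if (length(missing))
      stop("gene(s) not present in bulk matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    counts <- counts[genes, , drop = FALSE]
  }
  norm <- sweep(counts, 2, sf, "/")
  m1 <- rowMeans(norm[, gr$g1, drop = FALSE]) + pseudocount
  m2 <- rowMeans(norm[, gr$g2, drop = FALSE]) + pseudocount
  defined <- m1 > 0 & m2 > 0
  fc <- ifelse(defined, m2 / m1, NA_real_)
  data.frame(gene = rownames(counts), mean_1 = m1, mean_2 = m2,
             FC = fc, log_FC = log(fc), defined = defined, row.names = NULL)
}

#' Estimate cell-type proportion change from marker fold changes
#'
#' The proportion change of cell type j between disease and control,
#' `PC_j = p_j^disease / p_j^control`, is estimated from the bulk fold
#' changes of its marker genes: when a gene is specific to type j, its bulk
#' fold change factorizes as `FC_g ~ PC_j * FC_jg`, and if few markers are
#' truly differentially expressed the mean log fold change over the marker
#' set estimates `log PC_j`. The default is that arithmetic mean of log fold
#' changes (a geometric mean of FCs); trimmed mean and median are offered for
#' robustness when the marker set may contain differentially expressed genes.
#'
#' @param fold_changes data.frame from [bulk_fold_change()] restricted to one
#'   cell type's markers.
#' @param robust central tendency for the log fold changes.
#' @param trim trimming fraction per tail for `"trimmed_mean"`.
#' @param cell_type optional label stored in the result.
#' @return object of class `proportion_change`: list with `cell_type`, `PC`,
#'   `m_used`, `n_undefined`, `contributing_log_FCs`, `robust`.
#' @export
estimate_proportion_change <- function(fold_changes,
                                       robust = c("mean", "trimmed_mean",
                                                  "median"),
                                       trim = 0.1, cell_type = NA_character_) {
  robust <- match.arg(robust)
  lfc <- fold_changes$log_FC[fold_changes$defined]
  if (length(lfc) == 0)
    stop("no defined fold changes; proportion change is not estimable")
  center <- switch(robust,
                   mean = mean(lfc),
                   trimmed_mean = mean(lfc, trim = trim),
                   median = median(lfc))
  structure(list(cell_type = cell_type, PC = exp(center),
                 m_used = length(lfc),
                 n_undefined = sum(!fold_changes$defined),
                 contributing_log_FCs = lfc, robust = robust),
            class = "proportion_change")
}

#' @export
print.proportion_change <- function(x, ...) {
  cat(sprintf("proportion_change [%s]: PC = %.4f (%s of %d marker log fold changes; %d undefined)\n",
              x$cell_type, x$PC, x$robust, x$m_used, x$n_undefined))
  invisible(x)
}

#' Calibrate bulk expression for a cell type's proportion change
#'
#' Removes the composition component from disease-sample expression of one
#' cell type's marker genes so that the remaining disease-vs-control fold
#' change estimates the within-cell-type fold change. With the default
#' `direction = "corrected"`, disease expression is divided by `PC_j`
#' (equivalently a `+log PC_j` offset on disease samples in the NB model),
#' which makes the decomposition `log FC_g = log PC_j + log FC_jg` hold with
#' zero mean calibrated log fold change under the no-DE null.
#' `direction = "paper_literal"` instead multiplies disease expression by
#' `PC_j`; it is retained for faithful reproduction of the originally stated
#' transformation, which doubles rather than removes the composition factor,
#' and is not recommended (see the methods vignette).
#'
#' @param bulk a two-condition [bulk_matrix()].
#' @param pc a [estimate_proportion_change()] result or a positive scalar.
#' @param mode `"offset"` returns the counts untouched plus per-sample log
#'   offsets for [nb_de()]; `"scaled_counts"` rescales the disease columns
#'   (rounded half-to-even unless `round = FALSE`).
#' @param direction `"corrected"` (default) or `"paper_literal"`.
#' @param round round rescaled counts (only for `mode = "scaled_counts"`).
#' @return list with `bulk` (a [bulk_matrix()]), `offsets` (per-sample log
#'   offsets; zero in scaled mode), `PC`, `mode`, `direction`.
#' @export
calibrate_expression <- function(bulk, pc,
                                 mode = c("offset", "scaled_counts"),
                                 direction = c("corrected", "paper_literal"),
                                 round = TRUE) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  PC <- if (inherits(pc, "proportion_change")) pc$PC else pc
  if (!is.numeric(PC) || PC <= 0) stop("PC must be a positive real")
  gr <- .two_groups(bulk)
  disease <- gr$g2
  # corrected: divide disease counts by PC <=> +log(PC) model offset;
  # paper_literal: multiply disease counts by PC <=> -log(PC) model offset
  log_off <- if (direction == "corrected") log(PC) else -log(PC)
  if (mode == "offset") {
    offsets <- rep(0, ncol(bulk$counts))
    offsets[disease] <- log_off
    list(bulk = bulk, offsets = offsets, PC = PC, mode = mode,
         direction = direction)
  } else {
    counts <- bulk$counts
    scale <- exp(-log_off)
    counts[, disease] <- counts[, disease, drop = FALSE] * scale
    if (round) counts[, disease] <- base::round(counts[, disease, drop = FALSE])
    out <- bulk_matrix(counts, as.character(bulk$condition),
                       sample_ids = bulk$sample_ids,
                       levels = levels(bulk$condition))
    list(bulk = out, offsets = rep(0, ncol(counts)), PC = PC, mode = mode,
         direction = direction)
  }
}

#' Detect cell-type-specific differentially expressed genes
#'
#' For each cell type: estimate its proportion change from the bulk fold
#' changes of its markers (unless supplied), calibrate the disease samples by
#' that factor, and run the NB Wald test on the marker genes with the
#' calibration as a per-sample log offset. P-values are BH-adjusted within
#' each cell type's candidate family; a gene specific to several cell types
#' is tested under each of them.
#'
#' @param bulk a two-condition [bulk_matrix()] (see [subset_conditions()]).
#' @param markers [select_markers()] output, or a named list of gene-id
#'   vectors per cell type.
#' @param pc optional named list / vector of fixed proportion changes per
#'   cell type (e.g. `1` everywhere for an uncalibrated ablation); estimated
#'   from the data when NULL.
#' @param robust central tendency passed to [estimate_proportion_change()].
#' @param direction calibration direction, see [calibrate_expression()].
#' @param alpha BH-adjusted significance threshold used for the
#'   `significant` column.
#' @param sf size factors; computed from the full bulk matrix when NULL.
#' @param dispersion,phi dispersion handling passed to [nb_de()].
#' @return object of class `ctdeg_result`: data.frame with `cell_type`,
#'   `gene`, `calibrated_log2_FC`, `se`, `stat`, `p_raw`, `p_adj`,
#'   `direction` (up/down), `significant`; the per-type proportion-change
#'   table is in `attr(, "pc")`.
#' @export
detect_ctdegs <- function(bulk, markers, pc = NULL,
                          robust = c("mean", "trimmed_mean", "median"),
                          direction = c("corrected", "paper_literal"),
                          alpha = 0.05, sf = NULL,
                          dispersion = c("estimated", "fixed"), phi = NULL) {
  robust <- match.arg(robust)
  direction <- match.arg(direction)
  dispersion <- match.arg(dispersion)
  sets <- if (is.data.frame(markers)) marker_sets(markers) else markers
  if (is.null(sf)) sf <- size_factors(bulk)
  out <- list()
  pc_rows <- list()
  for (ct in names(sets)) {
    genes <- intersect(sets[[ct]], bulk$gene_ids)
    if (length(genes) == 0) {
      warning("no candidate genes in bulk matrix for cell type ", ct)
      next
    }
    fc <- bulk_fold_change(bulk, genes = genes, sf = sf)
    pc_ct <- if (!is.null(pc)) {
      structure(list(cell_type = ct, PC = unname(unlist(pc)[ct]),
                     m_used = NA_integer_, n_undefined = NA_integer_,
                     robust = "fixed"), class = "proportion_change")
    } else estimate_proportion_change(fc, robust = robust, cell_type = ct)
    cal <- calibrate_expression(bulk, pc_ct, mode = "offset",
                                direction = direction)
    de <- nb_de(bulk$counts[genes, , drop = FALSE],
                groups = bulk$condition, sf = sf, offsets = cal$offsets,
                dispersion = dispersion, phi = phi)
    de$p_adj <- bh_adjust(de$p_raw)
    out[[ct]] <- data.frame(cell_type = ct, gene = genes,
                            calibrated_log2_FC = de$log2_FC, se = de$se,
                            stat = de$stat, p_raw = de$p_raw,
                            p_adj = de$p_adj,
                            direction = ifelse(de$log2_FC >= 0, "up", "down"),
                            significant = de$p_adj < alpha,
                            row.names = NULL)
    pc_rows[[ct]] <- data.frame(cell_type = ct, PC = pc_ct$PC,
                                m_used = pc_ct$m_used,
                                n_undefined = pc_ct$n_undefined,
                                robust = pc_ct$robust, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cell_type = character(0), gene = character(0),
                      calibrated_log2_FC = numeric(0), se = numeric(0),
                      stat = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), direction = character(0),
                      significant = logical(0))
  attr(res, "pc") <- do.call(rbind, pc_rows)
  class(res) <- c("ctdeg_result", "data.frame")
  res
}
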