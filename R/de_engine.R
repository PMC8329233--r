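#' Filter genes by expressed-sample fraction
#'
#' Eliminates genes expressed (nonzero) in less than `min_sample_fraction` of
#' samples; a gene nonzero in exactly that fraction is retained.
#'
#' @param bulk a [bulk_matrix()] or plain count matrix.
#' @param min_sample_fraction minimum expressed fraction (default 0.20).
#' @return object of the same class restricted to retained genes.
#' @export
filter_genes <- function(bulk, min_sample_fraction = 0.20) {
  counts <- if (inherits(bulk, "bulk_matrix")) bulk$counts else as.matrix(bulk)
  keep <- rowMeans(counts > 0) >= min_sample_fraction
  if (inherits(bulk, "bulk_matrix"))
    bulk_matrix(counts[keep, , drop = FALSE], as.character(bulk$condition),
                sample_ids = bulk$sample_ids, levels = levels(bulk$condition))
  else counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: for each gene expressed in every
#' sample, the ratio of its count to its geometric mean across samples; the
#' sample's factor is the median of these ratios. Factors are rescaled so
#' their geometric mean is 1. If no gene is positive in all samples, genes
#' positive in at least `fallback_fraction` of samples are used, with
#' geometric means and medians taken over their positive entries.
#'
#' @param bulk a [bulk_matrix()] or count matrix.
#' @param fallback use the relaxed gene set when no gene is positive
#'   everywhere (default TRUE).
#' @param fallback_fraction positivity fraction for the fallback set.
#' @return positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(bulk, fallback = TRUE, fallback_fraction = 0.9) {
  counts <- if (inherits(bulk, "bulk_matrix")) bulk$counts else as.matrix(bulk)
  pos_all <- rowSums(counts > 0) == ncol(counts)
  if (any(pos_all)) {
    sub <- counts[pos_all, , drop = FALSE]
    gm <- exp(rowMeans(log(sub)))
    sf <- apply(sub, 2, function(col) median(col / gm))
  } else if (fallback) {
    pos <- rowMeans(counts > 0) >= fallback_fraction
    if (!any(pos)) stop("no genes usable for size-factor estimation")
    sub <- counts[pos, , drop = FALSE]
    gm <- apply(sub, 1, function(r) exp(mean(log(r[r > 0]))))
    sf <- apply(sub, 2, function(col) {
      ratios <- col / gm
      median(ratios[col > 0])
    })
  } else stop("no gene is positive in all samples and fallback is disabled")
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' A self-contained NB test over all genes of a two-condition count matrix.
#' The model for gene g is `mu_i = s_i * exp(o_i) * q_{group(i)}`: size
#' factor, optional per-sample log offset (used for proportion-change
#' calibration), and a group mean on the normalized scale. Group means are
#' estimated as means of normalized counts; the gene-wise dispersion is a
#' method-of-moments estimate from squared Pearson-type residuals around the
#' fitted means (floored at `dispersion_floor`); the Wald statistic is
#' `log2(q2/q1)` over its standard error from the observed Fisher
#' information, referred to the normal distribution.
#'
#' There is deliberately no dispersion shrinkage, outlier filtering, or
#' independent filtering: the calibration method is agnostic to the DE
#' backend and this engine keeps its behavior transparent and exactly
#' invariant under offset shifts and size-factor rescaling.
#'
#' @param bulk a [bulk_matrix()] with exactly two condition levels (reference
#'   first), or a count matrix plus `groups`.
#' @param groups factor of length n_samples with two levels (ignored when
#'   `bulk` is a `bulk_matrix`).
#' @param sf per-sample size factors; computed by [size_factors()] when NULL.
#' @param offsets per-sample log offsets (default 0).
#' @param dispersion `"estimated"` or `"fixed"`.
#' @param phi dispersion value(s) when `dispersion = "fixed"` (scalar or
#'   per-gene).
#' @param dispersion_floor lower bound on the dispersion estimate.
#' @return data.frame with `gene`, `base_mean`, `log2_FC`, `se`, `stat`,
#'   `p_raw`, `p_adj`, `dispersion`, `flag` (`""`, `"all_zero"` or
#'   `"zero_group"`). `log2_FC` is condition 2 vs condition 1.
#' @export
nb_de <- function(bulk, groups = NULL, sf = NULL, offsets = 0,
                  dispersion = c("estimated", "fixed"), phi = NULL,
                  dispersion_floor = 1e-8) {
  dispersion <- match.arg(dispersion)
  if (inherits(bulk, "bulk_matrix")) {
    gr <- .two_groups(bulk)
    counts <- bulk$counts
    g1 <- gr$g1; g2 <- gr$g2
  } else {
    counts <- as.matrix(bulk)
    groups <- droplevels(as.factor(groups))
    if (nlevels(groups) != 2) stop("groups must have exactly two levels")
    g1 <- which(groups == levels(groups)[1])
    g2 <- which(groups == levels(groups)[2])
    if (length(g1) < 2 || length(g2) < 2)
      stop("each group needs at least 2 samples")
  }
  n <- ncol(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  offsets <- rep_len(offsets, n)
  t_i <- sf * exp(offsets)
  z <- sweep(counts, 2, t_i, "/")
  q1 <- rowMeans(z[, g1, drop = FALSE])
  q2 <- rowMeans(z[, g2, drop = FALSE])

  flag <- rep("", nrow(counts))
  flag[q1 == 0 & q2 == 0] <- "all_zero"
  zero_grp <- (q1 == 0) != (q2 == 0)
  flag[zero_grp] <- "zero_group"
  # continuity guard: a group with no counts gets half a count spread over
  # its total exposure so the log fold change stays finite
  q1g <- ifelse(zero_grp & q1 == 0, 0.5 / sum(t_i[g1]), q1)
  q2g <- ifelse(zero_grp & q2 == 0, 0.5 / sum(t_i[g2]), q2)

  qg <- matrix(0, nrow(counts), n)
  qg[, g1] <- q1g
  qg[, g2] <- q2g
  mu <- sweep(qg, 2, t_i, "*")

  if (dispersion == "fixed") {
    if (is.null(phi)) stop("phi required when dispersion = 'fixed'")
    phi_hat <- pmax(rep_len(phi, nrow(counts)), dispersion_floor)
  } else {
    resid2 <- (counts - mu)^2 - mu
    ratio <- ifelse(mu > 0, resid2 / mu^2, 0)
    df <- pmax(rowSums(mu > 0) - 2, 1)
    phi_hat <- pmax(rowSums(ratio) / df, dispersion_floor)
  }

  info <- mu / (1 + phi_hat * mu)
  I1 <- rowSums(info[, g1, drop = FALSE])
  I2 <- rowSums(info[, g2, drop = FALSE])
  se_log <- sqrt(1 / pmax(I1, 1e-300) + 1 / pmax(I2, 1e-300))
  log2fc <- log2(q2g / q1g)
  se <- se_log / log(2)
  stat <- log2fc / se
  p <- pmin(1, 2 * pnorm(-abs(stat)))

  dead <- flag == "all_zero"
  log2fc[dead] <- 0; stat[dead] <- 0; p[dead] <- 1; se[dead] <- NA_real_

  data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             base_mean = rowMeans(z),
             log2_FC = log2fc, se = se, stat = stat,
             p_raw = p, p_adj = bh_adjust(p),
             dispersion = phi_hat, flag = flag, row.names = NULL)
}

#' Single-gene NB Wald test
#'
#' Convenience wrapper over [nb_de()] for one gene's counts.
#'
#' @param counts numeric vector of one gene's counts.
#' @param groups two-level factor of group assignments.
#' @param sf size factors (default all 1).
#' @param offsets per-sample log offsets.
#' @param ... further arguments to [nb_de()].
#' @return single-row data.frame as in [nb_de()].
#' @export
nb_wald_test <- function(counts, groups, sf = rep(1, length(counts)),
                         offsets = 0, ...) {
  m <- matrix(counts, nrow = 1, dimnames = list("gene", NULL))
  nb_de(m, groups = groups, sf = sf, offsets = offsets, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
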