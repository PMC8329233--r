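#' Construct simulation ground truth
#'
#' Draws the latent quantities of the mixture model: per-cell-type relative
#' expression profiles (columns summing to 1), planted marker genes, planted
#' cell-type-specific DEGs with their effect multipliers, and the true
#' per-cell-type proportion change of every non-control condition relative to
#' control.
#'
#' Marker genes get a low relative weight in off-target types (so most
#' off-target cells show zero counts) and a `marker_fc`-fold higher weight in
#' their own type. Planted ctDEG effects multiply the affected cell type's
#' profile entries in non-control conditions; the column is deliberately not
#' renormalized, so every unplanted gene remains exactly null at the
#' cell-type level.
#'
#' @param config a [sim_config()].
#' @return An object of class `ground_truth`: list with `profiles` (gene x C,
#'   columns sum to 1), `condition_profiles` (list of gene x C matrices, one
#'   per condition), `proportions_by_condition`, `true_PC` (K x C matrix of
#'   p_j^k / p_j^1), `planted_markers` (list of gene-id vectors per type),
#'   `planted_ctdegs` (list of data.frames gene/effect per type),
#'   `celltypes`, `gene_ids`. `true_proportions` is filled by
#'   [simulate_bulk()].
#' @export
make_ground_truth <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  C <- config$n_celltypes
  G <- config$n_genes
  celltypes <- colnames(config$proportions_by_condition)
  if (is.null(celltypes)) celltypes <- .celltype_names(C)
  gene_ids <- sprintf("gene%05d", seq_len(G))

  base_w <- rgamma(G, shape = 1.5, rate = 1.5)
  W <- matrix(base_w, G, C, dimnames = list(gene_ids, celltypes))

  marker_pool <- sample.int(G, sum(config$markers_per_type))
  offs <- c(0L, cumsum(config$markers_per_type))
  # off-target marker weight giving roughly marker_base_count expected counts
  # per reference cell (relative to the non-marker weight mass)
  w0 <- config$marker_base_count *
    sum(if (length(marker_pool)) base_w[-marker_pool] else base_w) /
    config$library_size_mean
  planted_markers <- planted_ctdegs <- setNames(vector("list", C), celltypes)
  for (j in seq_len(C)) {
    idx <- marker_pool[(offs[j] + 1L):offs[j + 1L]]
    if (config$markers_per_type[j] == 0L) idx <- integer(0)
    W[idx, ] <- w0
    W[idx, j] <- w0 * config$marker_fc
    planted_markers[[j]] <- gene_ids[idx]
    n_de <- round(config$ctdeg_fraction[j] * length(idx))
    de_idx <- if (n_de > 0) sample(idx, n_de) else integer(0)
    planted_ctdegs[[j]] <- data.frame(gene = gene_ids[de_idx],
                                      effect = rep(config$ctdeg_fc,
                                                   length(de_idx)))
  }
  profiles <- sweep(W, 2, colSums(W), "/")

  K <- length(config$conditions)
  condition_profiles <- vector("list", K)
  names(condition_profiles) <- names(config$conditions)
  condition_profiles[[1]] <- profiles
  if (K > 1) for (k in 2:K) {
    Xk <- profiles
    for (j in seq_len(C)) {
      de <- planted_ctdegs[[j]]
      if (nrow(de)) Xk[de$gene, j] <- Xk[de$gene, j] * de$effect
    }
    condition_profiles[[k]] <- Xk
  }

  P <- config$proportions_by_condition
  true_PC <- sweep(P, 2, P[1, ], "/")
  structure(list(profiles = profiles,
                 condition_profiles = condition_profiles,
                 proportions_by_condition = P,
                 true_PC = true_PC,
                 planted_markers = planted_markers,
                 planted_ctdegs = planted_ctdegs,
                 celltypes = celltypes,
                 gene_ids = gene_ids,
                 true_proportions = NULL),
            class = "ground_truth")
}

# NB sampler in mean/dispersion parameterization; dispersion 0 -> Poisson
.rnb <- function(n, mu, dispersion) {
  if (dispersion < 1e-12) rpois(n, lambda = mu)
  else rnbinom(n, mu = mu, size = 1 / dispersion)
}

# Dirichlet draw with concentration alpha0 around mean p; Inf -> degenerate
.rdirichlet1 <- function(p, alpha0) {
  if (!is.finite(alpha0)) return(p)
  g <- rgamma(length(p), shape = alpha0 * p)
  if (sum(g) == 0) return(p)
  g / sum(g)
}

#' Simulate a labeled single-cell reference
#'
#' Draws per-cell counts NB(mean = library_size x profile, dispersion) for
#' `cells_per_type[j]` cells of each type, attaches cell-type and region
#' labels, and returns the matrix together with the ground truth that
#' generated it.
#'
#' @param config a [sim_config()].
#' @param truth optional precomputed [make_ground_truth()] result (so several
#'   datasets can share one truth); generated from `config` if missing.
#' @param seed seed for the cell-level draws; defaults to `config$seed + 1`.
#' @return list with elements `sc` ([single_cell_matrix()]) and `truth`
#'   ([make_ground_truth()] output).
#' @export
simulate_reference <- function(config, truth = NULL, seed = config$seed + 1L) {
  config <- validate_sim_config(config)
  if (is.null(truth)) truth <- make_ground_truth(config)
  set.seed(seed)
  C <- config$n_celltypes
  n_cells <- sum(config$cells_per_type)
  counts <- matrix(0, config$n_genes, n_cells,
                   dimnames = list(truth$gene_ids, NULL))
  cell_types <- character(n_cells)
  regions <- character(n_cells)
  at <- 0L
  for (j in seq_len(C)) {
    nj <- config$cells_per_type[j]
    mu <- config$library_size_mean * truth$profiles[, j]
    for (i in seq_len(nj)) {
      counts[, at + i] <- .rnb(config$n_genes, mu, config$nb_dispersion)
    }
    cell_types[at + seq_len(nj)] <- truth$celltypes[j]
    n_mac <- round(config$region_fraction * nj)
    regions[at + seq_len(nj)] <- rep(c("macula", "periphery"),
                                     c(n_mac, nj - n_mac))
    at <- at + nj
  }
  colnames(counts) <- sprintf("cell%06d", seq_len(n_cells))
  list(sc = single_cell_matrix(counts, cell_types, regions),
       truth = truth)
}

#' Simulate bulk RNA-seq mixtures with known composition
#'
#' For each sample of condition k, subject-level proportions are drawn from a
#' Dirichlet centered on the condition's proportion vector; the expected
#' count of gene g is `library_i * sum_j p_ij * X_jg(condition)`, the
#' proportion-weighted mixture of cell-type profiles (with planted ctDEG
#' effects folded into non-control profiles); observed counts are negative
#' binomial around that mean.
#'
#' @param config a [sim_config()].
#' @param truth a [make_ground_truth()] result consistent with `config`.
#' @param seed seed for sample-level draws; defaults to `config$seed + 2`.
#' @return list with `bulk` ([bulk_matrix()]), `truth` (with
#'   `true_proportions`, a sample x cell-type matrix, filled in), and
#'   `means` (the gene x sample expected-count matrix before NB sampling).
#' @export
simulate_bulk <- function(config, truth, seed = config$seed + 2L) {
  config <- validate_sim_config(config)
  if (!identical(rownames(truth$profiles), truth$gene_ids) ||
      nrow(truth$profiles) != config$n_genes)
    stop("gene set of truth does not match config (dimension error)")
  set.seed(seed)
  K <- length(config$conditions)
  n_samples <- sum(config$conditions)
  G <- config$n_genes
  counts <- means <- matrix(0, G, n_samples,
                            dimnames = list(truth$gene_ids,
                                            sprintf("sample%03d",
                                                    seq_len(n_samples))))
  condition <- character(n_samples)
  props <- matrix(NA_real_, n_samples, config$n_celltypes,
                  dimnames = list(colnames(counts), truth$celltypes))
  at <- 0L
  for (k in seq_len(K)) {
    Xk <- truth$condition_profiles[[k]]
    pk <- config$proportions_by_condition[k, ]
    for (i in seq_len(config$conditions[k])) {
      s <- at + i
      p_i <- .rdirichlet1(pk, config$proportion_noise)
      lib <- rlnorm(1, meanlog = log(config$bulk_library_size) -
                      config$bulk_library_sdlog^2 / 2,
                    sdlog = config$bulk_library_sdlog)
      mu <- lib * as.vector(Xk %*% p_i)
      means[, s] <- mu
      counts[, s] <- .rnb(G, mu, config$nb_dispersion)
      props[s, ] <- p_i
      condition[s] <- names(config$conditions)[k]
    }
    at <- at + config$conditions[k]
  }
  truth$true_proportions <- props
  list(bulk = bulk_matrix(counts, condition, levels = names(config$conditions)),
       truth = truth,
       means = means)
}
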