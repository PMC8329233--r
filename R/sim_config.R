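#' Simulation configuration
#'
#' Parameters of the ground-truth simulator. The generator emulates the study
#' design this package targets: a labeled single-cell reference over ~11
#' retinal cell types in two tissue regions, and small bulk cohorts whose
#' cell-type composition shifts with disease stage, with counts drawn from a
#' negative-binomial mixture of cell-type expression profiles.
#'
#' @param n_celltypes number of cell types C.
#' @param n_genes total number of genes (>= `n_celltypes * markers_per_type`).
#' @param cells_per_type integer scalar or length-C vector of reference cells
#'   per type.
#' @param markers_per_type integer scalar or length-C vector: number of
#'   marker genes planted per cell type.
#' @param marker_fc expression multiplier of a marker in its own cell type
#'   relative to all other types (1 = no marker structure). The default (500)
#'   emulates strongly specific markers such as rod phototransduction genes,
#'   whose off-target expression is near zero; the calibration method's
#'   factorization of bulk fold changes relies on exactly this property.
#' @param marker_base_count approximate expected off-target counts per
#'   reference cell for a marker gene. Chosen low so that off-target cells
#'   mostly show zero counts, giving markers the expressed-fraction structure
#'   (pct > 50% in the own type, < 30% elsewhere) that selection relies on.
#' @param conditions named integer vector of per-condition sample counts;
#'   the first entry is the control condition.
#' @param proportions_by_condition K x C matrix (rows = conditions) of
#'   cell-type proportion vectors, each row summing to 1.
#' @param ctdeg_fraction fraction of each type's marker set planted as
#'   cell-type-specific DE in non-control conditions (scalar or length-C).
#' @param ctdeg_fc effect multiplier applied to planted ctDEGs in the affected
#'   cell type's profile (e.g. 0.25 = 4-fold down-regulation).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param library_size_mean mean per-cell library size of the single-cell
#'   reference.
#' @param bulk_library_size mean per-sample library size of bulk samples.
#' @param bulk_library_sdlog lognormal sdlog of bulk library sizes.
#' @param proportion_noise Dirichlet concentration of subject-level
#'   proportions around the condition means; `Inf` fixes composition exactly.
#'   The default (500) mirrors the working assumption that composition is
#'   similar across subjects within a condition (about 2% s.d. on a
#'   proportion of 0.25).
#' @param region_fraction fraction of reference cells labeled "macula"
#'   (the rest are "periphery").
#' @param seed integer seed; all stage-level draws derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_celltypes = 11,
                       n_genes = 5000,
                       cells_per_type = 150,
                       markers_per_type = 25,
                       marker_fc = 500,
                       marker_base_count = 0.1,
                       conditions = c(control = 6, early = 4, advanced = 3),
                       proportions_by_condition = NULL,
                       ctdeg_fraction = 0,
                       ctdeg_fc = 1,
                       nb_dispersion = 0.1,
                       library_size_mean = 5000,
                       bulk_library_size = 2e5,
                       bulk_library_sdlog = 0.15,
                       proportion_noise = 500,
                       region_fraction = 0.5,
                       seed = 1L) {
  conditions <- unlist(conditions)                 # YAML-friendly
  if (is.list(proportions_by_condition))
    proportions_by_condition <- do.call(rbind, proportions_by_condition)
  cfg <- list(n_celltypes = as.integer(n_celltypes),
              n_genes = as.integer(n_genes),
              cells_per_type = rep_len(as.integer(cells_per_type), n_celltypes),
              markers_per_type = rep_len(as.integer(markers_per_type), n_celltypes),
              marker_fc = marker_fc,
              marker_base_count = marker_base_count,
              conditions = conditions,
              proportions_by_condition = proportions_by_condition,
              ctdeg_fraction = rep_len(ctdeg_fraction, n_celltypes),
              ctdeg_fc = ctdeg_fc,
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              bulk_library_size = bulk_library_size,
              bulk_library_sdlog = bulk_library_sdlog,
              proportion_noise = proportion_noise,
              region_fraction = region_fraction,
              seed = as.integer(seed))
  if (is.null(cfg$proportions_by_condition))
    cfg$proportions_by_condition <- .default_proportions(cfg)
  P <- as.matrix(cfg$proportions_by_condition)
  rownames(P) <- names(conditions)
  if (is.null(colnames(P))) colnames(P) <- .celltype_names(n_celltypes)
  cfg$proportions_by_condition <- P
  validate_sim_config(structure(cfg, class = "sim_config"))
}

# Default composition: rod-dominated control retina; with disease progression
# rods decline while glial/immune types (astrocytes, Muller, microglia,
# endothelium) expand, qualitatively matching deconvolution observations in
# degenerating retina.
.default_proportions <- function(cfg) {
  C <- cfg$n_celltypes
  K <- length(cfg$conditions)
  base <- rgamma_fixed(C)
  P <- matrix(NA_real_, K, C,
              dimnames = list(names(cfg$conditions), .celltype_names(C)))
  P[1, ] <- base
  if (K > 1) {
    for (k in 2:K) {
      sev <- (k - 1) / (K - 1)
      w <- base
      w[1] <- w[1] * (1 - 0.5 * sev)           # first type shrinks (rod-like)
      idx_up <- seq_len(min(3, C - 1)) + 1     # a few types expand (glial-like)
      w[idx_up] <- w[idx_up] * (1 + 0.8 * sev)
      P[k, ] <- w / sum(w)
    }
  }
  P
}

# deterministic, seed-independent pseudo-random base composition
rgamma_fixed <- function(C) {
  v <- 0.3 * 0.55 ^ (seq_len(C) - 1) + 0.02
  v / sum(v)
}

.celltype_names <- function(C) {
  nm <- c("rod", "astrocyte", "muller", "microglia", "endothelium", "cone",
          "bipolar", "amacrine", "horizontal", "ganglion", "pericyte")
  if (C <= length(nm)) nm[seq_len(C)] else
    c(nm, sprintf("type%02d", seq_len(C - length(nm))))
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` object (or plain list with the same fields).
#' @return The validated config, invisibly classed as `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  err <- function(field, msg) stop(sprintf("invalid sim_config field '%s': %s",
                                           field, msg), call. = FALSE)
  C <- cfg$n_celltypes
  if (is.na(C) || C < 1) err("n_celltypes", "must be a positive integer")
  if (cfg$n_genes < sum(cfg$markers_per_type))
    err("n_genes", "must be >= total number of planted markers")
  if (any(cfg$cells_per_type < 2)) err("cells_per_type", "each type needs >= 2 cells")
  if (!is.numeric(cfg$marker_fc) || cfg$marker_fc <= 0)
    err("marker_fc", "must be a positive real")
  if (cfg$marker_base_count <= 0) err("marker_base_count", "must be > 0")
  if (length(cfg$conditions) < 1 || any(cfg$conditions < 1))
    err("conditions", "needs >= 1 samples per condition")
  if (is.null(names(cfg$conditions)) || any(!nzchar(names(cfg$conditions))))
    err("conditions", "must be a named vector of sample counts")
  P <- cfg$proportions_by_condition
  if (nrow(P) != length(cfg$conditions) || ncol(P) != C)
    err("proportions_by_condition", "must be K x C (conditions x cell types)")
  if (any(P < 0)) err("proportions_by_condition", "must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-9))
    err("proportions_by_condition", "each row must sum to 1 (tol 1e-9)")
  if (any(cfg$ctdeg_fraction < 0 | cfg$ctdeg_fraction > 1))
    err("ctdeg_fraction", "must be in [0, 1]")
  if (cfg$ctdeg_fc <= 0) err("ctdeg_fc", "must be a positive real")
  if (cfg$nb_dispersion < 0) err("nb_dispersion", "must be >= 0")
  if (cfg$library_size_mean <= 0) err("library_size_mean", "must be > 0")
  if (cfg$bulk_library_size <= 0) err("bulk_library_size", "must be > 0")
  if (cfg$proportion_noise <= 0) err("proportion_noise", "must be > 0 (Inf allowed)")
  if (cfg$region_fraction < 0 || cfg$region_fraction > 1)
    err("region_fraction", "must be in [0, 1]")
  invisible(structure(cfg, class = "sim_config"))
}
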