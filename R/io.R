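#' Write a single-cell matrix to a directory
#'
#' Layout: `matrix.mtx` (MatrixMarket, genes x cells), `genes.tsv` (gene_id),
#' `cells.tsv` (cell_id, cell_type, region).
#'
#' @param sc a [single_cell_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_single_cell <- function(sc, dir) {
  stopifnot(inherits(sc, "single_cell_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(sc$counts, file.path(dir, "matrix.mtx"))
  write.table(data.frame(gene_id = sc$gene_ids),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(cell_id = sc$cell_ids, cell_type = sc$cell_types,
                         region = sc$regions),
              file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a single-cell matrix written by [write_single_cell()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return a [single_cell_matrix()].
#' @export
read_single_cell <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- read.delim(file.path(dir, "genes.tsv"))
  cells <- read.delim(file.path(dir, "cells.tsv"))
  single_cell_matrix(m, cells$cell_type, cells$region,
                     gene_ids = genes$gene_id, cell_ids = cells$cell_id)
}

#' Write a bulk matrix to a directory
#'
#' Layout: `bulk_counts.tsv` (gene_id plus one column per sample) and
#' `samples.tsv` (sample_id, condition).
#'
#' @param bulk a [bulk_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bulk <- function(bulk, dir) {
  stopifnot(inherits(bulk, "bulk_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(data.frame(gene_id = bulk$gene_ids, bulk$counts,
                         check.names = FALSE),
              file.path(dir, "bulk_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = bulk$sample_ids,
                         condition = as.character(bulk$condition)),
              file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a bulk matrix written by [write_bulk()]
#'
#' @param dir directory containing `bulk_counts.tsv` and `samples.tsv`.
#' @param levels optional condition level order (first = control).
#' @return a [bulk_matrix()].
#' @export
read_bulk <- function(dir, levels = NULL) {
  tab <- read.delim(file.path(dir, "bulk_counts.tsv"), check.names = FALSE)
  samples <- read.delim(file.path(dir, "samples.tsv"))
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$gene_id
  counts <- counts[, samples$sample_id, drop = FALSE]
  bulk_matrix(counts, samples$condition, sample_ids = samples$sample_id,
              levels = levels)
}

#' Write ground-truth tables
#'
#' Writes `true_proportions.tsv`, `true_pc.tsv`, `planted_markers.tsv` and
#' `planted_ctdegs.tsv` for a simulation record.
#'
#' @param truth a [make_ground_truth()] result (after [simulate_bulk()] if
#'   subject-level proportions should be included).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(truth$true_proportions))
    write.table(data.frame(sample_id = rownames(truth$true_proportions),
                           truth$true_proportions, check.names = FALSE),
                file.path(dir, "true_proportions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(data.frame(condition = rownames(truth$true_PC), truth$true_PC,
                         check.names = FALSE),
              file.path(dir, "true_pc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pm <- do.call(rbind, lapply(names(truth$planted_markers), function(ct)
    if (length(truth$planted_markers[[ct]]))
      data.frame(cell_type = ct, gene = truth$planted_markers[[ct]])))
  write.table(pm %||% data.frame(cell_type = character(0), gene = character(0)),
              file.path(dir, "planted_markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pd <- do.call(rbind, lapply(names(truth$planted_ctdegs), function(ct) {
    de <- truth$planted_ctdegs[[ct]]
    if (nrow(de)) cbind(cell_type = ct, de)
  }))
  write.table(pd %||% data.frame(cell_type = character(0),
                                 gene = character(0), effect = numeric(0)),
              file.path(dir, "planted_ctdegs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
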