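#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]: either a `sim` block (arguments
#' of [sim_config()]) for synthetic mode, or `sc_dir` / `bulk_dir` pointing
#' at data written in the package's on-disk layout. Unknown keys anywhere in
#' the structure are rejected by name.
#'
#' @param config named list, or path to a YAML file with the same structure.
#'   Recognized top-level keys: `sim`, `sc_dir`, `bulk_dir`, `markers`
#'   (`scope`, `p_adj_max`, `fc_min`, `pct_target_min`, `pct_other_max`),
#'   `deconvolution` (`min_pct`, `min_cells`, `marker_genes_only`, `group1`,
#'   `group2`), `ctdeg` (`conditions`, `robust`, `direction`, `alpha`),
#'   `filter` (`min_sample_fraction`), `seed`, `out_dir`.
#' @param ... overrides merged over the file/list values.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  config <- utils::modifyList(config, list(...))
  known <- list(
    sim = names(formals(sim_config)),
    sc_dir = NULL, bulk_dir = NULL,
    markers = c("scope", "p_adj_max", "fc_min", "pct_target_min",
                "pct_other_max"),
    deconvolution = c("min_pct", "min_cells", "marker_genes_only",
                      "group1", "group2"),
    ctdeg = c("conditions", "robust", "direction", "alpha"),
    filter = "min_sample_fraction",
    seed = NULL, out_dir = NULL)
  bad <- setdiff(names(config), names(known))
  if (length(bad))
    stop("unknown pipeline config key(s): ", paste(bad, collapse = ", "))
  for (blk in intersect(names(config), names(known))) {
    if (is.null(known[[blk]]) || !is.list(config[[blk]])) next
    badk <- setdiff(names(config[[blk]]), known[[blk]])
    if (length(badk))
      stop("unknown key(s) in '", blk, "' block: ",
           paste(badk, collapse = ", "))
  }
  if (is.null(config$sim) && (is.null(config$sc_dir) || is.null(config$bulk_dir)))
    stop("config needs either a 'sim' block or both 'sc_dir' and 'bulk_dir'")
  for (d in c(config$sc_dir, config$bulk_dir))
    if (!dir.exists(d)) stop("input directory does not exist: ", d)
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> marker selection -> deconvolution ->
#' proportion-change calibration -> ctDEG detection, writing every stage's
#' table plus a machine-readable manifest to `out_dir`. All randomness flows
#' from the single config seed via fixed per-stage offsets, so a rerun with
#' the same config is bit-identical.
#'
#' @param config a [pipeline_config()] (or list/YAML path accepted by it).
#' @param out_dir output directory; overrides `config$out_dir`.
#' @param seed overrides `config$seed`.
#' @return invisible list with elements `sc`, `bulk`, `truth`, `markers`,
#'   `signature`, `proportions`, `prop_tests`, `ctdegs`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("retdeconv")),
                   seed = config$seed,
                   config_hash = .config_hash(config),
                   stages = list())
  truth <- NULL
  if (!is.null(config$sim)) {
    scfg <- do.call(sim_config, utils::modifyList(config$sim,
                                                  list(seed = config$seed)))
    ref <- simulate_reference(scfg)
    sc <- ref$sc
    sim <- simulate_bulk(scfg, ref$truth)
    bulk <- sim$bulk
    truth <- sim$truth
    write_single_cell(sc, file.path(out_dir, "sc"))
    write_bulk(bulk, file.path(out_dir, "bulk"))
    write_ground_truth(truth, file.path(out_dir, "truth"))
    manifest$stages$simulate <- list(n_genes = nrow(bulk$counts),
                                     n_cells = ncol(sc$counts),
                                     n_samples = ncol(bulk$counts))
  } else {
    sc <- read_single_cell(config$sc_dir)
    bulk <- read_bulk(config$bulk_dir)
    manifest$stages$load <- list(n_genes = nrow(bulk$counts),
                                 n_cells = ncol(sc$counts),
                                 n_samples = ncol(bulk$counts))
  }

  mcfg <- config$markers %||% list()
  markers <- do.call(select_markers, c(list(sc = sc), mcfg))
  write.table(markers, file.path(out_dir, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$markers <- list(n_markers = nrow(markers),
                                  n_celltypes = length(unique(markers$cell_type)))

  dcfg <- config$deconvolution %||% list()
  sig <- build_signature(sc,
                         min_pct = dcfg$min_pct %||% 0.05,
                         min_cells = dcfg$min_cells %||% 10,
                         genes = if (isTRUE(dcfg$marker_genes_only))
                           unique(markers$gene) else NULL)
  props <- estimate_proportions(bulk, sig)
  write.table(props, file.path(out_dir, "proportions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lev <- levels(bulk$condition)
  g1 <- dcfg$group1 %||% lev[1]
  g2 <- dcfg$group2 %||% lev[length(lev)]
  prop_tests <- test_proportion_difference(props, g1, g2)
  write.table(prop_tests, file.path(out_dir, "prop_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$deconvolution <- list(n_signature_genes = length(sig$genes),
                                        groups = c(g1, g2))

  ccfg <- config$ctdeg %||% list()
  conds <- ccfg$conditions %||% c(lev[1], lev[length(lev)])
  bulk2 <- subset_conditions(bulk, conds)
  bulk2 <- filter_genes(bulk2, (config$filter %||% list())$min_sample_fraction
                        %||% 0.20)
  ctdegs <- detect_ctdegs(bulk2, markers,
                          robust = ccfg$robust %||% "mean",
                          direction = ccfg$direction %||% "corrected",
                          alpha = ccfg$alpha %||% 0.05)
  write.table(as.data.frame(ctdegs), file.path(out_dir, "ctdegs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pc_tab <- attr(ctdegs, "pc")
  write.table(pc_tab, file.path(out_dir, "pc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$ctdeg <- list(conditions = conds,
                                n_candidates = nrow(ctdegs),
                                n_significant = sum(ctdegs$significant))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sc = sc, bulk = bulk, truth = truth, markers = markers,
                 signature = sig, proportions = props,
                 prop_tests = prop_tests, ctdegs = ctdegs,
                 manifest = manifest))
}

.config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # digest via md5 of the serialized config written to a temp file
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}
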