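test_that("bulk fold changes follow the group-mean ratio definition", {
  bulk <- bulk_matrix(rbind(g1 = c(10, 10, 20, 20),
                            g2 = c(5, 7, 5, 7),
                            g3 = c(0, 0, 4, 4)),
                      rep(c("ctrl", "amd"), each = 2),
                      levels = c("ctrl", "amd"))
  fc <- bulk_fold_change(bulk, sf = rep(1, 4))
  expect_equal(fc$FC[1], 2)
  expect_equal(fc$FC[2], 1)
  expect_false(fc$defined[3])            # zero control mean: flagged
  # brute-force oracle on a random matrix
  set.seed(18)
  m <- matrix(rpois(30 * 8, 25), 30)
  b2 <- bulk_matrix(m, rep(c("a", "b"), each = 4))
  sf <- size_factors(b2)
  fc2 <- bulk_fold_change(b2, sf = sf)
  naive <- apply(sweep(m, 2, sf, "/"), 1,
                 function(r) mean(r[5:8]) / mean(r[1:4]))
  expect_equal(fc2$FC, naive, tolerance = 1e-12)
})

test_that("proportion change is the geometric mean of marker fold changes", {
  mk_fc <- function(fcs) data.frame(gene = seq_along(fcs), FC = fcs,
                                    log_FC = log(fcs), defined = TRUE)
  expect_equal(estimate_proportion_change(mk_fc(c(1, 1, 1)))$PC, 1)
  expect_equal(estimate_proportion_change(mk_fc(c(2, 8)))$PC, 4)
  pc <- estimate_proportion_change(mk_fc(c(2, 8)))
  expect_equal(pc$PC, exp(mean(pc$contributing_log_FCs)), tolerance = 1e-12)
  expect_equal(estimate_proportion_change(mk_fc(c(1, 1, 1, 100)),
                                          robust = "median")$PC, 1)
  und <- data.frame(gene = 1, FC = NA, log_FC = NA, defined = FALSE)
  expect_error(estimate_proportion_change(und), "not estimable")
})

test_that("calibration identities hold exactly", {
  sim <- small_bulk()
  bulk <- sim$bulk
  sf <- size_factors(bulk)
  genes <- sim$truth$planted_markers[[1]]
  fc <- bulk_fold_change(bulk, genes = genes, sf = sf)
  pc <- estimate_proportion_change(fc)
  # PC = 1 leaves expression untouched
  cal1 <- calibrate_expression(bulk, 1, mode = "scaled_counts")
  expect_identical(cal1$bulk$counts, bulk$counts)
  # PC = 0.5, disease count 10 -> corrected scaled count 20
  b <- bulk_matrix(rbind(g = c(10, 10, 10, 10)), rep(c("c", "d"), each = 2),
                   levels = c("c", "d"))
  cal2 <- calibrate_expression(b, 0.5, mode = "scaled_counts")
  expect_equal(unname(cal2$bulk$counts[1, 3:4]), c(20, 20))
  # literal direction multiplies instead
  cal3 <- calibrate_expression(b, 0.5, mode = "scaled_counts",
                               direction = "paper_literal")
  expect_equal(unname(cal3$bulk$counts[1, 3:4]), c(5, 5))
  # decomposition identity: mean log FC = log PC + mean log calibrated FC
  cal <- calibrate_expression(bulk, pc, mode = "scaled_counts", round = FALSE)
  fc_cal <- bulk_fold_change(cal$bulk, genes = genes, sf = sf)
  expect_lt(abs(mean(fc$log_FC) - log(pc$PC) - mean(fc_cal$log_FC)), 1e-9)
})

test_that("condition-label swap inverts fold changes and proportion change", {
  sim <- small_bulk()
  bulk <- sim$bulk
  sf <- size_factors(bulk)
  genes <- sim$truth$planted_markers[[2]]
  swapped <- bulk_matrix(bulk$counts, as.character(bulk$condition),
                         levels = rev(levels(bulk$condition)))
  fc <- bulk_fold_change(bulk, genes = genes, sf = sf)
  fcs <- bulk_fold_change(swapped, genes = genes, sf = sf)
  expect_equal(fcs$FC, 1 / fc$FC, tolerance = 1e-12)
  expect_equal(estimate_proportion_change(fcs)$PC,
               1 / estimate_proportion_change(fc)$PC, tolerance = 1e-12)
})

test_that("PC estimation is invariant to common library rescaling", {
  sim <- small_bulk()
  genes <- sim$truth$planted_markers[[1]]
  pc0 <- estimate_proportion_change(bulk_fold_change(sim$bulk, genes = genes))
  scaled <- bulk_matrix(sim$bulk$counts * 7, as.character(sim$bulk$condition),
                        levels = levels(sim$bulk$condition))
  pc1 <- estimate_proportion_change(bulk_fold_change(scaled, genes = genes))
  expect_equal(pc1$PC, pc0$PC, tolerance = 1e-12)
})

test_that("PC estimates converge to the truth as samples grow", {
  p1 <- c(0.5, 0.3, 0.2); p2 <- c(0.25, 0.45, 0.3)
  errs <- sapply(c(10, 50, 200), function(n) {
    cfg <- sim_config(n_celltypes = 3, n_genes = 800, markers_per_type = 10,
                      conditions = c(control = n, advanced = n),
                      proportions_by_condition = rbind(p1, p2),
                      proportion_noise = Inf, seed = 31)
    truth <- make_ground_truth(cfg)
    reps <- sapply(1:6, function(r) {
      sim <- simulate_bulk(cfg, truth, seed = 100 * n + r)
      fc <- bulk_fold_change(sim$bulk, genes = truth$planted_markers[[1]])
      abs(log(estimate_proportion_change(fc)$PC / 0.5))
    })
    mean(reps)
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.03)
})

test_that("calibration removes composition confounding of null marker genes", {
  sim <- small_bulk()
  truth <- sim$truth
  ct <- detect_ctdegs(sim$bulk, truth$planted_markers)
  ct0 <- detect_ctdegs(sim$bulk, truth$planted_markers,
                       pc = setNames(rep(1, 3), names(truth$planted_markers)))
  # calibrated mean log fold change over each marker set is near zero
  for (tp in names(truth$planted_markers)) {
    lfc <- ct$calibrated_log2_FC[ct$cell_type == tp]
    expect_lt(abs(mean(lfc)), 0.15)
  }
  # the uncalibrated ablation is dominated by composition change
  expect_gt(mean(ct0$p_raw < 0.05), mean(ct$p_raw < 0.05))
  expect_equal(sum(ct$significant), 0)
})

test_that("calibrated p-values are attenuated for direction-confounded ctDEGs", {
  # rods shrink (PC < 1) and rod ctDEGs are down-regulated: the naive bulk
  # test conflates both signals, so calibration must attenuate significance
  p1 <- c(0.5, 0.3, 0.2); p2 <- c(0.25, 0.45, 0.3)
  cfg <- sim_config(n_celltypes = 3, n_genes = 800,
                    markers_per_type = c(40, 10, 10),
                    ctdeg_fraction = c(0.25, 0, 0), ctdeg_fc = 0.25,
                    conditions = c(control = 12, advanced = 12),
                    proportions_by_condition = rbind(p1, p2), seed = 33)
  truth <- make_ground_truth(cfg)
  sim <- simulate_bulk(cfg, truth)
  mk <- list(rod = truth$planted_markers[[1]])
  cal <- detect_ctdegs(sim$bulk, mk, robust = "median")
  naive <- detect_ctdegs(sim$bulk, mk, pc = c(rod = 1))
  de_genes <- truth$planted_ctdegs[[1]]$gene
  p_cal <- cal$p_raw[match(de_genes, cal$gene)]
  p_naive <- naive$p_raw[match(de_genes, naive$gene)]
  expect_true(median(log(p_cal / p_naive)) > 0)
  # planted effects are still recovered after calibration
  hits <- cal$gene[cal$significant]
  expect_gt(length(intersect(hits, de_genes)) / length(de_genes), 0.8)
})
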