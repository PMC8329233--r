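test_that("signature gene filter matches a brute-force evaluation", {
  ref <- small_reference()
  sig <- build_signature(ref$sc, min_pct = 0.05, min_cells = 10)
  counts <- ref$sc$counts
  types <- ref$sc$cell_types
  keep <- vapply(rownames(counts), function(g) {
    any(vapply(unique(types), function(tp) {
      idx <- which(types == tp)
      n_expr <- sum(counts[g, idx] > 0)
      n_expr / length(idx) >= 0.05 && n_expr > 10
    }, logical(1)))
  }, logical(1))
  expect_setequal(sig$genes, rownames(counts)[keep])
  expect_equal(colSums(sig$profiles), setNames(rep(1, 3), sig$celltypes),
               tolerance = 1e-9)
})

test_that("a gene below both filter thresholds in every type is excluded", {
  set.seed(7)
  counts <- matrix(rpois(40 * 300, 5), 40)
  counts[1, ] <- 0
  counts[1, sample(300, 8)] <- 1    # ~2.7% of cells, <= 10 cells everywhere
  sc <- single_cell_matrix(counts, rep(c("A", "B", "C"), each = 100))
  sig <- build_signature(sc)
  expect_false("gene00001" %in% sig$genes)
})

test_that("noiseless mixtures are recovered exactly", {
  set.seed(8)
  for (i in 1:20) {
    G <- 60; C <- 4
    S <- matrix(rgamma(G * C, 1), G)
    S <- sweep(S, 2, colSums(S), "/")
    rownames(S) <- sprintf("gene%05d", 1:G)
    sig <- structure(list(profiles = S, genes = rownames(S),
                          celltypes = paste0("t", 1:C)),
                     class = "signature_matrix")
    colnames(sig$profiles) <- sig$celltypes
    p_true <- rgamma(C, 1)
    p_true <- p_true / sum(p_true)
    y <- S %*% p_true * 5e5
    bulk <- bulk_matrix(cbind(y, y), c("a", "b"))
    est <- estimate_proportions(bulk, sig)
    expect_lt(max(abs(as.numeric(est[1, sig$celltypes]) - p_true)), 1e-6)
    expect_lt(max(est$residual_norm), 1e-8)
  }
})

test_that("residual norm matches the Euclidean fit residual", {
  sim <- small_bulk()
  sig <- build_signature(small_reference()$sc)
  est <- estimate_proportions(sim$bulk, sig)
  expect_true(all(est$residual_norm > 0))
  # recompute for the first sample from the unnormalized NNLS solution
  shared <- intersect(sim$bulk$gene_ids, sig$genes)
  S <- sig$profiles[shared, ]
  S <- sweep(S, 2, colSums(S), "/")
  y <- sim$bulk$counts[shared, 1]
  y <- y / sum(y)
  fit <- pracma::lsqnonneg(S, y)
  expect_equal(est$residual_norm[1], sqrt(sum((y - S %*% fit$x)^2)),
               tolerance = 1e-10)
})

test_that("a bulk sample equal to one signature column is assigned proportion 1", {
  ref <- small_reference()
  sig <- build_signature(ref$sc)
  y <- sig$profiles[, 2] * 1e6
  bulk <- bulk_matrix(cbind(y, y), c("a", "b"), gene_ids = sig$genes)
  est <- estimate_proportions(bulk, sig)
  p <- as.numeric(est[1, sig$celltypes])
  expect_lt(max(abs(p - c(0, 1, 0))), 1e-8)
})

test_that("proportion estimates ignore library size and cell-type order", {
  sim <- small_bulk()
  ref <- small_reference()
  sig <- build_signature(ref$sc)
  est <- estimate_proportions(sim$bulk, sig)
  scaled <- sim$bulk
  scaled$counts[, 1] <- scaled$counts[, 1] * 10
  est2 <- estimate_proportions(scaled, sig)
  expect_equal(as.numeric(est[1, sig$celltypes]),
               as.numeric(est2[1, sig$celltypes]), tolerance = 1e-9)
  # permute cell-type columns of the signature
  perm <- c(3, 1, 2)
  sigp <- sig
  sigp$profiles <- sig$profiles[, perm]
  sigp$celltypes <- sig$celltypes[perm]
  estp <- estimate_proportions(sim$bulk, sigp)
  expect_equal(as.numeric(est[1, sig$celltypes]),
               as.numeric(estp[1, sig$celltypes]), tolerance = 1e-9)
})

test_that("noisy synthetic mixtures are recovered within the oracle bound", {
  # pre-registered bound: mean absolute proportion error < 0.05 at n = 11,
  # dispersion 0.1, marker-informed signature
  sim <- small_bulk()
  sig <- build_signature(small_reference()$sc)
  est <- estimate_proportions(sim$bulk, sig)
  mae <- mean(abs(as.matrix(est[, sig$celltypes]) -
                  sim$truth$true_proportions[, sig$celltypes]))
  expect_lt(mae, 0.05)
})

test_that("duplicate signature columns are flagged as rank-deficient", {
  ref <- small_reference()
  sig <- build_signature(ref$sc)
  sig$profiles[, 2] <- sig$profiles[, 1]
  sim <- small_bulk()
  expect_warning(est <- estimate_proportions(sim$bulk, sig), "rank-deficient")
  expect_true(attr(est, "rank_deficient"))
})

test_that("proportion difference testing is calibrated and detects shifts", {
  set.seed(9)
  # null: equal means; empirical type-I error near nominal over 1000 reps
  hits <- replicate(1000, {
    d <- data.frame(condition = rep(c("a", "b"), each = 10),
                    ct1 = rnorm(20, 0.5, 0.05))
    test_proportion_difference(d, "a", "b", celltypes = "ct1")$p_raw < 0.05
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
  # planted 5x shift with small noise
  d <- data.frame(condition = rep(c("a", "b"), each = 6),
                  ct1 = c(rnorm(6, 0.1, 0.01), rnorm(6, 0.5, 0.01)),
                  ct2 = rnorm(12, 0.3, 0.01))
  res <- test_proportion_difference(d, "a", "b", celltypes = c("ct1", "ct2"))
  expect_lt(res$p_adj[res$cell_type == "ct1"], 0.05)
  # degenerate duplicated estimates
  d2 <- data.frame(condition = rep(c("a", "b"), each = 3),
                   ct1 = rep(0.4, 6))
  r2 <- test_proportion_difference(d2, "a", "b", celltypes = "ct1")
  expect_true(r2$degenerate)
  expect_equal(r2$p_raw, 1)
})
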