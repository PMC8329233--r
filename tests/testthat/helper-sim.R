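# Shared small simulation fixtures, built once per test run.

# three cell types, clearly separated markers
small_cfg <- function(seed = 7, ...) {
  sim_config(n_celltypes = 3, n_genes = 800, cells_per_type = 100,
             markers_per_type = 10,
             conditions = c(control = 6, advanced = 5),
             proportions_by_condition = rbind(c(0.5, 0.3, 0.2),
                                              c(0.25, 0.45, 0.3)),
             seed = seed, ...)
}

.fixture_env <- new.env()

small_reference <- function() {
  if (is.null(.fixture_env$ref)) .fixture_env$ref <- simulate_reference(small_cfg())
  .fixture_env$ref
}

small_bulk <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_bulk(small_cfg(), small_reference()$truth)
  .fixture_env$sim
}

# brute-force two-sided Wilcoxon p by enumerating all rank assignments
enumerate_wilcoxon <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(N, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# direct step-up BH: min over k >= i of p(k) * m / k, clipped at 1
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- rev(adj)
  out
}
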