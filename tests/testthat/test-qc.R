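test_that("beta/M transform is the log2 odds and inverts exactly", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  x <- seq(0.001, 0.999, length.out = 200)
  expect_equal(m_to_beta(beta_to_m(x)), x, tolerance = 1e-14)
  # strictly increasing bijection
  expect_true(all(diff(beta_to_m(x)) > 0))
  expect_error(beta_to_m(0), "strictly")
  expect_error(beta_to_m(1), "strictly")
})

test_that("mean-beta band and missingness filters follow the strict rules", {
  ns <- 122
  b <- rbind(rep(0.005, ns), rep(0.5, ns), rep(0.995, ns), rep(0.5, ns))
  b[2, 1:11] <- NA   # 11 missing: removed
  b[4, 1:10] <- NA   # 10 missing: retained
  colnames(b) <- sprintf("s%03d", 1:ns)
  m <- meth_matrix(b, rep("chr1", 4), c(10, 20, 30, 40))
  fl <- filter_cpgs(m)
  expect_equal(fl$report$n_removed_extreme_mean, 2)
  expect_equal(fl$report$n_removed_missing, 1)
  expect_equal(fl$report$n_retained, 1)
  expect_equal(rownames(fl$matrix$beta), "chr1:40")
  # counts additive (first-failing-filter attribution)
  expect_equal(fl$report$n_input,
               fl$report$n_retained + fl$report$n_removed_extreme_mean +
                 fl$report$n_removed_missing)
})

test_that("the shipped 6-CpG toy retains exactly 4 CpGs", {
  f <- system.file("extdata", "qc_toy_beta.tsv", package = "twinmeth")
  fl <- filter_cpgs(read_beta_matrix(f))
  expect_equal(fl$report$n_input, 6)
  expect_equal(fl$report$n_retained, 4)
})

test_that("filtering is idempotent", {
  sim <- quick_sim(11, n_pairs = 8, n_cpgs = 50, missing_rate = 0.2)
  f1 <- filter_cpgs(sim$matrix, max_missing = 2)
  f2 <- filter_cpgs(f1$matrix, max_missing = 2)
  expect_identical(f2$matrix$beta, f1$matrix$beta)
  expect_equal(f2$report$n_retained, f2$report$n_input)
})

test_that("composition components recover a planted 2-cell-type mixture", {
  sim <- simulate_cohort(sim_config(
    n_pairs = 61, n_cpgs = 1000, n_causal = 0, n_reverse_causal = 0,
    n_confounded = 0, n_cell_types = 2, cell_frac = 0.2, cell_sd = 2,
    missing_rate = 0.03, seed = 21))
  comp <- refactor_components(sim$matrix, k = 5, t = 300)
  expect_gt(abs(cor(comp$scores[, 1], sim$cell_props[, 1])), 0.9)
  # score columns are orthogonal
  cp <- crossprod(comp$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
})

test_that("pure-noise components explain roughly their share of variance", {
  sim <- quick_sim(22, n_pairs = 30, n_cpgs = 400,
                   familial_var_share = 0, rho_eps = 0)
  comp <- refactor_components(sim$matrix, k = 5, t = 200)
  b <- sim$matrix$beta
  bs <- t(scale(t(b[comp$ranked_cpg_indices[1:200], ])))
  total_var <- sum(apply(t(bs), 2, var))
  frac <- sum(comp$sdev^2) / total_var
  # Marchenko-Pastur-style loose bound: k/n inflated by the aspect ratio,
  # well below half the variance for 5 of 60 possible components
  expect_lt(frac, 0.5)
  expect_gt(frac, 5 / 60)
})

test_that("component scores are invariant to sample reordering", {
  sim <- quick_sim(23, n_pairs = 10, n_cpgs = 200, n_cell_types = 2)
  comp <- refactor_components(sim$matrix, k = 3, t = 100)
  perm <- sample(ncol(sim$matrix$beta))
  m2 <- sim$matrix[, perm]
  comp2 <- refactor_components(m2, k = 3, t = 100)
  # same scores up to the permutation and column sign
  for (j in 1:3) {
    a <- comp$scores[m2$samples, j]; b <- comp2$scores[, j]
    expect_equal(min(max(abs(a - b)), max(abs(a + b))), 0, tolerance = 1e-8)
  }
})

test_that("rank-1 planted structure gives near-zero reconstruction distance", {
  set.seed(31)
  u <- rnorm(50); v <- rnorm(20)
  sig <- 0.4 + 0.1 * tcrossprod(u, v) / max(abs(tcrossprod(u, v)))
  noise <- matrix(0.4 + rnorm(50 * 20, 0, 0.1), 50, 20)
  b <- pmin(pmax(rbind(sig, noise), 0.01), 0.99)
  colnames(b) <- sprintf("s%02d", 1:20)
  m <- meth_matrix(b, rep("chr1", 100), seq(100, by = 50, length.out = 100))
  comp <- refactor_components(m, k = 1, t = 50)
  # the 50 rank-1 signal CpGs are the best-reconstructed ones
  expect_gte(mean(comp$ranked_cpg_indices[1:50] <= 50), 0.9)
})
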