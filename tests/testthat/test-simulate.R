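test_that("identical config and seed give byte-identical output", {
  cfg <- sim_config(n_pairs = 10, n_cpgs = 50, seed = 5,
                    n_causal = 2, n_reverse_causal = 1, n_confounded = 1)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$matrix$beta, s2$matrix$beta)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth, s2$truth)
})

test_that("cohort structure matches the MZ design", {
  sim <- quick_sim(6, n_pairs = 61, n_cpgs = 30)
  co <- sim$cohort
  expect_equal(nrow(co), 122)
  expect_true(all(table(co$pair_id) == 2))
  # pair-shared covariates identical within pair
  expect_true(all(tapply(co$age, co$pair_id, function(x) x[1] == x[2])))
  expect_true(all(tapply(co$sex, co$pair_id, function(x) x[1] == x[2])))
  expect_true(all(co$alt > 0))
  # the discordance inclusion rule
  expect_true(all(abs(tapply(co$alt, co$pair_id, diff)) >= 1))
})

test_that("no planted signal means no M-ALT correlation", {
  cors <- vapply(1:20, function(r) {
    sim <- quick_sim(300 + r, n_pairs = 61, n_cpgs = 5, role = "causal",
                     effect = 0, r2_me = 0)
    g <- which(sim$truth$role == "causal")
    cor(m_values(sim$matrix)[g, ], sim$cohort$alt)
  }, 1)
  expect_lt(abs(mean(cors)), 2 / sqrt(20 * 122))
})

test_that("within-pair M correlation at null CpGs matches the planted share", {
  # with no individual-residual correlation the within-pair correlation is
  # the familial variance share itself
  sim <- quick_sim(7, n_pairs = 61, n_cpgs = 2000,
                   familial_var_share = 0.5, rho_eps = 0)
  M <- m_values(sim$matrix)
  i1 <- seq(1, 122, 2); i2 <- seq(2, 122, 2)
  d1 <- M[, i1] - rowMeans(M[, i1]); d2 <- M[, i2] - rowMeans(M[, i2])
  expect_equal(cor(as.vector(d1), as.vector(d2)), 0.5, tolerance = 0.05)
  # at the defaults the correlation is fvs + (1 - fvs) * rho_eps
  sim2 <- quick_sim(8, n_pairs = 61, n_cpgs = 2000,
                    familial_var_share = 0.5, rho_eps = 0.1)
  M <- m_values(sim2$matrix)
  d1 <- M[, i1] - rowMeans(M[, i1]); d2 <- M[, i2] - rowMeans(M[, i2])
  expect_equal(cor(as.vector(d1), as.vector(d2)), 0.55, tolerance = 0.05)
})

test_that("masking rate lands inside its binomial confidence band", {
  b <- matrix(0.5, 100, 100,
              dimnames = list(NULL, sprintf("s%03d", 1:100)))
  m <- meth_matrix(b, rep("chr1", 100), seq(100, by = 50, length.out = 100))
  expect_identical(apply_missingness(m, 0, 1)$beta, m$beta)
  masked <- apply_missingness(m, 0.05, 3)
  frac <- mean(is.na(masked$beta))
  half <- 2.576 * sqrt(0.05 * 0.95 / 10000)
  expect_gt(frac, 0.05 - half)
  expect_lt(frac, 0.05 + half)
  expect_error(apply_missingness(m, 1, 1), "rate")
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_pairs = 1), "n_pairs")
  expect_error(sim_config(n_cpgs = 5, n_causal = 3, n_reverse_causal = 2,
                          n_confounded = 1), "exceed")
  expect_error(sim_config(familial_var_share = 1.2), "\\[0, 1\\]")
})

test_that("confounded CpGs associate with ALT but only via the shared latent", {
  # marginal association present; within-pair (familial-free) association absent
  marg <- within <- numeric(15)
  for (r in 1:15) {
    sim <- quick_sim(400 + r, n_pairs = 100, n_cpgs = 5, role = "confounded")
    g <- which(sim$truth$role == "confounded")
    M <- m_values(sim$matrix)[g, ]
    alt <- sim$cohort$alt
    marg[r] <- cor(M, alt)
    i1 <- seq(1, 200, 2); i2 <- seq(2, 200, 2)
    within[r] <- cor(M[i1] - M[i2], alt[i1] - alt[i2])
  }
  expect_gt(mean(marg), 0.1)
  expect_lt(abs(mean(within)), 0.05)
})

test_that("synthetic validation cohort has cases defined by ALT > 40", {
  v <- simulate_validation_cohort(n = 300, seed = 4)
  expect_equal(v$samples$case, as.integer(v$samples$alt > 40))
  expect_equal(rownames(v$meth), v$samples$sample_id)
})

test_that("synthetic gene and term annotations cover the track", {
  sim <- quick_sim(9, n_pairs = 4, n_cpgs = 60)
  genes <- simulate_genes(sim$matrix, seed = 2)
  expect_gt(length(genes), 0)
  expect_true(all(as.character(GenomicRanges::strand(genes)) %in% c("+", "-")))
  terms <- simulate_terms(genes, n_terms = 5, seed = 2)
  expect_length(terms, 5)
  expect_true(all(unlist(terms) %in% S4Vectors::mcols(genes)$name))
})
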