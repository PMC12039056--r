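# an independent Stouffer-Liptak oracle: variance of the summed z through a
# Cholesky factorization instead of the direct entry sum
sl_oracle <- function(pvals, sigma) {
  z <- qnorm(1 - pvals)
  w <- chol(sigma) %*% rep(1, nrow(sigma))   # Var(sum z) = ||L %*% 1||^2
  1 - pnorm(sum(z) / sqrt(sum(w^2)))
}

test_that("ACF of independent p-values is near zero, duplicates near one", {
  set.seed(81)
  n <- 600
  pos <- sort(sample(1:50000, n))
  p <- runif(n)
  acf <- suppressWarnings(estimate_acf(p, rep("chr1", n), pos, 500, 50))
  expect_true(all(abs(acf$cor[acf$n >= 100]) < 0.1))
  # duplicated p at adjacent positions: bin-1 correlation ~ 1
  pos2 <- as.vector(rbind(seq(100, by = 400, length.out = 200),
                          seq(110, by = 400, length.out = 200)))
  p2 <- rep(runif(200), each = 2)
  acf2 <- suppressWarnings(estimate_acf(p2, rep("chr1", 400), pos2, 500, 50))
  expect_gt(acf2$cor[1], 0.95)
  # empty bins fall back to zero with a warning
  w <- testthat::capture_warnings(
    estimate_acf(runif(20), rep("chr1", 20),
                 seq(1000, by = 1000, length.out = 20), 500, 50))
  expect_true(any(grepl("fewer than 10", w)))
})

test_that("slk correction: identity for isolated CpGs, closed form for pairs", {
  acf0 <- data.frame(lo = c(0, 50), hi = c(50, 100), cor = 0, n = 100L)
  class(acf0) <- c("acf_estimate", "data.frame")
  # isolated CpG keeps its p-value
  out <- slk_correct(c(0.3), "chr1", 1000, acf0, window = 300)
  expect_equal(out, 0.3)
  # two independent neighbours at p = 0.05 each
  out2 <- slk_correct(c(0.05, 0.05), c("chr1", "chr1"), c(1000, 1040),
                      acf0, window = 300)
  zc <- 2 * qnorm(0.95) / sqrt(2)
  expect_equal(out2, rep(1 - pnorm(zc), 2), tolerance = 1e-12)
  expect_equal(round(out2[1], 4), 0.0100)
})

test_that("Stouffer-Liptak agrees with a Cholesky oracle on arbitrary PD sigma", {
  set.seed(82)
  acf0 <- data.frame(lo = 0, hi = 50, cor = 0, n = 100L)
  for (m in c(3, 5, 8)) {
    A <- matrix(rnorm(m * m), m)
    sigma <- cov2cor(crossprod(A) + diag(m))
    p <- runif(m, 0.001, 0.6)
    got <- twinmeth:::stouffer_liptak(p, sigma)
    expect_equal(got, sl_oracle(p, sigma), tolerance = 1e-10)
  }
})

test_that("with zero ACF the slk correction is plain Stouffer combination", {
  set.seed(83)
  acf0 <- data.frame(lo = c(0, 50, 100), hi = c(50, 100, 150), cor = 0,
                     n = 100L)
  class(acf0) <- c("acf_estimate", "data.frame")
  pos <- c(100, 140, 190)
  p <- c(0.02, 0.3, 0.11)
  out <- slk_correct(p, rep("chr1", 3), pos, acf0, window = 100)
  z <- qnorm(1 - p)
  # middle CpG sees both neighbours
  expect_equal(out[2], 1 - pnorm(sum(z) / sqrt(3)), tolerance = 1e-12)
})

test_that("region growing respects the seed threshold and gap rule", {
  pos <- c(seq(1000, by = 50, length.out = 5), 2300, 3500, 3600)
  p <- c(rep(0.001, 5), 0.9, 0.01, 0.01)
  r <- find_regions(p, rep("chr1", 8), pos, seed_p = 0.05, max_gap = 300)
  expect_equal(nrow(r), 2)
  expect_equal(r$n_cpgs, c(5, 2))
  expect_equal(r$start, c(1000, 3500))
  # all-dull track: nothing
  expect_equal(nrow(find_regions(rep(0.5, 8), rep("chr1", 8), pos)), 0)
  # two clusters split by a 1 kb gap under max_gap 300
  pos2 <- c(1000, 1100, 2100, 2200)
  r2 <- find_regions(rep(0.01, 4), rep("chr1", 4), pos2, 0.05, 300)
  expect_equal(nrow(r2), 2)
})

test_that("region scoring matches the closed form and Sidak dominates slk", {
  acf0 <- data.frame(lo = 0, hi = 50, cor = 0, n = 100L)
  sc <- score_region(c(0.01, 0.01), c(100, 160), acf0, total_bases = 10000)
  zc <- 2 * qnorm(0.99) / sqrt(2)
  expect_equal(sc$slk_p, 1 - pnorm(zc), tolerance = 1e-12)
  expect_equal(sc$slk_p, 5.0e-4, tolerance = 0.01)
  expect_gte(sc$sidak_p, sc$slk_p)
  expect_error(score_region(0.01, 100, acf0, 1000), "at least 2")
})

test_that("decreasing a member p never increases the slk region p", {
  acf0 <- data.frame(lo = 0, hi = 50, cor = 0.2, n = 100L)
  base <- score_region(c(0.05, 0.2, 0.4), c(100, 140, 180), acf0, 1e4)$slk_p
  better <- score_region(c(0.01, 0.2, 0.4), c(100, 140, 180), acf0, 1e4)$slk_p
  expect_lt(better, base)
})

test_that("region direction follows the 80% member-sign rule", {
  expect_equal(region_direction(c(-1, -2, -0.5)), "negative")
  expect_equal(region_direction(c(1, 2, 0.5, 3, 4)), "positive")
  expect_equal(region_direction(c(1, 1, 1, -1, -1)), "uncertain")
})

test_that("a planted co-methylated causal cluster is called as one region", {
  sim <- simulate_cohort(sim_config(
    n_pairs = 61, n_cpgs = 120, n_causal = 10, n_reverse_causal = 0,
    n_confounded = 0, effect_m_to_alt = 1, cluster_causal = TRUE,
    n_cell_types = 0, missing_rate = 0, seed = 85))
  rec <- run_ewas(sim$matrix, sim$cohort, NULL, ewas_config(covariates = NULL))
  dmrs <- call_dmrs(rec)
  expect_gt(nrow(dmrs), 0)
  planted <- planted_key(sim, "causal")
  overlap <- max(vapply(dmrs$members[dmrs$significant],
                        function(m) mean(planted %in% m), 1))
  expect_gte(overlap, 0.8)
})
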