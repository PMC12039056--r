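test_that("matching takes up to 3 in-caliper controls per case, greedily", {
  v <- simulate_validation_cohort(n = 500, seed = 31)
  m <- propensity_match(v$samples, ratio = 3, caliper = 0.1, seed = 1)
  sizes <- table(m$strata$stratum)
  expect_true(all(sizes >= 2 & sizes <= 4))
  # controls used at most once
  ctrl <- m$strata$sample_id[m$strata$case == 0]
  expect_false(anyDuplicated(ctrl) > 0)
  # caliper honoured within every stratum
  by_str <- split(m$strata, m$strata$stratum)
  ok <- vapply(by_str, function(s)
    all(abs(s$ps[s$case == 0] - s$ps[s$case == 1]) <= 0.1), TRUE)
  expect_true(all(ok))
  # same seed, same strata
  m2 <- propensity_match(v$samples, ratio = 3, caliper = 0.1, seed = 1)
  expect_identical(m$strata, m2$strata)
})

test_that("identical covariates let every case take a full control triple", {
  n_cases <- 54; n_ctrl <- 400
  samples <- data.frame(
    sample_id = sprintf("v%03d", 1:(n_cases + n_ctrl)),
    age = 50, sex = "woman",
    case = rep(c(1L, 0L), c(n_cases, n_ctrl)))
  m <- propensity_match(samples, ratio = 3, caliper = 0.1, seed = 2)
  expect_equal(sum(m$strata$case == 1), 54)
  expect_equal(sum(m$strata$case == 0), 162)
  expect_length(m$unmatched_cases, 0)
})

test_that("an out-of-caliper control is never matched", {
  samples <- data.frame(
    sample_id = c("case1", "ctrlA", "ctrlB", "ctrlC", "farctrl"),
    age = c(50, 50, 50, 50, 95),
    sex = "woman",
    case = c(1L, 0L, 0L, 0L, 0L))
  # age 95 control sits far in propensity space once age matters
  samples2 <- rbind(samples,
                    data.frame(sample_id = sprintf("x%02d", 1:20),
                               age = seq(40, 92, length.out = 20),
                               sex = "woman",
                               case = rep(c(1L, 0L), 10)))
  m <- propensity_match(samples2, ratio = 3, caliper = 0.05, seed = 3)
  strat_of_case1 <- m$strata$stratum[m$strata$sample_id == "case1"]
  mates <- m$strata$sample_id[m$strata$stratum == strat_of_case1]
  expect_false("farctrl" %in% mates)
})

test_that("conditional logistic equals the McNemar ratio on 1:1 binary data", {
  set.seed(35)
  n <- 40
  exp_case <- rbinom(n, 1, 0.6); exp_ctrl <- rbinom(n, 1, 0.3)
  mc <- toy_matched(exp_case, exp_ctrl)
  meth <- stats::setNames(as.numeric(rbind(exp_case, exp_ctrl)),
                          mc$strata$sample_id)
  r <- conditional_logistic(mc, meth)
  n10 <- sum(exp_case == 1 & exp_ctrl == 0)
  n01 <- sum(exp_case == 0 & exp_ctrl == 1)
  expect_equal(r$or, n10 / n01, tolerance = 1e-6)
  expect_false(r$flagged)
})

test_that("odds ratios are invariant to a stratum-constant covariate", {
  set.seed(36)
  n <- 60
  mc <- toy_matched(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
  meth <- stats::setNames(rnorm(2 * n), mc$strata$sample_id)
  r1 <- conditional_logistic(mc, meth)
  covs <- data.frame(sample_id = mc$strata$sample_id,
                     shared = rep(rnorm(n), each = 2))
  r2 <- conditional_logistic(mc, meth, covs)
  expect_equal(r2$or, r1$or, tolerance = 1e-6)
})

test_that("degenerate methylation and separation are flagged, not estimated", {
  n <- 30
  mc <- toy_matched(rep(1, n), rep(1, n))
  meth <- stats::setNames(rep(0.4, 2 * n), mc$strata$sample_id)
  r <- conditional_logistic(mc, meth)
  expect_true(r$flagged)
  # perfect separation: exposure identical to case status
  sep <- stats::setNames(rep(c(1, 0), n), mc$strata$sample_id)
  r2 <- conditional_logistic(mc, sep)
  expect_true(r2$flagged)
})

test_that("planted hypomethylation in cases yields OR < 1 with small p", {
  hits <- vapply(1:20, function(r) {
    v <- simulate_validation_cohort(n = 450, effect = -0.5, seed = 600 + r)
    res <- run_validation(v$samples, v$meth[, 1, drop = FALSE], seed = r)
    rec <- res$records
    isTRUE(!rec$flagged && rec$or < 1 && rec$p < 0.05)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("grouped methylation averages adjacent CpGs per sample", {
  m <- matrix(1:12, 3, 4, dimnames = list(c("a", "b", "c"),
                                          sprintf("cpg%d", 1:4)))
  g <- group_methylation(m, list(g1 = c("cpg1", "cpg2"), g2 = "cpg4"))
  expect_equal(g[, "g1"], rowMeans(m[, 1:2]))
  expect_equal(g[, "g2"], m[, 4])
})
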