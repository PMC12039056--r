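make_de <- function(seed = 71, n_pairs = 61, role = "causal", effect = 9.2,
                    covariates = NULL) {
  sim <- quick_sim(seed, n_pairs = n_pairs, n_cpgs = 10, role = role,
                   effect = effect)
  g <- which(sim$truth$role == role)
  m <- stats::setNames(m_values(sim$matrix)[g, ], sim$matrix$samples)
  alt <- stats::setNames(sim$cohort$alt, sim$cohort$sample_id)
  list(sim = sim, tab = double_enter(sim$cohort, m, alt, covariates))
}

test_that("double entry produces two role-swapped rows per complete pair", {
  d <- make_de(71)
  expect_equal(nrow(d$tab), 122)
  # role-swap symmetry: each pair's two rows mirror each other
  by_pair <- split(d$tab, d$tab$pair_id)
  ok <- vapply(by_pair, function(p)
    p$predictor_self[1] == p$predictor_cotwin[2] &&
      p$predictor_self[2] == p$predictor_cotwin[1], TRUE)
  expect_true(all(ok))
  # idempotent
  sim <- d$sim
  g <- which(sim$truth$role == "causal")
  m <- stats::setNames(m_values(sim$matrix)[g, ], sim$matrix$samples)
  alt <- stats::setNames(sim$cohort$alt, sim$cohort$sample_id)
  expect_identical(double_enter(sim$cohort, m, alt), d$tab)
})

test_that("a pair with a missing value is dropped entirely", {
  d <- make_de(72, n_pairs = 10)
  sim <- d$sim
  g <- which(sim$truth$role == "causal")
  m <- stats::setNames(m_values(sim$matrix)[g, ], sim$matrix$samples)
  m[1] <- NA
  alt <- stats::setNames(sim$cohort$alt, sim$cohort$sample_id)
  expect_message(tab <- double_enter(sim$cohort, m, alt), "dropped")
  expect_equal(nrow(tab), 18)
  expect_false(sim$cohort$pair_id[1] %in% tab$pair_id)
})

test_that("relabeling twins within pairs leaves the coefficients unchanged", {
  d <- make_de(73)
  f1 <- fit_models(d$tab)
  swapped <- do.call(rbind, lapply(split(d$tab, d$tab$pair_id),
                                   function(p) p[2:1, ]))
  f2 <- fit_models(swapped)
  expect_equal(f2$beta_self, f1$beta_self, tolerance = 1e-10)
  expect_equal(f2$beta_cotwin, f1$beta_cotwin, tolerance = 1e-10)
  expect_equal(f2$beta_cotwin_cond, f1$beta_cotwin_cond, tolerance = 1e-10)
})

test_that("a purely pair-shared predictor is rejected as degenerate", {
  d <- make_de(74, n_pairs = 10)
  shared <- rep(rnorm(10), each = 2)
  d$tab$predictor_self <- shared
  d$tab$predictor_cotwin <- shared
  expect_error(fit_models(d$tab), "degenerate within-pair")
})

test_that("AVR reproduces the worked coefficient-change examples", {
  expect_equal(round(avr(0.809, 2.642), 3), 3.266)
  expect_equal(round(avr(0.550, 1.628), 3), 2.960)
  expect_equal(avr(-1.7, -1.7), 1)
  expect_true(is.na(avr(0, 2)))
})

test_that("the verdict follows the AVR rule with its guards", {
  # AVR 3.266 with clean attenuation: causal
  v1 <- classify(beta_self = 2, beta_cotwin = 2.642, beta_self_cond = 1.191,
                 beta_cotwin_cond = 0, p_cotwin_change = 0.002,
                 p_self_change = 0.5)
  expect_equal(round(v1$avr, 3), 3.266)
  expect_equal(v1$verdict, "causal")
  # equal changes: familial confounding
  v2 <- classify(2, 2, 1, 1)
  expect_equal(v2$avr, 1)
  expect_equal(v2$verdict, "familial_confounding")
  # zero self change: inconclusive
  v3 <- classify(2, 2, 2, 1)
  expect_equal(v3$verdict, "inconclusive")
  # non-significant co-twin change blocks the causal call
  v4 <- classify(2, 2.642, 1.191, 0, p_cotwin_change = 0.3)
  expect_equal(v4$verdict, "familial_confounding")
  # a significantly changing self coefficient blocks it too
  v5 <- classify(2, 2.642, 1.191, 0, p_cotwin_change = 0.002,
                 p_self_change = 0.001)
  expect_equal(v5$verdict, "familial_confounding")
})

test_that("rescaling the predictor rescales coefficients and leaves AVR fixed", {
  d <- make_de(75)
  f1 <- fit_models(d$tab)
  tab2 <- d$tab
  tab2$predictor_self <- tab2$predictor_self * 10
  tab2$predictor_cotwin <- tab2$predictor_cotwin * 10
  f2 <- fit_models(tab2)
  expect_equal(f2$beta_self, f1$beta_self / 10, tolerance = 1e-9)
  expect_equal(f2$beta_cotwin_cond, f1$beta_cotwin_cond / 10, tolerance = 1e-9)
  a1 <- avr(f1$beta_self - f1$beta_self_cond,
            f1$beta_cotwin - f1$beta_cotwin_cond)
  a2 <- avr(f2$beta_self - f2$beta_self_cond,
            f2$beta_cotwin - f2$beta_cotwin_cond)
  expect_equal(a2, a1, tolerance = 1e-9)
})

test_that("bootstrap change p-values are seeded and stable in B", {
  d <- make_de(76, n_pairs = 30)
  p1 <- bootstrap_change_p(d$tab, n_boot = 200, seed = 5)
  p2 <- bootstrap_change_p(d$tab, n_boot = 200, seed = 5)
  expect_identical(p1$p_self_change, p2$p_self_change)
  expect_identical(p1$p_cotwin_change, p2$p_cotwin_change)
  p3 <- bootstrap_change_p(d$tab, n_boot = 400, seed = 9)
  expect_lt(abs(p1$p_cotwin_change - p3$p_cotwin_change), 0.1)
  expect_error(bootstrap_change_p(d$tab, n_boot = 50), "100")
})

test_that("both directions are reported per CpG and empty subsets pass through", {
  sim <- quick_sim(77, n_pairs = 20, n_cpgs = 6, role = "causal")
  keys <- rownames(sim$matrix$beta)[1:3]
  rec <- run_both_directions(sim$cohort, sim$matrix, keys, n_boot = 0)
  expect_equal(nrow(rec), 6)
  expect_equal(sort(unique(rec$direction)), c("alt_to_m", "m_to_alt"))
  expect_equal(nrow(run_both_directions(sim$cohort, sim$matrix,
                                        character(0))), 0)
})

test_that("the reverse-causal direction is detected as causal", {
  hits <- vapply(1:30, function(r) {
    sim <- quick_sim(7700 + r, n_pairs = 61, n_cpgs = 10,
                     role = "reverse_causal")
    rec <- run_both_directions(sim$cohort, sim$matrix,
                               planted_key(sim, "reverse_causal"),
                               n_boot = 0, seed = r)
    rec$verdict[rec$direction == "alt_to_m"] == "causal"
  }, TRUE)
  expect_gte(mean(hits), 0.7)
})
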