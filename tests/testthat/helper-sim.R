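# shared simulation shortcuts for the test suite

quick_sim <- function(seed, n_pairs = 61, n_cpgs = 20, role = "null",
                      effect = 5, n_cell_types = 0, missing_rate = 0, ...) {
  cfg <- sim_config(
    n_pairs = n_pairs, n_cpgs = n_cpgs,
    n_causal = as.integer(role == "causal"),
    n_reverse_causal = as.integer(role == "reverse_causal"),
    n_confounded = as.integer(role == "confounded"),
    effect_m_to_alt = effect,
    n_cell_types = n_cell_types, missing_rate = missing_rate,
    seed = seed, ...)
  simulate_cohort(cfg)
}

planted_key <- function(sim, role) {
  i <- which(sim$truth$role == role)
  paste(sim$truth$chrom[i], sim$truth$pos[i], sep = ":")
}

# verdict of the methylation-to-ALT direction for the planted CpG
m_to_alt_verdict <- function(sim, role, seed = 1) {
  rec <- run_both_directions(sim$cohort, sim$matrix, planted_key(sim, role),
                             n_boot = 0, seed = seed)
  rec$verdict[rec$direction == "m_to_alt"]
}

# a hand-built 1:1 matched cohort for conditional-logistic oracles
toy_matched <- function(case_exposure, control_exposure) {
  n <- length(case_exposure)
  ids <- sprintf("s%03d", seq_len(2 * n))
  structure(list(
    strata = data.frame(sample_id = ids, stratum = rep(seq_len(n), each = 2),
                        case = rep(c(1L, 0L), n), ps = 0.5),
    unmatched_cases = character(0),
    ps = stats::setNames(rep(0.5, 2 * n), ids),
    ratio = 1, caliper = 0.1), class = "matched_cohort")
}
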