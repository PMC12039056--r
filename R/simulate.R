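#' Simulation configuration for synthetic MZ twin cohorts
#'
#' Bundles and validates the parameters of the generative model. Defaults
#' emulate the study conditions: 61 monozygotic pairs, RRBS-like CpG-island
#' layout, half of the methylation variance pair-shared
#' (`familial_var_share = 0.5`), within-pair residual correlation
#' `rho_eps = 0.1`, phenotype heritability `h2 = 0.6`, and
#' methylation-environment coupling `r2_me = 0.1`.
#'
#' @param n_pairs number of MZ twin pairs (>= 2).
#' @param n_cpgs number of CpGs.
#' @param n_causal number of planted causal CpGs (methylation -> ALT).
#' @param n_reverse_causal number of planted reverse-causal CpGs (ALT ->
#'   methylation).
#' @param n_confounded number of CpGs associated with ALT purely through a
#'   pair-shared confounder.
#' @param effect_m_to_alt causal effect, ALT U/L per unit M-value.
#' @param effect_alt_to_m reverse-causal effect, M-value units per ALT U/L.
#' @param familial_var_share share of per-CpG M variance carried by the
#'   pair-shared component, in `[0, 1]`.
#' @param rho_eps within-pair correlation of the individual M residual.
#' @param h2 pair-shared (heritable) share of log-ALT baseline variance.
#' @param r2_me squared correlation between the causal CpG's individual
#'   environmental residual and the phenotype's environmental residual.
#' @param n_cell_types number of latent cell types (0 disables the
#'   cell-composition signal).
#' @param missing_rate probability an entry is masked (RRBS dropout), `< 1`.
#' @param seed integer seed; identical seed + config gives byte-identical
#'   output.
#' @param m_sd total per-CpG M-value standard deviation around its baseline.
#' @param cluster_causal place the causal CpGs contiguously (one island) with
#'   co-methylation `rho_cluster` — the planted DMR scenario.
#' @param rho_cluster within-cluster co-methylation of clustered causal CpGs.
#' @param cell_frac fraction of CpGs carrying cell-composition signal.
#' @param cell_sd M-value scale of the cell-composition signal.
#' @param confound_effect ALT U/L per unit of the shared confounder latent;
#'   `NULL` (default) matches the confounded CpGs' marginal M-ALT
#'   covariance to the causal CpGs' (`effect_m_to_alt * m_sd /
#'   sqrt(familial_var_share)`), so the two planted classes present equally
#'   strong marginal associations.
#' @param island_size,island_spacing,island_gap CpG track layout: CpGs per
#'   island, intra-island spacing (bp) and gap between islands (bp).
#' @param log_alt_mu,log_alt_sd location/scale of baseline log-ALT.
#' @param min_delta_alt required within-pair ALT discordance (U/L); pairs
#'   below it have their phenotype residuals redrawn (the study's inclusion
#'   rule).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 61, n_cpgs = 5000,
                       n_causal = 10, n_reverse_causal = 5, n_confounded = 5,
                       effect_m_to_alt = 5, effect_alt_to_m = 0.02,
                       familial_var_share = 0.5, rho_eps = 0.1,
                       h2 = 0.6, r2_me = 0.1,
                       n_cell_types = 3, missing_rate = 0.03, seed = 1,
                       m_sd = 0.5, cluster_causal = FALSE, rho_cluster = 0.7,
                       cell_frac = 0.2, cell_sd = 1, confound_effect = NULL,
                       island_size = 10, island_spacing = 50,
                       island_gap = 10000,
                       log_alt_mu = log(17), log_alt_sd = 0.55,
                       min_delta_alt = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$confound_effect))
    cfg$confound_effect <- if (familial_var_share > 0)
      abs(effect_m_to_alt) * m_sd / sqrt(familial_var_share) else 0
  shares <- c(familial_var_share = familial_var_share, rho_eps = rho_eps,
              h2 = h2, r2_me = r2_me, rho_cluster = rho_cluster)
  if (any(shares < 0 | shares > 1))
    stop("variance shares / correlations must lie in [0, 1]")
  if (n_pairs < 2) stop("n_pairs must be >= 2")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (n_causal + n_reverse_causal + n_confounded > n_cpgs)
    stop("planted CpGs exceed n_cpgs")
  if (m_sd <= 0) stop("m_sd must be positive")
  structure(cfg, class = "sim_config")
}

# pair-correlated standard-normal pairs: cor(x1, x2) = rho
pair_corr_normal <- function(n_pairs, rho) {
  z <- rnorm(n_pairs)
  w <- matrix(rnorm(2 * n_pairs), n_pairs, 2)
  sqrt(rho) * z + sqrt(1 - rho) * w
}

sim_layout <- function(n_cpgs, island_size, island_spacing, island_gap) {
  n_islands <- ceiling(n_cpgs / island_size)
  # ~8 islands per chromosome so each chromosome's tested span includes the
  # inter-island gaps, as in a real RRBS track
  n_chrom <- min(22L, max(1L, ceiling(n_islands / 8)))
  chroms <- paste0("chr", seq_len(n_chrom))
  isl_chrom <- chroms[((seq_len(n_islands) - 1) %% n_chrom) + 1]
  chrom <- character(n_cpgs); pos <- integer(n_cpgs)
  idx <- 1L
  isl_count <- setNames(integer(22), chroms)
  for (i in seq_len(n_islands)) {
    k <- min(island_size, n_cpgs - (i - 1L) * island_size)
    ch <- isl_chrom[i]
    start <- 1000000L + isl_count[ch] *
      as.integer(island_size * island_spacing + island_gap)
    isl_count[ch] <- isl_count[ch] + 1L
    chrom[idx:(idx + k - 1L)] <- ch
    pos[idx:(idx + k - 1L)] <- as.integer(start + (0:(k - 1L)) * island_spacing)
    idx <- idx + k
  }
  data.frame(chrom = chrom, pos = pos, island = rep(seq_len(n_islands),
             each = island_size)[seq_len(n_cpgs)], stringsAsFactors = FALSE)
}

#' Simulate a discordant MZ twin cohort with planted causal structure
#'
#' Generates per-CpG M-values as baseline + pair-shared familial component +
#' (optional cell-composition term) + within-pair-correlated individual
#' residual; serum ALT as an exponentiated log-normal baseline with a
#' pair-shared heritable component, covariate contributions, the planted
#' causal methylation effects, and the shared-confounder contribution.
#' Reverse-causal CpGs receive `effect_alt_to_m * (ALT - mean(ALT))` after
#' the phenotype is drawn. Beta-values are obtained by the inverse-logistic
#' transform and clipped to `[0.001, 0.999]`.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (sample sheet data.frame), `matrix`
#'   (a [meth_matrix()]), `truth` (data.frame: chrom, pos, role in
#'   causal/reverse_causal/confounded/null, effect, cell_signal flag),
#'   `config`, and `cell_props` (samples x cell types, or NULL).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  np <- cfg$n_pairs; ns <- 2L * np; ng <- cfg$n_cpgs

  ## --- covariates (sub-stream seed + 1) ------------------------------------
  set.seed(cfg$seed + 1L)
  pair_id <- sprintf("pair%03d", seq_len(np))
  sample_id <- paste0(rep(pair_id, each = 2), c("_a", "_b"))
  age <- rep(runif(np, 40, 60), each = 2)
  sex <- rep(ifelse(runif(np) < 0.5, "woman", "man"), each = 2)
  xb <- as.vector(t(pair_corr_normal(np, 0.3)))
  bmi <- 25 + 3 * xb
  xa <- as.vector(t(pair_corr_normal(np, 0.3)))
  alcohol <- pmax(0, 8 * (xa - 0.5))
  xh <- as.vector(t(pair_corr_normal(np, 0.3)))
  hypertension <- as.integer(xh > qnorm(1 - 0.55))
  xd <- as.vector(t(pair_corr_normal(np, 0.3)))
  diabetes <- as.integer(xd > qnorm(1 - 0.10))

  ## --- CpG track and planted roles (sub-stream seed + 2) -------------------
  set.seed(cfg$seed + 2L)
  layout <- sim_layout(ng, cfg$island_size, cfg$island_spacing, cfg$island_gap)
  o <- cpg_order(layout$chrom, layout$pos)
  layout <- layout[o, ]
  role <- rep("null", ng)
  n_planted <- cfg$n_causal + cfg$n_reverse_causal + cfg$n_confounded
  if (cfg$cluster_causal && cfg$n_causal > 0) {
    causal_idx <- which(layout$chrom == layout$chrom[1])[seq_len(cfg$n_causal)]
    rest <- setdiff(seq_len(ng), causal_idx)
    others <- if (n_planted - cfg$n_causal > 0)
      sample(rest, n_planted - cfg$n_causal) else integer(0)
  } else {
    planted <- if (n_planted > 0) sample(seq_len(ng), n_planted) else integer(0)
    causal_idx <- planted[seq_len(cfg$n_causal)]
    others <- setdiff(planted, causal_idx)
  }
  rev_idx <- others[seq_len(cfg$n_reverse_causal)]
  conf_idx <- setdiff(others, rev_idx)
  role[causal_idx] <- "causal"
  role[rev_idx] <- "reverse_causal"
  role[conf_idx] <- "confounded"
  n_cell_cpg <- round(cfg$cell_frac * ng)
  cell_idx <- if (cfg$n_cell_types > 0 && n_cell_cpg > 0) {
    pool <- which(role == "null")
    sample(pool, min(n_cell_cpg, length(pool)))
  } else integer(0)

  ## baseline methylation level per CpG: bimodal, mid-range minority
  comp <- sample(1:3, ng, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  mu_beta <- pmin(0.98, pmax(0.02, ifelse(comp == 1, rbeta(ng, 8, 2),
                              ifelse(comp == 2, rbeta(ng, 2, 8),
                                     rbeta(ng, 2, 2)))))
  mu_m <- beta_to_m(mu_beta)

  ## --- methylation (sub-stream seed + 3) -----------------------------------
  set.seed(cfg$seed + 3L)
  fvs <- cfg$familial_var_share
  a_sd <- sqrt(fvs) * cfg$m_sd
  e_sd <- sqrt(1 - fvs) * cfg$m_sd
  C_conf <- rnorm(np)                       # shared confounder latent, per pair
  R_pair <- rnorm(np)                       # regional latent for clustered causal
  R_ind <- as.vector(t(pair_corr_normal(np, cfg$rho_eps)))
  M <- matrix(0, ng, ns)
  e_causal <- matrix(0, 0, ns)   # individual residuals at causal CpGs
  if (cfg$n_causal > 0) e_causal <- matrix(0, cfg$n_causal, ns)
  # cell-type proportions per sample (Dirichlet via gamma)
  if (cfg$n_cell_types > 0) {
    gam <- matrix(stats::rgamma(ns * cfg$n_cell_types, shape = 4), ns)
    props <- gam / rowSums(gam)
  } else props <- NULL
  for (g in seq_len(ng)) {
    Cg <- if (role[g] == "confounded") C_conf else rnorm(np)
    eg <- as.vector(t(pair_corr_normal(np, cfg$rho_eps)))
    if (cfg$cluster_causal && role[g] == "causal") {
      Cg <- sqrt(cfg$rho_cluster) * R_pair + sqrt(1 - cfg$rho_cluster) * Cg
      eg <- sqrt(cfg$rho_cluster) * R_ind + sqrt(1 - cfg$rho_cluster) * eg
    }
    if (role[g] == "causal") e_causal[match(g, causal_idx), ] <- eg
    M[g, ] <- mu_m[g] + a_sd * rep(Cg, each = 2) + e_sd * eg
  }
  if (length(cell_idx)) {
    delta <- matrix(rnorm(length(cell_idx) * cfg$n_cell_types),
                    length(cell_idx))
    centered <- props - 1 / cfg$n_cell_types
    M[cell_idx, ] <- M[cell_idx, ] +
      cfg$cell_sd * delta %*% t(centered) * sqrt(cfg$n_cell_types)
  }

  ## --- phenotype (sub-stream seed + 4) -------------------------------------
  set.seed(cfg$seed + 4L)
  A <- rnorm(np)                             # heritable pair-shared component
  w <- rnorm(ns)                             # individual environmental residual
  # couple the phenotype's environmental residual to the causal CpGs'
  # individual environmental deviations (the methylation-environment R^2)
  if (cfg$n_causal > 0 && cfg$r2_me > 0) {
    ubar <- colMeans(e_causal)
    ubar <- (ubar - mean(ubar)) / max(sd(ubar), 1e-12)
    mix_eps <- function(w_vec) sqrt(cfg$r2_me) * ubar +
      sqrt(1 - cfg$r2_me) * w_vec
  } else mix_eps <- identity
  eps <- mix_eps(w)
  cov_term <- 0.15 * (age - 50) + 4 * (sex == "man") + 0.4 * (bmi - 25) +
    0.05 * alcohol + 2 * hypertension + 3 * diabetes
  causal_term <- if (cfg$n_causal > 0)
    cfg$effect_m_to_alt *
      colSums(M[causal_idx, , drop = FALSE] - mu_m[causal_idx]) else 0
  conf_term <- if (cfg$n_confounded > 0)
    cfg$confound_effect * rep(C_conf, each = 2) else 0
  make_alt <- function(eps_vec) {
    base <- exp(cfg$log_alt_mu + cfg$log_alt_sd *
                  (sqrt(cfg$h2) * rep(A, each = 2) + sqrt(1 - cfg$h2) * eps_vec))
    pmax(0.5, base + cov_term + causal_term + conf_term)
  }
  alt <- make_alt(eps)
  # enforce within-pair discordance >= min_delta_alt by redrawing the
  # individual phenotype residual of non-discordant pairs
  for (iter in 1:100) {
    d_alt <- abs(alt[seq(1, ns, 2)] - alt[seq(2, ns, 2)])
    bad <- which(d_alt < cfg$min_delta_alt)
    if (!length(bad)) break
    rows <- as.vector(rbind(2 * bad - 1, 2 * bad))
    w[rows] <- rnorm(length(rows))
    eps <- mix_eps(w)
    alt <- make_alt(eps)
  }

  ## reverse causality: ALT feeds back into methylation at planted CpGs
  if (cfg$n_reverse_causal > 0) {
    shift <- cfg$effect_alt_to_m * (alt - mean(alt))
    M[rev_idx, ] <- M[rev_idx, ] + rep(shift, each = length(rev_idx))
  }

  beta <- m_to_beta(M)
  beta <- pmin(pmax(beta, 0.001), 0.999)
  colnames(beta) <- sample_id
  mat <- meth_matrix(beta, layout$chrom, layout$pos)

  cohort <- data.frame(sample_id = sample_id, pair_id = rep(pair_id, each = 2),
                       alt = alt, age = age, sex = sex, bmi = bmi,
                       alcohol = alcohol, hypertension = hypertension,
                       diabetes = diabetes, stringsAsFactors = FALSE)
  effect <- numeric(ng)
  effect[causal_idx] <- cfg$effect_m_to_alt
  effect[rev_idx] <- cfg$effect_alt_to_m
  effect[conf_idx] <- cfg$confound_effect
  truth <- data.frame(chrom = layout$chrom, pos = layout$pos, role = role,
                      effect = effect,
                      cell_signal = as.integer(seq_len(ng) %in% cell_idx),
                      stringsAsFactors = FALSE)
  # align truth rows to the sorted matrix order
  key_m <- rownames(mat$beta)
  key_t <- paste(truth$chrom, truth$pos, sep = ":")
  truth <- truth[match(key_m, key_t), ]
  rownames(truth) <- NULL
  if (cfg$missing_rate > 0)
    mat <- apply_missingness(mat, cfg$missing_rate, cfg$seed + 5L)
  if (!is.null(props)) rownames(props) <- sample_id
  list(cohort = cohort, matrix = mat, truth = truth, config = cfg,
       cell_props = props)
}

#' Mask methylation entries at random (RRBS-like coverage dropout)
#'
#' @param matrix a [meth_matrix()].
#' @param rate per-entry masking probability, in `[0, 1)`.
#' @param seed integer seed.
#' @return the matrix with masked entries set to `NA`.
#' @export
apply_missingness <- function(matrix, rate, seed) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(matrix)
  set.seed(seed)
  b <- matrix$beta
  mask <- stats::runif(length(b)) < rate
  b[mask] <- NA_real_
  meth_matrix(b, matrix$cpgs$chrom, matrix$cpgs$pos)
}

#' Write a simulated cohort to disk as plain-text fixtures
#'
#' Emits `samples.tsv`, `beta.tsv`, `cpgs.bed` (0-based half-open) and
#' `truth.tsv` into `dir`; the files round-trip losslessly through
#' [read_fixture()].
#'
#' @param cohort,matrix,truth as returned by [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory path.
#' @export
write_fixture <- function(cohort, matrix, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sample_sheet(cohort, file.path(dir, "samples.tsv"))
  write_beta_matrix(matrix, file.path(dir, "beta.tsv"))
  write_cpg_bed(matrix, file.path(dir, "cpgs.bed"))
  write_truth(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  list(cohort = read_sample_sheet(file.path(dir, "samples.tsv")),
       matrix = read_beta_matrix(file.path(dir, "beta.tsv")),
       truth = read_truth(file.path(dir, "truth.tsv")))
}

#' Simulate a gene/TSS annotation matched to a CpG track
#'
#' Places one gene per CpG island (TSS near the island start, random strand)
#' so nearest-gene annotation and enrichment are exercisable on synthetic
#' data.
#'
#' @param matrix a [meth_matrix()].
#' @param seed integer seed.
#' @param gene_length gene body length in bp.
#' @return `GRanges` with metadata column `name`.
#' @export
simulate_genes <- function(matrix, seed = 1, gene_length = 2000) {
  set.seed(seed)
  cp <- matrix$cpgs
  # one gene per island: cluster CpGs by gaps > 2 kb
  genes <- do.call(rbind, lapply(split(cp, cp$chrom), function(d) {
    d <- d[order(d$pos), ]
    brk <- cumsum(c(1, diff(d$pos) > 2000))
    starts <- tapply(d$pos, brk, min)
    data.frame(chrom = d$chrom[1], tss = as.integer(starts),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[cpg_order(genes$chrom, genes$tss), ]
  n <- nrow(genes)
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  offset <- sample(-500:500, n, replace = TRUE)
  tss <- pmax(1L, genes$tss + offset)
  start <- ifelse(strand == "+", tss, pmax(1L, tss - gene_length))
  end <- ifelse(strand == "+", tss + gene_length, tss)
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(start = start, end = end),
                               strand = strand)
  S4Vectors::mcols(gr)$name <- sprintf("GENE%04d", seq_len(n))
  gr
}

#' Simulate a term-to-gene table (GMT-like)
#'
#' @param genes character vector of gene symbols (or a GRanges with `name`).
#' @param n_terms number of terms.
#' @param seed integer seed.
#' @param size_range min/max genes per term.
#' @return named list of gene vectors.
#' @export
simulate_terms <- function(genes, n_terms = 20, seed = 1,
                           size_range = c(3, 15)) {
  if (inherits(genes, "GRanges")) genes <- S4Vectors::mcols(genes)$name
  set.seed(seed)
  terms <- lapply(seq_len(n_terms), function(i) {
    k <- sample(size_range[1]:min(size_range[2], length(genes)), 1)
    sample(genes, k)
  })
  setNames(terms, sprintf("TERM%03d", seq_len(n_terms)))
}

#' Simulate an unrelated validation cohort with abnormal-ALT cases
#'
#' Emulates the community-based replication sample: unrelated adults with
#' age, sex, BMI, alcohol, hypertension and diabetes; case status defined as
#' ALT > 40 U/L; quantified methylation at a small set of CpGs with a planted
#' case effect (negative = hypomethylation in cases).
#'
#' @param n total sample size.
#' @param n_cpgs number of quantified CpGs.
#' @param effect per-CpG M-value difference in cases (0 = null).
#' @param seed integer seed.
#' @param case_rate approximate fraction of abnormal-ALT individuals.
#' @return list with `samples` (data.frame incl. logical-int `case`) and
#'   `meth` (samples x CpGs M-value matrix).
#' @export
simulate_validation_cohort <- function(n = 600, n_cpgs = 4, effect = -0.5,
                                       seed = 1, case_rate = 0.12) {
  set.seed(seed)
  age <- runif(n, 40, 75)
  sex <- ifelse(runif(n) < 0.5, "woman", "man")
  bmi <- rnorm(n, 25, 3)
  alcohol <- pmax(0, 8 * (rnorm(n) - 0.5))
  hypertension <- rbinom(n, 1, plogis(-3 + 0.05 * age))
  diabetes <- rbinom(n, 1, 0.12)
  # ALT rises mildly with age/BMI so matching on age+sex is non-trivial
  lp <- log(16) + 0.008 * (age - 55) + 0.15 * (sex == "man") +
    0.02 * (bmi - 25)
  alt <- exp(lp + rnorm(n, 0, 0.62) + qnorm(case_rate * 2) * 0)
  case <- as.integer(alt > 40)
  meth <- matrix(rnorm(n * n_cpgs, 0, 0.5), n, n_cpgs,
                 dimnames = list(sprintf("V%04d", seq_len(n)),
                                 sprintf("cpg%02d", seq_len(n_cpgs))))
  meth <- meth + effect * case
  samples <- data.frame(sample_id = rownames(meth), age = age, sex = sex,
                        bmi = bmi, alcohol = alcohol,
                        hypertension = hypertension, diabetes = diabetes,
                        alt = alt, case = case, stringsAsFactors = FALSE)
  list(samples = samples, meth = meth)
}
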