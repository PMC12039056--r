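# ICE FALCON: Inference about Causation through Examination of FAmiliaL
# CONfounding. For each CpG (and each direction) three marginal regressions
# are fitted to double-entered twin data by GEE:
#   Model 1: outcome_self ~ predictor_self            -> beta_self
#   Model 2: outcome_self ~ predictor_cotwin          -> beta_cotwin
#   Model 3: outcome_self ~ predictor_self + cotwin   -> conditional betas
# The coefficient changes (marginal minus conditional) and their absolute
# ratio AVR = |cotwin change| / |self change| discriminate causation
# (AVR > 1.5: the co-twin coefficient attenuates once the self predictor is
# held fixed) from familial confounding (both change alike).

#' Build a double-entry twin table
#'
#' Two rows per complete pair: each twin appears once as "self" with the
#' co-twin's predictor alongside. Pairs with a missing predictor or outcome
#' in either twin are dropped entirely.
#'
#' @param cohort sample sheet with `sample_id`, `pair_id` and covariates.
#' @param predictor named numeric vector (names = sample ids).
#' @param outcome named numeric vector (names = sample ids).
#' @param covariates covariate column names to carry along (default none).
#' @return data.frame with columns outcome_self, predictor_self,
#'   predictor_cotwin, pair_id, sample_id and any covariates.
#' @export
double_enter <- function(cohort, predictor, outcome, covariates = NULL) {
  pred <- predictor[cohort$sample_id]
  out <- outcome[cohort$sample_id]
  covm <- if (length(covariates))
    build_covariate_matrix(cohort, covariates) else NULL
  ok <- !is.na(pred) & !is.na(out)
  if (!is.null(covm)) ok <- ok & complete.cases(covm)
  pair_ok <- tapply(ok, cohort$pair_id, function(z) length(z) == 2 && all(z))
  keep_pairs <- names(pair_ok)[pair_ok]
  n_drop <- sum(!pair_ok)
  if (n_drop > 0)
    message(n_drop, " incomplete pair(s) dropped from double entry")
  if (!length(keep_pairs)) stop("no complete pairs")
  rows <- lapply(keep_pairs, function(pp) {
    i <- which(cohort$pair_id == pp)
    d <- data.frame(outcome_self = out[i], predictor_self = pred[i],
                    predictor_cotwin = pred[rev(i)],
                    pair_id = pp, sample_id = cohort$sample_id[i],
                    stringsAsFactors = FALSE)
    if (!is.null(covm)) d <- cbind(d, covm[i, , drop = FALSE])
    d
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Fit ICE FALCON Models 1-3 by GEE
#'
#' @param table a double-entry table from [double_enter()].
#' @param corstr GEE working correlation (see [gee_gaussian()]).
#' @return list: beta_self, beta_cotwin, beta_self_cond, beta_cotwin_cond,
#'   their robust SEs, and the underlying GEE fits.
#' @export
fit_models <- function(table, corstr = "independence") {
  n_pairs <- length(unique(table$pair_id))
  if (n_pairs < 3) stop("need at least 3 complete pairs")
  if (sd(table$predictor_self - table$predictor_cotwin) < 1e-12)
    stop("degenerate within-pair variance: predictor is purely pair-shared")
  covcols <- setdiff(names(table), c("outcome_self", "predictor_self",
                                     "predictor_cotwin", "pair_id",
                                     "sample_id"))
  covm <- if (length(covcols)) as.matrix(table[, covcols, drop = FALSE]) else NULL
  y <- table$outcome_self
  base <- cbind(`(Intercept)` = rep(1, nrow(table)), covm)
  m1 <- gee_gaussian(y, cbind(base, self = table$predictor_self),
                     table$pair_id, corstr)
  m2 <- gee_gaussian(y, cbind(base, cotwin = table$predictor_cotwin),
                     table$pair_id, corstr)
  m3 <- gee_gaussian(y, cbind(base, self = table$predictor_self,
                              cotwin = table$predictor_cotwin),
                     table$pair_id, corstr)
  se_of <- function(fit, nm) sqrt(diag(fit$vcov))[match(nm, names(fit$coefficients))]
  # cluster-robust SEs for the coefficient CHANGES: the change is a
  # functional of two jointly-estimated GEE fits, so its variance comes from
  # the per-cluster influence contributions of both models
  chg_se <- function(fa, nma, fb, nmb) {
    d <- fa$influence[, nma] - fb$influence[, nmb]
    sqrt(sum(d^2))
  }
  se_self_change <- chg_se(m1, "self", m3, "self")
  se_cotwin_change <- chg_se(m2, "cotwin", m3, "cotwin")
  self_change <- m1$coefficients[["self"]] - m3$coefficients[["self"]]
  cotwin_change <- m2$coefficients[["cotwin"]] - m3$coefficients[["cotwin"]]
  list(beta_self = m1$coefficients[["self"]],
       beta_cotwin = m2$coefficients[["cotwin"]],
       beta_self_cond = m3$coefficients[["self"]],
       beta_cotwin_cond = m3$coefficients[["cotwin"]],
       se_self = se_of(m1, "self"), se_cotwin = se_of(m2, "cotwin"),
       se_self_cond = se_of(m3, "self"), se_cotwin_cond = se_of(m3, "cotwin"),
       se_self_change = se_self_change, se_cotwin_change = se_cotwin_change,
       p_self_change_wald = 2 * pnorm(-abs(self_change / se_self_change)),
       p_cotwin_change_wald = 2 * pnorm(-abs(cotwin_change / se_cotwin_change)),
       fits = list(m1 = m1, m2 = m2, m3 = m3))
}

#' Absolute value of the ratio of coefficient changes
#'
#' `AVR = |beta_cotwin_change| / |beta_self_change|`; undefined (NA) when the
#' self change is zero.
#'
#' @param beta_self_change marginal-minus-conditional change of the self
#'   coefficient.
#' @param beta_cotwin_change the co-twin analogue.
#' @return non-negative ratio, or `NA` for a zero denominator.
#' @export
avr <- function(beta_self_change, beta_cotwin_change) {
  if (is.na(beta_self_change) || abs(beta_self_change) < 1e-12)
    return(NA_real_)
  abs(beta_cotwin_change) / abs(beta_self_change)
}

#' Causal verdict from the coefficient changes
#'
#' `causal` when AVR exceeds `threshold` (default 1.5), the co-twin
#' coefficient attenuates towards zero (its change shares the sign of the
#' marginal co-twin coefficient), and — when a change p-value is supplied —
#' the co-twin change is distinguishable from noise at `p_change_alpha`
#' (without this guard the AVR, a ratio of two near-zero noisy changes,
#' fires on null CpGs far too often); `familial_confounding` when the
#' changes are of similar magnitude; `inconclusive` when AVR is undefined.
#'
#' @param beta_self,beta_cotwin marginal coefficients (Models 1-2).
#' @param beta_self_cond,beta_cotwin_cond conditional coefficients (Model 3).
#' @param threshold AVR cutoff for causation.
#' @param p_cotwin_change,p_self_change optional p-values of the changes
#'   (Wald or bootstrap); `NA` disables the corresponding guard. The causal
#'   pattern requires a significant co-twin change together with a self
#'   coefficient that does not change materially.
#' @param p_change_alpha significance level for the guards.
#' @return list: beta_self_change, beta_cotwin_change, avr, verdict.
#' @export
classify <- function(beta_self, beta_cotwin, beta_self_cond,
                     beta_cotwin_cond, threshold = 1.5,
                     p_cotwin_change = NA_real_, p_self_change = NA_real_,
                     p_change_alpha = 0.05) {
  self_change <- beta_self - beta_self_cond
  cotwin_change <- beta_cotwin - beta_cotwin_cond
  ratio <- avr(self_change, cotwin_change)
  verdict <- if (is.na(ratio)) "inconclusive"
  else if (ratio > threshold &&
           sign(cotwin_change) == sign(beta_cotwin) &&
           (is.na(p_cotwin_change) || p_cotwin_change < p_change_alpha) &&
           (is.na(p_self_change) || p_self_change >= p_change_alpha))
    "causal"
  else "familial_confounding"
  list(beta_self_change = self_change, beta_cotwin_change = cotwin_change,
       avr = ratio, verdict = verdict)
}

#' Bootstrap p-values for the coefficient changes
#'
#' Twin pairs are resampled with replacement; Models 1-3 are refitted per
#' resample and two-sided percentile p-values are computed for each change
#' against zero. Resamples with fewer than 3 distinct pairs are redrawn.
#'
#' @param table a double-entry table.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @return list: p_self_change, p_cotwin_change, boot (matrix of resampled
#'   changes).
#' @export
bootstrap_change_p <- function(table, n_boot = 1000, seed = 1) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  set.seed(seed)
  pairs <- unique(table$pair_id)
  rows_by_pair <- split(seq_len(nrow(table)), table$pair_id)
  boot <- matrix(NA_real_, n_boot, 2,
                 dimnames = list(NULL, c("self_change", "cotwin_change")))
  b <- 1L
  guard <- 0L
  while (b <= n_boot && guard < 20L * n_boot) {
    guard <- guard + 1L
    draw <- sample(pairs, length(pairs), replace = TRUE)
    if (length(unique(draw)) < 3) next
    idx <- unlist(rows_by_pair[draw], use.names = FALSE)
    tb <- table[idx, ]
    # resampled pairs must be distinct clusters
    tb$pair_id <- rep(seq_along(draw), times = lengths(rows_by_pair[draw]))
    fit <- tryCatch(fit_models(tb), error = function(e) NULL)
    if (is.null(fit)) next
    boot[b, ] <- c(fit$beta_self - fit$beta_self_cond,
                   fit$beta_cotwin - fit$beta_cotwin_cond)
    b <- b + 1L
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  pct_p <- function(x) {
    lo <- mean(x <= 0); hi <- mean(x >= 0)
    max(min(2 * min(lo, hi), 1), 1 / nrow(boot))
  }
  list(p_self_change = pct_p(boot[, 1]),
       p_cotwin_change = pct_p(boot[, 2]),
       boot = boot)
}

ice_one <- function(cohort, predictor, outcome, direction, covariates,
                    threshold, n_boot, seed) {
  tab <- double_enter(cohort, predictor, outcome, covariates)
  fit <- fit_models(tab)
  cls <- classify(fit$beta_self, fit$beta_cotwin, fit$beta_self_cond,
                  fit$beta_cotwin_cond, threshold,
                  p_cotwin_change = fit$p_cotwin_change_wald,
                  p_self_change = fit$p_self_change_wald)
  ps <- if (!is.null(n_boot) && n_boot > 0)
    bootstrap_change_p(tab, n_boot, seed) else
      list(p_self_change = fit$p_self_change_wald,
           p_cotwin_change = fit$p_cotwin_change_wald)
  data.frame(direction = direction,
             beta_self = fit$beta_self, beta_cotwin = fit$beta_cotwin,
             beta_self_cond = fit$beta_self_cond,
             beta_cotwin_cond = fit$beta_cotwin_cond,
             beta_self_change = cls$beta_self_change,
             beta_cotwin_change = cls$beta_cotwin_change,
             p_self_change = ps$p_self_change,
             p_cotwin_change = ps$p_cotwin_change,
             avr = cls$avr, verdict = cls$verdict,
             n_pairs = length(unique(tab$pair_id)),
             stringsAsFactors = FALSE)
}

#' Run ICE FALCON in both directions over a CpG subset
#'
#' For each CpG, the methylation-to-ALT direction (outcome ALT, predictor
#' M-value) and the reverse ALT-to-methylation direction are evaluated,
#' yielding two records per CpG.
#'
#' @param cohort sample sheet.
#' @param matrix a [meth_matrix()].
#' @param cpg_subset CpG keys (`"chrom:pos"`) or row indices — typically the
#'   EWAS-significant set.
#' @param covariates covariate columns included in all three models
#'   (defaults to the EWAS adjustment set; `NULL` for unadjusted).
#' @param threshold AVR cutoff.
#' @param n_boot bootstrap resamples for the change p-values (0 to skip).
#' @param seed integer seed.
#' @return data.frame of ICE FALCON records, two rows per CpG (failures are
#'   reported with `verdict = "error"` and the message in `reason`).
#' @export
run_both_directions <- function(cohort, matrix, cpg_subset,
                                covariates = c("age", "sex", "alcohol", "bmi",
                                               "hypertension", "diabetes"),
                                threshold = 1.5, n_boot = 0, seed = 1) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (!length(cpg_subset)) return(data.frame())
  keys <- rownames(matrix$beta)
  idx <- if (is.numeric(cpg_subset)) as.integer(cpg_subset)
         else match(cpg_subset, keys)
  if (anyNA(idx)) stop("cpg_subset entries not found in matrix")
  M <- m_values(matrix)
  alt <- setNames(cohort$alt, cohort$sample_id)
  out <- vector("list", 2L * length(idx))
  for (j in seq_along(idx)) {
    g <- idx[j]
    m <- setNames(M[g, ], matrix$samples)
    for (k in 1:2) {
      dirn <- c("m_to_alt", "alt_to_m")[k]
      rec <- tryCatch({
        if (dirn == "m_to_alt")
          ice_one(cohort, m, alt, dirn, covariates, threshold, n_boot,
                  seed + 2L * j + k)
        else
          ice_one(cohort, alt, m, dirn, covariates, threshold, n_boot,
                  seed + 2L * j + k)
      }, error = function(e) data.frame(
        direction = dirn, beta_self = NA, beta_cotwin = NA,
        beta_self_cond = NA, beta_cotwin_cond = NA, beta_self_change = NA,
        beta_cotwin_change = NA, p_self_change = NA, p_cotwin_change = NA,
        avr = NA, verdict = "error", n_pairs = NA,
        stringsAsFactors = FALSE))
      rec <- cbind(data.frame(chrom = matrix$cpgs$chrom[g],
                              pos = matrix$cpgs$pos[g],
                              stringsAsFactors = FALSE), rec)
      out[[2L * (j - 1L) + k]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write ICE FALCON records as TSV
#' @param records ICE FALCON records.
#' @param path output path.
#' @export
write_icefalcon <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
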