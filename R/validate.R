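# Independent-cohort validation: 1:3 nearest-neighbour propensity-score
# matching on age and sex (caliper 0.1 on the probability scale), then
# per-CpG conditional logistic regression of abnormal-ALT case status on
# methylation, adjusted for BMI, alcohol, diabetes and hypertension within
# match strata.

#' Propensity-score matching of abnormal-ALT cases to controls
#'
#' The propensity is a logistic model of case status on age and sex; cases
#' are processed in a seed-randomized order and each greedily takes up to
#' `ratio` nearest unmatched controls within the caliper (without
#' replacement). Cases with no in-caliper control are dropped and logged.
#'
#' @param samples data.frame with `sample_id`, `age`, `sex` and a 0/1 `case`
#'   column.
#' @param ratio controls per case (default 3).
#' @param caliper maximal propensity-score distance on the probability
#'   scale (default 0.1).
#' @param seed integer seed for the case processing order.
#' @return list of class `matched_cohort`: `strata` (data.frame sample_id,
#'   stratum, case, ps), `unmatched_cases`, `ps` (all scores), `ratio`,
#'   `caliper`.
#' @export
propensity_match <- function(samples, ratio = 3, caliper = 0.1, seed = 1) {
  stopifnot(all(c("sample_id", "age", "sex", "case") %in% names(samples)))
  if (sum(samples$case == 1) < 1) stop("no cases to match")
  if (sum(samples$case == 0) < ratio) stop("fewer controls than ratio")
  fml <- if (length(unique(samples$sex)) > 1)
    case ~ age + factor(sex) else case ~ age
  ps_fit <- glm(fml, binomial, data = samples)
  ps <- fitted(ps_fit)
  names(ps) <- samples$sample_id
  cases <- which(samples$case == 1)
  controls <- which(samples$case == 0)
  set.seed(seed)
  cases <- cases[sample.int(length(cases))]
  available <- rep(TRUE, nrow(samples))
  strata <- list(); unmatched <- character(0)
  stratum_id <- 0L
  for (ci in cases) {
    pool <- controls[available[controls]]
    d <- abs(ps[pool] - ps[ci])
    pool <- pool[d <= caliper]
    d <- d[d <= caliper]
    if (!length(pool)) { unmatched <- c(unmatched, samples$sample_id[ci]); next }
    take <- pool[order(d, samples$sample_id[pool])][seq_len(min(ratio,
                                                                length(pool)))]
    available[take] <- FALSE
    stratum_id <- stratum_id + 1L
    strata[[stratum_id]] <- data.frame(
      sample_id = samples$sample_id[c(ci, take)],
      stratum = stratum_id,
      case = c(1L, rep(0L, length(take))),
      ps = unname(ps[c(ci, take)]), stringsAsFactors = FALSE)
  }
  if (!length(strata)) stop("no case could be matched within the caliper")
  if (length(unmatched))
    message(length(unmatched), " case(s) had no in-caliper control and were dropped")
  structure(list(strata = do.call(rbind, strata),
                 unmatched_cases = unmatched, ps = ps,
                 ratio = ratio, caliper = caliper),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("matched_cohort: %d strata, %d cases, %d controls (%d unmatched cases)\n",
              max(x$strata$stratum), sum(x$strata$case == 1),
              sum(x$strata$case == 0), length(x$unmatched_cases)))
  invisible(x)
}

#' Conditional logistic regression within match strata
#'
#' Maximizes the stratum-conditional likelihood of case status on a
#' methylation measure, adjusted for any supplied covariates; reports the
#' odds ratio per methylation unit with a Wald confidence interval. Degenerate
#' inputs (no within-stratum methylation variation) and complete separation
#' are flagged instead of estimated.
#'
#' @param matched a [propensity_match()] result.
#' @param methylation named numeric vector (names = sample ids): the CpG or
#'   CpG-group methylation measure.
#' @param covariates optional data.frame of per-sample covariates with a
#'   `sample_id` column (e.g. bmi, alcohol, diabetes, hypertension).
#' @param conf_level confidence level for the interval.
#' @return one-row data.frame: or, ci_low, ci_high, p, n_strata, flagged,
#'   reason.
#' @export
conditional_logistic <- function(matched, methylation, covariates = NULL,
                                 conf_level = 0.95) {
  stopifnot(inherits(matched, "matched_cohort"))
  d <- matched$strata
  d$meth <- methylation[d$sample_id]
  if (anyNA(d$meth)) stop("methylation missing for matched samples")
  covnames <- NULL
  if (!is.null(covariates)) {
    idx <- match(d$sample_id, covariates$sample_id)
    covnames <- setdiff(names(covariates), "sample_id")
    for (nm in covnames) {
      v <- covariates[[nm]][idx]
      d[[nm]] <- if (is.character(v) || is.factor(v))
        as.numeric(factor(v)) - 1 else as.numeric(v)
    }
  }
  informative <- tapply(d$meth, d$stratum, function(x) sd(x) > 1e-12)
  n_inf <- sum(informative)
  flag <- function(reason) data.frame(
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
    n_strata = n_inf, flagged = TRUE, reason = reason)
  if (n_inf < 5) return(flag("fewer than 5 informative strata"))
  fml <- as.formula(paste("case ~ meth",
                          if (length(covnames))
                            paste("+", paste(covnames, collapse = " + "))
                          else "",
                          "+ strata(stratum)"))
  fit <- tryCatch(survival::clogit(fml, data = d),
                  warning = function(w) w, error = function(e) e)
  if (inherits(fit, "condition")) {
    fit2 <- suppressWarnings(tryCatch(survival::clogit(fml, data = d),
                                      error = function(e) NULL))
    if (is.null(fit2)) return(flag(conditionMessage(fit)))
    fit <- fit2
  }
  b <- coef(fit)["meth"]; se <- sqrt(diag(vcov(fit)))["meth"]
  if (!is.finite(b) || !is.finite(se) || abs(b) > 15 || se > 100)
    return(flag("complete or quasi-complete separation"))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * pnorm(-abs(b / se))
  data.frame(or = exp(b), ci_low = exp(b - zq * se), ci_high = exp(b + zq * se),
             p = unname(p), n_strata = n_inf, flagged = FALSE,
             reason = NA_character_, row.names = NULL)
}

#' Average methylation over user-defined CpG groups
#'
#' Pre-step for validating grouped signals: the mean methylation of closely
#' adjacent CpGs, per sample.
#'
#' @param meth samples x CpGs matrix.
#' @param groups named list mapping group id to CpG column names.
#' @return samples x groups matrix of group means.
#' @export
group_methylation <- function(meth, groups) {
  out <- vapply(groups, function(cols)
    rowMeans(meth[, cols, drop = FALSE]), numeric(nrow(meth)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(meth))
  rownames(out) <- rownames(meth)
  colnames(out) <- names(groups)
  out
}

#' Run the validation stage over a methylation table
#'
#' Matches the cohort, then fits [conditional_logistic()] per methylation
#' column.
#'
#' @param samples validation sample sheet (incl. `case`, `age`, `sex` and
#'   adjustment covariates).
#' @param meth samples x CpGs (or CpG groups) methylation matrix.
#' @param covariates adjustment covariate names (default bmi, alcohol,
#'   diabetes, hypertension).
#' @param ratio,caliper,seed matching parameters.
#' @return list: `matched` and `records` (one row per methylation column).
#' @export
run_validation <- function(samples, meth,
                           covariates = c("bmi", "alcohol", "diabetes",
                                          "hypertension"),
                           ratio = 3, caliper = 0.1, seed = 1) {
  matched <- propensity_match(samples, ratio, caliper, seed)
  covdf <- samples[, c("sample_id", covariates)]
  recs <- do.call(rbind, lapply(colnames(meth), function(cg) {
    v <- setNames(meth[, cg], rownames(meth))
    cbind(data.frame(cpg = cg, stringsAsFactors = FALSE),
          conditional_logistic(matched, v, covdf))
  }))
  rownames(recs) <- NULL
  list(matched = matched, records = recs)
}
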