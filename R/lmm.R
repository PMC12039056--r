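# Linear mixed model with a single random intercept over twin pairs,
# specialized for clusters of size <= 2.
#
# With V_i = sigma_e^2 * I + sigma_a^2 * J per pair, the orthogonal
# (sum, difference)/sqrt(2) transform of each complete pair whitens V into
# independent rows with variances sigma_e^2 * (1 + 2*phi) and sigma_e^2,
# phi = sigma_a^2 / sigma_e^2; singletons (co-twin dropped by missingness)
# have variance sigma_e^2 * (1 + phi). REML then reduces to a 1-D profile
# optimization over phi with a weighted least-squares solve per evaluation.
# Satterthwaite degrees of freedom come from the delta method on the
# REML-variance-component covariance (finite-difference Hessian), the same
# construction lmerTest uses.

pair_transform <- function(y, X, pair_id) {
  pair_id <- as.character(pair_id)
  tab <- table(pair_id)
  if (any(tab > 2)) stop("more than two samples share a pair id")
  complete <- names(tab)[tab == 2]
  single <- names(tab)[tab == 1]
  s2 <- sqrt(2)
  rows_y <- numeric(0); rows_X <- NULL; type <- character(0)
  if (length(complete)) {
    i1 <- match(complete, pair_id)
    # second member of each pair
    i2 <- vapply(complete, function(p) which(pair_id == p)[2], 1L)
    yp <- (y[i1] + y[i2]) / s2; ym <- (y[i1] - y[i2]) / s2
    Xp <- (X[i1, , drop = FALSE] + X[i2, , drop = FALSE]) / s2
    Xm <- (X[i1, , drop = FALSE] - X[i2, , drop = FALSE]) / s2
    rows_y <- c(yp, ym); rows_X <- rbind(Xp, Xm)
    type <- c(rep("plus", length(yp)), rep("minus", length(ym)))
  }
  if (length(single)) {
    is <- match(single, pair_id)
    rows_y <- c(rows_y, y[is])
    rows_X <- rbind(rows_X, X[is, , drop = FALSE])
    type <- c(type, rep("single", length(is)))
  }
  list(y = rows_y, X = rows_X, type = type,
       n = length(y), n_complete = length(complete))
}

# -2 * restricted log-likelihood profiled over sigma_e^2, up to a constant
reml_profile <- function(phi, tr, p) {
  cvec <- c(plus = 1 + 2 * phi, minus = 1, single = 1 + phi)[tr$type]
  w <- 1 / cvec
  fit <- lm.wfit(tr$X, tr$y, w)
  rss <- sum(w * fit$residuals^2)
  n <- tr$n
  XtWX <- crossprod(tr$X * sqrt(w))
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  sigma_e2 <- rss / (n - p)
  list(crit = (n - p) * log(sigma_e2) + sum(log(cvec)) + as.numeric(ld),
       sigma_e2 = sigma_e2, fit = fit, w = w, XtWX = XtWX)
}

# -2 restricted log-likelihood at given (sigma_a^2, sigma_e^2), no profiling
reml_at <- function(sa2, se2, tr, p) {
  phi <- sa2 / se2
  cvec <- c(plus = 1 + 2 * phi, minus = 1, single = 1 + phi)[tr$type]
  w <- 1 / cvec
  fit <- lm.wfit(tr$X, tr$y, w)
  rss <- sum(w * fit$residuals^2)
  XtWX <- crossprod(tr$X * sqrt(w))
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  tr$n * log(se2) + sum(log(cvec)) + as.numeric(ld) - p * log(se2) + rss / se2
}

se2_of <- function(sa2, se2, tr, j) {
  phi <- sa2 / se2
  cvec <- c(plus = 1 + 2 * phi, minus = 1, single = 1 + phi)[tr$type]
  w <- 1 / cvec
  XtWX <- crossprod(tr$X * sqrt(w))
  se2 * solve(XtWX)[j, j]
}

#' Fit the twin-pair linear mixed model
#'
#' REML fit of `y ~ X + (1 | pair)` for clusters of at most two observations
#' (MZ twin pairs, possibly reduced to singletons by missingness), with
#' Satterthwaite degrees of freedom per coefficient. Equivalent to
#' `lmerTest::lmer(y ~ X + (1 | pair))` but orders of magnitude faster for
#' this design, which the per-CpG association scan and the simulation suites
#' rely on.
#'
#' @param y numeric response.
#' @param X design matrix including the intercept column.
#' @param pair_id cluster (twin-pair) identifier per observation.
#' @return list with `coefficients` (data.frame: estimate, se, df, t, p),
#'   `sigma_a2`, `sigma_e2`, `phi`, `n`, `n_pairs_complete`, `singular`.
#' @export
fit_pair_lmm <- function(y, X, pair_id) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("degenerate predictor: design matrix is rank-deficient")
  if (length(y) - p < 1) stop("insufficient observations")
  tr <- pair_transform(y, X, pair_id)
  obj <- function(lphi) reml_profile(exp(lphi), tr, p)$crit
  opt <- optimize(obj, c(-14, 8), tol = 1e-9)
  cand <- c(exp(opt$minimum), 0)
  crits <- c(opt$objective, reml_profile(0, tr, p)$crit)
  phi <- cand[which.min(crits)]
  prof <- reml_profile(phi, tr, p)
  se2 <- prof$sigma_e2
  sa2 <- phi * se2
  beta <- prof$fit$coefficients
  vc <- se2 * solve(prof$XtWX)
  se <- sqrt(diag(vc))
  n <- tr$n
  singular <- phi < 1e-7

  df <- rep(n - p, p)
  if (!singular) {
    # Satterthwaite: Cov(variance components) from the REML Hessian,
    # then the delta method on se^2_j(sa2, se2)
    h <- c(max(1e-8, 1e-5 * sa2), max(1e-8, 1e-5 * se2))
    H <- matrix(NA_real_, 2, 2)
    f0 <- reml_at(sa2, se2, tr, p)
    fpp <- reml_at(sa2 + h[1], se2 + h[2], tr, p)
    fpm <- reml_at(sa2 + h[1], se2 - h[2], tr, p)
    fmp <- reml_at(sa2 - h[1], se2 + h[2], tr, p)
    fmm <- reml_at(sa2 - h[1], se2 - h[2], tr, p)
    fp0 <- reml_at(sa2 + h[1], se2, tr, p)
    fm0 <- reml_at(sa2 - h[1], se2, tr, p)
    f0p <- reml_at(sa2, se2 + h[2], tr, p)
    f0m <- reml_at(sa2, se2 - h[2], tr, p)
    H[1, 1] <- (fp0 - 2 * f0 + fm0) / h[1]^2
    H[2, 2] <- (f0p - 2 * f0 + f0m) / h[2]^2
    H[1, 2] <- H[2, 1] <- (fpp - fpm - fmp + fmm) / (4 * h[1] * h[2])
    cov_vc <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov_vc) && all(is.finite(cov_vc)) &&
        all(diag(cov_vc) > 0)) {
      for (j in seq_len(p)) {
        g <- c((se2_of(sa2 + h[1], se2, tr, j) -
                  se2_of(sa2 - h[1], se2, tr, j)) / (2 * h[1]),
               (se2_of(sa2, se2 + h[2], tr, j) -
                  se2_of(sa2, se2 - h[2], tr, j)) / (2 * h[2]))
        denom <- drop(t(g) %*% cov_vc %*% g)
        if (is.finite(denom) && denom > 0) {
          dfj <- 2 * (se[j]^2)^2 / denom
          if (is.finite(dfj) && dfj > 0) df[j] <- min(dfj, n - p)
        }
      }
    }
  }
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  coefs <- data.frame(estimate = beta, se = se, df = df, t = tstat, p = pval,
                      row.names = colnames(X))
  list(coefficients = coefs, sigma_a2 = sa2, sigma_e2 = se2, phi = phi,
       n = n, n_pairs_complete = tr$n_complete, singular = singular)
}
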