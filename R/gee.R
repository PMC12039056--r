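# Gaussian generalized estimating equations with an exchangeable working
# correlation over twin-pair clusters and robust (sandwich) standard errors.
# Written in-package: the estimator is the standard Liang-Zeger GLS
# iteration; clusters here have size <= 2 so V_i inverts analytically.

#' Fit a Gaussian GEE over twin-pair clusters
#'
#' Working correlation `"independence"` (default) estimates the marginal
#' coefficients by ordinary least squares with cluster-robust sandwich
#' standard errors; `"exchangeable"` iterates the Liang-Zeger GLS update
#' with a moment estimate of the within-pair correlation. For double-entered
#' co-twin regressions the independence structure is the right default: the
#' co-twin predictor's within-pair contrast is the negative of the self
#' contrast, so an exchangeable GLS step mixes in a sign-flipped within-pair
#' regression and distorts the marginal co-twin coefficient the method
#' interprets.
#'
#' @param y numeric response.
#' @param X design matrix including the intercept.
#' @param id cluster identifier (twin pair).
#' @param corstr working correlation structure.
#' @param max_iter,tol iteration control.
#' @return list: `coefficients`, `vcov` (robust sandwich), `vcov_model`
#'   (model-based), `influence` (per-cluster contributions), `alpha`
#'   (working correlation), `sigma2`, `n_clusters`.
#' @export
gee_gaussian <- function(y, X, id, corstr = c("independence", "exchangeable"),
                         max_iter = 25, tol = 1e-10) {
  corstr <- match.arg(corstr)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p)
    stop("degenerate within-pair variance: design matrix is rank-deficient")
  id <- as.character(id)
  groups <- split(seq_len(n), id)
  beta <- qr.solve(X, y)
  alpha <- 0
  for (iter in seq_len(max_iter)) {
    r <- y - X %*% beta
    sigma2 <- sum(r^2) / (n - p)
    num <- 0; cnt <- 0
    for (g in groups) if (length(g) == 2) {
      num <- num + r[g[1]] * r[g[2]]; cnt <- cnt + 1
    }
    alpha_new <- if (corstr == "exchangeable" && cnt > p)
      (num / (cnt - p)) / sigma2 else 0
    alpha_new <- max(-0.95, min(0.95, alpha_new))
    # GLS update with V_i = sigma2 * [(1 - a) I + a J]
    A <- matrix(0, p, p); b <- numeric(p)
    for (g in groups) {
      Xi <- X[g, , drop = FALSE]; yi <- y[g]
      if (length(g) == 2) {
        det <- 1 - alpha_new^2
        Vinv <- matrix(c(1, -alpha_new, -alpha_new, 1), 2) / det
      } else Vinv <- matrix(1, 1, 1)
      A <- A + t(Xi) %*% Vinv %*% Xi
      b <- b + t(Xi) %*% Vinv %*% yi
    }
    beta_new <- solve(A, b)
    done <- max(abs(beta_new - beta)) < tol && abs(alpha_new - alpha) < tol
    beta <- beta_new; alpha <- alpha_new
    if (done || corstr == "independence" && iter >= 2) break
  }
  # sandwich; per-cluster influence contributions are kept so that
  # functionals across models (ICE FALCON coefficient changes) get
  # cluster-robust standard errors
  r <- y - X %*% beta
  sigma2 <- sum(r^2) / (n - p)
  A <- matrix(0, p, p)
  U <- matrix(0, length(groups), p, dimnames = list(names(groups),
                                                    colnames(X)))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    Xi <- X[g, , drop = FALSE]; ri <- r[g]
    if (length(g) == 2) {
      det <- 1 - alpha^2
      Vinv <- matrix(c(1, -alpha, -alpha, 1), 2) / (det * sigma2)
    } else Vinv <- matrix(1 / sigma2, 1, 1)
    XtV <- t(Xi) %*% Vinv
    A <- A + XtV %*% Xi
    U[gi, ] <- drop(XtV %*% ri)
  }
  Ainv <- solve(A)
  infl <- U %*% Ainv   # cluster i's contribution to beta_hat
  list(coefficients = setNames(drop(beta), colnames(X)),
       vcov = t(infl) %*% infl,
       vcov_model = Ainv,
       influence = infl,
       alpha = alpha, sigma2 = sigma2, n_clusters = length(groups))
}
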