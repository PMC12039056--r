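#' Beta- to M-value transformation and its inverse
#'
#' `M = log2(beta / (1 - beta))`; strictly increasing bijection on (0, 1).
#' Values of exactly 0 or 1 are rejected — quality control guarantees they do
#' not occur downstream.
#'
#' @param beta methylation proportion(s) strictly inside (0, 1).
#' @return M-value(s).
#' @export
beta_to_m <- function(beta) {
  if (any(!is.na(beta) & (beta <= 0 | beta >= 1)))
    stop("beta must lie strictly inside (0, 1)")
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m M-value(s).
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

#' CpG-level quality filters
#'
#' Removes CpGs whose mean beta-value (over observed entries) is below
#' `mean_low` or above `mean_high`, or that have more than `max_missing`
#' missing observations. Each removed CpG is attributed to the first filter
#' it fails (extreme mean checked first), so the report counts are additive.
#'
#' @param matrix a [meth_matrix()].
#' @param mean_low,mean_high retained mean-beta band (defaults 0.01 / 0.99).
#' @param max_missing maximum tolerated missing observations per CpG; a CpG
#'   with strictly more is removed.
#' @return list with `matrix` (filtered) and `report` (a `qc_report`:
#'   n_input, n_removed_extreme_mean, n_removed_missing, n_retained, plus the
#'   per-filter CpG keys).
#' @export
filter_cpgs <- function(matrix, mean_low = 0.01, mean_high = 0.99,
                        max_missing = 10) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (!(mean_low >= 0 && mean_low < mean_high && mean_high <= 1))
    stop("require 0 <= mean_low < mean_high <= 1")
  b <- matrix$beta
  if (nrow(b) == 0) stop("empty methylation matrix")
  mean_beta <- rowMeans(b, na.rm = TRUE)
  n_missing <- rowSums(is.na(b))
  fail_mean <- is.nan(mean_beta) | mean_beta < mean_low | mean_beta > mean_high
  fail_missing <- !fail_mean & n_missing > max_missing
  keep <- !fail_mean & !fail_missing
  report <- structure(list(
    n_input = nrow(b),
    n_removed_extreme_mean = sum(fail_mean),
    n_removed_missing = sum(fail_missing),
    n_retained = sum(keep),
    removed_extreme_mean = rownames(b)[fail_mean],
    removed_missing = rownames(b)[fail_missing]), class = "qc_report")
  list(matrix = matrix[keep, ], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: %d CpGs in; %d removed (extreme mean), ",
                     "%d removed (missingness); %d retained\n"),
              x$n_input, x$n_removed_extreme_mean, x$n_removed_missing,
              x$n_retained))
  invisible(x)
}

#' Write a QC report as TSV + JSON summary
#' @param report a `qc_report`.
#' @param dir output directory.
#' @export
write_qc_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report[c("n_input", "n_removed_extreme_mean",
                                "n_removed_missing", "n_retained")],
                       file.path(dir, "qc_summary.json"), auto_unbox = TRUE)
  removed <- data.frame(
    cpg = c(report$removed_extreme_mean, report$removed_missing),
    filter = rep(c("extreme_mean", "missing"),
                 c(length(report$removed_extreme_mean),
                   length(report$removed_missing))))
  write.table(removed, file.path(dir, "qc_removed.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Reference-free cell-composition components (ReFACTor-style)
#'
#' Sparse-PCA-flavoured procedure: (1) standardize each CpG across samples;
#' (2) form the rank-`k` SVD approximation; (3) rank CpGs by reconstruction
#' distance (ascending — the best-approximated CpGs carry the dominant
#' low-rank structure, i.e. cell composition); (4) take principal components
#' of the top-`t` ranked CpGs and return the first `k` sample scores.
#'
#' Missing beta-values are imputed with the per-CpG observed mean for the
#' component extraction only.
#'
#' @param matrix a [meth_matrix()].
#' @param k number of components (the analysis uses the top five).
#' @param t number of top-ranked CpGs used for the final PCA.
#' @return list of class `composition_components`: `scores` (samples x k,
#'   orthogonal columns), `ranked_cpg_indices`, `k`, `t`, `sdev`.
#' @export
refactor_components <- function(matrix, k = 5, t = 500) {
  stopifnot(inherits(matrix, "meth_matrix"))
  b <- matrix$beta
  t <- min(t, nrow(b))
  if (k >= t) stop("require k < t <= number of CpGs")
  # mean-impute missing entries per CpG
  if (anyNA(b)) {
    mu <- rowMeans(b, na.rm = TRUE)
    idx <- which(is.na(b), arr.ind = TRUE)
    b[idx] <- mu[idx[, 1]]
  }
  s <- apply(b, 1, sd)
  keep <- which(s > 0)
  bs <- (b[keep, , drop = FALSE] - rowMeans(b[keep, , drop = FALSE])) / s[keep]
  sv <- svd(bs, nu = k, nv = k)
  approx <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  dist <- sqrt(rowSums((bs - approx)^2))
  ranked <- keep[order(dist)]
  top <- bs[match(ranked[seq_len(t)], keep), , drop = FALSE]
  pc <- stats::prcomp(t(top), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- matrix$samples
  colnames(scores) <- paste0("comp", seq_len(k))
  structure(list(scores = scores, ranked_cpg_indices = ranked,
                 k = k, t = t, sdev = pc$sdev[seq_len(k)]),
            class = "composition_components")
}

#' @export
print.composition_components <- function(x, ...) {
  cat(sprintf("composition_components: k = %d over top %d CpGs\n", x$k, x$t))
  invisible(x)
}
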