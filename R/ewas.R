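#' EWAS configuration
#'
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param covariates covariate columns of the sample sheet to adjust for
#'   (the analysis set: age, sex, alcohol, bmi, hypertension, diabetes).
#' @param n_components number of cell-composition components to include.
#' @param log_alt analyse ALT on the log scale (off by default; effects are
#'   reported in U/L).
#' @param min_n minimum complete observations per CpG.
#' @param min_pairs minimum complete twin pairs per CpG.
#' @return list of class `ewas_config`.
#' @export
ewas_config <- function(alpha = 0.05,
                        covariates = c("age", "sex", "alcohol", "bmi",
                                       "hypertension", "diabetes"),
                        n_components = 5, log_alt = FALSE,
                        min_n = 10, min_pairs = 2) {
  structure(as.list(environment()), class = "ewas_config")
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of CpGs tested.
#' @return `alpha / n_tests` (0.05 over 233,720 CpGs gives 2.14e-7).
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

build_covariate_matrix <- function(cohort, covariates) {
  if (!length(covariates)) return(NULL)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop("covariates absent from sample sheet: ",
                         paste(miss, collapse = ", "))
  cols <- lapply(covariates, function(nm) {
    v <- cohort[[nm]]
    if (nm == "sex" || is.character(v) || is.factor(v)) {
      as.numeric(factor(v, levels = sort(unique(as.character(v))))) - 1
    } else as.numeric(v)
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- covariates
  mat
}

#' Per-CpG mixed-model association fit
#'
#' Fits `ALT ~ M + covariates + components + (1 | pair)` by REML with a
#' twin-pair random intercept; the reported effect is the M-value
#' coefficient (ALT U/L per unit M) with a Satterthwaite-df t-test.
#' Complete-case within CpG: samples missing this CpG are dropped, keeping
#' the co-twin as a singleton cluster.
#'
#' @param alt per-sample ALT (U/L).
#' @param m per-sample M-values at one CpG (`NA` = missing).
#' @param covariates covariate matrix (or NULL), rows aligned with samples.
#' @param components cell-composition score matrix (or NULL).
#' @param pair_ids twin-pair identifier per sample.
#' @return one-row data.frame: beta_hat, se, df, t, p, n_used, sigma_a2,
#'   sigma_e2, singular, skipped, reason.
#' @export
fit_cpg <- function(alt, m, covariates = NULL, components = NULL, pair_ids) {
  skip <- function(reason) data.frame(
    beta_hat = NA_real_, se = NA_real_, df = NA_real_, t = NA_real_,
    p = NA_real_, n_used = 0L, sigma_a2 = NA_real_, sigma_e2 = NA_real_,
    singular = NA, skipped = TRUE, reason = reason)
  X_extra <- cbind(covariates, components)
  ok <- !is.na(alt) & !is.na(m)
  if (!is.null(X_extra)) ok <- ok & complete.cases(X_extra)
  n <- sum(ok)
  pid <- pair_ids[ok]
  n_complete_pairs <- sum(table(pid) == 2)
  if (n < 10) return(skip("fewer than 10 complete observations"))
  if (n_complete_pairs < 2) return(skip("fewer than 2 complete pairs"))
  mv <- m[ok]
  if (sd(mv) < 1e-12) stop("degenerate predictor: constant M values")
  X <- cbind(`(Intercept)` = 1, m = mv,
             if (!is.null(X_extra)) X_extra[ok, , drop = FALSE])
  # drop aliased covariate columns (e.g. a flag constant in a small cohort);
  # the intercept and M must survive
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    keep <- sort(qd$pivot[seq_len(qd$rank)])
    if (!all(1:2 %in% keep)) stop("degenerate predictor: constant M values")
    X <- X[, keep, drop = FALSE]
  }
  fit <- tryCatch(fit_pair_lmm(alt[ok], X, pid), error = function(e) e)
  if (inherits(fit, "error")) {
    if (grepl("degenerate", conditionMessage(fit))) stop(fit)
    return(skip(conditionMessage(fit)))
  }
  co <- fit$coefficients["m", ]
  if (!is.finite(co$se) || fit$sigma_e2 < 1e-12)
    return(data.frame(beta_hat = co$estimate, se = NA_real_, df = NA_real_,
                      t = NA_real_, p = NA_real_, n_used = n,
                      sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
                      singular = TRUE, skipped = FALSE, reason = "singular fit"))
  data.frame(beta_hat = co$estimate, se = co$se, df = co$df, t = co$t,
             p = co$p, n_used = n, sigma_a2 = fit$sigma_a2,
             sigma_e2 = fit$sigma_e2, singular = fit$singular,
             skipped = FALSE, reason = NA_character_)
}

#' Epigenome-wide association scan
#'
#' Runs [fit_cpg()] for every CpG of a QC'd matrix and returns records
#' ordered by p-value, with the Bonferroni significance flag computed over
#' the number of successfully fitted CpGs.
#'
#' @param matrix a [meth_matrix()] after QC.
#' @param cohort sample sheet (must cover `matrix$samples`).
#' @param components optional `composition_components` (or a score matrix).
#' @param config an [ewas_config()].
#' @return data.frame of EWAS records (chrom, pos, beta_hat, se, df, p,
#'   n_used, significant, ...) sorted by p ascending; attributes `n_tests`
#'   and `threshold`; skipped CpGs are dropped from the records and listed
#'   in attribute `skipped`.
#' @export
run_ewas <- function(matrix, cohort, components = NULL,
                     config = ewas_config()) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (nrow(matrix$beta) == 0) {
    warning("no CpGs to test after QC")
    return(data.frame())
  }
  idx <- match(matrix$samples, cohort$sample_id)
  if (anyNA(idx)) stop("samples in matrix missing from sample sheet")
  cohort <- cohort[idx, ]
  alt <- if (config$log_alt) log(cohort$alt) else cohort$alt
  covm <- build_covariate_matrix(cohort, config$covariates)
  comp <- NULL
  if (!is.null(components)) {
    scores <- if (inherits(components, "composition_components"))
      components$scores else as.matrix(components)
    k <- min(config$n_components, ncol(scores))
    comp <- scores[matrix$samples, seq_len(k), drop = FALSE]
  }
  M <- m_values(matrix)
  rows <- vector("list", nrow(M))
  for (g in seq_len(nrow(M))) {
    rows[[g]] <- cbind(chrom = matrix$cpgs$chrom[g], pos = matrix$cpgs$pos[g],
                       fit_cpg(alt, M[g, ], covm, comp, cohort$pair_id),
                       stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  skipped <- rec[rec$skipped | is.na(rec$p), ]
  rec <- rec[!rec$skipped & !is.na(rec$p), ]
  n_tests <- nrow(rec)
  thr <- if (n_tests > 0) bonferroni_threshold(config$alpha, n_tests) else NA
  rec$significant <- rec$p < thr
  rec <- rec[order(rec$p), ]
  rownames(rec) <- NULL
  attr(rec, "n_tests") <- n_tests
  attr(rec, "threshold") <- thr
  attr(rec, "skipped") <- skipped
  rec
}

#' Annotate EWAS records with the nearest gene
#'
#' Distance 0 if the CpG lies inside a gene interval; ties (equidistant
#' genes) are broken deterministically by the lower start coordinate and
#' logged via `message()`. CpGs on chromosomes absent from the annotation
#' get `gene = NA`.
#'
#' @param records EWAS records data.frame (chrom, pos).
#' @param genes `GRanges` with a `name` metadata column (see
#'   [read_gene_bed()]).
#' @return the records with `gene` and `distance_to_gene` columns added.
#' @export
annotate_nearest_gene <- function(records, genes) {
  if (length(genes) == 0) stop("empty gene annotation")
  cpg <- GenomicRanges::GRanges(records$chrom,
                                IRanges::IRanges(records$pos, records$pos))
  # strand-agnostic nearest; resolve ties by lower gene start
  hits <- GenomicRanges::distanceToNearest(cpg, genes, ignore.strand = TRUE)
  gene <- rep(NA_character_, nrow(records))
  dist <- rep(NA_integer_, nrow(records))
  qh <- S4Vectors::queryHits(hits)
  d <- S4Vectors::mcols(hits)$distance
  # candidates at exactly the nearest distance: expand each CpG by that
  # distance and overlap (nearest() does not report ties)
  expanded <- GenomicRanges::resize(cpg[qh], width = 2 * (d + 1) + 1,
                                    fix = "center")
  ov <- GenomicRanges::findOverlaps(expanded, genes, ignore.strand = TRUE)
  cand_by_q <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  n_tied <- 0L
  for (i in seq_along(qh)) {
    q <- qh[i]
    cand <- cand_by_q[[as.character(i)]]
    dd <- GenomicRanges::distance(rep(cpg[q], length(cand)), genes[cand],
                                  ignore.strand = TRUE)
    cand <- cand[dd == min(dd)]
    if (length(cand) > 1) {
      n_tied <- n_tied + 1L
      cand <- cand[order(GenomicRanges::start(genes)[cand])]
    }
    gene[q] <- S4Vectors::mcols(genes)$name[cand[1]]
    dist[q] <- d[i]
  }
  if (n_tied > 0)
    message(n_tied, " CpG(s) equidistant between genes; lower start chosen")
  records$gene <- gene
  records$distance_to_gene <- dist
  records
}

#' Write EWAS records as TSV
#' @param records EWAS records.
#' @param path output path.
#' @export
write_ewas <- function(records, path) {
  cols <- intersect(c("chrom", "pos", "p", "beta_hat", "gene", "se", "df",
                      "n_used", "significant", "distance_to_gene"),
                    names(records))
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_ewas
#' @export
read_ewas <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}
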