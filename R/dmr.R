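# comb-p-style DMR detection: (1) estimate the autocorrelation of the
# probit-transformed EWAS p-value track as a function of genomic distance;
# (2) smooth each p-value by the Stouffer-Liptak-Kechris combination of its
# window, using the ACF-derived correlation; (3) grow candidate regions from
# runs of small smoothed p-values; (4) score each region by the
# Stouffer-Liptak combination of its members' raw p-values (slk p) and
# correct for the number of possible same-sized regions (Sidak p).

probit_z <- function(p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  qnorm(1 - p)
}

#' Estimate the distance-binned autocorrelation of a p-value track
#'
#' For each distance bin (bp), the Pearson correlation of
#' `z = qnorm(1 - p)` over all CpG pairs whose separation falls in the bin,
#' pooled across chromosomes. Bins with fewer than 10 pairs get correlation
#' 0 with a warning.
#'
#' @param pvals per-CpG p-values.
#' @param chrom,positions CpG coordinates (positions sorted within
#'   chromosome).
#' @param max_dist largest pair separation considered (bp).
#' @param bin_width bin width (bp).
#' @return data.frame of class `acf_estimate`: lo, hi, cor, n.
#' @export
estimate_acf <- function(pvals, chrom, positions, max_dist = 500,
                         bin_width = 50) {
  z <- probit_z(pvals)
  breaks <- seq(0, max_dist, by = bin_width)
  nb <- length(breaks) - 1
  zi <- vector("list", nb); zj <- vector("list", nb)
  for (b in seq_len(nb)) { zi[[b]] <- list(); zj[[b]] <- list() }
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sel <- sel[order(positions[sel])]
    pos <- positions[sel]
    n <- length(sel)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      j <- i + 1
      while (j <= n && pos[j] - pos[i] <= max_dist) {
        b <- min(nb, max(1L, ceiling((pos[j] - pos[i]) / bin_width)))
        zi[[b]][[length(zi[[b]]) + 1L]] <- z[sel[i]]
        zj[[b]][[length(zj[[b]]) + 1L]] <- z[sel[j]]
        j <- j + 1
      }
    }
  }
  out <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                    cor = 0, n = 0L)
  for (b in seq_len(nb)) {
    x <- unlist(zi[[b]]); y <- unlist(zj[[b]])
    out$n[b] <- length(x)
    if (length(x) >= 10) {
      r <- suppressWarnings(cor(x, y))
      out$cor[b] <- if (is.finite(r)) r else 0
    } else {
      warning("fewer than 10 CpG pairs in distance bin (",
              out$lo[b], ", ", out$hi[b], "]; correlation set to 0")
    }
  }
  class(out) <- c("acf_estimate", "data.frame")
  out
}

acf_lookup <- function(acf, dist) {
  out <- numeric(length(dist))
  inside <- dist > 0 & dist <= max(acf$hi)
  b <- pmin(nrow(acf), pmax(1L, ceiling(dist[inside] / (acf$hi[1] - acf$lo[1]))))
  # negative estimated autocorrelation is sampling noise at these scales;
  # clamp at 0 so the stepped correlation matrix stays near-PD
  out[inside] <- pmax(0, acf$cor[b])
  out[dist == 0] <- 1
  out
}

# Stouffer-Liptak combination of p-values under correlation matrix sigma;
# repairs a non-positive-definite sigma by eigenvalue clipping
stouffer_liptak <- function(pvals, sigma) {
  z <- probit_z(pvals)
  denom <- sum(sigma)
  if (denom <= 0 || any(eigen(sigma, symmetric = TRUE,
                              only.values = TRUE)$values < -1e-10)) {
    message("non-positive-definite correlation matrix repaired by eigenvalue clipping")
    es <- eigen(sigma, symmetric = TRUE)
    vals <- pmax(es$values, 1e-8)
    sigma <- es$vectors %*% (vals * t(es$vectors))
    denom <- sum(sigma)
  }
  1 - pnorm(sum(z) / sqrt(denom))
}

#' Autocorrelation-corrected smoothing of a p-value track
#'
#' Each p-value is replaced by the Stouffer-Liptak combination of itself and
#' its neighbours within `window` bp, with pairwise correlations taken from
#' the ACF estimate. An isolated CpG keeps its own p-value.
#'
#' @param pvals,chrom,positions the p-value track.
#' @param acf an [estimate_acf()] result.
#' @param window neighbourhood half-width in bp (must be at least the ACF
#'   bin width).
#' @return numeric vector of corrected p-values.
#' @export
slk_correct <- function(pvals, chrom, positions, acf, window = 300) {
  if (window < (acf$hi[1] - acf$lo[1])) stop("window smaller than ACF bin width")
  n <- length(pvals)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(chrom == chrom[i] & abs(positions - positions[i]) <= window)
    if (length(nb) == 1) { out[i] <- pvals[i]; next }
    d <- abs(outer(positions[nb], positions[nb], "-"))
    sigma <- matrix(acf_lookup(acf, as.vector(d)), length(nb))
    diag(sigma) <- 1
    out[i] <- stouffer_liptak(pvals[nb], sigma)
  }
  out
}

#' Grow candidate regions from a corrected p-value track
#'
#' Maximal runs of CpGs with corrected p below `seed_p` and inter-CpG gap at
#' most `max_gap` bp; runs of at least 2 CpGs are kept.
#'
#' @param corrected corrected p-values ([slk_correct()]).
#' @param chrom,positions CpG coordinates.
#' @param seed_p seed threshold.
#' @param max_gap maximal gap between consecutive member CpGs (bp).
#' @return data.frame: chrom, start, end (1-based inclusive), n_cpgs, and a
#'   list-column `members` of CpG indices into the input track.
#' @export
find_regions <- function(corrected, chrom, positions, seed_p = 0.05,
                         max_gap = 300) {
  ok <- which(corrected < seed_p)
  if (!length(ok)) return(data.frame())
  o <- ok[cpg_order(chrom[ok], positions[ok])]
  new_run <- c(TRUE, chrom[o[-1]] != chrom[o[-length(o)]] |
                 diff(positions[o]) > max_gap)
  run_id <- cumsum(new_run)
  regions <- lapply(split(o, run_id), function(m) {
    if (length(m) < 2) return(NULL)
    data.frame(chrom = chrom[m[1]], start = min(positions[m]),
               end = max(positions[m]), n_cpgs = length(m),
               members = I(list(m)), stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, regions[!vapply(regions, is.null, TRUE)])
  if (is.null(regions)) return(data.frame())
  rownames(regions) <- NULL
  regions
}

#' Score a candidate region
#'
#' `slk_p` is the Stouffer-Liptak combination of the member CpGs' raw
#' p-values under the ACF correlation; `sidak_p = 1 - (1 - slk_p)^m` with
#' `m = total_bases / region_length`, the number of possible regions of this
#' size in the tested track.
#'
#' @param member_pvals raw p-values of the member CpGs.
#' @param member_positions their positions (same chromosome).
#' @param acf an [estimate_acf()] result.
#' @param total_bases total bases spanned by the tested track.
#' @return list: slk_p, sidak_p.
#' @export
score_region <- function(member_pvals, member_positions, acf, total_bases) {
  if (length(member_pvals) < 2) stop("a region requires at least 2 member CpGs")
  len <- max(member_positions) - min(member_positions) + 1
  if (len <= 0) stop("region length must be positive")
  d <- abs(outer(member_positions, member_positions, "-"))
  sigma <- matrix(acf_lookup(acf, as.vector(d)), length(member_pvals))
  diag(sigma) <- 1
  slk_p <- stouffer_liptak(member_pvals, sigma)
  m <- max(1, total_bases / len)
  sidak_p <- 1 - (1 - slk_p)^m
  list(slk_p = slk_p, sidak_p = sidak_p)
}

#' Direction of association of a region
#'
#' `positive` if at least `frac` of the member CpGs have a positive EWAS
#' effect, `negative` if at least `frac` are negative, otherwise
#' `uncertain`.
#'
#' @param member_betas member CpG effect estimates.
#' @param frac majority fraction (default 0.8).
#' @return one of "positive", "negative", "uncertain".
#' @export
region_direction <- function(member_betas, frac = 0.8) {
  pos <- mean(member_betas > 0)
  neg <- mean(member_betas < 0)
  if (pos >= frac) "positive" else if (neg >= frac) "negative" else "uncertain"
}

#' Call differentially methylated regions from EWAS records
#'
#' Full comb-p-style pipeline over the EWAS p-value track: ACF estimation,
#' Stouffer-Liptak-Kechris smoothing, region growing, region scoring and
#' direction assignment.
#'
#' The `significant` flag defaults to the Sidak-corrected region p-value
#' (`sig_on = "sidak"`), which is the multiplicity control the region scan
#' needs over a dense track; set `sig_on = "slk"` to flag on the
#' uncorrected region p instead.
#'
#' @param records EWAS records (chrom, pos, p, beta_hat).
#' @param seed_p,max_gap region-growing parameters.
#' @param window smoothing window half-width (bp).
#' @param max_dist,bin_width ACF estimation parameters.
#' @param alpha significance level for the region call.
#' @param sig_on `"sidak"` (default) or `"slk"`.
#' @return data.frame of DMR records: chrom, start, end, n_cpgs, slk_p,
#'   sidak_p, direction, significant, members (list of `"chrom:pos"` keys).
#' @export
call_dmrs <- function(records, seed_p = 0.05, max_gap = 300, window = 300,
                      max_dist = 500, bin_width = 50, alpha = 0.05,
                      sig_on = c("sidak", "slk")) {
  sig_on <- match.arg(sig_on)
  o <- cpg_order(records$chrom, records$pos)
  records <- records[o, ]
  acf <- suppressWarnings(
    estimate_acf(records$p, records$chrom, records$pos, max_dist, bin_width))
  corrected <- slk_correct(records$p, records$chrom, records$pos, acf, window)
  regions <- find_regions(corrected, records$chrom, records$pos, seed_p,
                          max_gap)
  if (!nrow(regions)) return(data.frame())
  spans <- tapply(records$pos, records$chrom,
                  function(x) max(x) - min(x) + 1)
  total_bases <- sum(spans)
  regions$slk_p <- NA_real_; regions$sidak_p <- NA_real_
  regions$direction <- NA_character_
  keys <- paste(records$chrom, records$pos, sep = ":")
  member_keys <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    m <- regions$members[[i]]
    sc <- score_region(records$p[m], records$pos[m], acf, total_bases)
    regions$slk_p[i] <- sc$slk_p
    regions$sidak_p[i] <- sc$sidak_p
    regions$direction[i] <- region_direction(records$beta_hat[m])
    member_keys[[i]] <- keys[m]
  }
  regions$members <- I(member_keys)
  regions$significant <- if (sig_on == "sidak")
    regions$sidak_p < alpha else regions$slk_p < alpha
  attr(regions, "acf") <- acf
  regions[order(regions$slk_p), ]
}

#' Write DMR records as BED6+ and a TSV mirror
#'
#' BED output is 0-based half-open; the TSV keeps 1-based inclusive
#' coordinates with slk/Sidak p-values, CpG count and direction.
#'
#' @param dmrs DMR records from [call_dmrs()].
#' @param path output path (`.bed`; a `.tsv` twin is written alongside).
#' @export
write_dmrs <- function(dmrs, path) {
  if (nrow(dmrs)) {
    bed <- data.frame(dmrs$chrom, dmrs$start - 1L, dmrs$end,
                      sprintf("DMR%03d", seq_len(nrow(dmrs))),
                      0L, ".",
                      signif(dmrs$slk_p, 6), signif(dmrs$sidak_p, 6),
                      dmrs$n_cpgs, dmrs$direction)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    tsv <- dmrs[, c("chrom", "start", "end", "n_cpgs", "slk_p", "sidak_p",
                    "direction", "significant")]
    write.table(tsv, sub("\\.bed$", ".tsv", path), sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    file.create(path)
  }
  invisible(path)
}
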