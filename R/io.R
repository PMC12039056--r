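#' @importFrom stats as.formula binomial coef cor glm lm.wfit median na.omit
#'   optimize pbinom plogis pnorm pt qnorm quantile rbeta rbinom rnorm runif
#'   sd setNames vcov complete.cases fitted qbeta var
#' @importFrom utils read.delim write.table head
NULL

# chromosome ordering used throughout: chr1 < chr2 < ... < chr22 < chrX < chrY,
# anything else after, alphabetically
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(core))
  rank <- ifelse(!is.na(num), num,
                 ifelse(core == "X", 23L, ifelse(core == "Y", 24L, 25L)))
  order_key <- rank * 1e0
  order_key + match(chrom, sort(unique(chrom))) / 1e6
}

cpg_order <- function(chrom, pos) order(chrom_rank(chrom), pos)

#' Construct a CpG-by-sample methylation matrix
#'
#' Bundles a beta-value matrix (rows = CpGs, columns = samples) with the CpG
#' genomic coordinates (1-based positions). Rows are sorted by (chromosome,
#' position); missing observations are `NA` in `beta`.
#'
#' @param beta numeric matrix of methylation proportions in `[0, 1]`
#'   (`NA` = missing); column names are sample identifiers.
#' @param chrom character vector of chromosome names, one per row.
#' @param pos integer vector of 1-based CpG positions, one per row.
#' @return An object of class `meth_matrix`: a list with elements `beta`
#'   (matrix, rownames `"chrom:pos"`), `cpgs` (data.frame with `chrom`,
#'   `pos`) and `samples` (character).
#' @export
meth_matrix <- function(beta, chrom, pos) {
  beta <- as.matrix(beta)
  stopifnot(length(chrom) == nrow(beta), length(pos) == nrow(beta))
  if (is.null(colnames(beta))) stop("beta must have sample ids as column names")
  obs <- beta[!is.na(beta)]
  if (length(obs) && (any(obs < 0) || any(obs > 1)))
    stop("beta values must lie in [0, 1]")
  pos <- as.integer(pos)
  key <- paste(chrom, pos, sep = ":")
  if (anyDuplicated(key)) stop("duplicate CpG coordinates")
  o <- cpg_order(chrom, pos)
  beta <- beta[o, , drop = FALSE]
  chrom <- chrom[o]; pos <- pos[o]
  rownames(beta) <- paste(chrom, pos, sep = ":")
  structure(list(beta = beta,
                 cpgs = data.frame(chrom = chrom, pos = pos,
                                   stringsAsFactors = FALSE),
                 samples = colnames(beta)),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpGs x %d samples (%.2f%% missing)\n",
              nrow(x$beta), ncol(x$beta), 100 * mean(is.na(x$beta))))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$beta)

#' Subset a methylation matrix by CpG and/or sample
#' @param x a `meth_matrix`.
#' @param i CpG (row) index.
#' @param j sample (column) index.
#' @param ... ignored.
#' @export
`[.meth_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$beta))
  if (missing(j)) j <- seq_len(ncol(x$beta))
  meth_matrix(x$beta[i, j, drop = FALSE], x$cpgs$chrom[i], x$cpgs$pos[i])
}

#' M-values of a methylation matrix
#'
#' Returns `log2(beta / (1 - beta))` entrywise; `NA` where beta is missing.
#' @param x a `meth_matrix`.
#' @return numeric matrix of M-values with the same dimnames as `x$beta`.
#' @export
m_values <- function(x) {
  stopifnot(inherits(x, "meth_matrix"))
  b <- x$beta
  out <- matrix(NA_real_, nrow(b), ncol(b), dimnames = dimnames(b))
  ok <- !is.na(b)
  out[ok] <- beta_to_m(b[ok])
  out
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
}

#' Write / read a twin-cohort sample sheet (TSV)
#'
#' Columns: sample_id, pair_id, alt, age, sex, bmi, alcohol, hypertension,
#' diabetes. `sex` is stored as `woman` / `man`; the flags as 0/1.
#'
#' @param cohort data.frame with the columns above.
#' @param path output path.
#' @export
write_sample_sheet <- function(cohort, path) {
  cols <- c("sample_id", "pair_id", "alt", "age", "sex", "bmi", "alcohol",
            "hypertension", "diabetes")
  stopifnot(all(cols %in% names(cohort)))
  out <- cohort[, cols]
  for (nm in c("alt", "age", "bmi", "alcohol")) out[[nm]] <- fmt_num(out[[nm]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("sample_id", "pair_id", "alt", "age", "sex", "bmi", "alcohol",
            "hypertension", "diabetes")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  d$sample_id <- as.character(d$sample_id)
  d$pair_id <- as.character(d$pair_id)
  d$hypertension <- as.integer(d$hypertension)
  d$diabetes <- as.integer(d$diabetes)
  d
}

#' Write / read a beta matrix as TSV
#'
#' Rows are keyed `chrom:pos` in the first column (`cpg`); remaining columns
#' are samples. Missing observations are written as empty cells.
#'
#' @param x a `meth_matrix`.
#' @param path file path.
#' @export
write_beta_matrix <- function(x, path) {
  stopifnot(inherits(x, "meth_matrix"))
  b <- x$beta
  out <- data.frame(cpg = rownames(b), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(b))) out[[colnames(b)[j]]] <- fmt_num(b[, j])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  check.names = FALSE)
  if (names(d)[1] != "cpg") stop("beta matrix must start with a 'cpg' column")
  key <- strsplit(d$cpg, ":", fixed = TRUE)
  bad <- which(lengths(key) != 2)
  if (length(bad)) stop("malformed CpG key at data row ", bad[1], ": ", d$cpg[bad[1]])
  chrom <- vapply(key, `[`, "", 1)
  pos <- as.integer(vapply(key, `[`, "", 2))
  b <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(b)) stop("non-numeric beta entries")
  meth_matrix(b, chrom, pos)
}

#' Write / read CpG coordinates as BED3
#'
#' On disk BED is 0-based half-open; internally positions are 1-based, so a
#' CpG at internal position `p` is written as `(p - 1, p)`.
#'
#' @param x a `meth_matrix` (or data.frame with `chrom`, `pos`).
#' @param path file path.
#' @export
write_cpg_bed <- function(x, path) {
  cpgs <- if (inherits(x, "meth_matrix")) x$cpgs else x
  out <- data.frame(cpgs$chrom, cpgs$pos - 1L, cpgs$pos)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cpg_bed
#' @export
read_cpg_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("BED3 requires 3 columns")
  data.frame(chrom = d[[1]], pos = as.integer(d[[3]]), stringsAsFactors = FALSE)
}

#' Read a gene annotation BED into a GRanges
#'
#' BED6 (or BED4) with gene symbol in the name column; strand in column 6 if
#' present. Coordinates are converted from 0-based half-open to the 1-based
#' GRanges convention.
#'
#' @param path BED file path.
#' @return `GRanges` with metadata column `name`.
#' @export
read_gene_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 4) stop("gene BED requires at least 4 columns (name in col 4)")
  strand <- if (ncol(d) >= 6) d[[6]] else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = d[[1]],
    ranges = IRanges::IRanges(start = as.integer(d[[2]]) + 1L,
                              end = as.integer(d[[3]])),
    strand = strand)
  S4Vectors::mcols(gr)$name <- as.character(d[[4]])
  gr
}

#' Write a GRanges gene/TSS annotation as BED6
#' @param gr `GRanges` with a `name` metadata column.
#' @param path output path.
#' @export
write_gene_bed <- function(gr, path) {
  out <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L,
                    GenomicRanges::end(gr),
                    S4Vectors::mcols(gr)$name,
                    0L,
                    as.character(GenomicRanges::strand(gr)))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a GMT-like term-to-gene table
#'
#' Each line: term, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list mapping term to a character vector of genes.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, "", 1))
}

#' @rdname read_gmt
#' @param terms named list of gene vectors.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(nm) {
    paste(c(nm, "na", terms[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a planted ground-truth table (TSV)
#' @param truth data.frame with columns chrom, pos, role, effect.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$effect <- fmt_num(out$effect)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  d$effect[is.na(d$effect)] <- 0
  d
}
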