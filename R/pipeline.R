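# End-to-end orchestration: simulate (or ingest) -> qc -> ewas -> icefalcon
# -> dmr -> enrich, with a manifest of seeds and per-stage counts so reruns
# can be compared stage by stage. Every stage is also consumable standalone
# from the previous stage's files.

#' Pipeline configuration
#'
#' Per-module parameter blocks with defaults equal to the analysis values:
#' QC band 0.01/0.99 with at most 10 missing observations; 5 cell
#' composition components; EWAS alpha 0.05 (Bonferroni over tested CpGs);
#' AVR threshold 1.5; DMR seed p 0.05; matching ratio 3 with caliper 0.1.
#'
#' @param sim a [sim_config()] describing the synthetic cohort (ignored
#'   when `input_dir` points at existing fixtures).
#' @param input_dir optional directory of fixtures ([read_fixture()] layout)
#'   to ingest instead of simulating.
#' @param qc list: mean_low, mean_high, max_missing, k, t.
#' @param ewas an [ewas_config()].
#' @param icefalcon list: threshold, n_boot, max_cpgs (cap on the subset
#'   carried into causal inference).
#' @param dmr list: seed_p, max_gap, window, max_dist, bin_width, alpha,
#'   sig_on.
#' @param enrich list: n_terms, genome_size (NULL = synthetic track span),
#'   query_p (EWAS p cutoff for the query set).
#' @param seed global seed; stage sub-streams are derived by fixed offsets.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            input_dir = NULL,
                            qc = list(mean_low = 0.01, mean_high = 0.99,
                                      max_missing = 10, k = 5, t = 500),
                            ewas = ewas_config(),
                            icefalcon = list(threshold = 1.5, n_boot = 200,
                                             max_cpgs = 20),
                            dmr = list(seed_p = 0.05, max_gap = 300,
                                       window = 300, max_dist = 500,
                                       bin_width = 50, alpha = 0.05,
                                       sig_on = "sidak"),
                            enrich = list(n_terms = 20, genome_size = NULL,
                                          query_p = 0.05),
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created; stage outputs and
#'   `manifest.json` are written there).
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }

  ## ingest or simulate ------------------------------------------------------
  sim <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      for (f in c("samples.tsv", "beta.tsv")) {
        if (!file.exists(file.path(config$input_dir, f)))
          stop("missing input file: ", file.path(config$input_dir, f))
      }
      read_fixture(config$input_dir)
    } else {
      s <- simulate_cohort(config$sim)
      write_fixture(s$cohort, s$matrix, s$truth, file.path(out_dir, "input"))
      s
    }
  })
  manifest$stages$simulate <- list(
    n_pairs = length(unique(sim$cohort$pair_id)),
    n_samples = nrow(sim$cohort), n_cpgs = nrow(sim$matrix$beta),
    beta_fingerprint = signif(sum(sim$matrix$beta, na.rm = TRUE), 12))

  ## qc ----------------------------------------------------------------------
  qc <- stage("qc", {
    fl <- filter_cpgs(sim$matrix, config$qc$mean_low, config$qc$mean_high,
                      config$qc$max_missing)
    comp <- refactor_components(fl$matrix, config$qc$k,
                                min(config$qc$t, nrow(fl$matrix$beta) - 1))
    write_qc_report(fl$report, file.path(out_dir, "qc"))
    list(matrix = fl$matrix, report = fl$report, components = comp)
  })
  manifest$stages$qc <- list(n_retained = qc$report$n_retained,
                             n_removed = qc$report$n_input -
                               qc$report$n_retained)

  ## ewas --------------------------------------------------------------------
  genes <- stage("annotation", simulate_genes(qc$matrix,
                                              seed = config$seed + 11L))
  ewas <- stage("ewas", {
    rec <- run_ewas(qc$matrix, sim$cohort, qc$components, config$ewas)
    rec <- annotate_nearest_gene(rec, genes)
    write_ewas(rec, file.path(out_dir, "ewas.tsv"))
    rec
  })
  manifest$stages$ewas <- list(
    n_tests = attr(ewas, "n_tests"),
    threshold = attr(ewas, "threshold"),
    n_significant = sum(ewas$significant))

  ## icefalcon ---------------------------------------------------------------
  ice <- stage("icefalcon", {
    sig <- ewas[ewas$significant, ]
    if (nrow(sig) == 0) sig <- head(ewas, 5)  # fall back to the top signals
    sig <- head(sig, config$icefalcon$max_cpgs)
    keys <- paste(sig$chrom, sig$pos, sep = ":")
    rec <- run_both_directions(sim$cohort, qc$matrix, keys,
                               covariates = config$ewas$covariates,
                               threshold = config$icefalcon$threshold,
                               n_boot = config$icefalcon$n_boot,
                               seed = config$seed + 23L)
    write_icefalcon(rec, file.path(out_dir, "icefalcon.tsv"))
    rec
  })
  manifest$stages$icefalcon <- list(
    n_records = nrow(ice),
    n_causal_m_to_alt = sum(ice$direction == "m_to_alt" &
                              ice$verdict == "causal"))

  ## dmr ---------------------------------------------------------------------
  dmrs <- stage("dmr", {
    d <- call_dmrs(ewas, config$dmr$seed_p, config$dmr$max_gap,
                   config$dmr$window, config$dmr$max_dist,
                   config$dmr$bin_width, config$dmr$alpha, config$dmr$sig_on)
    write_dmrs(d, file.path(out_dir, "dmrs.bed"))
    d
  })
  manifest$stages$dmr <- list(
    n_candidates = nrow(dmrs),
    n_significant = if (nrow(dmrs)) sum(dmrs$significant) else 0L)

  ## enrich ------------------------------------------------------------------
  enr <- stage("enrich", {
    terms <- simulate_terms(genes, config$enrich$n_terms,
                            seed = config$seed + 31L)
    write_gmt(terms, file.path(out_dir, "terms.gmt"))
    write_gene_bed(genes, file.path(out_dir, "genes.bed"))
    doms <- build_domains(genes)
    qry <- ewas[ewas$p < config$enrich$query_p, ]
    gsize <- config$enrich$genome_size
    if (is.null(gsize)) {
      spans <- tapply(qc$matrix$cpgs$pos, qc$matrix$cpgs$chrom,
                      function(x) max(x) + 1000000)
      gsize <- sum(spans)
    }
    if (nrow(qry) == 0) data.frame() else {
      q <- GenomicRanges::GRanges(qry$chrom,
                                  IRanges::IRanges(qry$pos, qry$pos))
      e <- binomial_enrichment(q, doms, terms, gsize)
      write_enrichment(e, file.path(out_dir, "enrichment.tsv"))
      e
    }
  })
  manifest$stages$enrich <- list(
    n_terms = nrow(enr),
    n_significant = if (nrow(enr)) sum(enr$p_bonferroni < 0.05) else 0L)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, qc = qc, genes = genes, ewas = ewas, ice = ice,
                 dmrs = dmrs, enrich = enr, manifest = manifest))
}
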