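#' Pipeline configuration
#'
#' Assembles (and validates) the settings for a full [run_pipeline()] run.
#' Either `counts`/`annotation`/`samples` paths or a `simulate` block must
#' be given.
#'
#' @param counts,annotation,samples input TSV paths (ignored when
#'   simulating).
#' @param simulate `NULL`, or a list of [sim_config()] arguments.
#' @param normalization `"tmm"` (default) or `"tpm"`.
#' @param alpha FDR threshold for significance calls.
#' @param n_factors `"auto"` or an integer.
#' @param account_covariates metadata columns (plus `"H_s"`) to run
#'   [account()] on.
#' @param downsample `NULL`, or a target depth / `"auto"` to also compute
#'   depth-equalized diversity.
#' @param factors_file optional externally computed factor TSV; overrides
#'   internal inference.
#' @param seed integer seed for all stochastic stages.
#' @param out_dir output directory for stage TSVs and the JSON report.
#' @return object of class `txdiv_pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, annotation = NULL, samples = NULL,
                            simulate = NULL,
                            normalization = c("tmm", "tpm"),
                            alpha = 0.05,
                            n_factors = "auto",
                            account_covariates = "H_s",
                            downsample = NULL,
                            factors_file = NULL,
                            seed = 1L,
                            out_dir = tempfile("txdiv_run_")) {
  normalization <- match.arg(normalization)
  assert_scalar_num(alpha, "alpha", lo = 1e-12, hi = 1 - 1e-12)
  if (is.null(simulate) && (is.null(counts) || is.null(annotation)))
    stopf("either input paths (counts + annotation) or a simulate block is required")
  structure(list(counts = counts, annotation = annotation, samples = samples,
                 simulate = simulate, normalization = normalization,
                 alpha = alpha, n_factors = n_factors,
                 account_covariates = account_covariates,
                 downsample = downsample, factors_file = factors_file,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "txdiv_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are the arguments of [pipeline_config()]; a `simulate`
#' mapping holds [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return `txdiv_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full transcriptome-diversity analysis
#'
#' Executes, in order: (optional) simulation, normalization, gene filtering,
#' diversity, gene-wise association with diversity, PCA and query-variance
#' decomposition, latent-factor inference, factor--diversity correlations,
#' and variance accounting for each requested covariate. All intermediate
#' tables are written as TSV under `config$out_dir` together with a JSON
#' report; the run is deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()] (or the path to a YAML file for
#'   [read_pipeline_config()]).
#' @param quiet suppress per-stage progress messages.
#' @return the report, invisibly: a list mirroring `report.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "txdiv_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  tsv <- function(df, name) {
    write.table(df, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
    name
  }
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(code, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    r
  }

  inputs <- stage("input", {
    if (!is.null(config$simulate)) {
      sim_args <- modifyList(config$simulate, list(seed = config$seed))
      sim <- simulate_dataset(do.call(sim_config, sim_args))
      write_dataset(sim, file.path(config$out_dir, "simulated"))
      list(counts = sim$counts, annotation = sim$annotation,
           samples = sim$samples, truth = sim$truth)
    } else {
      counts <- read_count_matrix(config$counts)
      ann <- read_annotation(config$annotation)
      check_ids_match(rownames(counts), ann$gene_id, "annotation gene")
      smp <- if (!is.null(config$samples)) read_samples(config$samples) else
        data.frame(sample_id = colnames(counts), stringsAsFactors = FALSE)
      check_ids_match(colnames(counts), smp$sample_id, "metadata sample")
      list(counts = counts, annotation = ann, samples = smp, truth = NULL)
    }
  })
  # fail on missing covariate columns before any compute
  meta_cols <- setdiff(config$account_covariates, "H_s")
  missing_cols <- setdiff(meta_cols, names(inputs$samples))
  if (length(missing_cols))
    stopf("metadata column(s) not found: %s", paste(missing_cols, collapse = ", "))

  norm <- stage("normalize", {
    if (config$normalization == "tmm") {
      tmm <- compute_tmm(inputs$counts)
      tsv(data.frame(sample_id = names(tmm$factors), factor = tmm$factors),
          "tmm_factors.tsv")
      tmm$expression
    } else compute_tpm(inputs$counts, inputs$annotation)
  })

  keep <- stage("filter", {
    if (config$normalization == "tmm") filter_genes(norm)
    else {
      # gene filter is defined on the TMM scale regardless of analysis unit
      filter_genes(compute_tmm(inputs$counts)$expression)
    }
  })
  expr <- norm[keep, , drop = FALSE]
  attr(expr, "unit") <- attr(norm, "unit")

  div <- stage("diversity", {
    d <- transcriptome_diversity(inputs$counts, inputs$annotation)
    tsv(d, "diversity.tsv")
    d
  })

  down <- NULL
  if (!is.null(config$downsample)) {
    down <- stage("downsample", {
      d <- downsample_diversity(inputs$counts, inputs$annotation,
                                target_depth = config$downsample,
                                seed = config$seed)
      tsv(d, "diversity_downsampled.tsv")
      d
    })
  }

  assoc <- stage("associate", {
    a <- associate(expr, div$H_s)
    tsv(a, "associations.tsv")
    a
  })
  assoc_summary <- summarize_associations(assoc, alpha = config$alpha)
  tsv(assoc_summary, "association_summary.tsv")
  attr_reg <- stage("attributes", {
    r <- attribute_regression(assoc, inputs$annotation)
    tsv(r, "attribute_regression.tsv")
    r
  })

  pca <- stage("pca", expr_pca(expr))
  qv <- query_variance(pca, div$H_s)
  pc_tab <- pc_correlation_table(pca, div$H_s)
  tsv(pc_tab, "pc_correlations.tsv")

  factors <- stage("factors", {
    f <- if (!is.null(config$factors_file))
      read_factors(config$factors_file, sample_ids = colnames(expr))
    else infer_factors(expr, n_factors = config$n_factors)
    write_factors(f, file.path(config$out_dir, "factors.tsv"))
    f
  })
  fac_cor <- factor_covariate_correlations(factors, div$H_s, pca = pca)
  tsv(fac_cor, "factor_correlations.tsv")

  accounting <- stage("account", {
    covs <- config$account_covariates
    res <- lapply(covs, function(cn) {
      v <- if (cn == "H_s") div$H_s else
        inputs$samples[[cn]][match(colnames(expr), inputs$samples$sample_id)]
      account(expr, factors, v, covariate_name = cn, pca = pca)
    })
    names(res) <- covs
    tsv(data.frame(covariate = covs,
                   median_r1_sq = vapply(res, `[[`, 1, "median_r1_sq"),
                   median_r2_sq = vapply(res, `[[`, 1, "median_r2_sq"),
                   delta_median = vapply(res, `[[`, 1, "delta_median"),
                   accounted_fraction = vapply(res, `[[`, 1, "accounted_fraction"),
                   mw_p = vapply(res, `[[`, 1, "mw_p")),
        "accounting.tsv")
    res
  })

  report <- list(
    seed = config$seed,
    normalization = config$normalization,
    n_genes_total = nrow(inputs$counts),
    n_genes_kept = sum(keep),
    n_samples = ncol(inputs$counts),
    diversity = list(median_H_s = median(div$H_s),
                     min_H_s = min(div$H_s), max_H_s = max(div$H_s)),
    downsampled_spearman = if (!is.null(down))
      spearman(div$H_s, down$H_s)$rho else NULL,
    association = as.list(assoc_summary),
    v_total_H_s = qv$v_total,
    best_pc = list(pc = attr(pc_tab, "best_pc"),
                   rho = attr(pc_tab, "best_rho")),
    n_factors = ncol(factors),
    n_factors_significant = sum(fac_cor$significant),
    accounting = lapply(accounting, function(a)
      a[c("median_r1_sq", "median_r2_sq", "delta_median",
          "accounted_fraction", "mw_p")])
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  say("report written to %s", file.path(config$out_dir, "report.json"))
  invisible(report)
}
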