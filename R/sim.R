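#' Simulation configuration
#'
#' Bundles and validates the parameters of the compositional RNA-seq
#' simulator. Defaults describe a bulk RNA-seq cohort of 200 samples by 2000
#' genes sequenced at about one million reads: log-normal baseline
#' abundances, per-sample evenness exponents spanning clearly distinct
#' diversity levels, mild depth variation negatively coupled to the evenness
#' exponent (so deeper libraries are more diverse), and sex/batch
#' fold-changes on a 10\% gene subset.
#'
#' @param n_genes,n_samples matrix dimensions (n_genes >= 2).
#' @param abundance_sigma SD of the per-gene log baseline abundance.
#' @param tau_range bounds of the per-sample evenness exponent tau; higher
#'   tau sharpens the abundance profile and lowers diversity.
#' @param depth_log_mean,depth_log_sd mean and SD of natural-log library
#'   size.
#' @param depth_tau_corr Gaussian-copula correlation in \[-1, 1\] between tau
#'   and log depth; negative values make deep libraries more diverse.
#' @param length_range integer bounds (bp) for effective gene lengths.
#' @param gc_beta_params shape parameters of the Beta distribution of GC
#'   fraction.
#' @param sex_effect_sd,batch_effect_sd SDs of the log2 fold-changes applied
#'   to affected genes for the sex and batch covariates.
#' @param affected_fraction fraction of genes carrying each covariate effect.
#' @param seed integer; all randomness flows from this one seed.
#' @return object of class `txdiv_sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_samples = 200L,
                       abundance_sigma = 1.5,
                       tau_range = c(0.6, 1.4),
                       depth_log_mean = log(1e6), depth_log_sd = 0.1,
                       depth_tau_corr = -0.3,
                       length_range = c(200L, 10000L),
                       gc_beta_params = c(5, 5),
                       sex_effect_sd = 0.3, batch_effect_sd = 0.2,
                       affected_fraction = 0.1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              abundance_sigma = abundance_sigma, tau_range = tau_range,
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              depth_tau_corr = depth_tau_corr,
              length_range = as.integer(length_range),
              gc_beta_params = gc_beta_params,
              sex_effect_sd = sex_effect_sd, batch_effect_sd = batch_effect_sd,
              affected_fraction = affected_fraction, seed = as.integer(seed))
  if (cfg$n_genes < 2L) stopf("n_genes must be >= 2")
  if (cfg$n_samples < 1L) stopf("n_samples must be >= 1")
  assert_scalar_num(cfg$abundance_sigma, "abundance_sigma", lo = 1e-12)
  if (length(cfg$tau_range) != 2L || any(cfg$tau_range <= 0) ||
      cfg$tau_range[1L] > cfg$tau_range[2L])
    stopf("tau_range must be an increasing pair of positive reals")
  assert_scalar_num(cfg$depth_tau_corr, "depth_tau_corr", lo = -1, hi = 1)
  if (length(cfg$length_range) != 2L || cfg$length_range[1L] < 1L ||
      cfg$length_range[1L] > cfg$length_range[2L])
    stopf("length_range must be an increasing pair of integers >= 1")
  if (length(cfg$gc_beta_params) != 2L || any(cfg$gc_beta_params <= 0))
    stopf("gc_beta_params must be two positive shapes")
  if (cfg$sex_effect_sd < 0 || cfg$batch_effect_sd < 0)
    stopf("effect SDs must be non-negative")
  assert_scalar_num(cfg$affected_fraction, "affected_fraction", lo = 0, hi = 1)
  assert_scalar_num(cfg$depth_log_sd, "depth_log_sd", lo = 0)
  structure(cfg, class = "txdiv_sim_config")
}

#' Sharpen or flatten an abundance profile
#'
#' Raises a baseline molar abundance vector to the power `tau` and closes it
#' to sum one: `m_i` proportional to `a_i^tau`. `tau = 1` returns the
#' baseline, `tau -> 0` flattens towards uniform, `tau > 1` concentrates
#' mass on abundant genes. For any non-uniform baseline the Shannon entropy
#' of the result is non-increasing in tau, which is what lets the simulator
#' plant a known per-sample diversity ordering.
#'
#' @param a strictly positive abundance vector summing to 1.
#' @param tau positive evenness exponent.
#' @return probability vector `m` with `m_i` proportional to `a_i^tau`.
#' @export
evenness_profile <- function(a, tau) {
  assert_scalar_num(tau, "tau", lo = .Machine$double.xmin)
  if (tau <= 0) stopf("tau must be positive")
  if (anyNA(a) || any(a <= 0)) stopf("baseline abundances must be strictly positive")
  if (abs(sum(a) - 1) > 1e-6) stopf("baseline abundances must sum to 1")
  # work in log space so large tau cannot underflow all entries at once
  lw <- tau * log(a)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Simulate a count matrix with planted diversity structure
#'
#' Draws a gene-by-sample read count matrix from the generative model:
#' per-gene baseline molar abundances are log-normal; each sample s has an
#' evenness exponent `tau_s` (uniform on `tau_range`) giving molar profile
#' `m_s = a^tau_s` (closed to 1); read probabilities are proportional to
#' `m_s * length * 2^(covariate log2 fold-changes)`, renormalized; counts
#' are multinomial with the sample's library size. `tau` and log library
#' size are drawn jointly from a Gaussian copula with correlation
#' `depth_tau_corr`. Everything is reproducible from `config$seed`.
#'
#' The returned truth records, per gene, the analytic expected sign of the
#' association between its expression and transcriptome diversity:
#' `sign(-(log a_i - sum_j a_j log a_j))` -- genes below the
#' abundance-weighted mean log-abundance gain relative expression as
#' diversity rises, so with right-skewed log abundances most signs are
#' positive.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (integer matrix), `annotation`
#'   (gene_id / effective_length / gc_fraction), `samples`
#'   (sample_id / sex / batch / library_size), `truth` (list: per-sample
#'   `tau`, `library_size`; per-gene `baseline_abundance`, `lengths`, `gc`,
#'   `effect_log2fc` (sex, batch columns), `expected_assoc_sign`), and the
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "txdiv_sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ng <- config$n_genes; ns <- config$n_samples
  gene_ids <- sprintf("g%05d", seq_len(ng))
  sample_ids <- sprintf("s%04d", seq_len(ns))

  log_a <- rnorm(ng, 0, config$abundance_sigma)
  a <- exp(log_a - max(log_a)); a <- a / sum(a)
  lengths <- sample(seq(config$length_range[1L], config$length_range[2L]),
                    ng, replace = TRUE)
  gc <- rbeta(ng, config$gc_beta_params[1L], config$gc_beta_params[2L])

  # tau and log depth from a Gaussian copula with the configured correlation
  z1 <- rnorm(ns)
  z2 <- config$depth_tau_corr * z1 +
    sqrt(1 - config$depth_tau_corr^2) * rnorm(ns)
  tau <- config$tau_range[1L] +
    diff(config$tau_range) * pnorm(z1)
  lib <- pmax(1, round(exp(config$depth_log_mean + config$depth_log_sd * z2)))
  if (any(!is.finite(lib)) || any(lib < 1)) stopf("invalid library size drawn")

  sex <- sample(c("female", "male"), ns, replace = TRUE)
  batch <- sample(c("b1", "b2"), ns, replace = TRUE)
  fc_sex <- ifelse(runif(ng) < config$affected_fraction,
                   rnorm(ng, 0, config$sex_effect_sd), 0)
  fc_batch <- ifelse(runif(ng) < config$affected_fraction,
                     rnorm(ng, 0, config$batch_effect_sd), 0)
  if (config$sex_effect_sd == 0) fc_sex[] <- 0
  if (config$batch_effect_sd == 0) fc_batch[] <- 0

  counts <- matrix(0, ng, ns, dimnames = list(gene_ids, sample_ids))
  for (s in seq_len(ns)) {
    m <- evenness_profile(a, tau[s])
    w <- m * lengths *
      2^(fc_sex * (sex[s] == "female") + fc_batch * (batch[s] == "b2"))
    counts[, s] <- rmultinom(1L, size = lib[s], prob = w / sum(w))
  }

  centered_log_a <- log(a) - sum(a * log(a))
  truth <- list(tau = stats::setNames(tau, sample_ids),
                library_size = stats::setNames(as.numeric(lib), sample_ids),
                baseline_abundance = stats::setNames(a, gene_ids),
                lengths = stats::setNames(lengths, gene_ids),
                gc = stats::setNames(gc, gene_ids),
                sex = stats::setNames(sex, sample_ids),
                batch = stats::setNames(batch, sample_ids),
                effect_log2fc = data.frame(gene_id = gene_ids, sex = fc_sex,
                                           batch = fc_batch,
                                           stringsAsFactors = FALSE),
                expected_assoc_sign = stats::setNames(
                  as.integer(sign(-centered_log_a)), gene_ids))
  list(counts = counts,
       annotation = data.frame(gene_id = gene_ids,
                               effective_length = lengths,
                               gc_fraction = gc, stringsAsFactors = FALSE),
       samples = data.frame(sample_id = sample_ids, sex = sex, batch = batch,
                            library_size = as.numeric(lib),
                            stringsAsFactors = FALSE),
       truth = truth,
       config = config)
}

#' Write a simulated dataset to a directory of TSV files
#'
#' Emits `counts.tsv`, `annotation.tsv`, `samples.tsv` and two truth tables
#' (`truth_samples.tsv`, `truth_genes.tsv`) in the package's standard
#' dialects, ready to be fed back through the readers.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"))
  tsv(sim$annotation, "annotation.tsv")
  tsv(sim$samples, "samples.tsv")
  tsv(data.frame(sample_id = names(sim$truth$tau),
                 tau = sim$truth$tau,
                 library_size = sim$truth$library_size,
                 stringsAsFactors = FALSE), "truth_samples.tsv")
  tsv(data.frame(gene_id = names(sim$truth$baseline_abundance),
                 baseline_abundance = sim$truth$baseline_abundance,
                 effect_log2fc_sex = sim$truth$effect_log2fc$sex,
                 effect_log2fc_batch = sim$truth$effect_log2fc$batch,
                 expected_assoc_sign = sim$truth$expected_assoc_sign,
                 stringsAsFactors = FALSE), "truth_genes.tsv")
  invisible(dir)
}
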