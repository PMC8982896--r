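# small random count matrix with valid dimnames
rand_counts <- function(n_genes, n_samples, seed, mean_count = 30) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, rexp(n_genes, 1 / mean_count)),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "double"
  m
}

# the standard synthetic study: 2000 genes x 200 samples at ~1e6 reads,
# generated once per session and shared across test files
std_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 11L) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_dataset(sim_config(seed = seed))
    cache[[key]]
  }
})

# derived TMM expression for the standard study, filtered, cached alongside
std_expr <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 11L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      sim <- std_sim(seed)
      tmm <- compute_tmm(sim$counts)
      keep <- filter_genes(tmm$expression)
      e <- tmm$expression[keep, , drop = FALSE]
      attr(e, "unit") <- "tmm_cpm"
      cache[[key]] <- e
    }
    cache[[key]]
  }
})
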