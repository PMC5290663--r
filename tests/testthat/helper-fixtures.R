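# toy dataset builders used across test files

# one metabolite, explicit batches/values; detected wherever value is finite
toy_dataset <- function(values_by_batch, qc_per_batch = 0L) {
  batches <- names(values_by_batch)
  vals <- unlist(values_by_batch, use.names = FALSE)
  n <- length(vals)
  sample_ids <- sprintf("S%02d", seq_len(n))
  batch <- rep(batches, lengths(values_by_batch))
  run_order <- unlist(lapply(lengths(values_by_batch), seq_len), use.names = FALSE)
  m <- abundance_matrix(matrix(vals, nrow = 1,
                               dimnames = list("met1", sample_ids)))
  ann <- sample_annotation(data.frame(
    sample_id = sample_ids, batch = batch, run_order = run_order,
    sample_class = "analytical", stringsAsFactors = FALSE))
  list(matrix = m, annotation = ann)
}

# two-batch QC-only dataset with a known additive shift in batch 2;
# optionally gaussian noise
shifted_qc_dataset <- function(n_qc = 3L, base = 18, shift = 2, noise_sd = 0,
                               n_metab = 1L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_qc
  vals <- matrix(base, nrow = n_metab, ncol = n)
  vals[, (n_qc + 1L):n] <- vals[, (n_qc + 1L):n] + shift
  if (noise_sd > 0) vals <- vals + matrix(rnorm(n_metab * n, 0, noise_sd), n_metab)
  dimnames(vals) <- list(sprintf("met%d", seq_len(n_metab)),
                         sprintf("S%02d", seq_len(n)))
  m <- abundance_matrix(vals)
  ann <- sample_annotation(data.frame(
    sample_id = colnames(vals),
    batch = rep(c("b1", "b2"), each = n_qc),
    run_order = rep(seq_len(n_qc), 2L),
    sample_class = "qc", stringsAsFactors = FALSE))
  list(matrix = m, annotation = ann)
}

# small simulated experiment for property tests
small_sim <- function(n_metabolites = 40L, n_rounds = 3L, ...) {
  sim_config(n_metabolites = n_metabolites, n_rounds = n_rounds, ...)
}
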