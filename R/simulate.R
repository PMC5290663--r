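#' Configuration for the GC/MS experiment simulator
#'
#' Defaults reproduce the benchmark design this package is validated
#' against: 150 metabolites over 20 batches of 24 analytical + 3 QC samples
#' (480 analytical, 60 QC). Per-metabolite mean abundances are
#' `alpha_m ~ N(alpha_mean, alpha_sd^2)` on the log2 scale; each analytical
#' sample carries a phenotype `v_i ~ N(0, pheno_sd^2)` whose association
#' with metabolite m is `beta_m ~ N(0, beta_sd^2)`; measurement noise is
#' `N(0, (noise_cv * alpha_m)^2)`; per-(metabolite, batch) effects are
#' `N(0, batch_effect_sd^2)`; and batch detection thresholds span
#' `[threshold_low, threshold_high]` in `n_batches` equal increments,
#' randomly permuted onto batches each round. `alpha_m`, `beta_m` and `v_i`
#' are drawn once from `seed_constants` and held constant across rounds;
#' round-level noise comes from a stream deterministic in
#' `(seed_rounds, round_index)`.
#'
#' @param n_metabolites,n_batches,analytical_per_batch,qc_per_batch design counts.
#' @param alpha_mean,alpha_sd distribution of per-metabolite mean log2 abundance.
#' @param pheno_sd phenotype standard deviation.
#' @param beta_sd standard deviation of per-metabolite phenotype effects.
#' @param noise_cv coefficient of variation of measurement noise (fraction of
#'   `alpha_m`), in `(0, 1)`.
#' @param batch_effect_sd standard deviation of additive batch effects.
#' @param threshold_low,threshold_high detection-threshold range (log2 scale).
#' @param n_rounds number of simulation rounds the configuration describes.
#' @param seed_constants,seed_rounds integer seeds for the two streams.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_metabolites = 150L, n_batches = 20L,
                       analytical_per_batch = 24L, qc_per_batch = 3L,
                       alpha_mean = 18, alpha_sd = 2,
                       pheno_sd = 1, beta_sd = 1, noise_cv = 0.03,
                       batch_effect_sd = 2,
                       threshold_low = 12.5, threshold_high = 15,
                       n_rounds = 1000L,
                       seed_constants = 20L, seed_rounds = 400L) {
  cfg <- list(n_metabolites = as.integer(n_metabolites),
              n_batches = as.integer(n_batches),
              analytical_per_batch = as.integer(analytical_per_batch),
              qc_per_batch = as.integer(qc_per_batch),
              alpha_mean = alpha_mean, alpha_sd = alpha_sd,
              pheno_sd = pheno_sd, beta_sd = beta_sd, noise_cv = noise_cv,
              batch_effect_sd = batch_effect_sd,
              threshold_low = threshold_low, threshold_high = threshold_high,
              n_rounds = as.integer(n_rounds),
              seed_constants = as.integer(seed_constants),
              seed_rounds = as.integer(seed_rounds))
  with(cfg, {
    stopifnot(n_metabolites > 0L, n_batches > 0L, analytical_per_batch > 0L,
              qc_per_batch > 0L, noise_cv >= 0, noise_cv < 1,
              alpha_sd >= 0, batch_effect_sd >= 0,
              threshold_low <= threshold_high, n_rounds > 0L)
  })
  class(cfg) <- "sim_config"
  cfg
}

# run code with an isolated RNG state, restoring the caller's stream
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# constants held fixed across rounds: alpha_m, v_i, beta_m (drawn in this order)
.sim_constants <- function(cfg) {
  n_analytical <- cfg$n_batches * cfg$analytical_per_batch
  .with_seed(cfg$seed_constants, {
    alpha_m <- stats::rnorm(cfg$n_metabolites, cfg$alpha_mean, cfg$alpha_sd)
    v_i <- stats::rnorm(n_analytical, 0, cfg$pheno_sd)
    beta_m <- stats::rnorm(cfg$n_metabolites, 0, cfg$beta_sd)
    list(alpha_m = alpha_m, v_i = v_i, beta_m = beta_m)
  })
}

.round_seed <- function(cfg, round_index)
  as.integer((as.double(cfg$seed_rounds) + as.double(round_index) * 1000003) %% 2147483647)

#' Simulate one round of a batched GC/MS experiment
#'
#' Generates QC abundances `alpha_m + noise` and analytical abundances
#' `alpha_m + beta_m * v_i + noise`, adds per-(metabolite, batch) effects
#' shared by QC and analytical samples of the batch, then applies the
#' batch's detection threshold: every value below it (for any metabolite)
#' is marked undetected. Within each batch the run order places one QC at
#' the start, middle and end, with analytical samples between. The returned
#' truth object retains all latent quantities, the pre-batch-effect values,
#' and the true per-metabolite RSDs needed for evaluation.
#'
#' @param cfg a [sim_config()].
#' @param round_index round number in `[1, cfg$n_rounds]`.
#' @return list with `matrix` ([abundance_matrix()]), `annotation`
#'   ([sample_annotation()] with a `phenotype` column, `NA` for QCs), and
#'   `truth` (class `simulation_truth`).
#' @export
simulate_experiment <- function(cfg, round_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"),
            round_index >= 1L, round_index <= cfg$n_rounds)
  M <- cfg$n_metabolites; K <- cfg$n_batches
  nA <- cfg$analytical_per_batch; nQ <- cfg$qc_per_batch
  NA_tot <- K * nA; NQ_tot <- K * nQ
  const <- .sim_constants(cfg)

  rnd <- .with_seed(.round_seed(cfg, round_index), {
    eps_qc <- matrix(stats::rnorm(M * NQ_tot, 0, cfg$noise_cv * const$alpha_m),
                     nrow = M)
    eps_an <- matrix(stats::rnorm(M * NA_tot, 0, cfg$noise_cv * const$alpha_m),
                     nrow = M)
    b_mk <- matrix(stats::rnorm(M * K, 0, cfg$batch_effect_sd), nrow = M)
    thr_levels <- if (is.finite(cfg$threshold_low) || is.finite(cfg$threshold_high))
      seq(cfg$threshold_low, cfg$threshold_high, length.out = K)
    else rep(cfg$threshold_low, K)
    thr_batch <- sample(thr_levels, K, replace = FALSE)
    list(eps_qc = eps_qc, eps_an = eps_an, b_mk = b_mk, thr_batch = thr_batch)
  })

  batch_ids <- sprintf("B%02d", seq_len(K))
  qc_pre <- const$alpha_m + rnd$eps_qc                      # z_jm = alpha_m + eps
  an_pre <- const$alpha_m + outer(const$beta_m, const$v_i) + rnd$eps_an

  # column layout: batch by batch, QC columns first then analytical;
  # run order interleaves them (QC at start / middle / end of the batch)
  qc_cols <- matrix(seq_len(NQ_tot), nrow = nQ)             # per-batch QC index
  an_cols <- matrix(seq_len(NA_tot), nrow = nA)
  sample_ids <- character(NQ_tot + NA_tot)
  batch_of <- character(NQ_tot + NA_tot)
  class_of <- character(NQ_tot + NA_tot)
  run_of <- integer(NQ_tot + NA_tot)
  pheno <- rep(NA_real_, NQ_tot + NA_tot)
  pre <- matrix(NA_real_, nrow = M, ncol = NQ_tot + NA_tot)
  vals <- matrix(NA_real_, nrow = M, ncol = NQ_tot + NA_tot)
  n_per_batch <- nQ + nA
  qc_pos <- unique(round(seq(1L, n_per_batch, length.out = nQ)))
  col <- 0L
  for (k in seq_len(K)) {
    ords <- seq_len(n_per_batch)
    qc_at <- qc_pos
    an_at <- setdiff(ords, qc_at)
    for (j in seq_len(nQ)) {
      col <- col + 1L
      idx <- qc_cols[j, k]
      sample_ids[col] <- sprintf("%s_QC%d", batch_ids[k], j)
      batch_of[col] <- batch_ids[k]; class_of[col] <- "qc"
      run_of[col] <- qc_at[j]
      pre[, col] <- qc_pre[, idx]
    }
    for (j in seq_len(nA)) {
      col <- col + 1L
      idx <- an_cols[j, k]
      sample_ids[col] <- sprintf("%s_S%02d", batch_ids[k], j)
      batch_of[col] <- batch_ids[k]; class_of[col] <- "analytical"
      run_of[col] <- an_at[j]
      pre[, col] <- an_pre[, idx]
      pheno[col] <- const$v_i[idx]
    }
    bcols <- (col - n_per_batch + 1L):col
    vals[, bcols] <- pre[, bcols] + rnd$b_mk[, k]
  }
  thr_by_col <- rnd$thr_batch[match(batch_of, batch_ids)]
  detected <- sweep(vals, 2L, thr_by_col, ">=")

  dimnames(vals) <- dimnames(detected) <- dimnames(pre) <-
    list(sprintf("M%03d", seq_len(M)), sample_ids)
  m <- abundance_matrix(vals, detected)
  ann <- sample_annotation(data.frame(
    sample_id = sample_ids, batch = batch_of, run_order = run_of,
    sample_class = class_of, phenotype = pheno, stringsAsFactors = FALSE))

  is_q <- class_of == "qc"
  truth <- structure(list(
    alpha_m = stats::setNames(const$alpha_m, rownames(vals)),
    beta_m = stats::setNames(const$beta_m, rownames(vals)),
    v_i = stats::setNames(pheno[!is_q], sample_ids[!is_q]),
    b_mk = matrix(rnd$b_mk, nrow = M,
                  dimnames = list(rownames(vals), batch_ids)),
    thresholds = stats::setNames(rnd$thr_batch, batch_ids),
    pre_batch = pre,
    true_rsd_qc = apply(pre[, is_q, drop = FALSE], 1L, rsd),
    true_rsd_analytical = apply(pre[, !is_q, drop = FALSE], 1L, rsd),
    round_index = as.integer(round_index), config = cfg),
    class = "simulation_truth")
  list(matrix = m, annotation = ann, truth = truth)
}

#' Missingness bin labels used throughout the evaluation
#'
#' Exact zero is its own bin; positive fractions fall in 5%-wide
#' left-open/right-closed bins `(0,5%], (5,10%], ...` up to 80%; above 80%
#' the metabolite is excluded from analysis.
#'
#' @param fraction undetected fraction(s) in `[0, 1]`.
#' @return character vector of bin labels (`">80%"` marks exclusion).
#' @export
missingness_bin <- function(fraction) {
  lab <- character(length(fraction))
  lab[fraction == 0] <- "0"
  pos <- fraction > 0 & fraction <= 0.8
  up <- ceiling(fraction[pos] * 20) * 5          # right edge in percent
  lab[pos] <- sprintf("%d-%d%%", up - 5L, up)
  lab[fraction > 0.8] <- ">80%"
  lab
}

#' Per-metabolite undetected fraction and missingness bin
#'
#' @param m an [abundance_matrix()] (typically a simulated round).
#' @return data.frame with `metabolite_id`, `undetected_fraction`, `bin`,
#'   and `excluded` (`TRUE` above 80% undetected).
#' @export
truncation_profile <- function(m) {
  frac <- 1 - rowMeans(m$detected)
  data.frame(metabolite_id = m$metabolite_ids,
             undetected_fraction = frac,
             bin = missingness_bin(frac),
             excluded = frac > 0.8,
             stringsAsFactors = FALSE, row.names = NULL)
}
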