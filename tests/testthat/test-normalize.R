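test_that("a known noiseless batch shift is recovered and removed exactly", {
  d <- shifted_qc_dataset(n_qc = 3, base = 18, shift = 2, noise_sd = 0)
  model <- fit_mixnorm(d$matrix, d$annotation, min_detection = 0)
  expect_true(all(model$normalizable))
  # referent carries 0 by construction; the contrast between batches is +2
  bc <- model$batch_coef[1, ]
  expect_equal(bc[[model$referent[1]]], 0)
  expect_equal(unname(bc["b2"] - bc["b1"]), 2, tolerance = 1e-6)
  nm <- apply_mixnorm(model, d$matrix, d$annotation)
  means <- tapply(nm$values[1, ], d$annotation$batch, mean)
  expect_equal(unname(diff(means)), 0, tolerance = 1e-6)
  # grand-mean anchor preserves the overall location
  expect_equal(mean(nm$values[1, ]), mean(d$matrix$values[1, ]),
               tolerance = 0.05)
})

test_that("single-batch data pass through mixnorm unchanged", {
  set.seed(3)
  vals <- matrix(rnorm(20, 18, 0.5), nrow = 2,
                 dimnames = list(c("m1", "m2"), sprintf("s%d", 1:10)))
  m <- abundance_matrix(vals)
  ann <- sample_annotation(data.frame(
    sample_id = colnames(vals), batch = "b1", run_order = 1:10,
    sample_class = rep(c("qc", "analytical"), 5)))
  model <- fit_mixnorm(m, ann, min_detection = 0)
  nm <- apply_mixnorm(model, m, ann)
  expect_equal(nm$values, m$values, tolerance = 1e-8)
})

test_that("mixnorm never alters the detection mask and skips unfittable metabolites", {
  cfg <- small_sim(n_metabolites = 50L)
  sim <- simulate_experiment(cfg, 1L)
  model <- fit_mixnorm(sim$matrix, sim$annotation, min_detection = 0)
  nm <- apply_mixnorm(model, sim$matrix, sim$annotation)
  expect_identical(nm$detected, sim$matrix$detected)
  expect_true(all(is.na(nm$values[!nm$detected])))
  # below-filter metabolites are excluded with a reason and passed through
  model20 <- fit_mixnorm(sim$matrix, sim$annotation, min_detection = 0.9)
  low <- detection_fraction(sim$matrix) < 0.9
  expect_true(all(model20$status[low] == "below_detection_filter"))
  nm20 <- apply_mixnorm(model20, sim$matrix, sim$annotation)
  expect_equal(nm20$values[low, ], sim$matrix$values[low, ])
})

test_that("re-estimated batch effects on normalized QC data are null", {
  # fully detected case: the correction is exact linear algebra
  cfg <- small_sim(n_metabolites = 25L, threshold_low = -Inf,
                   threshold_high = -Inf)
  sim <- simulate_experiment(cfg, 1L)
  qc <- is_qc(sim$annotation)
  model <- fit_mixnorm(sim$matrix, sim$annotation, min_detection = 0)
  nm <- apply_mixnorm(model, sim$matrix, sim$annotation)
  refit <- fit_mixnorm(nm, sim$annotation, min_detection = 0)
  expect_true(max(abs(refit$batch_coef), na.rm = TRUE) < 1e-3)
  # truncated case: residual batch effects shrink by an order of magnitude
  cfgT <- small_sim(n_metabolites = 40L)
  simT <- simulate_experiment(cfgT, 1L)
  modelT <- fit_mixnorm(simT$matrix, simT$annotation, min_detection = 0)
  nmT <- apply_mixnorm(modelT, simT$matrix, simT$annotation)
  refitT <- fit_mixnorm(nmT, simT$annotation, min_detection = 0)
  spread <- function(bc) mean(apply(bc, 1, stats::sd, na.rm = TRUE), na.rm = TRUE)
  expect_lt(spread(refitT$batch_coef), 0.25 * spread(modelT$batch_coef))
})

test_that("mean centering matches hand arithmetic and preserves the grand mean", {
  # batch means 11 and 21, grand mean 16: shifts +5 and -5
  d <- toy_dataset(list(b1 = c(10, 12), b2 = c(20, 22)))
  mc <- mean_center(d$matrix, d$annotation)
  expect_equal(unname(mc$values[1, ]), c(15, 17, 15, 17))
  expect_equal(mean(mc$values[1, ]), mean(d$matrix$values[1, ]))
  # one batch only: batch mean equals grand mean
  d1 <- toy_dataset(list(b1 = c(10, 12, 20, 22)))
  expect_equal(mean_center(d1$matrix, d1$annotation)$values, d1$matrix$values)
})

test_that("median scaling matches hand arithmetic", {
  d <- toy_dataset(list(b1 = c(5, 10, 10), b2 = c(10, 20)))
  ms <- median_scale(d$matrix, d$annotation)
  # overall median 10; batch b2 median 15 -> ratio 1.5
  expect_equal(unname(ms$values[1, 4:5]), c(10 / 1.5, 20 / 1.5),
               tolerance = 1e-9)
  expect_equal(unname(ms$values[1, 1:3]), c(5, 10, 10))  # ratio 1
  dneg <- toy_dataset(list(b1 = c(-5, -10, 2)))
  expect_error(median_scale(dneg$matrix, dneg$annotation), "median")
})

test_that("quantile normalization equalizes distributions across samples", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("m1", "m2", "m3"), c("s1", "s2")))
  qn <- quantile_norm(abundance_matrix(v))
  expect_equal(unname(qn$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, 2]), c(2.5, 3.5, 4.5))
  # already-identical distributions are a fixed point
  v2 <- matrix(c(1, 2, 3, 3, 1, 2), nrow = 3,
               dimnames = list(c("m1", "m2", "m3"), c("s1", "s2")))
  qn2 <- quantile_norm(abundance_matrix(v2))
  expect_equal(qn2$values, v2 * 1.0)
  # undetected cells stay undetected, detected counts may differ
  v3 <- matrix(c(1, 2, NA, 4, 5, 6), nrow = 3,
               dimnames = list(c("m1", "m2", "m3"), c("s1", "s2")))
  qn3 <- quantile_norm(abundance_matrix(v3))
  expect_true(is.na(qn3$values[3, 1]))
  expect_identical(qn3$detected, abundance_matrix(v3)$detected)
})

test_that("external normalizers can be registered as plug-ins", {
  register_normalizer("shift_one", function(m, annotation)
    abundance_matrix(m$values + 1, m$detected))
  d <- toy_dataset(list(b1 = c(10, 12)))
  out <- normalize_by("shift_one", d$matrix, d$annotation)
  expect_equal(out$values, d$matrix$values + 1)
  expect_error(normalize_by("no_such_method", d$matrix, d$annotation),
               "unknown")
})

test_that("multiple QC types share batch effects; type shifts are opt-in", {
  K <- 4
  per_batch <- c("qc_a", "qc_b", "analytical", "analytical", "qc_a", "qc_b")
  batch <- rep(sprintf("b%d", 1:K), each = length(per_batch))
  cls <- rep(per_batch, K)
  ids <- sprintf("s%02d", seq_along(batch))
  b_k <- c(0, 3, -2, 1)
  type_shift <- ifelse(cls == "qc_b", 1.5, 0)
  vals <- matrix(20 + b_k[as.integer(factor(batch))] + type_shift, nrow = 1,
                 dimnames = list("m1", ids))
  ann <- sample_annotation(data.frame(
    sample_id = ids, batch = batch,
    run_order = rep(seq_along(per_batch), K),
    sample_class = cls))
  m <- abundance_matrix(vals)
  model <- fit_mixnorm(m, ann, x_covariates = "batch",
                       z_covariates = c("batch", "qc_type"), min_detection = 0)
  expect_equal(unname(model$qc_type_coef[1, "qc_b"]), 1.5, tolerance = 1e-6)
  nm <- apply_mixnorm(model, m, ann)
  qcv <- nm$values[1, is_qc(ann)]
  expect_lt(stats::sd(qcv), 1e-6)   # batches and QC types fully aligned
  anv <- nm$values[1, !is_qc(ann)]
  expect_lt(stats::sd(anv), 1e-6)   # batch effects removed from analytical too
})
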