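#' Relative standard deviation (RSD, %)
#'
#' `100 * sd / mean` over the supplied detected abundances (sample SD,
#' n - 1 divisor). With fewer than two values the RSD is undefined and
#' `NA` is returned.
#'
#' @param values numeric vector of detected abundances for one metabolite.
#' @return RSD in percent, or `NA`.
#' @export
rsd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) return(NA_real_)
  100 * stats::sd(values) / mean(values)
}

#' Per-metabolite RSD over a sample subset
#'
#' @param m an [abundance_matrix()].
#' @param samples logical or index vector of columns (default: all).
#' @return named numeric vector of RSD% per metabolite (`NA` where fewer
#'   than two detected values).
#' @export
rsd_per_metabolite <- function(m, samples = NULL) {
  vals <- if (is.null(samples)) m$values else m$values[, samples, drop = FALSE]
  apply(vals, 1L, rsd)
}

#' No-intercept RSD-recovery slope by missingness bin
#'
#' Regresses post-normalization RSD on true RSD through the origin,
#' separately within each missingness bin (see [missingness_bin()]):
#' `slope = sum(true * est) / sum(true^2)` over all (metabolite, round)
#' pairs in the bin. A slope of 1 means the normalizer recovers true
#' variability exactly; below 1, RSD is underestimated. Metabolites above
#' 80% undetected are omitted.
#'
#' @param true_rsd,est_rsd numeric vectors of per-metabolite RSD%, pooled
#'   across rounds.
#' @param missing_fraction undetected fraction per entry, in `[0, 1]`.
#' @return data.frame with `bin`, `slope`, `n` (entries per bin; empty bins
#'   have `NA` slope).
#' @export
rsd_recovery_slope <- function(true_rsd, est_rsd, missing_fraction) {
  stopifnot(length(true_rsd) == length(est_rsd),
            length(true_rsd) == length(missing_fraction))
  bins <- missingness_bin(missing_fraction)
  lev <- missingness_bin_levels()
  ok <- bins != ">80%" & is.finite(true_rsd) & is.finite(est_rsd)
  out <- data.frame(bin = lev, slope = NA_real_, n = 0L,
                    stringsAsFactors = FALSE)
  for (j in seq_along(lev)) {
    sel <- ok & bins == lev[j]
    out$n[j] <- sum(sel)
    if (any(sel))
      out$slope[j] <- sum(true_rsd[sel] * est_rsd[sel]) / sum(true_rsd[sel]^2)
  }
  out
}

#' Ordered missingness bin labels (0 through 80% undetected)
#' @return character vector of bin labels.
#' @export
missingness_bin_levels <- function()
  c("0", sprintf("%d-%d%%", seq(0L, 75L, 5L), seq(5L, 80L, 5L)))

#' Per-metabolite association scan against a phenotype
#'
#' Tests each metabolite's association with a phenotype over the analytical
#' samples, either by ordinary linear regression on the detected values
#' (two-sided t-test on the phenotype coefficient) or by the downstream
#' mixture model: [fit_mixture()] with the phenotype (and adjustments) in
#' both components, batch-minimum detection thresholds, and a Wald test on
#' the linear-component phenotype coefficient. Metabolites with fewer than
#' `min_samples` usable samples are skipped with a reason.
#'
#' @param m an [abundance_matrix()] (typically normalized).
#' @param annotation a [sample_annotation()] carrying the phenotype column.
#' @param phenotype name of the phenotype column.
#' @param adjustment character vector of additional annotation columns.
#' @param analysis `"linear"` or `"mixture"`.
#' @param min_samples minimum usable samples per metabolite (default 10).
#' @return data.frame with `metabolite_id`, `estimate`, `se`, `p_value`,
#'   `n_used`, `skipped` (reason or `NA`).
#' @export
association_scan <- function(m, annotation, phenotype,
                             adjustment = character(),
                             analysis = c("linear", "mixture"),
                             min_samples = 10L) {
  analysis <- match.arg(analysis)
  stopifnot(inherits(m, "abundance_matrix"))
  annotation <- annotation[match(m$sample_ids, annotation$sample_id), ]
  an <- !is_qc(annotation)
  ann <- annotation[an, , drop = FALSE]
  if (!phenotype %in% names(ann))
    stop("phenotype column '", phenotype, "' not in annotation", call. = FALSE)
  if (any(!is.finite(ann[[phenotype]])))
    stop("phenotype missing for some analytical samples", call. = FALSE)
  vals <- m$values[, an, drop = FALSE]
  det <- m$detected[, an, drop = FALSE]
  covars <- cbind(`(Intercept)` = 1,
                  stats::setNames(ann[c(phenotype, adjustment)],
                                  c(phenotype, adjustment)))
  X <- as.matrix(covars)
  if (analysis == "mixture")
    th <- compute_batch_thresholds(
      subset_metabolites(subset_samples(m, an), rowSums(det) > 0L), ann)

  res <- data.frame(metabolite_id = m$metabolite_ids,
                    estimate = NA_real_, se = NA_real_, p_value = NA_real_,
                    n_used = NA_integer_, skipped = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(nrow(vals))) {
    di <- det[i, ]
    if (analysis == "linear") {
      n_used <- sum(di)
      if (n_used < max(min_samples, ncol(X) + 1L)) {
        res$skipped[i] <- sprintf("only %d detected values", n_used); next
      }
      fit <- stats::lm.fit(X[di, , drop = FALSE], vals[i, di])
      dfres <- n_used - fit$rank
      s2 <- sum(fit$residuals^2) / dfres
      xtx_inv <- chol2inv(qr.R(fit$qr))
      jj <- match(phenotype, colnames(X))
      est <- fit$coefficients[jj]
      se <- sqrt(s2 * xtx_inv[jj, jj])
      tval <- est / se
      res$estimate[i] <- est; res$se[i] <- se
      res$p_value[i] <- 2 * stats::pt(-abs(tval), dfres)
      res$n_used[i] <- n_used
    } else {
      n_used <- length(di)
      if (sum(di) < min_samples) {
        res$skipped[i] <- sprintf("only %d detected values", sum(di)); next
      }
      if (!m$metabolite_ids[i] %in% rownames(th)) {
        res$skipped[i] <- "no detected values for thresholding"; next
      }
      thr_i <- th[m$metabolite_ids[i], ann$batch]
      des <- mixture_design(X, X)
      fit <- tryCatch(
        fit_mixture(vals[i, ], di, des, thr_i, compute_se = TRUE),
        error = function(e) e)
      if (inherits(fit, "error")) { res$skipped[i] <- conditionMessage(fit); next }
      wt <- tryCatch(wald_test(fit, phenotype, "linear"),
                     error = function(e) e)
      if (inherits(wt, "error")) { res$skipped[i] <- conditionMessage(wt); next }
      res$estimate[i] <- wt$estimate; res$se[i] <- wt$se
      res$p_value[i] <- wt$p_value; res$n_used[i] <- n_used
    }
  }
  res
}

#' True/false-positive probabilities over a grid of effect sizes
#'
#' Pools association-scan p-values over simulation rounds. The
#' true-positive probability at effect threshold `t` is the fraction of
#' (metabolite, round) tests with true `|beta| >= t` rejected at
#' `p < alpha`; the false-positive probability is the rejection fraction
#' among metabolites whose true `|beta|` is below `null_cut`.
#'
#' @param p_values numeric vector of pooled p-values (`NA` = skipped test).
#' @param true_beta true effect size aligned with `p_values`.
#' @param thresholds `|beta|` grid (defaults to the benchmark grid).
#' @param alpha nominal significance level (0.05).
#' @param null_cut `|beta|` below which a metabolite counts as null (0.05).
#' @return data.frame with rows for each threshold (`type = "TP"`) plus one
#'   `type = "FP"` row; columns `threshold`, `type`, `probability`, `n`.
#' @export
power_summary <- function(p_values, true_beta,
                          thresholds = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 1.0),
                          alpha = 0.05, null_cut = 0.05) {
  stopifnot(length(p_values) == length(true_beta))
  ok <- is.finite(p_values)
  rej <- p_values < alpha
  rows <- lapply(thresholds, function(t) {
    sel <- ok & abs(true_beta) >= t
    data.frame(threshold = t, type = "TP",
               probability = if (any(sel)) mean(rej[sel]) else NA_real_,
               n = sum(sel))
  })
  seln <- ok & abs(true_beta) < null_cut
  rows <- c(rows, list(data.frame(
    threshold = null_cut, type = "FP",
    probability = if (any(seln)) mean(rej[seln]) else NA_real_, n = sum(seln))))
  do.call(rbind, rows)
}

#' Pairwise Spearman correlations among QC samples of one class
#'
#' Computes the Spearman correlation over metabolites for every unordered
#' pair of QC samples of the given class, using pairwise-complete detected
#' cells and average ranks for ties. Metabolites are restricted to those
#' detected in at least `min_detection` of all samples.
#'
#' @param m an [abundance_matrix()].
#' @param annotation a [sample_annotation()].
#' @param qc_class QC class label (e.g. `"qc"`).
#' @param min_detection detection-fraction filter (default 0.2).
#' @return list with `mean`, `min`, `max`, `n_pairs`, and the vector of
#'   pairwise correlations.
#' @export
pairwise_qc_spearman <- function(m, annotation, qc_class,
                                 min_detection = 0.2) {
  annotation <- annotation[match(m$sample_ids, annotation$sample_id), ]
  sel <- annotation$sample_class == qc_class
  if (sum(sel) < 2L)
    stop("fewer than 2 QC samples of class '", qc_class, "'", call. = FALSE)
  keep <- detection_fraction(m) >= min_detection
  vals <- m$values[keep, sel, drop = FALSE]
  cors <- stats::cor(vals, method = "spearman", use = "pairwise.complete.obs")
  rho <- cors[upper.tri(cors)]
  list(mean = mean(rho, na.rm = TRUE), min = min(rho, na.rm = TRUE),
       max = max(rho, na.rm = TRUE), n_pairs = length(rho), rho = rho)
}

#' Spearman correlation of non-targeted metabolites with targeted assays
#'
#' For each mapped (non-targeted metabolite, targeted analyte) pair,
#' computes the Spearman correlation across the samples of each analytical
#' class, on pairwise-complete observations, plus per-class summaries.
#'
#' @param m an [abundance_matrix()] of non-targeted (normalized) data.
#' @param annotation a [sample_annotation()].
#' @param targeted data.frame with a `sample_id` column and one column per
#'   targeted analyte (concentrations; `NA` allowed).
#' @param mapping data.frame with columns `metabolite_id`, `analyte`.
#' @param classes analytical classes to evaluate (default: all non-QC
#'   classes present).
#' @return list with `per_analyte` (data.frame: class, metabolite_id,
#'   analyte, rho, n) and `summary` (data.frame: class, mean, min, max).
#' @export
targeted_correlation <- function(m, annotation, targeted, mapping,
                                 classes = NULL) {
  annotation <- annotation[match(m$sample_ids, annotation$sample_id), ]
  if (nrow(mapping) == 0L) stop("empty metabolite/analyte mapping", call. = FALSE)
  common <- intersect(m$sample_ids, targeted$sample_id)
  if (length(common) == 0L)
    stop("no samples in common between non-targeted and targeted data",
         call. = FALSE)
  if (is.null(classes))
    classes <- setdiff(unique(annotation$sample_class[!is_qc(annotation)]),
                       character(0))
  rows <- list()
  for (cl in classes) {
    ids <- intersect(annotation$sample_id[annotation$sample_class == cl], common)
    ti <- match(ids, targeted$sample_id)
    mi <- match(ids, m$sample_ids)
    for (r in seq_len(nrow(mapping))) {
      met <- mapping$metabolite_id[r]; ana <- mapping$analyte[r]
      if (!met %in% m$metabolite_ids || !ana %in% names(targeted)) next
      x <- m$values[met, mi]
      y <- targeted[[ana]][ti]
      use <- is.finite(x) & is.finite(y)
      rho <- if (sum(use) >= 3L)
        stats::cor(x[use], y[use], method = "spearman") else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(class = cl, metabolite_id = met, analyte = ana,
                   rho = rho, n = sum(use), stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  if (is.null(per)) stop("mapping matched no data", call. = FALSE)
  smry <- do.call(rbind, lapply(split(per, per$class), function(d)
    data.frame(class = d$class[1], mean = mean(d$rho, na.rm = TRUE),
               min = min(d$rho, na.rm = TRUE), max = max(d$rho, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  rownames(smry) <- NULL
  list(per_analyte = per, summary = smry)
}
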