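#' Fit QC-based mixture-model normalization (mixnorm)
#'
#' For each metabolite, fits the detectability/abundance mixture model to
#' the QC samples only, with batch indicators (and optionally QC-type and
#' log run-order terms) as covariates, and batch-minimum detection
#' thresholds. The referent batch — whose indicator coefficient is 0 by
#' construction — is the batch whose QC median abundance is the median
#' across batch medians for that metabolite (ties broken toward the lower
#' batch label). Batch and run-order effects are estimated jointly across
#' all QC types.
#'
#' @param m an [abundance_matrix()].
#' @param annotation a [sample_annotation()]; every batch must contain at
#'   least one QC sample.
#' @param x_covariates covariates for the logistic (presence) component:
#'   subset of `c("batch", "qc_type")`.
#' @param z_covariates covariates for the linear (mean) component: subset of
#'   `c("batch", "qc_type", "log_run_order", "run_order", "run_order2")`.
#' @param min_detection minimum overall detection fraction for a metabolite
#'   to be modeled (default 0.2); metabolites below it are excluded and
#'   passed through unchanged by [apply_mixnorm()].
#' @param qc_outlier_k optional: drop QC observations farther than
#'   `qc_outlier_k` standard deviations from the metabolite's QC mean before
#'   fitting (default `NULL`, no filtering).
#' @param ... further options passed to [fit_mixture()].
#' @return object of class `mixnorm_model`: per-metabolite fits, batch
#'   coefficient vectors (referent = 0), run-order and QC-type
#'   coefficients, thresholds used, and exclusion reasons.
#' @export
fit_mixnorm <- function(m, annotation,
                        x_covariates = "batch",
                        z_covariates = "batch",
                        min_detection = 0.2,
                        qc_outlier_k = NULL, ...) {
  stopifnot(inherits(m, "abundance_matrix"))
  annotation <- annotation[match(m$sample_ids, annotation$sample_id), ]
  qc <- is_qc(annotation)
  batches <- sort(unique(annotation$batch))
  no_qc <- setdiff(batches, unique(annotation$batch[qc]))
  if (length(no_qc))
    stop("batch(es) without QC samples: ", paste(no_qc, collapse = ", "),
         call. = FALSE)
  ok_x <- c("batch", "qc_type")
  ok_z <- c("batch", "qc_type", "log_run_order", "run_order", "run_order2")
  if (length(setdiff(x_covariates, ok_x)))
    stop("unsupported x covariate(s): ",
         paste(setdiff(x_covariates, ok_x), collapse = ", "), call. = FALSE)
  if (length(setdiff(z_covariates, ok_z)))
    stop("unsupported z covariate(s): ",
         paste(setdiff(z_covariates, ok_z), collapse = ", "), call. = FALSE)

  qc_ann <- annotation[qc, , drop = FALSE]
  qc_types <- sort(unique(qc_ann$sample_class))
  ref_qc_type <- qc_types[1]
  use_qc_type <- length(qc_types) > 1L

  keep <- rowSums(m$detected) > 0L
  th <- matrix(NA_real_, nrow(m$values), length(batches),
               dimnames = list(m$metabolite_ids, batches))
  th[keep, ] <- compute_batch_thresholds(
    subset_metabolites(m, keep), annotation)[, batches, drop = FALSE]

  det_frac <- detection_fraction(m)
  qvals <- m$values[, qc, drop = FALSE]
  qdet <- m$detected[, qc, drop = FALSE]
  qbatch <- qc_ann$batch

  # reusable design blocks on the QC samples
  batch_ind <- vapply(batches, function(b) as.numeric(qbatch == b),
                      numeric(nrow(qc_ann)))
  dim(batch_ind) <- c(nrow(qc_ann), length(batches))
  colnames(batch_ind) <- batches
  qc_type_ind <- NULL
  if (use_qc_type) {
    qc_type_ind <- vapply(qc_types[-1],
                          function(tp) as.numeric(qc_ann$sample_class == tp),
                          numeric(nrow(qc_ann)))
    dim(qc_type_ind) <- c(nrow(qc_ann), length(qc_types) - 1L)
    colnames(qc_type_ind) <- qc_types[-1]
  }
  ro_cols <- function(which) {
    cols <- NULL
    if ("log_run_order" %in% which)
      cols <- cbind(cols, log_run_order = log(qc_ann$run_order))
    if ("run_order" %in% which)
      cols <- cbind(cols, run_order = qc_ann$run_order)
    if ("run_order2" %in% which)
      cols <- cbind(cols, run_order2 = qc_ann$run_order^2)
    cols
  }
  z_extra <- ro_cols(z_covariates)

  build_design <- function(which, ref_batch, nonref_batches) {
    d <- matrix(1, nrow = nrow(qc_ann), ncol = 1,
                dimnames = list(NULL, "(Intercept)"))
    if ("batch" %in% which && length(nonref_batches)) {
      nb <- batch_ind[, nonref_batches, drop = FALSE]
      colnames(nb) <- paste0("batch", nonref_batches)
      d <- cbind(d, nb)
    }
    if ("qc_type" %in% which && use_qc_type) {
      qi <- qc_type_ind
      colnames(qi) <- paste0("qc_type", qc_types[-1])
      d <- cbind(d, qi)
    }
    d
  }

  fits <- vector("list", nrow(m$values))
  names(fits) <- m$metabolite_ids
  batch_coef <- matrix(0, nrow(m$values), length(batches),
                       dimnames = list(m$metabolite_ids, batches))
  ro_coef <- matrix(0, nrow(m$values), max(1L, NCOL(z_extra)),
                    dimnames = list(m$metabolite_ids,
                                    if (is.null(z_extra)) "none"
                                    else colnames(z_extra)))
  qc_type_coef <- matrix(0, nrow(m$values), length(qc_types),
                         dimnames = list(m$metabolite_ids, qc_types))
  referent <- stats::setNames(rep(NA_character_, nrow(m$values)), m$metabolite_ids)
  status <- stats::setNames(rep("ok", nrow(m$values)), m$metabolite_ids)
  normalizable <- stats::setNames(rep(FALSE, nrow(m$values)), m$metabolite_ids)

  for (i in seq_len(nrow(m$values))) {
    if (det_frac[i] < min_detection) { status[i] <- "below_detection_filter"; next }
    di <- qdet[i, ]
    if (!any(di)) { status[i] <- "no_detected_qc"; next }
    yi <- qvals[i, ]

    use <- rep(TRUE, length(yi))
    if (!is.null(qc_outlier_k) && sum(di) >= 3L) {
      mu_q <- mean(yi[di]); sd_q <- stats::sd(yi[di])
      if (is.finite(sd_q) && sd_q > 0)
        use <- !(di & abs(yi - mu_q) > qc_outlier_k * sd_q)
    }
    if (!any(di & use)) { status[i] <- "no_detected_qc"; next }

    # referent batch: QC median abundance at the median across batch medians
    med <- tapply(yi[di & use], qbatch[di & use], stats::median)
    med <- med[order(med, names(med))]
    ref <- names(med)[ceiling(length(med) / 2)]
    referent[i] <- ref

    # a batch effect is unidentifiable from QC data when no QC in the batch
    # is detected (the likelihood is flat as the batch mean falls below the
    # threshold, and the logistic indicator separates): drop those QC rows
    # and indicators, and mark the batch for the average correction.
    est_batches <- sort(unique(qbatch[di & use]))
    inest <- setdiff(batches, est_batches)
    if (length(inest)) {
      use <- use & qbatch %in% est_batches
      batch_coef[i, inest] <- NA_real_
    }

    xd <- build_design(x_covariates, ref,
                       setdiff(est_batches, ref))[use, , drop = FALSE]
    zd0 <- build_design(z_covariates, ref, setdiff(est_batches, ref))
    if (!is.null(z_extra)) zd0 <- cbind(zd0, z_extra)
    zd <- zd0[use, , drop = FALSE]
    thr_i <- th[i, qbatch][use]
    des <- tryCatch(mixture_design(xd, zd), error = function(e) e)
    if (inherits(des, "error")) { status[i] <- conditionMessage(des); next }
    fit <- tryCatch(
      fit_mixture(yi[use], di[use], des, thr_i,
                  metabolite_id = m$metabolite_ids[i], ...),
      error = function(e) e)
    if (inherits(fit, "error")) { status[i] <- conditionMessage(fit); next }
    fits[[i]] <- fit
    if (!fit$converged) { status[i] <- "not_converged"; next }
    normalizable[i] <- TRUE
    cf <- fit$alpha
    if ("batch" %in% z_covariates) {
      nonref <- setdiff(est_batches, ref)
      batch_coef[i, nonref] <- cf[paste0("batch", nonref)]
      # batches with no detected QC still carry information: every QC fell
      # below the batch threshold. Estimate their level by the posterior
      # mean under a Gaussian prior centered at the cross-batch mean with
      # spread taken from the fitted batch coefficients, conditioned on all
      # q QCs lying below T. Needs >= 3 estimated batches for the prior.
      bvec <- c(0, unname(batch_coef[i, nonref]))
      if (length(inest) && length(bvec) >= 3L &&
          "(Intercept)" %in% names(cf)) {
        a0 <- cf[["(Intercept)"]]
        mu0 <- a0 + mean(bvec)
        tau <- stats::sd(bvec)
        sig <- fit$sigma
        if (is.finite(tau) && tau > 0 && is.finite(sig) && sig > 0) {
          for (k in inest) {
            q <- sum(qbatch == k)
            grid <- seq(mu0 - 6 * tau, mu0 + 6 * tau, length.out = 241L)
            lw <- stats::dnorm(grid, mu0, tau, log = TRUE) +
              q * stats::pnorm((th[i, k] - grid) / sig, log.p = TRUE)
            w <- exp(lw - max(lw))
            batch_coef[i, k] <- sum(grid * w) / sum(w) - a0
          }
        }
      }
    }
    if (!is.null(z_extra))
      ro_coef[i, colnames(z_extra)] <- cf[colnames(z_extra)]
    if ("qc_type" %in% z_covariates && use_qc_type)
      qc_type_coef[i, qc_types[-1]] <- cf[paste0("qc_type", qc_types[-1])]
  }

  structure(list(fits = fits, batch_coef = batch_coef, ro_coef = ro_coef,
                 qc_type_coef = qc_type_coef, referent = referent,
                 normalizable = normalizable, status = status,
                 thresholds = th, batches = batches, qc_types = qc_types,
                 ref_qc_type = ref_qc_type,
                 x_covariates = x_covariates, z_covariates = z_covariates,
                 min_detection = min_detection),
            class = "mixnorm_model")
}

#' @export
print.mixnorm_model <- function(x, ...) {
  cat(sprintf("mixnorm_model: %d/%d metabolites normalizable; covariates x = {%s}, z = {%s}\n",
              sum(x$normalizable), length(x$normalizable),
              paste(x$x_covariates, collapse = ", "),
              paste(x$z_covariates, collapse = ", ")))
  invisible(x)
}

#' Apply mixnorm location-shift corrections to a dataset
#'
#' Subtracts each sample's fitted technical terms (batch coefficient plus
#' any run-order term) from every detected cell, then adds back the
#' unweighted mean of the batch coefficients so the normalized values sit
#' at the cross-batch average location (`anchor = "grand_mean"`, the
#' default, which makes output invariant to the referent choice);
#' `anchor = "referent"` keeps values at the referent-batch location.
#' QC-type location shifts are always removed from QC samples (aligning QC
#' pools); they are applied to analytical samples only when
#' `apply_qc_type_shift = TRUE`, using `qc_type_map` to name the QC type
#' each analytical class resembles. Undetected cells stay undetected; the
#' detection mask is never changed and nothing is imputed. Metabolites
#' without a converged fit pass through unchanged.
#'
#' @param model a [fit_mixnorm()] result.
#' @param m an [abundance_matrix()] (QC and/or analytical samples).
#' @param annotation matching [sample_annotation()]; every batch must
#'   appear in the model.
#' @param apply_qc_type_shift apply QC-type shifts to analytical samples?
#' @param qc_type_map named character vector, analytical class -> QC type.
#' @param anchor `"grand_mean"` or `"referent"`.
#' @return normalized [abundance_matrix()].
#' @export
apply_mixnorm <- function(model, m, annotation, apply_qc_type_shift = FALSE,
                          qc_type_map = NULL,
                          anchor = c("grand_mean", "referent")) {
  stopifnot(inherits(model, "mixnorm_model"), inherits(m, "abundance_matrix"))
  anchor <- match.arg(anchor)
  annotation <- annotation[match(m$sample_ids, annotation$sample_id), ]
  unknown <- setdiff(unique(annotation$batch), model$batches)
  if (length(unknown))
    stop("sample batch(es) absent from model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  mids <- intersect(m$metabolite_ids, rownames(model$batch_coef))
  vals <- m$values
  bc <- model$batch_coef[mids, , drop = FALSE]
  # batches whose effect was unidentifiable (no detected QC) carry NA and
  # receive the average estimated correction, i.e. no shift relative to the
  # cross-batch anchor
  coef_mean <- rowMeans(bc, na.rm = TRUE)
  for (i in seq_len(nrow(bc)))
    bc[i, is.na(bc[i, ])] <- coef_mean[i]
  addback <- if (anchor == "grand_mean") coef_mean else 0

  shift_cols <- bc[, annotation$batch, drop = FALSE]
  if (!identical(colnames(model$ro_coef), "none")) {
    for (tm in colnames(model$ro_coef)) {
      xval <- switch(tm,
                     log_run_order = log(annotation$run_order),
                     run_order = annotation$run_order,
                     run_order2 = annotation$run_order^2)
      shift_cols <- shift_cols + outer(model$ro_coef[mids, tm], xval)
    }
  }
  qc_sel <- is_qc(annotation)
  cls <- annotation$sample_class
  for (j in seq_len(ncol(vals))) {
    tp <- NULL
    if (qc_sel[j] && cls[j] %in% colnames(model$qc_type_coef)) tp <- cls[j]
    if (!qc_sel[j] && apply_qc_type_shift && !is.null(qc_type_map) &&
        cls[j] %in% names(qc_type_map)) tp <- qc_type_map[[cls[j]]]
    if (!is.null(tp))
      shift_cols[, j] <- shift_cols[, j] + model$qc_type_coef[mids, tp]
  }

  norm_rows <- model$normalizable[mids]
  rows <- match(mids, m$metabolite_ids)
  adj <- sweep(shift_cols, 1L, addback, "-")
  vals[rows[norm_rows], ] <- vals[rows[norm_rows], , drop = FALSE] -
    adj[norm_rows, , drop = FALSE]
  vals[!m$detected] <- NA_real_
  abundance_matrix(vals, m$detected,
                   metabolite_ids = m$metabolite_ids, sample_ids = m$sample_ids)
}

#' Batch mean centering
#'
#' Per metabolite, subtracts the difference between the batch-specific mean
#' and the grand mean (both over detected values across all samples) from
#' every detected cell of the batch. Batches with no detected values for a
#' metabolite are left uncorrected.
#'
#' @param m an [abundance_matrix()].
#' @param annotation a [sample_annotation()].
#' @return normalized [abundance_matrix()].
#' @export
mean_center <- function(m, annotation) {
  stopifnot(inherits(m, "abundance_matrix"))
  annotation <- annotation[match(m$sample_ids, annotation$sample_id), ]
  vals <- m$values
  grand <- rowMeans(vals, na.rm = TRUE)
  for (b in unique(annotation$batch)) {
    cols <- annotation$batch == b
    bm <- rowMeans(vals[, cols, drop = FALSE], na.rm = TRUE)
    shift <- bm - grand
    shift[!is.finite(shift)] <- 0        # batch with zero detections
    vals[, cols] <- vals[, cols, drop = FALSE] - shift
  }
  abundance_matrix(vals, m$detected,
                   metabolite_ids = m$metabolite_ids, sample_ids = m$sample_ids)
}

#' Batch median scaling
#'
#' Per metabolite, divides detected values in each batch by the ratio of
#' the batch-specific median to the overall median (both over detected
#' values). The overall median must be positive on the working scale (log2
#' peak areas are, in practice).
#'
#' @inheritParams mean_center
#' @return normalized [abundance_matrix()].
#' @export
median_scale <- function(m, annotation) {
  stopifnot(inherits(m, "abundance_matrix"))
  annotation <- annotation[match(m$sample_ids, annotation$sample_id), ]
  vals <- m$values
  overall <- apply(vals, 1L, stats::median, na.rm = TRUE)
  if (any(overall <= 0, na.rm = TRUE))
    stop("non-positive overall median on the working scale; ",
         "median scaling is defined for positive abundances", call. = FALSE)
  for (b in unique(annotation$batch)) {
    cols <- annotation$batch == b
    bm <- apply(vals[, cols, drop = FALSE], 1L, stats::median, na.rm = TRUE)
    ratio <- bm / overall
    ratio[!is.finite(ratio)] <- 1        # batch with zero detections
    vals[, cols] <- vals[, cols, drop = FALSE] / ratio
  }
  abundance_matrix(vals, m$detected,
                   metabolite_ids = m$metabolite_ids, sample_ids = m$sample_ids)
}

#' Quantile normalization across samples
#'
#' Classic quantile normalization of the detected values in each sample
#' column to the common distribution of mean ranked values, with
#' interpolation when detected counts differ between samples and average
#' target quantiles for ties (via `limma::normalizeQuantiles`). Undetected
#' cells are excluded from ranking and remain undetected. Samples with
#' fewer than two detected values are passed through unchanged.
#'
#' @param m an [abundance_matrix()].
#' @return normalized [abundance_matrix()].
#' @export
quantile_norm <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  vals <- m$values
  skip <- colSums(m$detected) < 2L
  out <- limma::normalizeQuantiles(vals, ties = TRUE)
  out[, skip] <- vals[, skip]
  out[!m$detected] <- NA_real_
  abundance_matrix(out, m$detected,
                   metabolite_ids = m$metabolite_ids, sample_ids = m$sample_ids)
}

#' Apply a normalization method by name
#'
#' Dispatch helper used by the benchmark driver and the command-line
#' interface. `"none"` returns the input; `"mixnorm"` fits on QCs and
#' applies to all samples. External normalizers registered with
#' [register_normalizer()] are recognized by name.
#'
#' @param method one of `"none"`, `"mixnorm"`, `"mean_center"`,
#'   `"median_scale"`, `"quantile"`, or a registered plug-in name.
#' @param m an [abundance_matrix()].
#' @param annotation a [sample_annotation()].
#' @param ... options forwarded to [fit_mixnorm()] for `method = "mixnorm"`.
#' @return normalized [abundance_matrix()].
#' @export
normalize_by <- function(method, m, annotation, ...) {
  if (method %in% names(.normalizer_registry))
    return(.normalizer_registry[[method]](m, annotation))
  switch(method,
         none = m,
         mixnorm = {
           model <- fit_mixnorm(m, annotation, ...)
           apply_mixnorm(model, m, annotation)
         },
         mean_center = mean_center(m, annotation),
         median_scale = median_scale(m, annotation),
         quantile = quantile_norm(m),
         stop("unknown normalization method: ", method, call. = FALSE))
}

.normalizer_registry <- new.env(parent = emptyenv())

#' Register an external normalizer plug-in
#'
#' Third-party normalization methods can enter the evaluation framework
#' without being reimplemented: register a function taking
#' `(abundance_matrix, sample_annotation)` and returning an
#' [abundance_matrix()], then refer to it by name in [normalize_by()] and
#' [run_benchmark()].
#'
#' @param name method name.
#' @param fun function of `(m, annotation)`.
#' @return invisibly, `name`.
#' @export
register_normalizer <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .normalizer_registry)
  invisible(name)
}

# row subset helper shared with io
subset_metabolites <- function(m, keep) {
  abundance_matrix(m$values[keep, , drop = FALSE],
                   m$detected[keep, , drop = FALSE],
                   metabolite_ids = m$metabolite_ids[keep],
                   sample_ids = m$sample_ids)
}
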