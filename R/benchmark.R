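#' Run the simulation benchmark: simulate, normalize, evaluate
#'
#' End-to-end driver for the simulation study. Each round: generate one
#' experiment, normalize with every requested method, and collect
#' per-metabolite RSDs (QC and analytical, over detected values),
#' undetected fractions, and (optionally) phenotype association scans.
#' Results are pooled over (metabolite, round) pairs into an evaluation
#' report. Metabolites above 80% undetected in a round are omitted from
#' that round's metrics. Failures at any (round, method, metabolite) are
#' recorded and the benchmark continues.
#'
#' @param cfg a [sim_config()].
#' @param n_rounds number of rounds to run (defaults to `cfg$n_rounds`).
#' @param methods normalization methods, a subset of `"none"`,
#'   `"mixnorm"`, `"mean_center"`, `"median_scale"`, `"quantile"` plus any
#'   [register_normalizer()] plug-in names.
#' @param scan_methods methods for which phenotype association scans are
#'   run (default none; scans dominate run time).
#' @param scan_analyses `"linear"`, `"mixture"`, or both.
#' @param mixnorm_min_detection detection filter for mixnorm fitting; the
#'   simulation benchmark models every metabolite with any detected QC
#'   value (0), matching the design in which only the >80%-undetected
#'   exclusion applies.
#' @param keep_rounds keep per-round detail tables? (default `FALSE`)
#' @param progress print one line per round?
#' @return object of class `evaluation_report`: `rsd_summary`,
#'   `slope_table`, `power_table`, `failures`, `n_rounds`, and (optionally)
#'   `detail`.
#' @export
run_benchmark <- function(cfg, n_rounds = cfg$n_rounds,
                          methods = c("none", "mixnorm", "mean_center",
                                      "median_scale", "quantile"),
                          scan_methods = character(),
                          scan_analyses = c("linear", "mixture"),
                          mixnorm_min_detection = 0,
                          keep_rounds = FALSE, progress = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), n_rounds >= 1L)
  scan_analyses <- match.arg(scan_analyses, several.ok = TRUE)
  stopifnot(all(scan_methods %in% methods))

  acc_rsd <- list(); acc_scan <- list(); failures <- list()
  for (r in seq_len(n_rounds)) {
    sim <- simulate_experiment(cfg, r)
    qc <- is_qc(sim$annotation)
    prof <- truncation_profile(sim$matrix)
    usable <- !prof$excluded
    for (method in methods) {
      nm <- tryCatch(
        normalize_by(method, sim$matrix, sim$annotation,
                     min_detection = mixnorm_min_detection),
        error = function(e) e)
      if (inherits(nm, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(round = r, method = method, stage = "normalize",
                     message = conditionMessage(nm))
        next
      }
      acc_rsd[[length(acc_rsd) + 1L]] <- data.frame(
        round = r, method = method,
        metabolite_id = sim$matrix$metabolite_ids[usable],
        rsd_qc = rsd_per_metabolite(nm, qc)[usable],
        rsd_analytical = rsd_per_metabolite(nm, !qc)[usable],
        true_rsd_qc = sim$truth$true_rsd_qc[usable],
        true_rsd_analytical = sim$truth$true_rsd_analytical[usable],
        undetected_fraction = prof$undetected_fraction[usable],
        stringsAsFactors = FALSE, row.names = NULL)
      if (method %in% scan_methods) {
        for (an in scan_analyses) {
          sc <- tryCatch(
            association_scan(nm, sim$annotation, "phenotype", analysis = an),
            error = function(e) e)
          if (inherits(sc, "error")) {
            failures[[length(failures) + 1L]] <-
              data.frame(round = r, method = method, stage = paste0("scan_", an),
                         message = conditionMessage(sc))
            next
          }
          sc <- sc[usable, , drop = FALSE]
          acc_scan[[length(acc_scan) + 1L]] <- data.frame(
            round = r, method = method, analysis = an,
            metabolite_id = sc$metabolite_id, p_value = sc$p_value,
            estimate = sc$estimate,
            true_beta = sim$truth$beta_m[sc$metabolite_id],
            stringsAsFactors = FALSE, row.names = NULL)
        }
      }
    }
    if (progress)
      message(sprintf("round %d/%d done", r, n_rounds))
  }

  detail <- do.call(rbind, acc_rsd)
  scans <- if (length(acc_scan)) do.call(rbind, acc_scan) else NULL

  smry <- function(x) c(mean = mean(x, na.rm = TRUE),
                        min = suppressWarnings(min(x, na.rm = TRUE)),
                        max = suppressWarnings(max(x, na.rm = TRUE)))
  rsd_rows <- list()
  for (method in methods) {
    d <- detail[detail$method == method, ]
    for (cls in c("qc", "analytical")) {
      v <- if (cls == "qc") d$rsd_qc else d$rsd_analytical
      s <- smry(v)
      rsd_rows[[length(rsd_rows) + 1L]] <- data.frame(
        method = method, sample_class = cls,
        mean = s["mean"], min = s["min"], max = s["max"],
        n = sum(is.finite(v)), stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  # the truth rows: RSD of pre-batch-effect values, same pooling
  d0 <- detail[detail$method == methods[1], ]
  for (cls in c("qc", "analytical")) {
    v <- if (cls == "qc") d0$true_rsd_qc else d0$true_rsd_analytical
    s <- smry(v)
    rsd_rows[[length(rsd_rows) + 1L]] <- data.frame(
      method = "truth", sample_class = cls,
      mean = s["mean"], min = s["min"], max = s["max"],
      n = sum(is.finite(v)), stringsAsFactors = FALSE, row.names = NULL)
  }
  rsd_summary <- do.call(rbind, rsd_rows)

  slope_rows <- lapply(methods, function(method) {
    d <- detail[detail$method == method, ]
    st <- rsd_recovery_slope(d$true_rsd_analytical, d$rsd_analytical,
                             d$undetected_fraction)
    cbind(method = method, st, stringsAsFactors = FALSE)
  })
  slope_table <- do.call(rbind, slope_rows)

  power_table <- NULL
  if (!is.null(scans)) {
    power_rows <- list()
    for (method in unique(scans$method)) for (an in unique(scans$analysis)) {
      s <- scans[scans$method == method & scans$analysis == an, ]
      if (!nrow(s)) next
      pt <- power_summary(s$p_value, s$true_beta)
      power_rows[[length(power_rows) + 1L]] <-
        cbind(method = method, analysis = an, pt, stringsAsFactors = FALSE)
    }
    power_table <- do.call(rbind, power_rows)
  }

  out <- list(rsd_summary = rsd_summary, slope_table = slope_table,
              power_table = power_table,
              failures = if (length(failures)) do.call(rbind, failures) else NULL,
              n_rounds = n_rounds,
              methods = methods,
              detail = if (keep_rounds) detail else NULL,
              scans = if (keep_rounds) scans else NULL)
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d rounds, methods: %s\n", x$n_rounds,
              paste(x$methods, collapse = ", ")))
  cat("\nRSD%% summary (mean over pooled metabolite-rounds):\n")
  print(x$rsd_summary, row.names = FALSE, digits = 4)
  if (!is.null(x$power_table)) {
    cat("\nTrue/false-positive probabilities:\n")
    print(x$power_table, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$failures))
    cat(sprintf("\n%d recorded failure(s)\n", nrow(x$failures)))
  invisible(x)
}

#' Write an evaluation report to TSV files
#'
#' Writes `<prefix>_rsd.tsv`, `<prefix>_slopes.tsv` and, when present,
#' `<prefix>_power.tsv`, one row per (method, metric, stratum), with
#' explicit `NA` for missing entries.
#'
#' @param report an `evaluation_report` from [run_benchmark()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, prefix) {
  paths <- character(0)
  w <- function(df, suffix) {
    p <- paste0(prefix, "_", suffix, ".tsv")
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths, w(report$rsd_summary, "rsd"),
             w(report$slope_table, "slopes"))
  if (!is.null(report$power_table))
    paths <- c(paths, w(report$power_table, "power"))
  invisible(paths)
}
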