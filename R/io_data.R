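#' Construct an abundance matrix
#'
#' An `abundance_matrix` carries log2-transformed MS peak areas for
#' metabolites (rows) by samples (columns) together with an explicit
#' detection mask. Cells where `detected` is `FALSE` hold no usable value:
#' every downstream computation ignores them, and they are serialized as
#' `NA`. No imputation is ever performed.
#'
#' @param values numeric matrix, metabolites x samples, log2 peak areas.
#'   May contain `NA` at undetected cells; such cells must be `FALSE` in
#'   `detected` (if `detected` is missing it is derived as `!is.na(values)`).
#' @param detected logical matrix congruent to `values`; `TRUE` = detected.
#' @param metabolite_ids,sample_ids character vectors of unique row/column
#'   labels; default to the dimnames of `values`.
#' @return an object of class `abundance_matrix` with elements `values`,
#'   `detected`, `metabolite_ids`, `sample_ids`.
#' @export
abundance_matrix <- function(values, detected = NULL,
                             metabolite_ids = rownames(values),
                             sample_ids = colnames(values)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(detected)) detected <- !is.na(values)
  if (!identical(dim(values), dim(detected)))
    stop("`values` and `detected` must have identical dimensions", call. = FALSE)
  if (is.null(metabolite_ids) || is.null(sample_ids))
    stop("metabolite and sample ids are required (dimnames or arguments)", call. = FALSE)
  metabolite_ids <- as.character(metabolite_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite_ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(metabolite_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  bad <- detected & !is.finite(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value flagged as detected at metabolite '%s', sample '%s'",
                 metabolite_ids[idx[1]], sample_ids[idx[2]]), call. = FALSE)
  }
  values[!detected] <- NA_real_
  dimnames(values) <- dimnames(detected) <- list(metabolite_ids, sample_ids)
  structure(list(values = values, detected = detected,
                 metabolite_ids = metabolite_ids, sample_ids = sample_ids),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d metabolites x %d samples (%.1f%% detected)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Construct and validate a sample annotation table
#'
#' Sample-level technical annotation: batch, run-order position within
#' batch, and sample class. The class `"analytical"` marks samples of
#' analytical interest; any other class label is treated as a named QC pool
#' type (e.g. `"qc"`, `"qc_maternal"`). Extra numeric columns are carried as
#' phenotype covariates.
#'
#' @param df data.frame with columns `sample_id`, `batch`, `run_order`,
#'   `sample_class`, plus optional phenotype columns.
#' @return a validated data.frame of class `sample_annotation`.
#' @export
sample_annotation <- function(df) {
  req <- c("sample_id", "batch", "run_order", "sample_class")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("annotation missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$batch <- as.character(df$batch)
  df$sample_class <- as.character(df$sample_class)
  df$run_order <- as.integer(df$run_order)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in annotation: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$run_order)) || any(df$run_order < 1L))
    stop("run_order must be a positive integer", call. = FALSE)
  dup <- duplicated(df[c("batch", "run_order")])
  if (any(dup))
    stop("run_order not unique within batch: batch ",
         df$batch[dup][1], ", position ", df$run_order[dup][1], call. = FALSE)
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Which samples are QC samples?
#'
#' @param annotation a [sample_annotation()] table.
#' @return logical vector, `TRUE` for every sample whose class is not
#'   `"analytical"`.
#' @export
is_qc <- function(annotation) annotation$sample_class != "analytical"

#' Read an abundance matrix and its sample annotation from TSV files
#'
#' The matrix file is tab-delimited with header
#' `metabolite_id<TAB><sample ids...>` and one row per metabolite; an empty
#' field or the literal token `NA` encodes an undetected cell. The
#' annotation file is tab-delimited with required columns `sample_id`,
#' `batch`, `run_order`, `sample_class`; any additional columns are kept as
#' phenotypes. Sample ids must match between the two files.
#'
#' @param matrix_path,annotation_path file paths.
#' @return list with elements `matrix` ([abundance_matrix()]) and
#'   `annotation` ([sample_annotation()]).
#' @export
read_dataset <- function(matrix_path, annotation_path) {
  for (p in c(matrix_path, annotation_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = c("NA", ""),
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L || names(raw)[1] != "metabolite_id")
    stop("malformed matrix header: first column must be 'metabolite_id'",
         call. = FALSE)
  met_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- !is.na(vals) & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric detected cell at metabolite '%s', sample '%s': '%s'",
                 met_ids[idx[1]], colnames(vals)[idx[2]], vals[idx[1], idx[2]]),
         call. = FALSE)
  }
  dimnames(num) <- list(met_ids, colnames(vals))
  m <- abundance_matrix(num)
  ann <- sample_annotation(utils::read.delim(annotation_path, header = TRUE,
                                             sep = "\t", check.names = FALSE,
                                             quote = ""))
  missing_ann <- setdiff(m$sample_ids, ann$sample_id)
  if (length(missing_ann))
    stop("annotation missing matrix sample id(s): ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  ann <- ann[match(m$sample_ids, ann$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(matrix = m, annotation = sample_annotation(ann))
}

#' Write an abundance matrix and annotation to TSV files
#'
#' Inverse of [read_dataset()]: undetected cells are written as `NA`.
#'
#' @param m an [abundance_matrix()].
#' @param annotation a [sample_annotation()] (optional).
#' @param matrix_path,annotation_path output paths; `annotation_path` may be
#'   `NULL` to write the matrix only.
#' @param digits significant digits for values (default 10, lossless for
#'   practical purposes).
#' @return invisibly, `matrix_path`.
#' @export
write_dataset <- function(m, annotation = NULL, matrix_path,
                          annotation_path = NULL, digits = 10) {
  vals <- m$values
  txt <- ifelse(m$detected, formatC(vals, digits = digits, format = "g"), "NA")
  df <- data.frame(metabolite_id = m$metabolite_ids, txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("metabolite_id", m$sample_ids)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(annotation) && !is.null(annotation_path))
    utils::write.table(annotation, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(matrix_path)
}

#' Per-metabolite, per-batch detection thresholds
#'
#' The detection threshold T for a metabolite in a batch is the minimum
#' detected value of that metabolite among all samples (QC and analytical)
#' run in that batch. When a metabolite has no detection in a batch, T
#' falls back to the metabolite's global minimum detected value so the
#' truncation probability remains computable. Metabolites with no detection
#' anywhere cannot be thresholded and raise an error; filter them out first.
#'
#' @param m an [abundance_matrix()].
#' @param annotation a [sample_annotation()] covering the samples of `m`.
#' @return numeric matrix of class `threshold_set`, metabolites x batches.
#' @export
compute_batch_thresholds <- function(m, annotation) {
  stopifnot(inherits(m, "abundance_matrix"))
  annotation <- annotation[match(m$sample_ids, annotation$sample_id), ]
  batches <- unique(annotation$batch)
  vals <- m$values
  never <- rowSums(m$detected) == 0L
  if (any(never))
    stop("metabolite(s) with zero detections anywhere: ",
         paste(m$metabolite_ids[never], collapse = ", "),
         "; filter them out before thresholding", call. = FALSE)
  global_min <- apply(vals, 1L, min, na.rm = TRUE)
  th <- matrix(NA_real_, nrow = nrow(vals), ncol = length(batches),
               dimnames = list(m$metabolite_ids, batches))
  for (b in batches) {
    cols <- annotation$batch == b
    bmin <- suppressWarnings(apply(vals[, cols, drop = FALSE], 1L, min,
                                   na.rm = TRUE))
    bmin[!is.finite(bmin)] <- global_min[!is.finite(bmin)]
    th[, b] <- bmin
  }
  structure(th, class = c("threshold_set", class(th)))
}

#' Fraction of samples in which each metabolite is detected
#'
#' @param m an [abundance_matrix()].
#' @return named numeric vector of detection fractions in `[0, 1]`.
#' @export
detection_fraction <- function(m) rowMeans(m$detected)

# subset an abundance matrix by sample index/logical, keeping the mask in step
subset_samples <- function(m, keep) {
  abundance_matrix(m$values[, keep, drop = FALSE],
                   m$detected[, keep, drop = FALSE],
                   metabolite_ids = m$metabolite_ids,
                   sample_ids = m$sample_ids[keep])
}
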