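#' Construct a time-course expression matrix
#'
#' Bundles a genes x samples matrix of log10-FPKM values with per-sample
#' metadata (time in hours, replicate, course). All stability statistics in
#' the package operate on this container.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene IDs, column names are sample IDs.
#' @param samples Data frame with columns `sample_id`, `time` (hours, >= 0),
#'   `replicate` (integer >= 1) and `course_id`; one row per matrix column,
#'   matched by `sample_id`.
#' @param scale Either `"absolute"` (log10 FPKM) or `"relative_to_t0"`
#'   (log10 ratios to the earliest time point).
#' @return An object of class `time_course_matrix`: a list with elements
#'   `values`, `samples` and `scale`.
#' @export
time_course_matrix <- function(values, samples, scale = c("absolute", "relative_to_t0")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene IDs as row names and sample IDs as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  samples <- as.data.frame(samples)
  required <- c("sample_id", "time", "replicate", "course_id")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0)
    stop("sample metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$course_id <- as.character(samples$course_id)
  samples$time <- as.numeric(samples$time)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample IDs in metadata")
  if (any(!is.finite(samples$time)) || any(samples$time < 0))
    stop("sample times must be finite and >= 0")
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1L))
    stop("replicate indices must be integers >= 1")
  key <- paste(samples$course_id, samples$time, samples$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("every (course_id, time, replicate) triple must be unique")
  absent <- setdiff(colnames(values), samples$sample_id)
  if (length(absent) > 0)
    stop("sample column(s) absent from metadata: ", paste(absent, collapse = ", "))
  extra <- setdiff(samples$sample_id, colnames(values))
  if (length(extra) > 0)
    stop("metadata sample(s) absent from matrix: ", paste(extra, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, scale = scale),
            class = "time_course_matrix")
}

#' @export
print.time_course_matrix <- function(x, ...) {
  cat(sprintf("time_course_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  courses: %s\n", paste(unique(x$samples$course_id), collapse = ", ")))
  cat(sprintf("  times: %s h\n",
              paste(sort(unique(x$samples$time)), collapse = ", ")))
  invisible(x)
}

#' Log10-transform FPKM values with a floor for zeros
#'
#' @param fpkm Numeric vector of FPKM values, >= 0.
#' @param floor Value substituted for `log10(0)`. The default of -4 lies below
#'   the conventional low-expression cutoff of -2, so zero-FPKM genes are
#'   always rejected by [expression_filter()].
#' @return `log10(fpkm)` elementwise, with zeros mapped to `floor`.
#' @examples
#' log_fpkm(c(1, 1000, 0))
#' @export
log_fpkm <- function(fpkm, floor = -4) {
  if (!is.numeric(fpkm)) stop("`fpkm` must be numeric")
  if (any(!is.na(fpkm) & fpkm < 0)) stop("negative FPKM value encountered")
  out <- ifelse(fpkm > 0, log10(fpkm), floor)
  out
}

#' Read an expression matrix and its sample metadata
#'
#' Expects genes as rows (first column gene ID, header row of sample IDs) and
#' a metadata table with columns `sample_id`, `time`, `replicate`,
#' `course_id`. Tab-delimited by default; comma-separated files are detected
#' from the `.csv` extension or can be forced with `sep`.
#'
#' @param matrix_path Path to the expression matrix (TSV/CSV).
#' @param meta_path Path to the sample metadata table (TSV/CSV).
#' @param log_transformed If `FALSE` (default) the file holds raw FPKM, which
#'   is log10-transformed on load via [log_fpkm()]; if `TRUE` it is already on
#'   the log scale and stored as is.
#' @param floor Floor passed to [log_fpkm()] for zero FPKM.
#' @param scale Scale declared for the loaded matrix (see
#'   [time_course_matrix()]).
#' @param sep Field separator; `NULL` (default) picks "," for `.csv`, tab
#'   otherwise.
#' @return A [time_course_matrix()].
#' @export
read_time_course <- function(matrix_path, meta_path, log_transformed = FALSE,
                             floor = -4, scale = "absolute", sep = NULL) {
  sep_for <- function(path) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(matrix_path, header = TRUE, sep = sep_for(matrix_path),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(raw) < 2)
    stop("expression matrix must have a gene-ID column plus sample columns: ",
         matrix_path)
  gene_ids <- as.character(raw[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ID in ", matrix_path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- colnames(vals)[!apply(vals, 2, function(col) all(!is.na(suppressWarnings(as.numeric(col)))))]
    stop("non-numeric values in column(s): ", paste(bad, collapse = ", "))
  }
  rownames(vals) <- gene_ids
  if (!log_transformed) {
    if (any(vals < 0))
      stop("negative FPKM in ", matrix_path,
           "; use log_transformed = TRUE for log-scale files")
    vals[] <- log_fpkm(vals, floor = floor)
  }
  meta <- utils::read.table(meta_path, header = TRUE, sep = sep_for(meta_path),
                            stringsAsFactors = FALSE, comment.char = "")
  time_course_matrix(vals, meta, scale = scale)
}

#' Write a time-course matrix and its metadata back to disk
#'
#' Emits the same dialect [read_time_course()] consumes. Values are written on
#' the log scale; reading back with `log_transformed = TRUE` round-trips.
#'
#' @param tcm A [time_course_matrix()].
#' @param matrix_path,meta_path Output paths.
#' @param sep Field separator (default tab).
#' @return Invisibly, `tcm`.
#' @export
write_time_course <- function(tcm, matrix_path, meta_path, sep = "\t") {
  stopifnot(inherits(tcm, "time_course_matrix"))
  df <- data.frame(gene_id = rownames(tcm$values), tcm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(tcm$samples, meta_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(tcm)
}

#' Normalize each gene to its earliest time point
#'
#' For induction-style courses reported relative to baseline: subtracts, per
#' gene and per course, the log value at the earliest time point (the mean
#' over t0 replicates when replicated). On the log scale this is equivalent to
#' dividing FPKM by the t0 level.
#'
#' @param tcm An absolute-scale [time_course_matrix()].
#' @return A `time_course_matrix` with `scale = "relative_to_t0"`; every
#'   gene's value at the earliest time point of each course is 0.
#' @export
normalize_to_t0 <- function(tcm) {
  stopifnot(inherits(tcm, "time_course_matrix"))
  if (tcm$scale != "absolute")
    stop("matrix is already on the relative_to_t0 scale")
  vals <- tcm$values
  for (course in unique(tcm$samples$course_id)) {
    in_course <- tcm$samples$course_id == course
    t0 <- min(tcm$samples$time[in_course])
    at_t0 <- in_course & tcm$samples$time == t0
    if (!any(at_t0))
      stop("no t0 sample for course ", course)
    baseline <- rowMeans(vals[, at_t0, drop = FALSE])
    vals[, in_course] <- vals[, in_course, drop = FALSE] - baseline
  }
  time_course_matrix(vals, tcm$samples, scale = "relative_to_t0")
}
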