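#' Phylotype-by-sample coverage matrix
#'
#' The central container of the pipeline: a non-negative numeric matrix
#' with phylotypes as rows and samples as columns, tagged with the
#' processing stage of its values (`raw` mapped-read coverage,
#' `normalized` coverage, or `relative` percent abundance).
#'
#' @param values Numeric matrix with unique, non-empty row and column
#'   names; all entries finite and >= 0.
#' @param stage One of `"raw"`, `"normalized"`, `"relative"`.
#' @return A validated matrix of class `coverage_matrix`.
#' @export
coverage_matrix <- function(values, stage = c("raw", "normalized", "relative")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry phylotype row names and sample column names")
  dup_r <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_r))
    stop("duplicate phylotype ids: ", paste(unique(dup_r), collapse = ", "))
  dup_c <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_c))
    stop("duplicate sample ids: ", paste(unique(dup_c), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("coverage values must be finite and non-missing")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative coverage at phylotype '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  structure(values, stage = stage, class = c("coverage_matrix", "matrix", "array"))
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("coverage_matrix: %d phylotypes x %d samples (stage: %s)\n",
              nrow(x), ncol(x), attr(x, "stage")))
  n <- min(nrow(x), 5L)
  m <- min(ncol(x), 5L)
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

coverage_stage <- function(m) attr(m, "stage")

#' Read a coverage matrix from TSV
#'
#' Expects a tab-separated table whose first column holds phylotype ids
#' and whose header row holds sample ids, with a numeric body. Rows that
#' are all zero are kept but flagged via a message and the `zero_rows`
#' attribute.
#'
#' @param path Path to the TSV file.
#' @param stage Stage tag to attach (default `"raw"`).
#' @return A `coverage_matrix`.
#' @export
read_coverage_matrix <- function(path, stage = "raw") {
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("coverage table needs an id column and >= 1 sample")
  ids <- as.character(df[[1]])
  samp <- colnames(df)[-1]
  dup <- samp[duplicated(samp)]
  if (length(dup))
    stop("duplicate sample ids in header: ", paste(unique(dup), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v))
      stop(sprintf("non-numeric coverage in sample '%s'", samp[j]))
    if (anyNA(v))
      stop(sprintf("missing coverage in sample '%s', phylotype '%s'",
                   samp[j], ids[which(is.na(v))[1]]))
    if (any(v < 0))
      stop(sprintf("negative coverage in sample '%s', phylotype '%s'",
                   samp[j], ids[which(v < 0)[1]]))
  }
  values <- as.matrix(body)
  rownames(values) <- ids
  m <- coverage_matrix(values, stage = stage)
  zero <- rownames(m)[rowSums(m) == 0]
  if (length(zero)) {
    message(length(zero), " phylotype(s) with all-zero coverage: ",
            paste(utils::head(zero, 5), collapse = ", "),
            if (length(zero) > 5) ", ..." else "")
    attr(m, "zero_rows") <- zero
  }
  m
}

#' Write a coverage matrix to TSV
#'
#' @param m A `coverage_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_matrix <- function(m, path) {
  df <- data.frame(phylotype_id = rownames(m), unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Required columns: `sample_id`, `habitat` (one of
#' [habitat_levels()]), `read_count`. Optional: `site_id` and any of the
#' 14 environmental variables of [env_variable_names()]; missing values
#' are written/read as `NA`. Latitude and longitude, when present, are
#' checked against their valid ranges.
#'
#' @param path Path to the TSV file.
#' @return A validated `data.frame` of class `sample_table`.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  validate_sample_table(df)
}

#' Validate a sample metadata table
#'
#' @param df A data frame with at least `sample_id`, `habitat`,
#'   `read_count` columns.
#' @return `df` with `habitat` as a factor over [habitat_levels()],
#'   classed `sample_table`.
#' @export
validate_sample_table <- function(df) {
  need <- c("sample_id", "habitat", "read_count")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "))
  bad_h <- setdiff(unique(as.character(df$habitat)), habitat_levels())
  if (length(bad_h))
    stop("unknown habitat label(s): ", paste(bad_h, collapse = ", "))
  df$habitat <- factor(as.character(df$habitat), levels = habitat_levels())
  if (!is.numeric(df$read_count) || anyNA(df$read_count) || any(df$read_count <= 0))
    stop("read_count must be a positive number for every sample")
  if ("LAT" %in% colnames(df)) {
    bad <- which(!is.na(df$LAT) & abs(df$LAT) > 90)
    if (length(bad))
      stop(sprintf("latitude out of [-90, 90] for sample '%s'",
                   df$sample_id[bad[1]]))
  }
  if ("LON" %in% colnames(df)) {
    bad <- which(!is.na(df$LON) & abs(df$LON) > 180)
    if (length(bad))
      stop(sprintf("longitude out of [-180, 180] for sample '%s'",
                   df$sample_id[bad[1]]))
  }
  for (v in intersect(env_variable_names(), colnames(df))) {
    if (!is.numeric(df[[v]]))
      stop(sprintf("environmental variable '%s' must be numeric", v))
    if (any(!is.finite(df[[v]]) & !is.na(df[[v]])))
      stop(sprintf("environmental variable '%s' has non-finite values", v))
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Write a sample table to TSV
#'
#' @param samples A `sample_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Environmental variables of a sample table as a matrix
#'
#' @param samples A `sample_table`.
#' @param variables Variable names (default: all of
#'   [env_variable_names()] present in the table).
#' @return Numeric matrix, samples as rows (named by `sample_id`).
#' @export
sample_env <- function(samples, variables = NULL) {
  if (is.null(variables))
    variables <- intersect(env_variable_names(), colnames(samples))
  miss <- setdiff(variables, colnames(samples))
  if (length(miss)) stop("variables not in sample table: ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(as.data.frame(samples)[, variables, drop = FALSE])
  rownames(m) <- samples$sample_id
  m
}

# align a sample table to the columns of a coverage matrix
match_samples <- function(m, samples) {
  idx <- match(colnames(m), samples$sample_id)
  if (anyNA(idx))
    stop("samples missing from sample table: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  samples[idx, , drop = FALSE]
}
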