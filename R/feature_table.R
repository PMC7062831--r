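#' Construct a single-cell feature table
#'
#' A feature table is the universal currency of the package: one row per
#' segmented cell, a `cell_id` column, a `sample_id` column identifying the
#' tissue section / batch, and one non-negative numeric column per marker
#' holding the cell's mean intensity in that channel (linear scale,
#' arbitrary fluorescence units).
#'
#' @param intensities numeric matrix or data.frame, cells x markers, with
#'   marker names as column names. All values must be finite and >= 0.
#' @param cell_id character vector of per-cell identifiers, unique within
#'   each sample.
#' @param sample_id character vector (or single value, recycled) naming the
#'   sample/section each cell belongs to.
#' @return A `feature_table`: a data.frame with columns `cell_id`,
#'   `sample_id`, then one column per marker.
#' @examples
#' ft <- feature_table(
#'   cbind(CK7 = c(9, 0.5, 8), CD45 = c(0.4, 7, 0.6)),
#'   cell_id = c("c1", "c2", "c3"), sample_id = "S1"
#' )
#' marker_names(ft)
#' @export
feature_table <- function(intensities, cell_id, sample_id) {
  intensities <- as.data.frame(intensities)
  if (is.null(names(intensities)) || any(!nzchar(names(intensities)))) {
    abort_format("marker columns must be named")
  }
  df <- data.frame(
    cell_id = as.character(cell_id),
    sample_id = as.character(rep_len(sample_id, nrow(intensities))),
    intensities,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  validate_feature_table(df)
}

#' Marker names of a feature table
#'
#' Every column other than `cell_id` and `sample_id` is a marker.
#' @param table a `feature_table`.
#' @return character vector of marker names, in column order.
#' @export
marker_names <- function(table) {
  setdiff(names(table), c("cell_id", "sample_id"))
}

#' Validate a feature table
#'
#' Enforces the container invariants: `cell_id`/`sample_id` present, at
#' least two marker columns, all intensities finite and non-negative,
#' `cell_id` unique within each `sample_id`, at least one cell.
#'
#' @param df data.frame to validate.
#' @param drop_bad_rows if `TRUE`, rows with negative or non-finite marker
#'   values are dropped (with a message) instead of raising an error.
#' @return the validated `feature_table` (invisibly classed).
#' @export
validate_feature_table <- function(df, drop_bad_rows = FALSE) {
  need <- c("cell_id", "sample_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_format(paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  markers <- setdiff(names(df), need)
  if (length(markers) < 2) {
    abort_format("a feature table needs at least 2 marker columns")
  }
  if (nrow(df) == 0) abort_restore("empty feature table", "restore_empty_error")

  # locate by name, order by convention
  df <- df[, c(need, markers)]
  df$cell_id <- as.character(df$cell_id)
  df$sample_id <- as.character(df$sample_id)
  for (m in markers) {
    v <- df[[m]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      df[[m]] <- v
    }
  }
  X <- as.matrix(df[, markers, drop = FALSE])
  bad <- !is.finite(X) | X < 0
  bad_row <- rowSums(bad) > 0
  if (any(bad_row)) {
    if (drop_bad_rows) {
      message(sum(bad_row), " row(s) with negative or non-finite intensities dropped")
      df <- df[!bad_row, , drop = FALSE]
      if (nrow(df) == 0) abort_restore("empty feature table after dropping bad rows",
                                       "restore_empty_error")
    } else {
      abort_integrity(paste0(
        sum(bad_row), " row(s) contain negative or non-finite marker values"
      ))
    }
  }
  key <- paste(df$sample_id, df$cell_id, sep = "\r")
  if (anyDuplicated(key)) {
    abort_integrity("duplicate (sample_id, cell_id) pairs")
  }
  rownames(df) <- NULL
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Read a feature table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row containing
#' `cell_id`, `sample_id` and at least two marker columns (located by name,
#' not position). Lines starting with `#` are treated as comments (the CLI
#' writes a config-hash header line).
#'
#' @param path path to the CSV file.
#' @param drop_bad_rows drop rows with negative/non-finite intensities
#'   instead of erroring (default `FALSE`: strict).
#' @return a validated [feature_table].
#' @export
read_feature_table <- function(path, drop_bad_rows = FALSE) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  validate_feature_table(df, drop_bad_rows = drop_bad_rows)
}

#' Write a feature table to CSV
#'
#' Serializes with 15 significant digits so a read/write round trip
#' reproduces intensities to full double precision for practical purposes.
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @param header_comment optional character line(s) written before the
#'   header, each prefixed with `#`.
#' @export
write_feature_table <- function(table, path, header_comment = NULL) {
  table <- validate_feature_table(table)
  out <- as.data.frame(table)
  for (m in marker_names(table)) {
    out[[m]] <- formatC(out[[m]], digits = 15, format = "g")
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a feature table to one or more samples
#'
#' @param table a `feature_table`.
#' @param samples character vector of `sample_id` values to keep.
#' @return a `feature_table` containing only those samples.
#' @export
subset_samples <- function(table, samples) {
  missing <- setdiff(samples, unique(table$sample_id))
  if (length(missing)) {
    abort_config(paste0("sample(s) not in table: ", paste(missing, collapse = ", ")))
  }
  out <- table[table$sample_id %in% samples, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}
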