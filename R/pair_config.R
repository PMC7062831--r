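#' Construct a marker pair configuration
#'
#' A pair configuration maps each *reference* marker to one or more
#' mutually exclusive *target* markers. Cells positive for a target cannot
#' express the reference, so they serve as negative controls when inferring
#' the reference marker's background level. Curated lists (e.g. cytokeratins
#' vs CD45) are the recommended input; data-driven candidates can be found
#' with [rank_exclusive_pairs()].
#'
#' @param pairs named list: reference marker -> character vector of target
#'   markers.
#' @return a `pair_config` (validated named list).
#' @examples
#' pair_config(list(CK7 = c("CD45", "CD8"), CD45 = "CK7"))
#' @export
pair_config <- function(pairs) {
  if (!is.list(pairs) || is.null(names(pairs)) || any(!nzchar(names(pairs)))) {
    abort_config("pair config must be a named list of reference -> targets")
  }
  pairs <- lapply(pairs, function(x) as.character(unlist(x)))
  for (ref in names(pairs)) {
    tg <- pairs[[ref]]
    if (length(tg) == 0) {
      abort_config(paste0("reference marker '", ref, "' has an empty target list"))
    }
    if (ref %in% tg) {
      abort_config(paste0("reference marker '", ref, "' lists itself as a target"))
    }
    if (anyDuplicated(tg)) {
      abort_config(paste0("duplicate targets for reference marker '", ref, "'"))
    }
  }
  structure(pairs, class = "pair_config")
}

#' Read a pair configuration from YAML or JSON
#'
#' The format mirrors a curated positive/negative marker set table: a
#' mapping from each reference marker to its mutually exclusive partners.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated [pair_config].
#' @export
read_pair_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::fromJSON(path, simplifyVector = TRUE),
    abort_config(paste0("unsupported pair-config format: .", ext))
  )
  pair_config(raw)
}

#' Check a pair configuration against a feature table
#'
#' Every reference and target marker named in the config must exist as a
#' marker column of the table.
#'
#' @param pairs a [pair_config].
#' @param table a [feature_table].
#' @return `pairs`, invisibly, if valid.
#' @export
validate_pairs <- function(pairs, table) {
  mk <- marker_names(table)
  named <- union(names(pairs), unlist(pairs, use.names = FALSE))
  missing <- setdiff(named, mk)
  if (length(missing)) {
    abort_config(paste0(
      "pair config references marker(s) absent from the table: ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(pairs)
}
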