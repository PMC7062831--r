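#' Infer the background level of one marker in one sample
#'
#' For each mutually exclusive target marker, slices the sample's
#' (reference, target) intensities, splits the cells into two groups with
#' [split_two_groups()], and summarizes the reference-marker intensity of
#' the reference-negative group — those cells do not express the reference
#' marker, so their reference-channel signal is pure background
#' (autofluorescence plus nonspecific staining, times the sample's gain).
#' In expectation the negative group's reference intensity equals the
#' sample's background level `B = G * b`, whatever the gain `G` is.
#'
#' The per-target summary statistic is the `mean` (default; background is
#' defined in expectations), the `max` (which yields the guarantee that
#' every negative cell normalizes to <= 1), or a `percentile` (a robust
#' max, default 99th). With several targets the per-target estimates are
#' combined by their median — multiple exclusive partners make the
#' inference robust to a single corrupted (non-specifically stained)
#' partner.
#'
#' @param table a [feature_table].
#' @param sample `sample_id` to infer for.
#' @param reference marker whose background is inferred.
#' @param targets character vector of mutually exclusive partner markers.
#' @param backend,lambda_rel,max_cells,min_mean_ratio,seed passed to
#'   [split_two_groups()].
#' @param method background statistic: `"mean"`, `"max"` or
#'   `"percentile"`.
#' @param percentile percentile used when `method = "percentile"`.
#' @return a `background_estimate`: list with `sample_id`, `reference`,
#'   `targets_used`, `B_bar` (> 0), `method`, `percentile`, `n_negative`
#'   (negative-group size of the last usable target), `per_target`
#'   (named per-target estimates) and `signal_level` (mean positive-group
#'   minus mean negative-group reference intensity, a diagnostic).
#' @export
infer_background <- function(table, sample, reference, targets,
                             backend = c("ssc", "nnmf", "gmm"),
                             method = c("mean", "max", "percentile"),
                             percentile = 99, lambda_rel = 0.05,
                             max_cells = 2000, min_mean_ratio = 1.2,
                             seed = 0) {
  backend <- match.arg(backend)
  method <- match.arg(method)
  if (reference %in% targets) abort_config("reference cannot be its own target")

  per_target <- stats::setNames(rep(NA_real_, length(targets)), targets)
  n_negative <- NA_integer_
  signal_level <- NA_real_
  for (tg in targets) {
    sl <- pair_slice(table, sample, reference, tg)
    grp <- tryCatch(
      split_two_groups(sl, backend = backend, lambda_rel = lambda_rel,
                       max_cells = max_cells, min_mean_ratio = min_mean_ratio,
                       seed = seed),
      restore_no_positive = function(e) NULL,
      restore_too_few_cells = function(e) NULL
    )
    if (is.null(grp)) next
    neg_ref <- sl$Y[grp$labels[sl$cell_id] == 0L, 1]
    per_target[tg] <- switch(method,
      mean = mean(neg_ref),
      max = max(neg_ref),
      percentile = unname(stats::quantile(neg_ref, percentile / 100, type = 7))
    )
    n_negative <- length(neg_ref)
    signal_level <- grp$group_means[["positive"]] - grp$group_means[["negative"]]
  }

  usable <- per_target[!is.na(per_target)]
  if (length(usable) == 0) {
    abort_infer(sprintf(
      "cannot infer background for ('%s', '%s'): no target yielded a usable split",
      sample, reference
    ))
  }
  B_bar <- stats::median(usable)
  if (B_bar <= 0) {
    col <- table[[reference]][table$sample_id == sample]
    pos_vals <- col[col > 0]
    if (length(pos_vals) == 0) {
      abort_infer(sprintf(
        "all '%s' intensities in sample '%s' are zero: background undefined",
        reference, sample
      ))
    }
    B_bar <- 0.5 * min(pos_vals)
    warning(sprintf(
      "background for ('%s', '%s') computed to 0; floored at %.4g",
      sample, reference, B_bar
    ), call. = FALSE)
  }
  structure(
    list(sample_id = sample, reference = reference,
         targets_used = names(usable), B_bar = B_bar, method = method,
         percentile = if (method == "percentile") percentile else NA_real_,
         n_negative = n_negative, per_target = per_target,
         signal_level = signal_level),
    class = "background_estimate"
  )
}

#' Infer backgrounds for every (sample, reference) in a pair config
#'
#' Loops [infer_background()] over all reference markers of `pairs` and
#' all samples of the table. In `"local"` mode (the method's default) a
#' background is inferred per sample; in `"global"` mode all samples'
#' cells are pooled, one background is inferred per reference marker, and
#' that single value is assigned to every sample — the comparison mode
#' that exposes batch effects when it disagrees with local inference.
#'
#' @param table a [feature_table].
#' @param pairs a [pair_config].
#' @param mode `"local"` or `"global"`.
#' @param samples samples to process (default: all in the table).
#' @inheritParams infer_background
#' @return a `background_table` data.frame: `sample_id`, `marker`,
#'   `B_bar`, `method`, `n_negative`, `targets_used` (semicolon-joined).
#'   (sample, marker) combinations whose inference failed are omitted
#'   with a warning.
#' @export
infer_backgrounds <- function(table, pairs, mode = c("local", "global"),
                              samples = unique(table$sample_id),
                              backend = c("ssc", "nnmf", "gmm"),
                              method = c("mean", "max", "percentile"),
                              percentile = 99, lambda_rel = 0.05,
                              max_cells = 2000, min_mean_ratio = 1.2,
                              seed = 0) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  method <- match.arg(method)
  validate_pairs(pairs, table)

  rows <- list()
  add <- function(est, sample) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample, marker = est$reference, B_bar = est$B_bar,
      method = est$method, n_negative = est$n_negative,
      targets_used = paste(est$targets_used, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }

  for (ref in names(pairs)) {
    targets <- pairs[[ref]]
    if (mode == "local") {
      for (s in samples) {
        est <- tryCatch(
          infer_background(table, s, ref, targets, backend = backend,
                           method = method, percentile = percentile,
                           lambda_rel = lambda_rel, max_cells = max_cells,
                           min_mean_ratio = min_mean_ratio, seed = seed),
          restore_infer_error = function(e) {
            warning(conditionMessage(e), call. = FALSE); NULL
          }
        )
        if (!is.null(est)) add(est, s)
      }
    } else {
      pooled <- table[table$sample_id %in% samples, , drop = FALSE]
      pooled$cell_id <- paste(pooled$sample_id, pooled$cell_id, sep = ":")
      pooled$sample_id <- "__pooled__"
      class(pooled) <- c("feature_table", "data.frame")
      est <- tryCatch(
        infer_background(pooled, "__pooled__", ref, targets, backend = backend,
                         method = method, percentile = percentile,
                         lambda_rel = lambda_rel, max_cells = max_cells,
                         min_mean_ratio = min_mean_ratio, seed = seed),
        restore_infer_error = function(e) {
          warning(conditionMessage(e), call. = FALSE); NULL
        }
      )
      if (!is.null(est)) for (s in samples) add(est, s)
    }
  }
  if (length(rows) == 0) {
    abort_infer("background inference failed for every (sample, marker)")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("background_table", "data.frame")
  out
}

#' Normalize a feature table by inferred backgrounds
#'
#' Divides each cell's intensity by the background estimate of its
#' (sample, marker): `y_norm = y / B_bar`. Because the background carries
#' the sample's multiplicative gain (`B_bar = G * b_bar`), the gain
#' cancels and normalized values are comparable across samples and
#' batches. After normalization 1 is the natural unit: with the `max`
#' background statistic every negative cell lands at <= 1 and positive
#' signal lies above 1. Within a (sample, marker) the cell ordering is
#' preserved exactly (division by a positive scalar).
#'
#' @param table a [feature_table].
#' @param backgrounds a `background_table` from [infer_backgrounds()],
#'   or any data.frame with columns `sample_id`, `marker`, `B_bar`.
#' @param strict error (rather than pass through unchanged with a
#'   message) when a (sample, marker) lacks an estimate.
#' @return a `feature_table` of unitless normalized intensities.
#' @export
normalize_intensities <- function(table, backgrounds, strict = FALSE) {
  stopifnot(all(c("sample_id", "marker", "B_bar") %in% names(backgrounds)))
  if (any(backgrounds$B_bar <= 0)) abort_integrity("background estimates must be > 0")
  out <- table
  mk <- marker_names(table)
  missing <- character(0)
  for (s in unique(table$sample_id)) {
    idx <- table$sample_id == s
    for (m in mk) {
      b <- backgrounds$B_bar[backgrounds$sample_id == s & backgrounds$marker == m]
      if (length(b) == 0) {
        missing <- c(missing, paste0(s, "/", m))
        next
      }
      if (length(b) > 1) abort_integrity(
        paste0("multiple background estimates for (", s, ", ", m, ")")
      )
      out[[m]][idx] <- table[[m]][idx] / b
    }
  }
  if (length(missing)) {
    missing <- unique(missing)
    if (strict) {
      abort_infer(paste0("no background estimate for: ",
                         paste(missing, collapse = ", ")))
    }
    message(length(missing),
            " (sample, marker) combination(s) passed through un-normalized")
  }
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Call marker-positive cells on a normalized table
#'
#' A cell is positive for a marker iff its normalized intensity is
#' strictly above `threshold`. After division by background, 1.0 is the
#' background level itself, so the default threshold is 1: a cell exactly
#' at background is not evidence of signal.
#'
#' @param normalized a normalized [feature_table].
#' @param threshold positivity cutoff (> 0, default 1).
#' @return logical matrix, cells x markers, with `cell_id` rownames.
#' @export
call_positive <- function(normalized, threshold = 1) {
  if (threshold <= 0) abort_config("threshold must be > 0")
  mk <- marker_names(normalized)
  P <- as.matrix(normalized[, mk, drop = FALSE]) > threshold
  rownames(P) <- normalized$cell_id
  P
}
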