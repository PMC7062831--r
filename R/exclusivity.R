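#' Mutual-exclusivity ratio of two marker intensity vectors
#'
#' Stacks the two raw (uncentered) intensity columns into an n x 2 matrix
#' D and returns the ratio of its singular values, r = sigma2 / sigma1.
#' The singular values are the semi-axes of the ellipse traced by D, so
#' highly correlated markers give an elongated ellipse (r near 0) while
#' mutually exclusive markers — every cell positive for at most one of
#' the two — spread mass along both axes and give r near 1.
#'
#' No centering or per-column standardization is applied: the ratio is
#' defined on the raw mean intensities, so the ellipse is anchored at the
#' origin. An exactly rank-1 pair (e.g. identical columns) returns 0.
#'
#' @param x_i,x_j non-negative numeric vectors of equal length (>= 2), the
#'   per-cell mean intensities of the two markers.
#' @return the ratio in `[0, 1]`.
#' @examples
#' exclusivity_ratio(c(1, 2, 3), c(2, 4, 6))      # rank-1: 0
#' exclusivity_ratio(c(1, 0), c(0, 1))            # orthonormal: 1
#' @export
exclusivity_ratio <- function(x_i, x_j) {
  if (length(x_i) != length(x_j)) abort_integrity("marker vectors differ in length")
  if (length(x_i) < 2) abort_integrity("need at least 2 cells")
  if (any(!is.finite(x_i)) || any(!is.finite(x_j)) || any(x_i < 0) || any(x_j < 0)) {
    abort_integrity("intensities must be finite and non-negative")
  }
  if (all(x_i == 0) && all(x_j == 0)) {
    abort_restore("all-zero intensity pair: exclusivity ratio undefined",
                  "restore_degenerate_error")
  }
  # singular values of D = [x_i x_j] via the closed-form eigenvalues of the
  # 2 x 2 Gram matrix; the discriminant (a - b)^2 + 4 c^2 makes the result
  # exactly symmetric under swapping the two markers
  a <- sum(x_i^2); b <- sum(x_j^2); cc <- sum(x_i * x_j)
  disc <- sqrt((a - b)^2 + 4 * cc^2)
  lam1 <- (a + b + disc) / 2
  lam2 <- max((a + b - disc) / 2, 0)
  r <- min(sqrt(lam2 / lam1), 1)
  # a rank-1 D has sigma2 = 0 up to floating-point dust; the Gram route
  # resolves ratios down to sqrt(machine eps), so anything below that is 0
  if (r < 1e-8) r <- 0
  r
}

#' Rank candidate mutually exclusive partners for a reference marker
#'
#' Computes the exclusivity ratio of the reference marker against every
#' other marker and returns the `top_k` partners by descending ratio —
#' the data-driven route to negative-control candidates (cross-check the
#' winners against biological knowledge before trusting them). Ties are
#' broken by marker name so the ranking is deterministic.
#'
#' @param table a [feature_table].
#' @param reference marker name to find partners for.
#' @param top_k number of top pairs to return (default 5).
#' @param log1p apply `log1p` to intensities before scoring (off by
#'   default; the ratio is defined on linear-scale intensities).
#' @param per_sample if `TRUE`, compute the ratio within each sample and
#'   rank by the median across samples (robust to batch effects in the
#'   ranking itself); default pools all cells.
#' @return data.frame with columns `marker_i`, `marker_j`, `ratio`,
#'   `n_cells`, ordered by descending `ratio`.
#' @export
rank_exclusive_pairs <- function(table, reference, top_k = 5,
                                 log1p = FALSE, per_sample = FALSE) {
  mk <- marker_names(table)
  if (!reference %in% mk) {
    abort_config(paste0("reference marker '", reference, "' not in table"))
  }
  if (top_k < 1) abort_config("top_k must be >= 1")
  others <- setdiff(mk, reference)
  tf <- if (log1p) base::log1p else identity

  score_one <- function(j) {
    if (!per_sample) {
      return(exclusivity_ratio(tf(table[[reference]]), tf(table[[j]])))
    }
    per <- vapply(split(seq_len(nrow(table)), table$sample_id), function(idx) {
      tryCatch(
        exclusivity_ratio(tf(table[[reference]][idx]), tf(table[[j]][idx])),
        restore_error = function(e) NA_real_
      )
    }, numeric(1))
    stats::median(per, na.rm = TRUE)
  }

  out <- data.frame(
    marker_i = reference,
    marker_j = others,
    ratio = vapply(others, score_one, numeric(1)),
    n_cells = nrow(table),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$ratio, out$marker_j), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' All-pairs exclusivity matrix
#'
#' Full m x m symmetric matrix of pairwise exclusivity ratios over the
#' pooled cells, a QC report for the whole panel. The diagonal is set to 0
#' by convention: a marker's pairing with itself is exactly rank-1.
#'
#' @inheritParams rank_exclusive_pairs
#' @return symmetric numeric matrix with marker dimnames, entries in
#'   `[0, 1]`, zero diagonal.
#' @export
exclusivity_matrix <- function(table, log1p = FALSE) {
  mk <- marker_names(table)
  tf <- if (log1p) base::log1p else identity
  m <- length(mk)
  R <- matrix(0, m, m, dimnames = list(mk, mk))
  for (a in seq_len(m - 1)) {
    for (b in seq((a + 1), m)) {
      r <- tryCatch(
        exclusivity_ratio(tf(table[[mk[a]]]), tf(table[[mk[b]]])),
        restore_error = function(e) NA_real_
      )
      R[a, b] <- R[b, a] <- r
    }
  }
  R
}
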