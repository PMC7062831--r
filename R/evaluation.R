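#' Correlation between two cell-composition vectors
#'
#' Composition vectors hold, per category (marker-positive class or
#' k-means cluster), the fraction of a sample's cells falling in it.
#' Adjacent replicate sections should show near-identical compositions,
#' so this correlation is the reproducibility metric: high when
#' normalization has removed between-section intensity variation.
#'
#' @param a,b numeric vectors over the same categories (names, if
#'   present, must match as sets).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   vector has zero variance.
#' @export
composition_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      abort_integrity("composition vectors cover different categories")
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b) || length(a) < 2) {
    abort_integrity("need >= 2 shared categories for a correlation")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance composition vector: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}

#' Coefficient of variation of replicate positive-cell counts
#'
#' `c_v = sigma / mu` (relative standard deviation) of the positive-cell
#' counts of one marker across replicate sections, with `sigma` the
#' sample standard deviation (denominator n - 1 — a handful of replicate
#' sections is a sample, not a population). Small `c_v` means the count
#' is reproducible across sections.
#'
#' @param counts numeric vector of per-replicate counts (length >= 2).
#' @return `sd(counts) / mean(counts)`, or `NA` (with a warning) when the
#'   mean is 0.
#' @examples
#' coefficient_of_variation(c(8, 10, 12))  # 0.2
#' @export
coefficient_of_variation <- function(counts) {
  if (length(counts) < 2) abort_integrity("need >= 2 replicates")
  mu <- mean(counts)
  if (mu == 0) {
    warning("zero mean count: coefficient of variation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::sd(counts) / mu
}

#' Per-sample marker-positive composition
#'
#' Counts and fractions of positive cells per marker and sample, from a
#' positivity matrix as produced by [call_positive()].
#'
#' @param positive logical cells x markers matrix.
#' @param sample_id character vector aligning rows of `positive` to
#'   samples.
#' @return data.frame: `sample_id`, `marker`, `count`, `total_cells`,
#'   `fraction`.
#' @export
positive_composition <- function(positive, sample_id) {
  stopifnot(nrow(positive) == length(sample_id))
  rows <- lapply(split(seq_along(sample_id), sample_id), function(idx) {
    data.frame(
      sample_id = sample_id[idx[1]],
      marker = colnames(positive),
      count = colSums(positive[idx, , drop = FALSE]),
      total_cells = length(idx),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fraction <- out$count / out$total_cells
  rownames(out) <- NULL
  out
}

# all unordered sample pairs of a character vector
sample_pairs <- function(samples) {
  if (length(samples) < 2) return(NULL)
  idx <- utils::combn(length(samples), 2)
  data.frame(sample_i = samples[idx[1, ]], sample_j = samples[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Local vs global background comparison on replicate groups
#'
#' The batch-effect detector: for each replicate group (e.g. the adjacent
#' sections of one TMA core), infers backgrounds per section ("local")
#' and on the pooled sections ("global"), calls positives, and reports
#' (1) pairwise correlations of the per-section marker-positive
#' composition vectors and (2) the per-marker coefficient of variation of
#' positive counts, under each mode. When sections carry different gains,
#' a single global background mis-thresholds some sections, so local
#' correlations exceed global ones and local `c_v` is smaller — when
#' there is no batch effect the two modes agree.
#'
#' @param table a [feature_table].
#' @param groups named list: group id -> character vector of >= 2
#'   `sample_id`s treated as near-technical replicates.
#' @param pairs a [pair_config].
#' @param modes which modes to run (default both).
#' @param threshold positivity threshold on normalized intensities.
#' @param cor_method correlation flavor for compositions.
#' @inheritParams infer_backgrounds
#' @return list of data.frames: `correlations` (group_id, mode, sample_i,
#'   sample_j, correlation), `cv` (group_id, mode, marker, cv) and
#'   `compositions` (per sample/marker/mode counts and fractions).
#' @export
local_vs_global_report <- function(table, groups, pairs,
                                   modes = c("local", "global"),
                                   backend = c("ssc", "nnmf", "gmm"),
                                   method = c("mean", "max", "percentile"),
                                   percentile = 99, threshold = 1,
                                   cor_method = "pearson",
                                   lambda_rel = 0.05, max_cells = 2000,
                                   min_mean_ratio = 1.2, seed = 0) {
  backend <- match.arg(backend)
  method <- match.arg(method)
  for (g in names(groups)) {
    if (length(groups[[g]]) < 2) {
      abort_config(paste0("replicate group '", g, "' needs >= 2 samples"))
    }
  }
  cors <- list(); cvs <- list(); comps <- list()
  for (g in names(groups)) {
    sub <- subset_samples(table, groups[[g]])
    for (mode in modes) {
      bg <- infer_backgrounds(sub, pairs, mode = mode, backend = backend,
                              method = method, percentile = percentile,
                              lambda_rel = lambda_rel, max_cells = max_cells,
                              min_mean_ratio = min_mean_ratio, seed = seed)
      norm <- normalize_intensities(sub, bg)
      pos <- call_positive(norm, threshold = threshold)
      # restrict to markers that actually have background estimates
      est_mk <- intersect(colnames(pos), unique(bg$marker))
      comp <- positive_composition(pos[, est_mk, drop = FALSE], norm$sample_id)
      comp$group_id <- g; comp$mode <- mode
      comps[[length(comps) + 1L]] <- comp

      frac <- stats::xtabs(fraction ~ sample_id + marker, data = comp)
      pr <- sample_pairs(rownames(frac))
      if (!is.null(pr)) {
        pr$correlation <- vapply(seq_len(nrow(pr)), function(i) {
          composition_correlation(frac[pr$sample_i[i], ], frac[pr$sample_j[i], ],
                                  method = cor_method)
        }, numeric(1))
        pr$group_id <- g; pr$mode <- mode
        cors[[length(cors) + 1L]] <- pr
      }
      cnt <- stats::xtabs(count ~ sample_id + marker, data = comp)
      cvs[[length(cvs) + 1L]] <- data.frame(
        group_id = g, mode = mode, marker = colnames(cnt),
        cv = apply(cnt, 2, coefficient_of_variation),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  list(
    correlations = do.call(rbind, cors)[, c("group_id", "mode", "sample_i",
                                            "sample_j", "correlation")],
    cv = do.call(rbind, cvs),
    compositions = do.call(rbind, comps)
  )
}

#' k-means composition concordance across replicate sections
#'
#' Pools the cells of each replicate group, clusters them with seeded
#' k-means for each `k`, and correlates the per-section cluster
#' composition vectors. Without normalization, sections with different
#' gains split the same cell type into section-specific clusters and the
#' concordance drops; run this on the raw and the normalized table to
#' quantify the batch effect and its removal.
#'
#' @param table a [feature_table] (raw or normalized).
#' @param groups named list: group id -> sample ids (>= 2).
#' @param k_values numbers of clusters to sweep (default 5, 10, 15, 20).
#' @param seed RNG seed (k-means++-style restarts: `nstart = 10`).
#' @param standardize z-score each marker over the pooled cells before
#'   clustering so markers contribute comparably to the Euclidean metric.
#' @param cor_method correlation flavor.
#' @return data.frame: `group_id`, `k`, `sample_i`, `sample_j`,
#'   `correlation`.
#' @export
kmeans_concordance <- function(table, groups, k_values = c(5, 10, 15, 20),
                               seed = 0, standardize = TRUE,
                               cor_method = "pearson") {
  mk <- marker_names(table)
  out <- list()
  for (g in names(groups)) {
    sub <- subset_samples(table, groups[[g]])
    X <- as.matrix(sub[, mk, drop = FALSE])
    if (standardize) {
      X <- scale(X)
      X[, !is.finite(colSums(X))] <- 0   # constant markers carry no signal
    }
    for (k in k_values) {
      if (k >= nrow(X)) abort_config("k must be smaller than the number of cells")
      set.seed(seed)
      cl <- stats::kmeans(X, centers = k, nstart = 10, iter.max = 50)$cluster
      tab <- table(sub$sample_id, factor(cl, levels = seq_len(k)))
      frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
      pr <- sample_pairs(rownames(frac))
      pr$correlation <- vapply(seq_len(nrow(pr)), function(i) {
        composition_correlation(frac[pr$sample_i[i], ], frac[pr$sample_j[i], ],
                                method = cor_method)
      }, numeric(1))
      pr$group_id <- g; pr$k <- k
      out[[length(out) + 1L]] <- pr
    }
  }
  do.call(rbind, out)[, c("group_id", "k", "sample_i", "sample_j", "correlation")]
}

#' Percentile-window quantile normalization (baseline comparator)
#'
#' The simple alignment this package's method is compared against: per
#' marker, each sample's intensity window between the `lower_pct` and
#' `upper_pct` percentiles (1st and 99th by default) is mapped affinely
#' onto the pooled window; values outside the window follow the same
#' affine map (clamped at 0 to keep intensities non-negative). When a
#' sample genuinely lacks positive cells for a marker, this forcibly
#' inflates its negatives up to the pooled scale — the known failure mode
#' that background-based normalization avoids.
#'
#' @param table a [feature_table] with >= 2 samples (with a single sample
#'   the transform is the identity).
#' @param lower_pct,upper_pct window percentiles (defaults 1 and 99).
#' @return a [feature_table] of aligned intensities.
#' @export
quantile_normalize <- function(table, lower_pct = 1, upper_pct = 99) {
  if (lower_pct >= upper_pct) abort_config("lower_pct must be < upper_pct")
  p <- c(lower_pct, upper_pct) / 100
  out <- table
  for (m in marker_names(table)) {
    ref <- stats::quantile(table[[m]], p, names = FALSE)
    if (ref[1] == ref[2]) {
      warning("degenerate pooled window for marker '", m, "': skipped",
              call. = FALSE)
      next
    }
    for (s in unique(table$sample_id)) {
      idx <- table$sample_id == s
      w <- stats::quantile(table[[m]][idx], p, names = FALSE)
      if (w[1] == w[2]) {
        warning("degenerate window for (", s, ", ", m, "): skipped",
                call. = FALSE)
        next
      }
      slope <- (ref[2] - ref[1]) / (w[2] - w[1])
      out[[m]][idx] <- pmax(0, ref[1] + (table[[m]][idx] - w[1]) * slope)
    }
  }
  class(out) <- c("feature_table", "data.frame")
  out
}
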