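#' Extract the two-marker slice of one sample
#'
#' Builds the n x 2 non-negative matrix of (reference, target) mean
#' intensities for the cells of one sample — the input to the two-group
#' splitters. Conceptually each row decomposes as baseline + signal on
#' each axis; a mutually exclusive pair has no cell with signal on both.
#'
#' @param table a [feature_table].
#' @param sample `sample_id` to slice.
#' @param reference,target marker names (columns 1 and 2 of the slice).
#' @return a `pair_slice`: list with `Y` (n x 2 matrix), `cell_id`,
#'   `sample_id`, `reference`, `target`.
#' @export
pair_slice <- function(table, sample, reference, target) {
  mk <- marker_names(table)
  for (m in c(reference, target)) {
    if (!m %in% mk) abort_config(paste0("marker '", m, "' not in table"))
  }
  if (reference == target) abort_config("reference and target must differ")
  idx <- table$sample_id == sample
  if (!any(idx)) abort_config(paste0("sample '", sample, "' not in table"))
  Y <- cbind(table[[reference]][idx], table[[target]][idx])
  colnames(Y) <- c(reference, target)
  structure(
    list(Y = Y, cell_id = table$cell_id[idx], sample_id = sample,
         reference = reference, target = target),
    class = "pair_slice"
  )
}

as_pair_slice <- function(Y, cell_id = NULL, sample_id = "S1",
                          reference = colnames(Y)[1], target = colnames(Y)[2]) {
  if (is.null(cell_id)) cell_id <- sprintf("c%d", seq_len(nrow(Y)))
  structure(
    list(Y = Y, cell_id = cell_id, sample_id = sample_id,
         reference = reference, target = target),
    class = "pair_slice"
  )
}

#' Sparse self-expression coefficients (SSC)
#'
#' Each cell's 2-D intensity profile is reconstructed as a sparse linear
#' combination of the other cells' profiles: minimize
#' `0.5 * ||Y' - Y'C||_F^2 + lambda * ||C||_1` subject to `diag(C) = 0`,
#' where `Y'` is the 2 x n transposed slice. Cells lying on the same axis
#' (same group) explain each other cheaply, so the nonzero pattern of `C`
#' is (approximately) block-diagonal by group. The hard equality
#' self-expression constraint is relaxed to this penalized least-squares
#' form, the standard practice with noisy data; non-negativity of the
#' coefficients is not enforced — the l1 penalty on non-negative data does
#' not select negative coefficients.
#'
#' `lambda = lambda_rel * max_{m != k} |y_m' y_k|`, so the solution is
#' invariant to a global rescaling of `Y`. Solved by ADMM; because the
#' data matrix has rank <= 2 the per-iteration linear solve reduces to a
#' 2 x 2 system (Woodbury identity), making the solver O(n^2) per sweep.
#'
#' @param Y n x 2 non-negative matrix (n >= 3).
#' @param lambda_rel relative l1 penalty (default 0.05).
#' @param rho ADMM penalty parameter; defaults to `lambda`.
#' @param max_iter,tol ADMM iteration cap and relative primal-residual
#'   tolerance.
#' @return n x n coefficient matrix with zero diagonal.
#' @export
ssc_coefficients <- function(Y, lambda_rel = 0.05, rho = NULL,
                             max_iter = 200, tol = 1e-5) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 3) abort_restore("SSC needs at least 3 cells", "restore_too_few_cells")
  if (any(Y < 0) || any(!is.finite(Y))) {
    abort_integrity("slice intensities must be finite and non-negative")
  }
  K <- tcrossprod(Y)                       # K[m, k] = <y_m, y_k>
  offmax <- max(abs(K - diag(diag(K), n)))
  if (offmax == 0) {
    abort_restore("degenerate slice: all pairwise inner products are zero",
                  "restore_degenerate_error")
  }
  lambda <- lambda_rel * offmax
  if (is.null(rho)) rho <- lambda
  # (K + rho I)^{-1} = (1/rho) [I - Y S Y'] with S = (rho I_2 + Y'Y)^{-1}
  S <- solve(rho * diag(2) + crossprod(Y))
  A <- matrix(0, n, n)
  U <- matrix(0, n, n)
  kappa <- lambda / rho
  for (it in seq_len(max_iter)) {
    M <- K + rho * (A - U)
    C <- (M - Y %*% (S %*% (t(Y) %*% M))) / rho
    Z <- C + U
    A_new <- sign(Z) * pmax(abs(Z) - kappa, 0)
    diag(A_new) <- 0
    U <- U + C - A_new
    delta <- sqrt(sum((C - A_new)^2)) / max(1, sqrt(sum(A_new^2)))
    A <- A_new
    if (delta < tol) break
  }
  A
}

# Normalized-Laplacian spectral bipartition of a symmetric affinity matrix.
# Top-2 eigenvectors of D^{-1/2} W D^{-1/2}, row-normalized, seeded k-means.
spectral_bipartition <- function(W, seed = 0) {
  n <- nrow(W)
  d <- rowSums(W)
  d[d < 1e-12] <- 1e-12
  inv_sqrt_d <- 1 / sqrt(d)
  Wn <- W * outer(inv_sqrt_d, inv_sqrt_d)
  V <- eigen(Wn, symmetric = TRUE)$vectors[, 1:2, drop = FALSE]
  rn <- sqrt(rowSums(V^2))
  rn[rn < 1e-12] <- 1
  V <- V / rn
  set.seed(seed)
  stats::kmeans(V, centers = 2, nstart = 10)$cluster
}

#' Rank-2 non-negative matrix factorization
#'
#' Frobenius-norm NNMF `Y ~ W H` with `W, H >= 0`, fit by multiplicative
#' updates. For a 2-column `Y` the unconstrained problem has the trivial
#' solution `W = Y, H = I`; the factors are therefore initialized at
#' random (off-identity) with a small number of seeded restarts, and the
#' best local optimum is returned. The per-iteration objective is
#' non-increasing, a property the test suite checks.
#'
#' @param Y non-negative matrix.
#' @param rank inner rank (default 2).
#' @param max_iter,tol iteration cap and relative objective-decrease
#'   stopping tolerance.
#' @param n_restarts random restarts (best kept).
#' @param seed RNG seed for initialization.
#' @return list with `W` (n x rank), `H` (rank x ncol), `loss` (final
#'   squared Frobenius error) and `trace` (objective per iteration of the
#'   winning restart).
#' @export
nnmf_factorize <- function(Y, rank = 2, max_iter = 500, tol = 1e-10,
                           n_restarts = 3, seed = 0) {
  Y <- as.matrix(Y)
  if (any(Y < 0) || any(!is.finite(Y))) abort_integrity("Y must be finite, non-negative")
  if (all(Y == 0)) abort_restore("all-zero matrix", "restore_degenerate_error")
  n <- nrow(Y); p <- ncol(Y)
  eps <- 1e-12
  best <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    W <- matrix(stats::runif(n * rank, 0.1, 1), n, rank) * sqrt(mean(Y) / rank)
    H <- matrix(stats::runif(rank * p, 0.1, 1), rank, p)
    obj <- rep(NA_real_, max_iter)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, Y)) / (crossprod(W) %*% H + eps)
      W <- W * (Y %*% t(H)) / (W %*% tcrossprod(H) + eps)
      o <- sum((Y - W %*% H)^2)
      obj[it] <- o
      if (is.finite(prev) && (prev - o) <= tol * max(prev, 1e-300)) {
        obj <- obj[seq_len(it)]
        break
      }
      prev <- o
    }
    fit <- list(W = W, H = H, loss = obj[length(obj)], trace = obj)
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  best
}

#' Split a pair slice into reference-positive and reference-negative cells
#'
#' Bipartitions the cells of one (reference, target) slice into two
#' groups, then labels the group with the lower mean reference intensity
#' as reference-negative (label 0) — those cells are the negative controls
#' whose reference-channel intensity measures background. Backends:
#'
#' * `ssc` (default): affinity `|C| + |C|'` from [ssc_coefficients()],
#'   spectral bipartition.
#' * `nnmf`: rank-2 [nnmf_factorize()], each cell assigned to its dominant
#'   factor.
#' * `gmm`: 2-component Gaussian mixture via \pkg{mclust}.
#'
#' The clustering recovers the two reference-intensity levels present in
#' the slice (signal and background). Because double-negative cells can
#' legitimately attach to either cluster — both resulting partitions
#' identify the same background level — the final per-cell labels are a
#' gate on the reference channel at the midpoint of the two cluster
#' means: cells below it are reference-negative (label 0). This puts
#' every background-level cell into the negative-control pool regardless
#' of which side of the ambiguous cut it landed on.
#'
#' If the two cluster means of the reference marker are closer than
#' `min_mean_ratio` (default 1.2), the split is declared unreliable and a
#' `restore_no_positive` condition is raised: a marker with no positive
#' cells in the sample cannot (and need not) be processed.
#'
#' For slices larger than `max_cells`, a seeded uniform subsample is
#' clustered; the gate derived from it labels all cells.
#'
#' @param slice a [pair_slice()].
#' @param backend one of `"ssc"`, `"nnmf"`, `"gmm"`.
#' @param lambda_rel SSC penalty (see [ssc_coefficients()]).
#' @param max_cells subsample threshold for the O(n^2) backends.
#' @param min_mean_ratio minimum ratio of group means of the reference
#'   marker below which the no-positive-cells condition is raised.
#' @param seed RNG seed for all stochastic steps.
#' @return a `group_labels` object: list with `labels` (named 0/1 integer
#'   vector, 1 = reference-positive), `backend`, `n_subsampled` (0 if no
#'   subsampling), `gate` (the reference-intensity cut used) and
#'   `group_means` (reference-marker means of the two labeled groups).
#' @export
split_two_groups <- function(slice, backend = c("ssc", "nnmf", "gmm"),
                             lambda_rel = 0.05, max_cells = 2000,
                             min_mean_ratio = 1.2, seed = 0) {
  backend <- match.arg(backend)
  Y <- slice$Y
  n <- nrow(Y)
  if (n < 2) abort_restore("need at least 2 cells to split", "restore_too_few_cells")

  n_subsampled <- 0L
  if (n > max_cells) {
    set.seed(seed)
    sub <- sort(sample.int(n, max_cells))
    n_subsampled <- as.integer(max_cells)
  } else {
    sub <- seq_len(n)
  }
  Ys <- Y[sub, , drop = FALSE]

  cl_sub <- switch(backend,
    ssc = {
      C <- ssc_coefficients(Ys, lambda_rel = lambda_rel)
      spectral_bipartition(abs(C) + t(abs(C)), seed = seed)
    },
    nnmf = {
      fit <- nnmf_factorize(Ys, rank = 2, seed = seed)
      max.col(fit$W, ties.method = "first")
    },
    gmm = {
      set.seed(seed)
      mclustBIC <- mclust::mclustBIC   # Mclust() resolves this in the caller
      fit <- tryCatch(
        mclust::Mclust(Ys, G = 2, verbose = FALSE),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        # zero-variance components make the mixture singular (e.g. exactly
        # constant groups); fall back to a seeded 2-means partition
        set.seed(seed)
        km <- tryCatch(stats::kmeans(Ys, centers = 2, nstart = 10),
                       error = function(e) NULL)
        if (is.null(km)) {
          abort_no_positive("Gaussian-mixture fit failed (degenerate slice)")
        }
        km$cluster
      } else {
        as.integer(fit$classification)
      }
    }
  )

  ref_sub <- Ys[, 1]
  mu <- vapply(1:2, function(g) mean(ref_sub[cl_sub == g]), numeric(1))
  if (any(!is.finite(mu))) {
    abort_no_positive("two-group split produced an empty group")
  }
  lo <- min(mu); hi <- max(mu)
  ratio <- if (lo > 0) hi / lo else if (hi > 0) Inf else NaN
  if (is.nan(ratio) || (is.finite(ratio) && ratio < min_mean_ratio)) {
    abort_no_positive(sprintf(
      "group means of '%s' indistinguishable (ratio %.3g < %.3g): no positive cells",
      slice$reference, ratio, min_mean_ratio
    ))
  }

  gate <- (lo + hi) / 2
  labels <- as.integer(Y[, 1] > gate)   # 1 = reference-positive
  if (all(labels == labels[1])) {
    # cannot happen when the gated cells include the clustered subsample,
    # but guard the contract: both groups must be non-empty
    abort_no_positive("reference gate produced a single group")
  }
  names(labels) <- slice$cell_id
  structure(
    list(labels = labels, backend = backend, n_subsampled = n_subsampled,
         gate = gate,
         group_means = c(negative = mean(Y[labels == 0L, 1]),
                         positive = mean(Y[labels == 1L, 1]))),
    class = "group_labels"
  )
}
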