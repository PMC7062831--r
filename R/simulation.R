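# Per-cell baseline draws around b_bar with relative spread noise_cv.
# Fluorescence backgrounds are positive and right-skewed, hence the
# lognormal default; "none" gives the exact noise-free b_bar.
draw_baseline <- function(n, b_bar, noise_cv, noise) {
  switch(noise,
    none = rep(b_bar, n),
    lognormal = {
      sdlog <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(n, meanlog = log(b_bar) - sdlog^2 / 2, sdlog = sdlog)
    },
    gamma = {
      shape <- 1 / noise_cv^2
      stats::rgamma(n, shape = shape, rate = shape / b_bar)
    },
    gaussian = pmax(stats::rnorm(n, b_bar, noise_cv * b_bar), 1e-9 * b_bar),
    abort_config(paste0("unknown noise model: ", noise))
  )
}

sim_noise_models <- c("lognormal", "gamma", "gaussian", "none")

#' Simulate two samples with different gains (two-marker design)
#'
#' The core gain/SBR study: two samples `p` and `q`, a reference marker
#' and one mutually exclusive partner. Every observed intensity is
#' `y = G * (b + s)`: a per-cell baseline `b` drawn around `b_bar`, a
#' deterministic signal `s = sbr * b_bar` on the marker the cell is
#' positive for (`s = 0` otherwise), and the sample's multiplicative gain
#' `G` lumping every technical source of intensity variation. Positive
#' cells carry reference signal; negative cells carry signal on the
#' partner instead, so they are genuine negative controls for the
#' reference channel.
#'
#' @param n_pos,n_neg cells per sample that are positive / negative for
#'   the reference marker.
#' @param gains per-sample gains: length-2 vector (applied to both
#'   markers) or 2 x 2 matrix (samples x markers). The default encodes a
#'   gain ratio `G2 / G1 = 0.5`.
#' @param sbr signal-to-baseline ratio `s / b_bar` in sample 1.
#' @param signal_ratio true signal ratio `s_q / s_p` (default 1: equal
#'   true signals).
#' @param b_bar mean baseline (both samples, both markers).
#' @param noise_cv relative spread of the per-cell baseline (default 0.2).
#' @param noise one of `"lognormal"` (default), `"gamma"`, `"gaussian"`
#'   (truncated at 0), `"none"` (exact baselines).
#' @param seed RNG seed; identical arguments give bit-identical output.
#' @param reference,target marker names.
#' @return list with `table` (a [feature_table], samples `"S1"`, `"S2"`)
#'   and `truth` (data.frame of per-cell latent `b`/`s` per marker and
#'   positivity `label`; gains, `b_bar`, and per-sample signals attached
#'   as attributes `gains`, `b_bar`, `signal`).
#' @export
simulate_two_samples <- function(n_pos = 2000, n_neg = 2000,
                                 gains = c(1, 0.5), sbr = 100,
                                 signal_ratio = 1, b_bar = 1,
                                 noise_cv = 0.2,
                                 noise = sim_noise_models, seed = 0,
                                 reference = "CK7", target = "CD45") {
  noise <- match.arg(noise)
  if (sbr < 0 || b_bar <= 0 || signal_ratio < 0) abort_config("invalid simulation config")
  G <- if (is.matrix(gains)) gains else cbind(gains, gains)
  if (!all(dim(G) == c(2, 2)) || any(G <= 0)) {
    abort_config("gains must be 2 positive per-sample values or a 2 x 2 positive matrix")
  }
  s_sig <- c(sbr * b_bar, signal_ratio * sbr * b_bar)

  set.seed(seed)
  tabs <- vector("list", 2); truths <- vector("list", 2)
  for (k in 1:2) {
    n <- n_pos + n_neg
    positive <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    b_ref <- draw_baseline(n, b_bar, noise_cv, noise)
    b_tgt <- draw_baseline(n, b_bar, noise_cv, noise)
    s_ref <- ifelse(positive, s_sig[k], 0)
    s_tgt <- ifelse(positive, 0, s_sig[k])
    X <- cbind(G[k, 1] * (b_ref + s_ref), G[k, 2] * (b_tgt + s_tgt))
    colnames(X) <- c(reference, target)
    ids <- sprintf("S%d_c%04d", k, seq_len(n))
    tabs[[k]] <- feature_table(X, cell_id = ids, sample_id = paste0("S", k))
    truths[[k]] <- data.frame(
      cell_id = ids, sample_id = paste0("S", k),
      label = ifelse(positive, "pos", "neg"),
      b_ref = b_ref, s_ref = s_ref, b_tgt = b_tgt, s_tgt = s_tgt,
      stringsAsFactors = FALSE
    )
  }
  table <- rbind(tabs[[1]], tabs[[2]])
  class(table) <- c("feature_table", "data.frame")
  truth <- rbind(truths[[1]], truths[[2]])
  dimnames(G) <- list(c("S1", "S2"), c(reference, target))
  attr(truth, "gains") <- G
  attr(truth, "b_bar") <- b_bar
  attr(truth, "signal") <- stats::setNames(s_sig, c("S1", "S2"))
  list(table = table, truth = truth)
}

#' Measured vs predicted cross-sample ratios over an SBR grid
#'
#' For every (SBR, true signal ratio) grid point, simulates the
#' two-sample design over seeded replicates and reports the mean
#' cross-sample ratio of positive-cell intensities, with and without
#' background normalization, next to the closed-form prediction
#' `(b_bar + s_q) / (b_bar + s_p)`. Backgrounds here are taken from the
#' simulator's true negative labels (mean reference intensity of the
#' negative cells), isolating the normalization arithmetic from the
#' clustering step. The normalized ratio approaches the true signal
#' ratio as SBR grows; the un-normalized ratio converges to the gain
#' ratio times the signal ratio — low SBR combined with a high true
#' ratio is the distortion region.
#'
#' @param sbr_grid,ratio_grid positive grids to sweep.
#' @param n_pos,n_neg,gains,b_bar,noise_cv,noise as in
#'   [simulate_two_samples()].
#' @param replicates seeded replicates per grid point.
#' @param seed base seed; replicate r of grid point g uses a seed derived
#'   deterministically from it.
#' @return data.frame: `sbr`, `true_ratio`, `normalized_ratio`,
#'   `unnormalized_ratio`, their Monte-Carlo standard errors, and
#'   `closed_form`.
#' @export
ratio_distortion_grid <- function(sbr_grid = c(1, 2, 5, 10, 100),
                                  ratio_grid = c(1, 2, 5, 10),
                                  n_pos = 500, n_neg = 500,
                                  gains = c(1, 0.5), b_bar = 1,
                                  noise_cv = 0.2,
                                  noise = sim_noise_models,
                                  replicates = 5, seed = 0) {
  noise <- match.arg(noise)
  if (!length(sbr_grid) || !length(ratio_grid)) abort_config("empty grid")
  out <- expand.grid(sbr = sbr_grid, true_ratio = ratio_grid,
                     KEEP.OUT.ATTRS = FALSE)
  out$normalized_ratio <- out$unnormalized_ratio <- NA_real_
  out$normalized_se <- out$unnormalized_se <- NA_real_
  out$closed_form <- NA_real_
  counter <- 0L
  for (i in seq_len(nrow(out))) {
    nr <- numeric(replicates); ur <- numeric(replicates)
    for (r in seq_len(replicates)) {
      counter <- counter + 1L
      sim <- simulate_two_samples(
        n_pos = n_pos, n_neg = n_neg, gains = gains, sbr = out$sbr[i],
        signal_ratio = out$true_ratio[i], b_bar = b_bar,
        noise_cv = noise_cv, noise = noise, seed = seed + 7919L * counter
      )
      ref <- marker_names(sim$table)[1]
      y <- sim$table[[ref]]
      pos <- sim$truth$label == "pos"
      s1 <- sim$table$sample_id == "S1"
      m1 <- mean(y[s1 & pos]); m2 <- mean(y[!s1 & pos])
      B1 <- mean(y[s1 & !pos]); B2 <- mean(y[!s1 & !pos])
      ur[r] <- m2 / m1
      nr[r] <- (m2 / B2) / (m1 / B1)
    }
    out$unnormalized_ratio[i] <- mean(ur)
    out$normalized_ratio[i] <- mean(nr)
    out$unnormalized_se[i] <- stats::sd(ur) / sqrt(replicates)
    out$normalized_se[i] <- stats::sd(nr) / sqrt(replicates)
    s_p <- out$sbr[i] * b_bar
    s_q <- out$true_ratio[i] * s_p
    out$closed_form[i] <- (b_bar + s_q) / (b_bar + s_p)
  }
  out
}

#' Three-group fixture for the separability guarantee
#'
#' Generates the canonical mutually exclusive configuration for one
#' (i, j) marker pair: group 1 cells positive for marker i, group 2
#' positive for marker j, group 3 double-negative. With signal well above
#' baseline (`s >> b`), no cell of one group is a positive linear
#' combination of cells from the other two groups, which is what makes
#' the two-group splitters identify the reference-positive set; the
#' fixture's truth labels are the oracle for that property.
#'
#' @param n integer vector of the three group sizes (each >= 2).
#' @param sbr signal-to-baseline ratio; a warning is issued below 5
#'   (the `s >> b` premise weakens) and below 1 (premise violated).
#' @param b_bar baseline mean, scalar or per-marker length 2.
#' @param gain multiplicative gain applied to the whole slice.
#' @inheritParams simulate_two_samples
#' @return list with `slice` (a `pair_slice`) and `truth` (data.frame:
#'   `cell_id`, `group` in 1:3, latent `b_i`, `b_j`, `s_i`, `s_j`).
#' @export
three_group_fixture <- function(n = c(40, 40, 40), sbr = 20, b_bar = 1,
                           noise_cv = 0.2, noise = sim_noise_models,
                           gain = 1, seed = 0,
                           reference = "CK7", target = "CD45") {
  noise <- match.arg(noise)
  if (length(n) != 3 || any(n < 2)) abort_config("need three group sizes >= 2")
  if (sbr <= 1) {
    warning("sbr <= 1: signal is not above baseline; separability premise violated",
            call. = FALSE)
  } else if (sbr < 5) {
    warning("sbr < 5: the s >> b premise is weak; splits may be unreliable",
            call. = FALSE)
  }
  b_bar <- rep_len(b_bar, 2)
  s_i <- sbr * b_bar[1]; s_j <- sbr * b_bar[2]
  N <- sum(n)
  group <- rep(1:3, n)

  set.seed(seed)
  b_i <- draw_baseline(N, b_bar[1], noise_cv, noise)
  b_j <- draw_baseline(N, b_bar[2], noise_cv, noise)
  sig_i <- ifelse(group == 1, s_i, 0)
  sig_j <- ifelse(group == 2, s_j, 0)
  Y <- gain * cbind(b_i + sig_i, b_j + sig_j)
  colnames(Y) <- c(reference, target)
  ids <- sprintf("c%04d", seq_len(N))
  truth <- data.frame(cell_id = ids, group = group,
                      b_i = b_i, b_j = b_j, s_i = sig_i, s_j = sig_j,
                      stringsAsFactors = FALSE)
  list(slice = as_pair_slice(Y, cell_id = ids, reference = reference,
                             target = target),
       truth = truth)
}

#' Expansion coefficients of one cell profile over two others
#'
#' Solves the 2 x 2 linear system `y_p = alpha * y_q + beta * y_r` for
#' cells drawn from the three mutually exclusive groups. Under `s >> b`
#' at least one of `alpha`, `beta` is negative for every such triple —
#' the separability argument behind the two-group splitters. Returns
#' `c(NA, NA)` when the system is (numerically) singular.
#'
#' @param y_p,y_q,y_r length-2 non-negative profiles.
#' @return named numeric `c(alpha, beta)`.
#' @export
triple_coefficients <- function(y_p, y_q, y_r) {
  A <- cbind(y_q, y_r)
  if (abs(det(A)) < 1e-12 * max(1, max(abs(A))^2)) {
    return(c(alpha = NA_real_, beta = NA_real_))
  }
  ab <- solve(A, y_p)
  c(alpha = ab[1], beta = ab[2])
}

#' Simulate adjacent replicate sections with planted batch effects
#'
#' Emulates adjacent sections cut from one tissue core: near-identical
#' cell-type composition (small Dirichlet-multinomial jitter) but
#' per-section, per-marker gains. The default panel has a cancer block
#' and an immune block; cancer cells express the cancer markers, immune
#' cells the immune markers, and the remaining cells neither — so every
#' cross-block pair is mutually exclusive by construction.
#'
#' @param n_sections number of sections (>= 2).
#' @param n_cells cells per section.
#' @param gains per-section gains for the `gain_block` markers (length
#'   `n_sections`), or a full `n_sections` x n_markers matrix. Markers
#'   outside the block keep gain 1. The default `c(1, 2, 0.5)` plants a
#'   strong batch effect on the cancer block.
#' @param panel named list of marker blocks; cells of type `t` are
#'   positive for exactly the markers in `panel[[t]]`.
#' @param gain_block name of the block the gain vector applies to
#'   (ignored for matrix `gains`; `NULL` applies it to all markers).
#' @param composition expected cell-type fractions over
#'   `c(names(panel), "negative")`; must sum to 1.
#' @param dirichlet_conc concentration of the per-section composition
#'   jitter (larger = more faithful replicates; default 200).
#' @param signal_cv relative spread of per-cell signal strength within a
#'   positive population (lognormal, default 0.5). Real marker expression
#'   is heterogeneous within a cell type; without this spread, clustering
#'   with more clusters than cell types would partition pure noise.
#' @inheritParams simulate_two_samples
#' @return list with `table` (a [feature_table], samples `"Sec1"` ...)
#'   and `truth` (data.frame: `cell_id`, `sample_id`, `cell_type`;
#'   attributes `gains` (sections x markers), `composition` (planted
#'   per-section fractions), `positive_markers` (list per cell type)).
#' @export
simulate_sections <- function(n_sections = 3, n_cells = 600,
                              gains = c(1, 2, 0.5),
                              panel = list(cancer = c("CK7", "Ecad"),
                                           immune = c("CD45", "CD8")),
                              gain_block = "cancer",
                              composition = c(cancer = 0.45, immune = 0.25,
                                              negative = 0.30),
                              dirichlet_conc = 200, sbr = 10, b_bar = 1,
                              noise_cv = 0.2, signal_cv = 0.5,
                              noise = sim_noise_models, seed = 0) {
  noise <- match.arg(noise)
  if (n_sections < 2) abort_config("need at least 2 sections")
  markers <- unlist(panel, use.names = FALSE)
  if (anyDuplicated(markers) || length(markers) < 2) {
    abort_config("panel blocks must name >= 2 distinct markers")
  }
  types <- c(names(panel), "negative")
  if (!setequal(names(composition), types)) {
    abort_config("composition must cover every panel block plus 'negative'")
  }
  composition <- composition[types]
  if (abs(sum(composition) - 1) > 1e-9) abort_config("composition must sum to 1")

  if (is.matrix(gains)) {
    if (!all(dim(gains) == c(n_sections, length(markers)))) {
      abort_config("gain matrix must be n_sections x n_markers")
    }
    G <- gains
  } else {
    if (length(gains) != n_sections) {
      abort_config("need one gain per section (or a full gain matrix)")
    }
    G <- matrix(1, n_sections, length(markers))
    affected <- if (is.null(gain_block)) markers else panel[[gain_block]]
    G[, match(affected, markers)] <- gains
  }
  if (any(G <= 0)) abort_config("gains must be > 0")
  dimnames(G) <- list(sprintf("Sec%d", seq_len(n_sections)), markers)

  s_sig <- sbr * b_bar
  set.seed(seed)
  tabs <- vector("list", n_sections); truths <- vector("list", n_sections)
  planted <- matrix(NA_real_, n_sections, length(types),
                    dimnames = list(rownames(G), types))
  for (k in seq_len(n_sections)) {
    w <- stats::rgamma(length(types), shape = dirichlet_conc * composition)
    w <- w / sum(w)
    counts <- as.vector(stats::rmultinom(1, n_cells, w))
    planted[k, ] <- counts / n_cells
    cell_type <- rep(types, counts)
    X <- matrix(NA_real_, n_cells, length(markers),
                dimnames = list(NULL, markers))
    for (m in seq_along(markers)) {
      b <- draw_baseline(n_cells, b_bar, noise_cv, noise)
      pos_types <- names(panel)[vapply(panel, function(bl) markers[m] %in% bl,
                                       logical(1))]
      h <- if (signal_cv > 0 && noise != "none") {
        draw_baseline(n_cells, 1, signal_cv, "lognormal")
      } else rep(1, n_cells)
      s <- ifelse(cell_type %in% pos_types, s_sig * h, 0)
      X[, m] <- G[k, m] * (b + s)
    }
    ids <- sprintf("Sec%d_c%04d", k, seq_len(n_cells))
    tabs[[k]] <- feature_table(X, cell_id = ids, sample_id = rownames(G)[k])
    truths[[k]] <- data.frame(cell_id = ids, sample_id = rownames(G)[k],
                              cell_type = cell_type, stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, tabs)
  class(table) <- c("feature_table", "data.frame")
  truth <- do.call(rbind, truths)
  attr(truth, "gains") <- G
  attr(truth, "composition") <- planted
  attr(truth, "positive_markers") <- panel
  list(table = table, truth = truth)
}

#' Cross-block pair configuration for a marker panel
#'
#' Builds the natural [pair_config] for a blocked panel: each marker's
#' mutually exclusive targets are all markers of the *other* blocks.
#'
#' @param panel named list of marker blocks, as in [simulate_sections()].
#' @return a [pair_config].
#' @export
panel_pair_config <- function(panel) {
  markers <- unlist(panel, use.names = FALSE)
  pairs <- list()
  for (bl in names(panel)) {
    others <- setdiff(markers, panel[[bl]])
    for (m in panel[[bl]]) pairs[[m]] <- others
  }
  pair_config(pairs)
}
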