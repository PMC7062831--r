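# separable constant-intensity sample: negatives at exactly 2, positives 12
constant_sample <- function(n_pos = 15, n_neg = 15) {
  feature_table(
    cbind(CK7 = rep(c(12, 2), c(n_pos, n_neg)),
          CD45 = rep(c(2, 12), c(n_pos, n_neg))),
    cell_id = sprintf("c%02d", seq_len(n_pos + n_neg)), sample_id = "S1"
  )
}

test_that("background of a separable constant sample is exact for each statistic", {
  ft <- constant_sample()
  for (b in c("ssc", "nnmf", "gmm")) {
    est <- infer_background(ft, "S1", "CK7", "CD45", backend = b, seed = 0)
    expect_equal(est$B_bar, 2.0)
    expect_equal(est$n_negative, 15L)
  }
  est_max <- infer_background(ft, "S1", "CK7", "CD45", method = "max", seed = 0)
  expect_equal(est_max$B_bar, 2.0)
  est_pct <- infer_background(ft, "S1", "CK7", "CD45", method = "percentile",
                              percentile = 90, seed = 0)
  expect_equal(est_pct$B_bar, 2.0)
})

test_that("two-sample simulation backgrounds land within 10% of G * b_bar", {
  for (seed in 1:5) {
    sim <- simulate_two_samples(n_pos = 250, n_neg = 250, sbr = 10, seed = seed)
    G <- attr(sim$truth, "gains")
    for (s in c("S1", "S2")) {
      est <- infer_background(sim$table, s, "CK7", "CD45",
                              backend = "ssc", seed = seed)
      expect_lt(abs(est$B_bar - G[s, "CK7"]) / G[s, "CK7"], 0.10)
    }
  }
})

test_that("the median across targets shrugs off one corrupted partner", {
  set.seed(33)
  n <- 60
  pos <- rep(c(TRUE, FALSE), each = n / 2)
  ref <- ifelse(pos, stats::runif(n, 10, 14), stats::runif(n, 1.8, 2.2))
  ft <- feature_table(
    cbind(CK7 = ref,
          CD45 = ifelse(pos, stats::runif(n, 1.8, 2.2), stats::runif(n, 10, 14)),
          CD8 = ifelse(pos, stats::runif(n, 1.8, 2.2), stats::runif(n, 10, 14)),
          BADTARGET = ref),   # positively correlated: useless as a control
    cell_id = sprintf("c%02d", 1:n), sample_id = "S1"
  )
  est <- infer_background(ft, "S1", "CK7", c("CD45", "CD8", "BADTARGET"),
                          backend = "gmm", seed = 1)
  expect_lt(abs(est$B_bar - 2) / 2, 0.10)
})

test_that("all-identical slices across every target raise cannot-infer", {
  ft <- feature_table(
    cbind(CK7 = rep(3, 10), CD45 = rep(5, 10)),
    cell_id = sprintf("c%02d", 1:10), sample_id = "S1"
  )
  expect_error(infer_background(ft, "S1", "CK7", "CD45", backend = "nnmf"),
               class = "restore_infer_error")
})

test_that("a zero background is floored with a warning, never divided by", {
  ft <- feature_table(
    cbind(CK7 = rep(c(10, 0), each = 10), CD45 = rep(c(0.5, 10), each = 10)),
    cell_id = sprintf("c%02d", 1:20), sample_id = "S1"
  )
  expect_warning(
    est <- infer_background(ft, "S1", "CK7", "CD45", backend = "gmm", seed = 0),
    "floored"
  )
  expect_gt(est$B_bar, 0)
})

test_that("normalization divides by B_bar: definitional unit, passthrough, strict mode", {
  ft <- constant_sample()
  bg <- data.frame(sample_id = "S1", marker = "CK7", B_bar = 2)
  expect_message(norm <- normalize_intensities(ft, bg), "passed through")
  expect_equal(norm$CK7, ft$CK7 / 2)        # a cell at y = B_bar maps to 1
  expect_equal(norm$CK7[ft$CK7 == 2], rep(1, sum(ft$CK7 == 2)))
  expect_identical(norm$CD45, ft$CD45)      # no estimate: untouched
  expect_error(suppressMessages(normalize_intensities(ft, bg, strict = TRUE)),
               class = "restore_infer_error")
})

test_that("normalization preserves within-sample intensity ranks exactly", {
  sim <- simulate_two_samples(n_pos = 100, n_neg = 100, sbr = 10, seed = 2)
  pc <- pair_config(list(CK7 = "CD45", CD45 = "CK7"))
  bg <- infer_backgrounds(sim$table, pc, backend = "gmm", seed = 2)
  norm <- normalize_intensities(sim$table, bg)
  for (s in c("S1", "S2")) {
    idx <- sim$table$sample_id == s
    expect_identical(order(norm$CK7[idx]), order(sim$table$CK7[idx]))
  }
})

test_that("gain on one (sample, marker) cancels end to end", {
  sim <- simulate_two_samples(n_pos = 150, n_neg = 150, sbr = 20, seed = 4)
  pc <- pair_config(list(CK7 = "CD45", CD45 = "CK7"))
  base <- normalize_intensities(
    sim$table, infer_backgrounds(sim$table, pc, backend = "gmm", seed = 4)
  )
  for (g in c(0.1, 3, 10)) {
    bumped <- sim$table
    bumped$CK7[bumped$sample_id == "S1"] <- g * bumped$CK7[bumped$sample_id == "S1"]
    norm <- normalize_intensities(
      bumped, infer_backgrounds(bumped, pc, backend = "gmm", seed = 4)
    )
    expect_equal(norm$CK7, base$CK7, tolerance = 1e-9)
    expect_equal(norm$CD45, base$CD45, tolerance = 1e-9)
  }
})

test_that("max-statistic backgrounds bound every true negative at 1 and positives above 1", {
  sim <- simulate_two_samples(n_pos = 200, n_neg = 200, sbr = 20, seed = 6)
  neg <- sim$truth$label == "neg"
  bg <- do.call(rbind, lapply(c("S1", "S2"), function(s) {
    idx <- sim$table$sample_id == s & neg
    data.frame(sample_id = s, marker = "CK7", B_bar = max(sim$table$CK7[idx]))
  }))
  norm <- suppressMessages(normalize_intensities(sim$table, bg))
  expect_lte(max(norm$CK7[neg]), 1)
  expect_gt(min(norm$CK7[!neg]), 1)
})

test_that("positive calls use a strict threshold and recover the planted fraction", {
  ft <- feature_table(cbind(A = c(1, 1.01, 0.2), B = c(2, 0.5, 1)),
                      cell_id = c("x", "y", "z"), sample_id = "S")
  P <- call_positive(ft, threshold = 1)
  expect_identical(unname(P[, "A"]), c(FALSE, TRUE, FALSE))  # 1.0 is not positive
  expect_error(call_positive(ft, threshold = 0), class = "restore_config_error")

  sim <- simulate_two_samples(n_pos = 300, n_neg = 700, sbr = 10, seed = 8)
  pc <- pair_config(list(CK7 = "CD45"))
  bg <- infer_backgrounds(sim$table, pc, backend = "gmm", method = "max", seed = 8)
  norm <- suppressMessages(normalize_intensities(sim$table, bg))
  P <- call_positive(norm, threshold = 1)
  for (s in c("S1", "S2")) {
    frac <- mean(P[norm$sample_id == s, "CK7"])
    expect_lt(abs(frac - 0.3), 0.02)
  }
})

test_that("normalized cross-sample ratios approach the true ratio as SBR grows", {
  grid <- ratio_distortion_grid(sbr_grid = c(1, 10, 100), ratio_grid = 5,
                                n_pos = 300, n_neg = 300, replicates = 3,
                                seed = 10)
  rel_err <- abs(grid$normalized_ratio - grid$true_ratio) / grid$true_ratio
  expect_true(all(diff(rel_err[order(grid$sbr)]) < 0))
})
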