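test_that("composition correlation: identity, antisymmetry, and the hand formula", {
  expect_equal(composition_correlation(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 1.0)
  # fractions summing pairwise to a constant are perfectly anti-correlated
  expect_equal(
    composition_correlation(c(0.1, 0.3, 0.6), 2 / 3 - c(0.1, 0.3, 0.6)), -1.0
  )

  set.seed(13)
  for (i in 1:20) {
    a <- stats::runif(6); b <- stats::runif(6)
    hand <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(composition_correlation(a, b), hand, tolerance = 1e-12)
  }

  expect_error(composition_correlation(1, 2), class = "restore_integrity_error")
  expect_error(composition_correlation(c(a = 1, b = 2), c(a = 1, z = 2)),
               class = "restore_integrity_error")
  expect_warning(r <- composition_correlation(c(1, 1, 1), c(0.3, 0.4, 0.3)),
                 "zero-variance")
  expect_true(is.na(r))
})

test_that("coefficient of variation uses the sample sd and is scale invariant", {
  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(8, 10, 12)), 0.2)  # sd = 2, mean = 10
  expect_equal(coefficient_of_variation(7 * c(8, 10, 12)), 0.2)
  expect_warning(v <- coefficient_of_variation(c(0, 0)), "zero mean")
  expect_true(is.na(v))
  expect_error(coefficient_of_variation(5), class = "restore_integrity_error")
})

test_that("statistics are invariant to consistent permutation of categories", {
  set.seed(19)
  a <- stats::runif(8); b <- stats::runif(8)
  p <- sample(8)
  expect_equal(composition_correlation(a[p], b[p]), composition_correlation(a, b))
  expect_equal(coefficient_of_variation(a[p]), coefficient_of_variation(a))
})

test_that("equal-gain sections show local ~ global; planted gains separate the modes", {
  groups <- list(core = c("Sec1", "Sec2", "Sec3"))

  flat <- simulate_sections(n_sections = 3, n_cells = 350, gains = c(1, 1, 1),
                            sbr = 20, seed = 41)
  pairs <- panel_pair_config(attr(flat$truth, "positive_markers"))
  rep_flat <- local_vs_global_report(flat$table, groups, pairs,
                                     backend = "gmm", method = "max", seed = 41)
  agg <- tapply(rep_flat$correlations$correlation, rep_flat$correlations$mode, mean)
  expect_gt(agg[["local"]], 0.8)
  expect_gt(agg[["global"]], 0.8)

  batch <- simulate_sections(n_sections = 3, n_cells = 350, gains = c(1, 2, 0.5),
                             sbr = 20, seed = 41)
  rep_batch <- local_vs_global_report(batch$table, groups, pairs,
                                      backend = "gmm", method = "max", seed = 41)
  aggb <- tapply(rep_batch$correlations$correlation, rep_batch$correlations$mode, mean)
  expect_gt(aggb[["local"]], aggb[["global"]])

  # c_v smaller under local thresholds for the gain-affected markers
  cv <- rep_batch$cv
  for (m in attr(batch$truth, "positive_markers")$cancer) {
    expect_lt(cv$cv[cv$mode == "local" & cv$marker == m],
              cv$cv[cv$mode == "global" & cv$marker == m])
  }
})

test_that("kmeans concordance is 1 on copied sections and seeded runs are reproducible", {
  set.seed(23)
  X <- matrix(stats::rexp(200 * 3, rate = 0.5), 200,
              dimnames = list(NULL, c("A", "B", "C")))
  twin <- rbind(
    feature_table(X, cell_id = sprintf("c%03d", 1:200), sample_id = "R1"),
    feature_table(X, cell_id = sprintf("c%03d", 1:200), sample_id = "R2")
  )
  class(twin) <- c("feature_table", "data.frame")
  km <- kmeans_concordance(twin, list(g = c("R1", "R2")), k_values = c(3, 5),
                           seed = 1)
  expect_equal(km$correlation, rep(1, 2))

  km2 <- kmeans_concordance(twin, list(g = c("R1", "R2")), k_values = c(3, 5),
                            seed = 1)
  expect_identical(km, km2)
  expect_error(kmeans_concordance(twin, list(g = c("R1", "R2")), k_values = 400),
               class = "restore_config_error")
})

test_that("normalization raises kmeans concordance on gain-affected sections for every k", {
  sim <- simulate_sections(n_sections = 3, n_cells = 400, gains = c(1, 2, 0.5),
                           sbr = 20, seed = 47)
  groups <- list(core = c("Sec1", "Sec2", "Sec3"))
  pairs <- panel_pair_config(attr(sim$truth, "positive_markers"))
  bg <- infer_backgrounds(sim$table, pairs, backend = "gmm", seed = 47)
  norm <- normalize_intensities(sim$table, bg)
  for (k in c(5, 10)) {
    raw_k <- mean(kmeans_concordance(sim$table, groups, k_values = k,
                                     seed = 47)$correlation)
    norm_k <- mean(kmeans_concordance(norm, groups, k_values = k,
                                      seed = 47)$correlation)
    expect_gt(norm_k, raw_k)
  }
})

test_that("quantile normalization aligns percentile windows and is identity on one sample", {
  one <- random_table(n = 40, samples = "solo", seed = 3)
  expect_equal(as.data.frame(quantile_normalize(one)), as.data.frame(one))

  set.seed(29)
  base <- stats::rexp(300) + 0.1
  two <- rbind(
    feature_table(cbind(M1 = base, M2 = rev(base)),
                  cell_id = sprintf("c%03d", 1:300), sample_id = "P"),
    feature_table(cbind(M1 = 3 * base, M2 = 3 * rev(base)),
                  cell_id = sprintf("c%03d", 1:300), sample_id = "Q")
  )
  class(two) <- c("feature_table", "data.frame")
  qn <- quantile_normalize(two)
  for (m in c("M1", "M2")) {
    w <- vapply(c("P", "Q"), function(s) {
      stats::quantile(qn[[m]][qn$sample_id == s], c(0.01, 0.99), names = FALSE)
    }, numeric(2))
    expect_equal(w[, "P"], w[, "Q"], tolerance = 1e-9)
  }
})

test_that("QN inflates a positive-free sample's negatives where background inference does not", {
  set.seed(37)
  n <- 200
  # sample A has CK17 positives; sample B genuinely lacks them
  a_pos <- rep(c(TRUE, FALSE), c(80, 120))
  tabA <- feature_table(
    cbind(CK17 = ifelse(a_pos, stats::runif(n, 15, 25), stats::runif(n, 0.5, 1.5)),
          CD45 = ifelse(a_pos, stats::runif(n, 0.5, 1.5), stats::runif(n, 15, 25))),
    cell_id = sprintf("c%03d", 1:n), sample_id = "A"
  )
  tabB <- feature_table(
    cbind(CK17 = stats::runif(n, 0.5, 1.5), CD45 = stats::runif(n, 15, 25)),
    cell_id = sprintf("c%03d", 1:n), sample_id = "B"
  )
  both <- rbind(tabA, tabB)
  class(both) <- c("feature_table", "data.frame")

  qn <- quantile_normalize(both)
  # QN drags B's pure-background CK17 up toward A's positive range
  expect_gt(max(qn$CK17[qn$sample_id == "B"]),
            max(qn$CK17[qn$sample_id == "A" & !a_pos]))

  # background normalization leaves B's cells at background level (<= ~1)
  # sample B raises no-positive for CK17 and is passed through untouched,
  # which is exactly the desired non-inflating behavior
  bg <- suppressWarnings(
    infer_backgrounds(both, pair_config(list(CK17 = "CD45")),
                      backend = "gmm", method = "max", seed = 1)
  )
  norm <- suppressMessages(normalize_intensities(both, bg))
  expect_lt(stats::quantile(norm$CK17[norm$sample_id == "B"], 0.99,
                            names = FALSE), 3)
  expect_gt(stats::quantile(qn$CK17[qn$sample_id == "B"], 0.99, names = FALSE),
            3 * stats::quantile(norm$CK17[norm$sample_id == "B"], 0.99,
                                names = FALSE))
})
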