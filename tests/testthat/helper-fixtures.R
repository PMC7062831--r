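# Shared fixtures built in code; every stochastic helper takes a seed.

# tiny valid table: 3 cells, 2 markers, 1 sample
tiny_table <- function() {
  feature_table(
    cbind(CK7 = c(9, 0.5, 8), CD45 = c(0.4, 7, 0.6)),
    cell_id = c("c1", "c2", "c3"), sample_id = "S1"
  )
}

# random valid table for round-trip / permutation properties
random_table <- function(n = 20, markers = c("CK7", "CD45", "Ecad"),
                         samples = c("A", "B"), seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rexp(n * length(markers)), n,
              dimnames = list(NULL, markers))
  feature_table(X, cell_id = sprintf("c%03d", seq_len(n)),
                sample_id = sample(samples, n, replace = TRUE))
}

# closed-form exclusivity oracle: sqrt of the Gram-matrix eigenvalue ratio,
# independent of the svd() route used by the implementation
gram_ratio_oracle <- function(x_i, x_j) {
  D <- cbind(x_i, x_j)
  ev <- eigen(crossprod(D), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  sqrt(ev[2] / ev[1])
}

ari <- mclust::adjustedRandIndex
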