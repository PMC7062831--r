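---
title: "Background-anchored intensity normalization: model, algorithms, design choices"
author: "restoreNorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background-anchored intensity normalization: model, algorithms, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restoreNorm)
```

## The measurement model

A cell's measured mean intensity for marker $i$ in sample $p$ is modeled
as

$$y_i^p = G_i^p\,(b_i^p + s_i^p),$$

where $b$ is the baseline (autofluorescence plus nonspecific staining),
$s$ is true signal ($s = 0$ for a cell not expressing the marker), and
$G$ is a multiplicative gain lumping every technical source of
between-sample variation: fixation, exposure, antibody lot, batch. The
gain is the nuisance; the biology lives in $s$.

If we can find, inside each sample, a set of cells known not to express
marker $i$, then their measured intensity $G_i^p b_i^p$ estimates the
sample's background level $\bar B_i^p = G_i^p \bar b_i^p$. Dividing by
it,

$$\bar y_i^p = \frac{y_i^p}{\bar B_i^p}
            = \frac{b_i^p}{\bar b_i^p} + \frac{s_i^p}{\bar b_i^p},$$

the gain cancels identically. Negative cells land at $\bar y \le 1$ (with
the *max* background statistic, exactly so) and positive cells at
$1 + s/\bar b \gg 1$ under a high signal-to-baseline ratio (SBR). For two
positive cells from samples $p$ and $q$ with equal baselines the
normalized cross-sample ratio is
$(\bar b + s^q)/(\bar b + s^p) \to s^q/s^p$ as SBR grows; without
normalization the measured ratio converges to the gain ratio times the
signal ratio. The method therefore preserves true signal ratios in the
high-SBR regime and is known to distort them when signal approaches
baseline — that distortion is quantified, not corrected
(`ratio_distortion_grid()`).

The negative controls come from *mutually exclusive marker pairs*: for a
reference marker (e.g. CK7), cells positive for an exclusive partner
(e.g. CD45) cannot express the reference, so they are reference-negative
by construction. Panels always contain such pairs (immune vs tumor
lineages); a curated pair list is the primary input
(`read_pair_config()`), and several partners per reference make the
inference robust to one misbehaving partner (median combination, below).

## Scoring exclusivity

`exclusivity_ratio()` stacks the two raw intensity columns into
$D \in \mathbb{R}^{n\times 2}$ and returns $r = \sigma_2/\sigma_1$, the
ratio of $D$'s singular values — the semi-axes of the ellipse the data
trace around the origin. Correlated markers give an elongated ellipse
($r \to 0$); exclusive markers fill both axes ($r \to 1$).

Deliberate choices:

* **No centering, no standardization.** The ratio is defined on raw mean
  intensities; centering would move the ellipse off the origin and
  change its meaning. An optional `log1p` transform exists but is off by
  default.
* **Computation.** $\sigma$'s come from the closed-form eigenvalues of
  the $2\times 2$ Gram matrix,
  $\lambda_\pm = \tfrac12\big(a + b \pm \sqrt{(a-b)^2 + 4c^2}\big)$,
  which is exactly symmetric under swapping the two markers (a LAPACK
  SVD of $D$ is not, at the last bit). The Gram route resolves ratios
  down to $\sqrt{\varepsilon_{mach}}$; anything below $10^{-8}$ is
  reported as exactly 0 (rank-1 up to floating-point dust).
* **Cells zero in both channels are retained.** They contribute to
  neither singular direction but keep $n$ honest.
* **Caveat.** The uncentered ratio is near 1 both for truly exclusive
  (L-shaped) data and for isotropic uncorrelated noise; the score ranks
  candidates, it does not certify them. Cross-check the ranking
  (`rank_exclusive_pairs()`, pooled by default, per-sample median via
  `per_sample = TRUE`) against biological knowledge.

## Splitting a pair into positive and negative cells

For one (reference, target) slice $\mathcal{Y} \in \mathbb{R}^{n\times2}$
the cells fall into three latent groups: reference-positive,
target-positive, double-negative. With $s \gg b$ a signal-bearing profile
cannot be written as a positive combination of profiles from the other
two groups (the 2×2 solve in `triple_coefficients()` always yields a
negative coefficient), which is what makes the groups separable. Note
the guarantee is directional: a *double-negative* profile **is** a small
positive combination of a positive cell from each axis, so the
double-negatives are geometrically ambiguous — they can attach to either
side of a forced two-cluster cut, and both resulting partitions identify
the same background level.

Three backends produce the two-cluster structure:

* **`ssc`** (default): sparse self-expression. Each cell is reconstructed
  as a sparse combination of the other cells,
  $\min_C \tfrac12\|Y' - Y'C\|_F^2 + \lambda\|C\|_1$, $\mathrm{diag}(C)=0$,
  the standard penalized relaxation of the exact self-expression
  constraint (infeasible under noise). We set
  $\lambda = \lambda_{rel}\max_{m\neq k} |y_m^\top y_k|$ with
  $\lambda_{rel} = 0.05$, making the solution invariant to a global
  rescaling of the slice. The solver is ADMM; because the data matrix has
  rank ≤ 2 the per-iteration linear solve reduces to a 2×2 system via the
  Woodbury identity, so each sweep is $O(n^2)$. Non-negativity of the
  coefficients is not enforced: on non-negative data the $\ell_1$ penalty
  does not select negative coefficients. The affinity $|C| + |C|^\top$ is
  bipartitioned with a normalized-Laplacian spectral embedding and seeded
  k-means.
* **`nnmf`**: rank-2 non-negative factorization by multiplicative
  updates, cells assigned to their dominant factor. For 2-column data the
  unconstrained problem has the trivial solution $W = Y, H = I$; the
  factors are initialized at random (off-identity, seeded, 3 restarts)
  and the best local optimum is kept. The update objective is
  non-increasing, which the test suite asserts.
* **`gmm`**: 2-component Gaussian mixture via **mclust** (deterministic
  given the data). Exactly-degenerate slices (zero-variance components)
  fall back to seeded 2-means.

**Final labels are a reference-channel gate.** After clustering, the two
cluster means of the reference channel give the signal and background
levels; cells are labeled reference-negative iff their reference
intensity falls below the midpoint of the two. This resolves the
double-negative ambiguity the same way regardless of backend, targets
exactly what the split is for, and places *all* background-level cells in
the negative-control pool (more negatives, same expectation, tighter
estimate). It also makes the labels invariant to a global gain on the
slice.

**No-positive-cells detection.** If the two cluster means of the
reference channel differ by less than a factor `min_mean_ratio`
(default 1.2), the split is declared unreliable and the (sample,
reference, target) combination is skipped with a classed condition: a
marker with no positive cells in a sample is by definition not usable
(and not needed) there. The 1.2 default is a conservative floor —
roughly one baseline coefficient of variation above equality.

**Scalability.** The $O(n^2)$ backends cluster a seeded uniform
subsample of `max_cells` (default 2000) cells when the slice is larger;
the gate derived from the subsample labels every cell, so subsampled and
direct runs agree on the subsampled cells by construction.

## Background inference and normalization

`infer_background()` summarizes the negative group's reference intensity
with one of three statistics:

* **mean** (default): the background is defined in expectations; the
  sample mean is its unbiased estimate.
* **max**: gives the hard guarantee that every negative cell normalizes
  to ≤ 1 — the natural choice when the normalized table feeds a
  positivity gate at 1. Being an extreme statistic it is
  outlier-sensitive: one dim positive cell mislabeled negative inflates
  it.
* **percentile** (default 99): a robust max, recommended on real data.

With several configured targets the per-target estimates are combined by
their **median**: robustness to a single corrupted partner (nonspecific
staining makes a partner positively correlated with the reference and
useless as a control). If the estimate computes to exactly 0 (all
negatives zero), it is floored at half the smallest positive intensity in
the column, with a loud warning — division by zero never occurs.

`normalize_intensities()` divides each (sample, marker) column by its
estimate; markers or samples without a usable estimate pass through
unchanged (logged; an error in `strict` mode). Normalization preserves
within-column ranks exactly, and `call_positive()` uses a strict `> 1`
gate: a cell exactly at background is not evidence of signal.

**Local vs global.** Backgrounds are inferred per sample (`mode =
"local"`, the method proper) or on the pooled cells of several samples
(`mode = "global"`, the comparison mode). When samples carry different
gains the pooled background mis-thresholds some samples; the divergence
between the two modes is the batch-effect readout of
`local_vs_global_report()`.

## Evaluation machinery

Adjacent replicate sections share cell-type composition, so composition
is the evaluation currency:

* `composition_correlation()`: Pearson (Spearman by flag) on *fractions*,
  not counts, so section-area differences don't masquerade as
  discordance. The statistic is only informative when the category
  fractions genuinely differ — near-uniform compositions make it
  noise-dominated — which real marker panels (and the simulator's
  default composition) satisfy.
* `coefficient_of_variation()`: $c_v = \sigma/\mu$ of positive counts
  across replicates, with the *sample* standard deviation
  (denominator $n-1$): a handful of sections is a sample, not a
  population.
* `kmeans_concordance()`: seeded k-means (`nstart = 10`) on the pooled
  cells of a replicate group, per-section cluster fractions, pairwise
  correlations, swept over $k \in \{5, 10, 15, 20\}$ by default. Markers
  are z-scored over the pooled cells before clustering so they
  contribute comparably to the Euclidean metric; run it on the raw and
  the normalized table to quantify batch-effect removal. With more
  clusters than latent cell types the extra clusters carve the
  within-type expression distribution; concordance therefore declines
  slowly with $k$ and is only meaningful when within-type heterogeneity
  is real (see the simulator notes).
* `quantile_normalize()`: the baseline comparator — per marker, each
  sample's [P1, P99] window is mapped affinely onto the pooled window
  (values outside follow the same map, clamped at 0). Its failure mode
  is reproduced in the tests: a sample genuinely lacking positives for a
  marker gets its background forcibly inflated toward the other
  samples' positive range, which background-anchored normalization
  avoids.

No multiple-testing machinery: these are descriptive statistics.

## The simulator

`simulate_two_samples()`, `three_group_fixture()`, `ratio_distortion_grid()`
and `simulate_sections()` generate every test input with full latent
truth ($b$, $s$, labels, gains) attached. Design:

* **Baseline noise**: lognormal around $\bar b = 1$ with CV 0.2 by
  default — fluorescence backgrounds are positive and right-skewed.
  Gamma and truncated-Gaussian alternatives exist for robustness tests;
  `noise = "none"` gives exact arithmetic used by the closed-form
  oracle checks. Signal in the two-sample design is deterministic,
  $s = \mathrm{SBR}\cdot\bar b$, so measured ratios have closed-form
  predictions.
* **Gain study conditions**: gain ratio $G_2/G_1 = 0.5$, equal true
  signals, SBR 100, 2000 positive cells per sample, 20 seeded
  replicates; SBR grid $\{1, 2, 5, 10, 100\}$ and true-ratio grid
  $\{1, 2, 5, 10\}$ for the distortion map.
* **Three-group fixture**: group sizes (40, 40, 40), SBR ≥ 10 (the
  $s \gg b$ premise; the generator warns below 5 and flags ≤ 1 as a
  violation).
* **Adjacent sections**: a cancer block and an immune block of markers;
  cancer cells express the cancer markers, immune cells the immune
  markers, the rest neither — cross-block pairs are exclusive by
  construction. Sections share an expected composition
  (cancer 0.45 / immune 0.25 / negative 0.30 — contrasted fractions, so
  composition correlation has signal to detect) with small
  Dirichlet-multinomial jitter (concentration 200: honest
  "almost-replicates"), and carry per-section gains (default
  (1, 2, 0.5) on the cancer block). Within-type signal strength is
  heterogeneous (lognormal, CV 0.5 by default): real marker expression
  varies broadly within a cell type, and without that spread any
  clustering with more clusters than cell types would partition pure
  noise. Set `signal_cv = 0` for the sharp-threshold regime in which
  positive-fraction recovery is exact.

What the simulator does **not** emulate: images, segmentation errors,
spatial structure, spectral bleed-through, cell-cycle or dim-expressing
intermediate populations, or markers whose baseline differs between cell
types. Tests passing on these fixtures show the algorithmic claims hold
under the stated model; they do not certify performance on any real
panel.

## Numerical and reproducibility choices

* Every stochastic step (subsampling, k-means, NNMF restarts, simulator
  draws) takes an explicit seed; identical configuration and seed give
  bit-identical output, including through the command-line interface.
* ADMM: penalty $\rho = \lambda$, 200 iteration cap, relative
  primal-residual tolerance $10^{-5}$.
* Spectral bipartition regularizes zero-degree affinity rows
  ($d \ge 10^{-12}$) and row-normalizes the embedding.
* NNMF: multiplicative updates with $10^{-12}$ denominators guards;
  convergence on relative objective decrease $10^{-10}$.
* Test problem sizes: slices of 60–500 cells, sections of 350–500 cells,
  two-sample studies of 400–4000 cells — large enough for the stated
  tolerances (background recovery within 10%, positive fractions within
  2 points, ARI ≥ 0.9), small enough that the full suite runs in a few
  minutes on one CPU.

## Known limitations

* Background is one scalar per (sample, marker); spatially varying
  autofluorescence is out of scope.
* Low-SBR signal ratios are distorted, as the model predicts; no
  correction is attempted.
* A reference marker with no positive cells in a sample is skipped, not
  imputed; its intensities pass through un-normalized.
* The exclusivity score cannot distinguish true exclusivity from
  isotropic noise on its own; curate the pair list.
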