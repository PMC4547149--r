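---
title: "Predicting miRNA targets from paired expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA targets from paired expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

MicroRNAs (miRNAs) are short regulatory RNAs that post-transcriptionally
down-regulate their target mRNAs. Sequence complementarity between a miRNA
seed region and an mRNA 3' UTR suggests *candidate* targets, but candidate
lists are long and noisy; when miRNA and mRNA expression have been profiled
over the *same* samples, the expression data can be used to keep the
candidates that the data actually support. `mirtarget` implements that
combined analysis as a load → filter → predict → visualize pipeline and
renders the resulting bipartite regulatory network.

```{r, message = FALSE}
library(mirtarget)
```

# The pipeline

## Filter

Two-sample experiments (treated vs control, paired or unpaired) are reduced
to differentially expressed entities before any pair scoring. `diff_stats()`
computes per entity the group means, a t statistic, a two-tailed p-value and
a **signed fold change**: `+r` when group 2 is `r`-fold above group 1, `-r`
when below, so `|fc| >= 1` by construction and `fc = +1` means unchanged.
Paired designs use the paired t-test on per-pair differences; unpaired
designs use Welch's test — the paper trail for such experiments rarely
justifies equal variances, so the unequal-variance form is the safer
default. `filter_two_sample(stats, p_max, min_abs_fc)` keeps entities
passing both thresholds (the case-study recipe uses raw `p <= 0.05`; a
Benjamini–Hochberg column is available via `adjust_p = TRUE` but the filter
deliberately uses raw p-values to match common practice for this screen).
Multisample matrices are instead filtered by mean expression
(`filter_multisample()`), which removes rows that are mostly zero.

Two degenerate cases are handled explicitly: an entity with zero variance
and equal means is kept with `t = 0, p = 1`, while zero variance with
*unequal* means leaves the t statistic undefined — such entities are
excluded with a warning rather than reported as `p = 0`, which would
otherwise flood the top of the ranking.

## Predict

Four expression-based scores are available for the surviving
(miRNA, mRNA) pairs, all computed across matched samples:

* **Correlation** (`correlation()`, `score_pairs(method = "pearson")` or
  `"spearman"`). Regulation is expected to be *negative*: the strongest
  predictions are the most negative coefficients, so selection orders
  correlation ascending.
* **Mutual information** (`ksg_mutual_information()`): the first
  Kraskov–Stögbauer–Grassberger k-nearest-neighbour estimator, in nats.
  For each point the distance to its k-th nearest neighbour in the joint
  space (max-norm) sets a scale; counting marginal neighbours strictly
  within that scale gives
  `I = psi(k) + psi(N) - mean(psi(n_x + 1) + psi(n_y + 1))`. The default
  `k = 3` is the usual bias/variance compromise. The estimator assumes
  continuous data, so exact ties are broken by a deterministic jitter of
  `1e-10` times the value range, seeded from a hash of the data: repeated
  calls give identical results and the global RNG stream is untouched.
  Slightly negative estimates on independent data are returned as computed.
* **MIC** (`mic()`): the maximal information coefficient, the maximum over
  axis-aligned grids (shape `p x q`, `p*q <= ceiling(n^0.6)`, `p, q >= 2`)
  of the grid mutual information normalised by `log2(min(p, q))`. MIC is 1
  for any noiseless functional relationship and 0 when either variable is
  constant, and it detects non-monotone association that correlation
  misses. Within each grid shape the best grid is found **exactly** when
  the number of cut-set enumerations on the axis with fewer bins is small
  (`choose(n-1, s-1) <= exact_limit`, default 2000): those cut sets are
  enumerated and the other axis is optimised by a dynamic programme over
  clump boundaries (implemented in C++), which is optimal for a fixed
  partition of the first axis. Larger shapes fall back to the standard
  equipartition heuristic (ties to the lower bin, both axis orientations,
  at most `c * p` candidate clumps with `c = 15`). The defaults
  `alpha = 0.6`, `c = 15` follow the original MIC recommendation; at the
  sample sizes typical of expression experiments (tens of samples) the
  exact path covers all two- and three-bin shapes.
* **GenMiR-style variational Bayes** (`genmir_fit()`), described next.

Before selection, candidate pairs can be restricted by sequence databases
(`read_sequence_target_db()`, TargetScan-style and microRNA.org-style
dialects) and by fold-change **direction** (`direction_filter()`): since
miRNAs repress their targets, pairs with an up-regulated miRNA and a
down-regulated mRNA (or the reverse) are biologically the most plausible;
`"opposite"` is the union of the two one-sided options. "Up" is read
strictly as `fc > +1` and "down" as `fc < -1`, so an unchanged entity
matches no directional option. The pipeline applies the direction filter to
the candidate pair set *before* scoring and selection; the filter does not
depend on scores, so this is equivalent to filtering afterwards and avoids
scoring pairs that cannot be kept.

`select_interactions()` then keeps either the pairs past a score threshold
or the top N, with a deterministic tie-break (score, then pair id), and
`combine_results()` merges the per-algorithm selections into one table with
a TRUE/FALSE evidence flag per algorithm — intersection for conservative
calls, union for sensitivity. Every row keeps the flag of every supplied
algorithm, so an intersection over three algorithms still shows which of
the remaining algorithms also supported the pair.

## The down-regulation model

`genmir_fit()` scores candidate pairs under a generative model of
repression: for mRNA `j` with candidate regulator set `C_j`,

$$x_j \mid s \sim N\Big(\mu - \sum_{k \in C_j} s_{jk}\,\gamma_k \Lambda z_k,\ \Sigma\Big),$$

where `z_k` is the miRNA expression profile, `s_jk ~ Bernoulli(pi)`
indicates a true target, `gamma_k >= 0` is the regulatory weight of miRNA
`k`, and `mu`, `Lambda`, `Sigma` are per-sample baseline, scaling and noise
(all diagonal). Inference is variational EM with a factorised posterior
`q(s_jk) = Bernoulli(beta_jk)`; `beta_jk` — the posterior probability that
the candidate pair is a true target — is the score. Every update (each
`beta_jk` exactly given the others, then `gamma` by projected coordinate
ascent, then `Lambda`, `mu`, `Sigma` in closed form) maximises the evidence
lower bound along its coordinate, so the ELBO is non-decreasing; the fit
stops when the relative ELBO change drops below `tol` (default `1e-5`) or
at `max_iter` (200), returning `converged = FALSE` with a warning in the
latter case.

Choices worth knowing about:

* `pi` (prior target probability, default 0.5) is held fixed; `beta` is
  initialised at `pi`, `mu` at the per-sample mean of mRNA expression,
  `Lambda` at 1, `Sigma` at the per-sample variance, `gamma` at
  `init_gamma` (0.01).
* Negative `gamma` or `Lambda` after an M-step is projected to 0: the model
  encodes down-regulation, so regulatory weights are nonnegative.
* Profiles are z-scored per entity by default (`standardize = TRUE`) so
  that `gamma` is comparable across miRNAs regardless of raw intensity;
  positivity of the input is still validated first, since the model is
  defined on expression levels.
* With a single candidate mRNA the per-sample baseline could fit the lone
  profile exactly and the model would be unidentifiable; in that degenerate
  case `mu`, `Lambda` and `Sigma` are pooled to scalars (constrained
  M-steps, ELBO still monotone).
* Internally, entities are processed in first-occurrence order of the
  candidate table, so relabelling miRNAs permutes the posteriors
  identically.

## Visualize

`build_network()` turns the combined table into a bipartite network whose
edge `support` (number of agreeing algorithms) drives link width.
`layout_network()` offers circular, Fruchterman–Reingold, Kamada–Kawai and
a **modified inverted-SOM** layout: a topology-only embedding tends to pile
all degree-1 targets of a miRNA onto one point, so after the ISOM pre-pass
every miRNA's degree-1 mRNA neighbours are re-placed at equal angular
spacing on a circle around it. The scatter radius is 0.35 times the
distance to the nearest other miRNA with a floor of 0.02 in unit
coordinates (a lone miRNA uses 0.25, a quarter of the canvas) — large
enough to read labels, small enough that neighbouring stars do not
interleave. Disconnected components are laid out separately and packed on a
grid with a single uniform scale so the circles stay circular; final
coordinates are normalised (aspect-preserving) to the unit square with
screen orientation (origin top-left, y down), and any exactly coincident
positions are spread apart deterministically. All layouts are deterministic
given `(network, method, seed)`.

`treemap_layout()` renders the two-level hierarchy — each miRNA a parent
tile with area proportional to its target count, each target an equal-area
leaf inside it, targets shared between miRNAs duplicated under each parent.
Both levels use squarified tiling, which keeps tiles near-square and
maximises label legibility. Fold changes map to colour via
`fold_change_color()`: white at `fc = ±1`, saturating to red (up) or blue
(down) at `|fc| = cap` (default 4, chosen so case-study-scale fold changes
of ±2.5 sit visibly inside the ramp); multisample networks have no fold
change and use fixed orange/dark-blue hues instead.

# Synthetic data and what the tests show

`generate_synthetic()` produces seeded bundles from the same generative
assumptions the Bayesian model encodes: lognormal miRNA profiles
(`meanlog 1, sdlog 0.5`), per-mRNA lognormal baselines (`meanlog 2.3`), and
additive repression `x_j = baseline - sum(gamma_true * z_k) + noise`,
floored at `1e-3` so fold-change ratios stay defined. The defaults — 50
miRNAs, 500 mRNAs, 20 samples (20 pairs in `paired2` mode), 50 planted
pairs of effect size 1, noise sd 0.3, 9 decoy candidates per true pair —
describe a mid-sized microarray-style screen with a clear but not trivial
signal. In `paired2` mode planted miRNAs are additionally scaled 2-fold up
in group 2 and their targets 2-fold down, so the differential filter and
the direction filter are exercised end to end.

The generator deliberately omits probe effects, batch structure, count
noise and correlated co-regulation. Passing tests therefore demonstrate
that the estimators and the pipeline recover the *model's* signal —
negative association plus planted fold changes — not that they are robust
to every artefact of real microarray data.

Problem sizes in the test-suite were chosen to exercise each method's
guarantees at desk scale: exhaustive-grid MIC comparisons use n = 16 (all
grids enumerable), the mutual-information closed-form checks use
1000–2000 points, the model-recovery checks use 100 candidate pairs over 30
samples, and the end-to-end run uses the default 50 × 500 bundle with
top-50 selections per algorithm.

# Numerical notes and limitations

* `mic()`'s `B(n) = ceiling(n^alpha)` uses the ceiling so the grid budget
  is integral; equipartition ties go to the lower bin for determinism.
* The KSG estimator is O(N²) in memory and time per pair; at the sample
  counts of expression experiments this is negligible, but it is not meant
  for N in the hundreds of thousands.
* `signed_fold_change()` requires positive means; log2-scale input is
  declared via `values_are_log2`, in which case the ratio is
  `2^(mean difference)` with the same sign convention.
* TCGA-style matrices are matched between assays by barcode prefix
  (default 15 characters); the exact upstream file layout varies, so the
  reader accepts any TSV matrix whose columns are barcodes.
* Missing values are rejected rather than imputed; inputs are assumed
  normalised and background-subtracted.
* Sequence databases are treated as boolean evidence (plus the mirSVR score
  where provided); no attempt is made to calibrate per-algorithm scores
  against each other, and the interaction table records flags, not a fused
  meta-score.
* Layouts are not stable under parameter changes: re-running with a
  different filter produces a different embedding. This is inherent to the
  seeded iterative layouts used here.

# A worked miniature

```{r, message = FALSE, warning = FALSE}
b <- generate_synthetic(synthetic_config(
  n_mirna = 10, n_mrna = 60, n_samples = 12, n_true_pairs = 10,
  mode = "paired2", seed = 42))

res <- run_pipeline(
  b$mirna_ds, b$mrna_ds,
  algorithms = c("pearson", "genmir"),
  p_max = 0.05, top_n = 20,
  direction = "opposite", combine = "intersection", seed = 42)

res$manifest
head(res$interactions)
```

```{r, fig.width = 6, fig.height = 5}
autoplot(res$layout, network = res$network)
autoplot(res$treemap)
```
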