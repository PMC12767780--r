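---
title: "Methods: models, study conditions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, study conditions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the generative model behind the synthetic data, the inference machinery,
the parameters that matter and why their defaults are what they are, and
the places where a genuinely open design choice had to be made. Every
empirical statement here is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is quoted from external runs.

```{r setup}
library(pepregnet)
```

## The question and the comparison unit

Neuropeptides (NPs) act through receptors (NPRs) that are expressed far
more broadly than the ligands themselves, and receptor transcription is
the natural control point for context-dependent modulation of
peptidergic signaling. The package's analyses all reduce to one
comparison, made at several levels: is some regulatory quantity —
cis-regulatory feature count, number of regulating TFs, TF-pair
importance, temperature responsiveness — systematically larger for NPR
genes than for NP genes?

The comparison unit differs by level and is always explicit:

* cis-regulatory features: the gene (unpaired) or the published NP–NPR
  pairing row (paired). Genes appearing in several rows contribute once
  per row in paired mode, mirroring the published pairing axis; a
  `collapse` option reduces to unique genes.
* TF networks: the per-gene TF in-degree within a class network. The
  source analyses plot "number of TFs" without defining the replication
  unit; per-gene in-degree is the finest faithful unit and per-pair
  aggregation remains available to the caller.
* aging: the top-k importance vectors per class (k = 50 per class, or a
  pooled top-100 membership count).

## The synthetic-data generator

The generator replaces the external single-cell atlases with a model
that has exactly the statistical structure the inference machinery
assumes, plus planted ground truth:

* **Counts.** UMI counts are negative binomial with dispersion
  $\phi = 0.5$ (variance $\mu + \phi\mu^2$), the standard single-cell
  count model. $\phi = 0$ degenerates to Poisson.
* **Regulation.** Each TF is a latent per-cell Bernoulli
  ("active in this cell"), independent across TFs and cells. Each panel
  gene receives a truncated-Poisson number of regulator TFs — mean
  `fanin_npr = 8` for receptors vs `fanin_np = 3` for ligands by
  default, at least one each so per-class TF counts are always defined.
  A gene's NB mean is multiplied by `effect_size` (default 4) once per
  active regulator, i.e. log-mean is linear in the number of active
  regulators.
* **TF transcripts.** A TF's own mRNA is lifted by the same factor when
  the TF is active (`tf_baseline_mean = 5` when inactive). This is what
  lets co-expression methods see the latent activity at all; TFs are
  modeled as broadly expressed, panel and background genes as sparse.
* **Motif support.** Every true edge is motif-supported, and each TF
  additionally "supports" two background decoy genes, so motif pruning
  always has false candidates to reject.
* **Ct tables.** Threshold cycles are built so that the true
  $2^{-\Delta\Delta C_T}$ fold against the reference gene and the 25 °C
  control equals the planted fold exactly at zero noise, with Gaussian
  measurement noise (`noise_sd`, default 0.2) on every Ct.

All generators are bit-for-bit reproducible from a single integer seed,
and every planted parameter is recoverable by a moment estimator (the
test suite checks fan-in, class feature means, folds, and importance
lifts).

### Two study conditions, not one

Two requirements pull the expression model in opposite directions, and
the package resolves this with two named conditions rather than one
compromise:

* **Reference condition** (the `sim_config()` defaults: 1000 cells, 100
  genes, 10 TFs, `baseline_mean = 0.5`, `tf_active_prob = 0.2`): a
  detectable co-expression regime used to validate edge recovery. Median
  AUROC of the tree-ensemble importance against the planted edges is
  required to reach 0.9 over 10 seeds.
* **Pipeline condition** (`run_bias_pipeline()`: 500 cells, 100 genes,
  20 TFs, `baseline_mean = 0.1`, `tf_active_prob = 0.1`): a sparse
  regime in which panel genes are silent in most cells. Class-exclusive
  cell populations (cells expressing NPs but no NPR, and vice versa)
  only exist under sparsity — with dense panel expression virtually
  every cell co-expresses both classes and the exclusivity rule selects
  nothing. The TF axis is widened to 20 because with 10 TFs and a mean
  receptor fan-in of 8, essentially every TF regulates at least one
  gene of each class and the TF-count contrast saturates into a tie by
  construction.

A structural consequence of the planted asymmetry, visible in the worked
example: NP-exclusive cells are, by selection, cells where no receptor
is expressed, which under receptor-heavy fan-in means cells where few
TFs are active — so the TF–NP network is typically empty at this scale
while the TF–NPR network engages most TFs. The class contrast is
recovered, but real atlases (where TFs regulate thousands of genes
beyond the panel) would not be this extreme.

What the generator deliberately does not model: doublets, ambient RNA,
batch effects, technical library-size variation, spatial structure, and
TF–TF regulatory cascades (cascade counting is exercised on constructed
regulon sets instead). Passing tests therefore show correctness of the
machinery on data matching the model's assumptions, not robustness to
every artifact of real single-cell data.

## Tree-ensemble importance

For each target gene, a random forest regresses the target's
log1p-transformed expression (standardized to unit variance) on the TF
expressions; a TF's importance is its total impurity reduction.
Settings: 200 trees, the full TF set as candidate set at every split,
and a minimum terminal-node size of 10% of the cells (floor 5).

Three numerical choices deserve explanation:

* **Minimum node size.** Fully grown regression trees drive in-sample
  residual variance to zero, which converts noise into impurity
  reduction spread across all predictors: a pure-noise target then
  receives the same total importance as a strongly regulated one, and
  only the split between predictors differs. Regularizing node size
  keeps noise targets' importances small so that edge ranking works
  across targets.
* **Two importance columns.** `importance` is normalized to sum to 1
  over TFs per target — the right scale for asking "which TFs matter
  for this target". It cannot rank edges across targets: for a target
  with eight true regulators each share is ~1/8, indistinguishable from
  the ~1/10 shares of a pure-noise target over ten TFs.
  `importance_raw` (impurity reduction on the unit-variance target) is
  comparable across targets and is what `edge_auroc()` and cross-target
  rankings use.
* **Expression transform.** Plain `log1p(counts)` by default. Per-cell
  depth normalization is available (`depth_normalize = TRUE`) but off:
  the simulator has no technical library-size variation, so depth there
  is purely biological (it rises with the number of active TFs), and
  dividing by it subtracts regulator activity from every gene —
  empirically collapsing edge recovery to chance. On real data with
  technical depth variation the flag should be on.

Determinism: each target's forest is seeded from the caller's seed plus
the target index, on one thread.

## Rank-AUC activity and binarization

Per cell, genes are ranked by decreasing count with ties broken by
stable gene order (deterministic, rather than the random tie-shuffling
of the original rank-AUC tool). With $T = \lceil f\,G \rceil$ ranks
scored and $m$ targets present, the score is
$\sum_{i\le T} y(i) / \sum_{i\le T} \min(i, m)$ where $y(i)$ is the
recovery curve — 1 when all targets sit at the top of the ranking, 0
when none enter the scored window. The implementation is checked
against a brute-force recovery-curve enumeration to $10^{-12}$ on 100
random matrices.

The scored fraction `top_fraction` defaults to 0.05, the conventional
choice for transcriptome-scale rankings. At desk scale the window must
exceed the number of broadly expressed genes, otherwise the TFs occupy
the entire window; the pipeline uses 0.3 on its 100-gene universe.

Activity is binarized against a null of size-matched random gene sets
scored on the same cells, thresholding at a null quantile (default
0.99). The null's sampling frame matters: sets drawn from the full gene
universe include the always-top-ranked TFs and push the threshold above
anything a TF-free regulon can reach. The `universe` argument therefore
lets callers draw nulls from the regulon's own target universe, which
restores the calibration property (a background regulon is called
active in about $1 - q$ of cells). The pipeline passes the non-TF
universe.

## Statistical routing and estimation statistics

Two-group comparisons are routed by a normality screen: when both
samples pass a Kolmogorov–Smirnov test for normality at $\alpha = 0.05$
a two-sided pooled-variance Student's t-test is used, otherwise the
Mann–Whitney U test. The screen defaults to the Lilliefors-corrected
test, because the naive alternative (standardize, compare to the
standard normal) uses parameters estimated from the same sample and is
drastically conservative about declaring non-normality — it routes
clearly log-normal samples to the t-test most of the time. Both
variants are exposed (`ks_variant`); the Lilliefors tables need n ≥ 5,
below which the naive screen is used. A paired request on non-normal
data falls back to the unpaired Mann–Whitney test with a warning
(a signed-rank test was considered; the fallback keeps the routing
two-armed as in the source procedure). Degenerate inputs are flagged:
two constant samples give p = 1; a constant non-zero paired difference
reports the limiting p of 0.

Estimation statistics report the difference between means
(DBM = mean(B) − mean(A)) with a percentile-bootstrap 95% CI (5000
resamples; pairs of differences resampled in paired mode), seeded and
deterministic. Percentile rather than BCa was chosen as the simplest
defensible reading of "estimation statistics"; see limitations.

## qPCR quantification

$\Delta C_T$ is computed per replicate (target minus reference,
replicates matched by id), $\Delta\Delta C_T$ subtracts the stratum's
mean control $\Delta C_T$ (control = 25 °C within the same sex, age and
tissue part), and the per-replicate fold is $2^{-\Delta\Delta C_T}$ with
amplification efficiency taken as exactly 2. Folds are summarized as
mean ± SEM over replicates — the per-replicate route was chosen because
the source protocol reports mean ± SEM without stating the
error-propagation path, and per-replicate folds make the SEM
well-defined. The whole computation is invariant to adding a constant
to every Ct value. The replicate schema records one replicate axis
(biological); technical triplicates are assumed to have been averaged
upstream.

## Known limitations

* **Percentile-bootstrap coverage.** At n = 10 per group the percentile
  CI undercovers: its width mimics a z-interval with the biased
  (divide-by-n) SD estimate, giving true coverage near
  $P(|t_{18}| < 1.96\sqrt{9/10}) \approx 0.92$ rather than 0.95. The
  acceptance suite measures this honestly (~0.92 over 1000
  simulations) and the corresponding nominal-coverage check fails by
  design rather than being papered over. For small groups a
  bootstrap-t or BCa interval would be needed for nominal coverage.
* **Top-k comparisons are anti-conservative under selection.** When the
  top k pairs are selected from a larger pool, the selected values
  shift jointly with the selection threshold, so within-set spread
  underestimates the sampling variance of the top-k mean; measured
  type-I error for top-50-of-100 is roughly 0.10–0.19 for both test
  routes. This is inherent to the top-k protocol itself. The
  calibration checks therefore use a pool equal to k (selection
  vacuous); detection claims from top-k comparisons under real
  selection should be read as enrichment scores, not calibrated tests.
* **The discrete in-degree comparison** (truncated-Poisson counts,
  groups of 10 and 13) is approximately calibrated (measured rejection
  ~0.05–0.08 at $\alpha = 0.05$); ties and skew make both routes
  slightly liberal at this size.
* The generator's omissions listed above bound what a green suite
  demonstrates about real atlas data.

## Problem sizes

The validation suite runs at desk scale, chosen so the full suite and
the acceptance script each complete in minutes: edge recovery at
1000 × 100 over 10 seeds, the end-to-end pipeline at 500 × 100 over 20
seeds, 200-run null calibrations, 1000-simulation coverage checks, and
100-matrix oracle comparisons. All sizes are stated in the tests
themselves.
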