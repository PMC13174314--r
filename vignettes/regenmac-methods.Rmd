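---
title: "Methods: scoring, mapping and testing a regeneration-associated macrophage state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, mapping and testing a regeneration-associated macrophage state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenmac)
```

## Scientific problem

Amputation through the mouse distal phalanx (P3) regenerates; amputation one
bone further (P2) heals by scarring. A striking correlate of this difference
is the myeloid compartment: regenerating digits harbor a spatially restricted
macrophage population near the bone stump that is biased toward fatty-acid
oxidation (FAO), expresses BMP ligands, and signals to stromal cells, whereas
the non-regenerating injury stays glycolysis-dominated and TNF-skewed.
`regenmac` packages the quantitative steps needed to detect and characterize
such a population across four data modalities — single-cell RNA-seq, spatial
transcriptomics, bulk metabolomics and extracellular-flux/qPCR assays — along
with seeded synthetic generators that plant each effect so every claim can be
verified against ground truth.

## Expression model and normalization

Counts live in an `ExpressionMatrix` (sparse genes × observations). The only
transformation used downstream is library-size log-normalization,

$$\tilde{x}_{gc} = \log\!\left(1 + s\,\frac{x_{gc}}{\sum_g x_{gc}}\right),
\qquad s = 10^4,$$

which removes depth differences while preserving sparsity (zero counts map to
zero). All scoring, marker testing and communication statistics operate on
this layer; none of them assume normality of $\tilde{x}$.

## Module scores with bin-matched controls

A gene set's activity per cell is its mean normalized expression minus the
mean of an expression-matched control pool (`module_score()`):

1. rank all genes by mean normalized expression and cut the ranks into
   `n_bins = 24` equal-frequency bins;
2. for each set gene, sample `n_ctrl = 100` control genes from its own bin
   (without replacement when the bin is large enough, with replacement
   otherwise);
3. pool the controls as a unique set and score each cell as
   `mean(set) - mean(controls)`.

Matching controls on mean expression removes the depth/abundance component
that makes naive set means correlate with library size, so 0 is the null: a
set indistinguishable from its expression-matched background scores 0 in
expectation, and a set equal to the whole gene universe scores exactly 0
whenever the pool covers every bin. Control sampling is seeded and restores
the caller's RNG state. The same scorer is reused verbatim on spatial spots
(`spot_scores()`), making cell-level and spot-level scores directly
comparable.

## Marker detection and signatures

`rank_markers()` contrasts one cluster against all other cells per gene with
a two-sided Wilcoxon rank-sum test. The exact distribution
(`stats::pwilcox`) is used when both groups have at most 50 observations and
the values are untied; otherwise a normal approximation with tie and
continuity corrections is used — the same convention as
`stats::wilcox.test`, and the reason small untied problems agree exactly
with full enumeration of group assignments. Fold changes are natural-log
ratios of `expm1` means with a $10^{-9}$ pseudocount; p-values are BH
adjusted across genes. `top_signature()` keeps positively enriched
significant genes (`lfc > 0`, `adj_p < 0.05`), orders by adjusted p, then
fold change, then gene id (a deterministic total order), and truncates at
`k = 50`.

## Metabolic state

`pathway_scores()` scores glycolysis, OXPHOS and fatty-acid-metabolism sets
with one shared seed and aggregates by (cluster, injury, timepoint). Because
module scores are background-centered they can be negative, so the
glycolysis-versus-FAO balance is summarized as a signed difference
(`metabolic_ratio()`, positive = glycolytic, negative = FAO-dominated); a
literal quotient is available but ill-defined near zero and not used by the
pipeline.

`variance_partition()` asks which factor structures expression overall: for
each gene and each factor separately it computes the one-way between-group
sum of squares and $\eta^2 = SS_{between}/SS_{total}$ on the normalized
values. $\eta^2$ is affine-invariant and bounded in $[0,1]$; constant genes
are excluded and counted. The pipeline evaluates the injury-versus-cluster
contrast in a regime where injury effects are planted larger, and checks
that the injury $\eta^2$ distribution dominates.

`ks_compare()` implements the two-sample Kolmogorov–Smirnov statistic from
first principles: $D$ is the supremum of the ECDF difference evaluated with
a tie-aware cumulative sum (only the gap after a full tie group counts), and
the p-value is the asymptotic Kolmogorov survival function
$Q(t) = 2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2t^2}$ at
$t = \sqrt{n_a n_b/(n_a+n_b)}\,D$, summed to 200 terms (machine precision
for any $t$ of practical size).

## Spatial mapping

Spots are scored with the cluster signatures and classified by
`classify_spots()`; since module scores are background-centered, the default
positive rule is `score > 0`, with a quantile rule available when the
expected positive fraction is known. `conditional_pathway()` then contrasts
BMP-pathway scores between predicted-positive and -negative spots (Welch t,
plus a rank-based AUC as a nonparametric effect size). The package's claim
structure is deliberately conditional: BMP activity is elevated *where the
inflammatory population is*, and not where the resolution population is —
the spatial co-location pattern, not a global spatial test.

## Cell–cell communication

`communication_score()` uses a deliberately transparent statistic: for a
ligand–receptor pair, sender cluster $S$ and receiver cluster $R$,

$$\mathrm{score} = \overline{\tilde{x}}_{lig,S}\times
\min_{r\,\in\,\mathrm{complex}} \overline{\tilde{x}}_{r,R},$$

with the min encoding AND semantics over receptor-complex members, and the
score gated to 0 when the expressing-cell fraction is below `min_frac = 0.1`
on either side (secreted ligands detected in a handful of cells should not
create edges). Significance comes from cluster-label permutations within the
condition with the add-one estimator $p = (1 + \#\{score^{perm} \ge
score\})/(n_{perm}+1)$, which is never 0 and is calibrated under label
exchangeability. `pathway_network()` BH-adjusts within pathway × condition
and keeps edges below `alpha`.

## Metabolomics

Abundances are log-transformed and unit-variance scaled (`preprocess()`;
Pareto and center-only scaling available). `pca()` is a truncated SVD with a
deterministic sign convention. `oplsda()` implements single-response O-PLS
in the orthogonal-signal-correction formulation: `n_ortho` components of
X-variation orthogonal to the class vector are extracted and deflated, then
one predictive PLS1 component is fitted; with `n_ortho = 0` it reduces
exactly to NIPALS PLS1 (the property tested against an independent oracle).
Variable importance is
$VIP_j = \sqrt{M \sum_c w_{jc}^2\,SSY_c / \sum_c SSY_c}$, which satisfies
$\overline{VIP^2} = 1$. Because the intended group sizes are tiny (n = 3
per group), the model reports leave-one-out $Q^2$ and a label-permutation
p-value rather than parametric claims; with n = 3 vs 3 the permutation p
cannot go below $1/\binom{6}{3} \cdot$ (a few), so it is reported as a
descriptive guard, not a gatekeeper. Per-metabolite tests are Welch t on
log abundances with BH adjustment.

## Flux traces and qPCR

`rate_trace()` stores injection-annotated rate series; phases are the
half-open intervals between injections. Metrics follow standard
mito-stress-test arithmetic: basal = mean of the last ≤ 3 baseline cycles
minus the non-mitochondrial rate (final rot/AA phase mean); maximal = FCCP
phase maximum minus non-mitochondrial; the etomoxir response is the percent
change of the post-injection phase mean relative to the preceding phase,
which is scale-invariant and therefore comparable across wells. Group
contrasts use Welch t-tests, with Dunnett many-to-one comparisons
(`multcomp`) when a control group is named. qPCR relative expression is
$2^{\Delta C_q}$ with $\Delta C_q = \bar{C_q}(\mathrm{housekeeping}) -
\bar{C_q}(\mathrm{target})$ per sample, with replicate-CV flagging.

## Synthetic generators and their realism

All generators are seeded, restore the caller's RNG state, and use disjoint
seed streams (a fixed offset per generator), so adding one analysis never
changes another's draws.

- **Single cell** (`simulate_scrna()`): negative-binomial counts
  (dispersion 10, i.e. moderate overdispersion) over four clusters × six
  injury/timepoint conditions. Cluster identity is 40 disjoint marker genes
  at log-fold 2; metabolic programs shift P2 macrophages toward glycolysis
  and P3 macrophages toward FAO at D10–D14; a BMP-ligand program is confined
  to P3 inflammatory macrophages, with the ligands given a low off-state
  baseline so that "off" means rarely detected, as secreted factors are.
  Fibroblast markers include the BMP/TNF receptors, planting the
  receiver side of communication.
- **Spatial** (`simulate_spatial()`): spots on a unit grid; mixing
  proportions are Dirichlet draws whose inflammatory weight is 0.6 inside
  the planted region (the left-most quarter of the x-axis, standing in for
  the bone stump) and 0.05 outside; spot counts are NB around the
  depth-scaled mixture of cluster mean profiles (depth 5000, concentration
  100 ≈ a spot sampling on the order of 100 cells). Outside spots genuinely
  contain a few percent inflammatory cells — spots are mixtures, not
  cell-type labels — which bounds the achievable precision of any hard
  classification while leaving ranking metrics (AUC) near 1.
- **Metabolomics / traces**: log-normal abundances with multiplicative
  group folds; piecewise-constant phase means with Gaussian noise.

## Numerical choices

Sparse column scaling is done directly on the `dgCMatrix` slots;
equal-frequency binning uses `rank(..., ties.method = "first")` so binning
is deterministic under ties; the KS statistic uses a cumulative-sum sweep
rather than ECDF function evaluation ($O(n\log n)$, exact tie handling);
permutation p-values use the add-one estimator; all file outputs are plain
text and the pipeline writes an md5 manifest so determinism is checkable at
the byte level.

## Limitations

- The communication score is a mean-product heuristic with a label-permutation
  null; it captures the planted sender/receiver contrast but is not a model
  of ligand diffusion, and its permutation null conditions on the observed
  expression matrix.
- The spot classifier is intentionally simple (thresholded module score);
  deconvolution of mixing proportions is out of scope.
- `variance_partition()` computes marginal one-way $\eta^2$ per factor;
  with unbalanced or correlated designs the factor shares need not sum
  to at most 1 and no interaction term is estimated.
- The OPLS-DA permutation test permutes labels globally and refits; with
  n = 3 per group its resolution is coarse by construction.
- Generators plant effects on the log-mean of an NB model with a single
  global dispersion; they are calibration targets, not a fitted model of
  any real dataset.

## A worked example

```{r example, eval = FALSE}
cfg <- default_sim_config(seed = 1)
sim <- simulate_scrna(cfg)
sim$em <- normalize_counts(sim$em)
sig <- top_signature(rank_markers(sim$em, sim$annotations,
                                  "inflammatory_mac"))
sd <- simulate_spatial(cfg, sim$truth)
sd$em <- normalize_counts(sd$em)
pred <- classify_spots(spot_scores(sd, sig))
conditional_pathway(sd, pred, gene_set("BMP", sim$truth$program_genes$bmp))
```

The full demonstration, including metabolomics, communication and flux
stages plus internal pass/fail checks, is `run_pipeline(default_run_config
(seed = 1), out_dir)` or, from the shell, the `regenmac run` wrapper under
`inst/scripts/`.
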