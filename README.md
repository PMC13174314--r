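# regenmac

Toolkit for identifying and characterizing a spatially restricted,
BMP-ligand-expressing, fatty-acid-oxidation (FAO)-biased macrophage
population that distinguishes regenerative from fibrotic bone injuries.

## The scientific problem

Amputation through the mouse distal phalanx (P3) regenerates the digit tip;
amputation one bone further (P2) heals by fibrosis. A key correlate is the
injury's myeloid compartment: regenerating digits harbor a macrophage
population near the bone stump that is FAO-biased, expresses BMP ligands,
and signals to stromal cells, while non-regenerating injuries remain
glycolysis-dominated and TNF-skewed. Establishing such a claim requires four
kinds of quantitative evidence, each with its own pitfalls:

1. **Single-cell RNA-seq** — defining macrophage states by marker
   signatures and scoring metabolic gene programs without library-depth
   artifacts;
2. **Spatial transcriptomics** — mapping where a population sits and
   whether pathway activity (BMP) co-locates with it;
3. **Cell–cell communication** — testing whether ligand–receptor structure
   (inflammatory macrophage → fibroblast BMP signaling) is condition-specific
   rather than an expression artifact;
4. **Metabolomics and functional assays** — multivariate group separation
   with variable importance at tiny sample sizes, and extracellular-flux /
   qPCR arithmetic.

`regenmac` implements these steps with transparent statistics, plus seeded
synthetic generators that plant every effect, so each analysis can be
validated against ground truth end to end.

## Core methods

- `module_score()` — gene-set scoring against expression-bin-matched
  control genes (24 equal-frequency bins, 100 controls per set gene,
  unique pooling), so 0 is the null and scores are depth-robust.
- `rank_markers()` / `top_signature()` — Wilcoxon rank-sum marker tests
  (exact for small untied groups, tie-corrected normal otherwise), BH
  adjustment, deterministic top-k signature selection.
- `pathway_scores()` / `metabolic_ratio()` / `variance_partition()` /
  `ks_compare()` — glycolysis-versus-FAO state summaries, per-gene
  eta-squared partition across factors, and a from-scratch two-sample
  Kolmogorov–Smirnov test.
- `spot_scores()` / `classify_spots()` / `conditional_pathway()` — the same
  module scorer applied to spatial spots, threshold classification, and a
  conditional contrast of pathway activity between predicted-positive and
  -negative spots.
- `communication_score()` / `pathway_network()` — ligand–receptor scores
  (sender ligand mean × min receptor-complex mean, expressing-fraction
  gated) with a within-condition cluster-label permutation null.
- `preprocess()` / `pca()` / `oplsda()` — metabolomics scaling, PCA, and
  single-response orthogonal PLS-DA with VIP, leave-one-out Q2 and a
  permutation model p-value.
- `rate_trace()` / `flux_metrics()` / `group_compare()` / `ddcq()` —
  mito-stress-test metrics (basal, maximal, percent change after
  injection), Welch/Dunnett group contrasts, and 2^ΔCq qPCR expression.
- `simulate_scrna()` / `simulate_spatial()` / `simulate_metabolomics()` /
  `simulate_traces()` — seeded negative-binomial / Dirichlet / log-normal
  generators with planted ground truth.
- `run_pipeline()` — the full demonstration: simulate, derive signatures,
  profile metabolic state, map space, score communication, analyze
  metabolomics and flux, and write a report with internal pass/fail checks
  and an md5 manifest.

## A worked example

Recover the inflammatory-macrophage signature from simulated single-cell
data, map it onto simulated spatial data, and test whether BMP-pathway
activity co-locates with the mapped population:

```r
library(regenmac)

cfg <- default_sim_config(seed = 1)
sim <- simulate_scrna(cfg)
sim$em <- normalize_counts(sim$em)
sim$em
#> ExpressionMatrix: 600 genes x 1440 obs (with normalized layer)

sig <- top_signature(rank_markers(sim$em, sim$annotations,
                                  "inflammatory_mac"))
sig
#> GeneSet 'inflammatory_mac': 50 genes
head(sig$genes, 8)
#> [1] "InflMk25" "InflMk15" "Cxcl2"    "InflMk32" "InflMk19" "Il1a"
#> [7] "InflMk18" "Cxcl3"

sd <- simulate_spatial(cfg, sim$truth)
sd$em <- normalize_counts(sd$em)
pred <- classify_spots(spot_scores(sd, sig))
sum(pred$positive)
#> [1] 100

bmp <- gene_set("BMP", sim$truth$program_genes$bmp)
cond <- conditional_pathway(sd, pred, bmp)
sprintf("t = %.2f, p = %.3g, AUC = %.3f", cond$t, cond$p, cond$auc)
#> [1] "t = 21.07, p = 6.61e-42, AUC = 0.961"
```

The full pipeline, from the shell:

```sh
Rscript inst/scripts/regenmac run /tmp/demo --seed 1
```

which ends with its internal check report:

```
regenmac pipeline report (seed 1)
verdict: PASS

  [ok] inflammatory_marker_recovery = 1
  [ok] metabolic_ratio_P2_D10_positive = 1.11403
  [ok] metabolic_ratio_P3_D10_negative = -1.25691
  [ok] injury_eta_sq_dominates_cluster = 0.074187
  [ok] spatial_region_auc = 1
  [ok] bmp_higher_in_inflammatory_spots = 6.60981e-42
  [ok] bmp_not_higher_in_resolution_spots = 5.515e-99
  [ok] bmp_edge_inflam_to_fibro_in_P3 = 1
  [ok] bmp_network_empty_in_P2 = 1
  [ok] planted_metabolites_in_top_vip = 1
  [ok] etomoxir_drop_in_P3_not_P2 = -29.3919
```

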