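# fanet — FA-weighted structural brain network analysis

`fanet` is an R package for constructing and statistically analysing
fractional-anisotropy (FA) weighted structural brain connectomes, the kind
produced by deterministic diffusion-MRI tractography over an N-region
parcellation (typically the 90 cerebral AAL regions). It is aimed at
researchers who study group differences in white-matter network topology —
for example between healthy controls and patients at successive stages of
cognitive impairment — and who need the full analysis layer between "one
connectivity matrix per subject" and "results tables".

## What it computes

Given symmetric FA-weighted matrices `W` (one per subject), the package
implements:

* **Network construction** (`track_fact`, `build_matrix`): deterministic
  FACT-style streamline tracking on voxel orientation fields (seed and stop
  at FA < 0.2, stop at turning angles > 45°), edges requiring ≥ 3 fibers,
  edge weight = mean FA along the connecting fiber bundles.
* **Graph metrics over sparsity thresholds** (`metric_curves`,
  `auc_summary`): at each sparsity `s` in 10–15% the strongest
  `K = round(s·N(N−1)/2)` edges are retained and, with edge distances
  `d = 1/w`, the package computes the clustering coefficient `Cp` (Onnela,
  max-normalized), characteristic path length `Lp`, global and local
  efficiency

  `Eglob = mean over pairs of 1/d_ij`,  `Eloc = mean over i of Eglob(G_i)`,

  nodal efficiency and betweenness centrality, each curve summarized by its
  trapezoidal area under the curve (AUC).
* **Small-world normalization** (`random_reference`): degree-preserving
  double-edge-swap surrogates with permuted weights give
  `γ = Cp/Cp_rand`, `λ = Lp/Lp_rand`, `σ = γ/λ`; `σ > 1` indicates
  small-world organization.
* **Hubs** (`identify_hubs`): nodes whose betweenness is ≥ mean + SD of the
  network betweenness, with cross-group hub comparison (`compare_hubs`).
* **Network-based statistic** (`nbs_test`): edge-wise ANOVA/t statistics, a
  primary component-forming threshold (p < 0.01 uncorrected), and a
  permutation null (default 5000 relabelings) for the maximal
  suprathreshold component size; component-level corrected p-values.
* **Group statistics** (`ancova_group_effect`, `posthoc_pairwise`,
  `nodal_group_table`): covariate-adjusted (age, sex) omnibus F tests of
  AUC metrics, gatekept post-hoc contrasts with Bonferroni/FDR correction,
  and Spearman brain–behaviour correlations (`spearman_corr`).
* **Synthetic cohorts** (`generate_cohort`): three groups of 30 subjects on
  a shared geometric-modular 90-node template with a graded
  global-efficiency deficit (×0.93 per group step), a planted 8-edge
  impaired subnetwork in the MCI group, and cognition scores linked to true
  network efficiency — the fully known ground truth used to validate every
  stage.

`run_pipeline()` ties the stages together from a directory of matrix TSVs
plus a phenotype CSV to a directory of results tables, and
`inst/scripts/fanet-cli.R` exposes `simulate` and `run` subcommands for
shell use.

## Worked example

```r
library(fanet)

# a synthetic cohort with the default study conditions
cohort <- generate_cohort(cohort_config(seed = 42))

# metric curves for one subject, normalized against 100 random networks
cur <- metric_curves(cohort$matrices[["S001"]], n_random = 100, seed = 1)
round(cur$global[, c("sparsity", "Cp", "Lp", "Eglob", "gamma", "lambda", "sigma")], 3)
#>   sparsity    Cp    Lp Eglob gamma lambda sigma
#> 1     0.10 0.106 3.867 0.287 1.497  1.033 1.450
#> 2     0.11 0.113 3.773 0.293 1.509  1.032 1.462
#> 3     0.12 0.130 3.706 0.298 1.614  1.035 1.559
#> 4     0.13 0.140 3.640 0.303 1.642  1.033 1.589
#> 5     0.14 0.149 3.591 0.306 1.607  1.033 1.556
#> 6     0.15 0.162 3.556 0.309 1.637  1.034 1.583
```

Every row has `sigma > 1`: the thresholded networks are small-world (high
normalized clustering `gamma`, near-random path length `lambda`). The AUC
summary collapses each curve into one number per metric:

```r
round(auc_summary(cur)$global, 4)
#>     Cp     Lp  Eglob   Eloc  gamma lambda  sigma
#> 0.0067 0.1842 0.0150 0.0103 0.0794 0.0517 0.0768
```

NBS recovery of a planted deficit: in a cohort whose *only* group effect is
a 0.2 FA reduction on 8 template edges in the MCI group, the HC-vs-MCI
contrast finds one significant component that contains all eight planted
edges (plus one false neighbour; Jaccard 8/9):

```r
pow <- generate_cohort(cohort_config(eglob_effect = 1, planted_delta = 0.2,
                                     seed = 42))
nbs_test(pow$matrices, pow$phenotypes$group,
         nbs_params(n_perm = 1000, seed = 7), contrast = c("HC", "MCI"))
#> Network-based statistic (HC vs MCI)
#>   1000 permutations, primary p < 0.01, alpha 0.05
#>   component 1: 9 edges / 10 nodes, corrected p = 0.0120 *
#>   component 2: 2 edges / 3 nodes, corrected p = 0.7433
#>   ...
```

The methods vignette (`vignettes/structural-connectome-analysis.Rmd`)
documents the model conventions, the synthetic-data design, and the
numerical choices in detail.

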