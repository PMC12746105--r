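# schptmbench

Benchmarking tools for imputation on single-cell histone-modification data.

Single-cell profiling of histone post-translational modifications (scHPTM;
sortChIC, scCUT&Tag and related assays) yields extremely sparse cell ×
genomic-bin count matrices — often a few hundred reads per cell spread over
tens of thousands of 50 kb bins. Many groups apply imputation algorithms
developed for scRNA-seq or scATAC-seq to these matrices, but whether any of
them actually help is hard to judge: real data has no ground truth.
`schptmbench` addresses this for method developers and analysts by

1. **simulating** scHPTM datasets with a *known* ground truth and controlled
   noise and read depth,
2. **scoring** any (raw, normalized or imputed) matrix with embedding-free
   metrics, and
3. **ranking** competing algorithms across simulation scenarios.

## The model

**Simulator.** From a labeled count matrix, counts are aggregated per cell
type into pseudobulks, the ground truth. Each cell's noiseless profile `P`
is its type's pseudobulk projected onto genome-wide bins. Uniform background
noise (unspecific cuts) is added at noise level `l`:

    N_ij = P_ij + l * mean_j(P_ij)

so the added noise mass is exactly `l` times the signal mass and the
signal-to-noise ratio is `1/l`. Finally each cell is downsampled to a fixed
read depth by multinomial sampling. The default grid — ten noise levels
(0–5) × three depths (100 / 1 000 / 10 000 reads per cell) — yields 30
datasets per modality.

**Metrics.** Computed directly on the matrix, without dimensionality
reduction:

- *Correlation to ground truth* — per-cell Pearson r against the cell
  type's pseudobulk, summarized by the median.
- *SiP (Signal in Peaks)* — fraction of a cell's signal in bins overlapping
  peak calls (the binned analogue of FRiP), with a shuffled-peak
  permutation null.
- *SIMIC* — the mean cosine similarity between each cell's type and the
  types of its k = 10 nearest neighbors (Pearson distance on the top 5 %
  variable bins), divided by the abundance-weighted expected similarity
  `ES = Σ_ij W_i W_j S_ij`. SIMIC = 1 means neighbors are no more similar
  than random cells; > 1 means cell-type structure.
- *KNN cell-type prediction* — confusion matrix, per-class sensitivity/FPR
  and macro averages from neighbor-type enrichment.
- *Enrichment metaprofiles* — region-normalized signal around peak centers
  or starts (± 0.5 Mb).

**Ranking.** Per scenario, each metric's summary is min-max scaled across
algorithms (`scaled(Y) = (Y − min Y)/(max Y − min Y)`); the three task
scores (correlation, similarity, enrichment) average into `S_scenario`, and
`S_overall` is the median `S_scenario` across scenarios. Algorithms that
fail a scenario score 0 there.

## Worked example

```r
library(schptmbench)

# synthetic dataset: 3 cell types x 40 cells, 400 x 50 kb bins, each type
# 8-fold enriched in its own 10% of bins, ~2000 reads/cell
fx <- make_fixture(n_types = 3, cells_per_type = 40, n_bins = 400,
                   frac_marked = 0.1, fold = 8, depth = 2000, seed = 1)

# two scenarios at 1000 reads/cell: no noise, and mid noise (l = 1.25)
res <- generate_scenario_grid(fx$counts, fx$labels, fx$grid,
                              noise_levels = c(0, 1.25), depths = 1000L,
                              seed = 1)
mask <- bins_in_peaks(fx$grid, fx$peaks)
for (sc in res$scenarios) {
  norm <- libsize_normalize(sc$counts)
  r  <- corr_to_ground_truth(norm, res$pseudobulks_genome, res$labels)
  s  <- sip_score(norm, mask)
  sm <- simic(norm, res$labels)
  kp <- knn_cluster_predict(norm, res$labels)
  cat(sprintf("%-12s median r = %.3f  median SiP = %.3f  SIMIC = %.3f  macro sens = %.3f\n",
              sc$spec$label, r$summary, s$summary, sm$simic,
              kp$macro_sensitivity))
}
#> l0_d1000     median r = 0.849  median SiP = 0.266  SIMIC = 1.536  macro sens = 1.000
#> l1.25_d1000  median r = 0.587  median SiP = 0.174  SIMIC = 1.136  macro sens = 1.000
```

Adding mid-level noise (SNR = 0.8) drags the median ground-truth
correlation from 0.85 to 0.59 and dilutes signal-in-peaks from 0.27 toward
the genomic background; SIMIC drops toward its random-neighbor baseline of
1 while 10-NN type prediction is still perfect — exactly the task
dissociation the framework is designed to expose. An imputation method is
evaluated by running it on `sc$counts` and passing its output matrix to the
same functions (imputed matrices are scored as returned, without
re-normalization), then aggregated:

```r
tab <- data.frame(
  algorithm = rep(c("none", "methodA", "methodB"), each = 3),
  scenario  = "l1.25_d1000",
  metric    = rep(c("correlation", "similarity", "sip"), 3),
  value     = c(0.62, 1.31, 0.23,  0.81, 1.52, 0.29,  0.74, 1.60, 0.21))
ranks <- overall_and_rank(task_and_scenario_scores(tab))
ranks$overall
#>   algorithm  S_overall rank
#> 1   methodA 0.90804598    1
#> 2   methodB 0.54385965    2
#> 3      none 0.08333333    3
```

The same pipeline is scriptable from a shell via the installed CLI
(`system.file("cli/schptmbench", package = "schptmbench")`) with
subcommands `fixture`, `simulate`, `evaluate`, `rank` and `profile`.

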