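---
title: "Benchmarking imputation for single-cell histone-modification data"
author: "schptmbench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking imputation for single-cell histone-modification data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schptmbench)
```

# Motivation

Single-cell histone-modification assays (sortChIC, scCUT&Tag) produce count
matrices that are sparse to the point where most analytical intuition from
scRNA-seq breaks down: a cell may carry a few hundred reads distributed over
tens of thousands of genomic bins, and the biological signal of interest is
a *regional* enrichment rather than a per-gene quantity. Imputation methods
promise to recover the underlying signal, but on real data there is no
ground truth to score them against. `schptmbench` evaluates imputation by
construction: it simulates datasets whose ground truth is known exactly,
scores arbitrary matrices with metrics that avoid embedding choices, and
aggregates the scores into per-task and overall rankings.

This vignette documents the model, the parameters that matter, the
numerical decisions, and what passing our tests does and does not imply
about real data.

# The simulation model

## Ground truth

Starting from a labeled cell × bin count matrix, counts are summed per cell
type into **pseudobulks**. The noiseless per-cell matrix $P$ assigns every
cell the pseudobulk profile of its type, projected onto a genome-wide grid
of fixed-width bins (50 kb by default; 10 kb suits higher-resolution
scCUT&Tag data). Cells of the same type are therefore exchangeable before
downsampling — all within-type variability in the generated data comes from
the sampling step, which mirrors the view that a cell type shares one
underlying epigenomic state.

## Uniform noise

Background in these assays is dominated by unspecific cuts that land
roughly uniformly along the genome. We model this by adding, to every bin
of cell $i$, the cell's mean bin count scaled by the noise level $l$:

$$N_{ij} = P_{ij} + l \cdot \frac{\sum_j P_{ij}}{n}.$$

Two properties make this parameterization convenient. First, the added
noise mass equals $l$ times the signal mass, for every cell and globally,
so the signal-to-noise ratio is exactly $1/l$: the mid-noise levels
($l = 0.75, 1, 1.25$) bracket SNR $\in [0.8, 1.4]$ and the high levels
($l = 2, 3.5, 5$) give SNR $\le 0.5$. Second, it leaves the *relative*
signal shape untouched, so metric degradation is attributable to noise and
sparsity alone. A `mode = "global"` variant adds the grand mean instead of
the per-cell mean; the two coincide when all cells have equal totals, and
both satisfy the mass identity $\sum (N - P) = l \sum P$ to machine
precision. We default to the per-cell form because the noise floor of a
cell in real data scales with its own coverage.

Noise is added as a real-valued intensity and *not* rounded: integrality
and sparsity are restored by downsampling. Rounding at 50 kb bins would
distort low-$l$ scenarios, where the per-bin increment is well below one
count.

The framework deliberately models only uniform background. Open-chromatin-
biased noise — unspecific cuts concentrated in accessible regions, which
differ between cell types — is out of scope; results on simulated data
therefore say nothing about an algorithm's robustness to structured,
type-correlated background.

## Downsampling and the scenario grid

Each cell is thinned to a target depth by drawing exactly `depth` reads
from a multinomial with probabilities $N_{ij} / \sum_j N_{ij}$. The
fixed-total multinomial is the canonical model of uniform read thinning;
it fixes every row sum exactly, which makes the depth contract testable
(`rowSums == depth`) and removes depth as a nuisance covariate within a
scenario. Cell-to-cell variability within a type arises here.

A **scenario** is one (noise level, depth) pair. The default grid of ten
noise levels $\{0, 0.25, 0.35, 0.5, 0.75, 1, 1.25, 2, 3.5, 5\}$ × three
depths $\{100, 1000, 10000\}$ reads/cell produces the standard 30 datasets
per modality; extreme levels (e.g. $l = 10, 50$) can be appended to probe
failure regimes. Reproducibility is hierarchical: a master seed spawns one
child seed per scenario via a fixed affine rule modulo $2^{31}-1$
(`child_seed()`), so any single scenario can be regenerated without
replaying the grid.

## The synthetic fixture

`make_fixture()` provides a self-contained stand-in for a real labeled
dataset: a toy two-chromosome genome, `n_types` cell types each owning a
disjoint set of marked bins covering `frac_marked` of the genome, and
Poisson counts at `fold` times the background rate in a cell's own marked
bins. The marked bins double as the peak set, so every metric can be
exercised end to end. `fold = 1` produces a structureless null in which
labels carry no information — the calibration case for SIMIC. Defaults
(4 types × 100 cells, 2 000 bins, 10 % marked, fold 8, ~5 000 reads/cell)
give a clearly structured but not trivially separable dataset of the size a
desk-scale benchmark needs.

The fixture emulates type-specific regional enrichment, uniform background
and Poisson sampling. It does not emulate batch effects, fragment-length
structure, chromatin-accessibility-correlated background, or the
long-range autocorrelation of real domains; a method that excels on
fixtures may still fail on those features.

# Evaluation metrics

## Correlation to ground truth

Per cell, the Pearson correlation between the cell's profile and its
type's pseudobulk, summarized by the median over cells. Pearson (rather
than rank) correlation is used because residual dropout and additive noise
should be penalized, not rank-normalized away. Pre-imputation matrices are
library-size normalized first; imputed matrices are scored exactly as
returned, because the imputation algorithm owns its output scale. All
shared bins enter the correlation (not only nonzero-truth bins): imputing
signal into empty regions is an error the metric should see. Constant
cells (or truth rows) have undefined $r$ and are excluded and counted,
never imputed as zero.

## Signal in Peaks

$\mathrm{SiP} = \text{signal in peak-overlapping bins} / \text{total
signal}$ per cell, median-summarized — the binned analogue of FRiP. Peak
calls are pre-processed the way broad-domain callers require: isolated
calls (no neighbor within 50 kb) are removed, calls within 5 kb are merged,
and merged intervals below 10 kb are dropped, in that order. The rule
order follows the procedure's description; because it is linguistic rather
than demonstrated, `isolate_after_merge` can swap the first two stages.
Note the composed filter is *not* idempotent on pathological inputs:
merging a tight cluster can leave it isolated, so a second pass would drop
it. This is a property of the rules themselves, not of the implementation.

The permutation null (`sip_null`) relocates each peak uniformly within its
chromosome, preserving widths and chromosome assignment, and reports the
25th/75th percentiles of the null median SiP over 1 000 sets. A subtlety
worth knowing: a randomly placed peak of $k$ bin-widths almost surely
straddles $k + 1$ bins, so the null expectation exceeds the naive
peak-bp fraction by about one bin per peak.

## SIMIC

SIMIC asks whether cells sit near cells of similar *type*, without ever
embedding the data. The expected similarity is
$ES = \sum_{i,j} W_i W_j S_{ij}$, where $S$ is the cosine similarity
between type pseudobulks and $W$ the cell-type proportions. Cosine
similarity is used directly — for non-negative profiles it already lies in
$[0, 1]$ and keeps $S_{ii} = 1$ interpretable — and the diagonal terms are
included in $ES$: both choices are required for the null calibration below.
Observed similarity $S_{obs}$ is the mean, over cells, of the mean
$S(\text{type}(c), \text{type}(u))$ across the cell's $k = 10$ nearest
neighbors under Pearson distance on the top 5 % variable bins (variance
computed on the matrix as supplied; the caller normalizes raw counts).
$\mathrm{SIMIC} = S_{obs} / ES$.

Under random neighbor structure the expected per-cell score is exactly the
abundance-weighted mean similarity, i.e. $ES$, so SIMIC calibrates to 1 —
the property the acceptance suite verifies to within ±0.05 over 20
structureless fixtures. Self is never a neighbor; distance ties break by
cell order; constant cells are excluded from both the neighbor pool and the
average, and counted.

## KNN cell-type prediction

The same neighbor graph drives a label predictor: each type's neighbor
fraction is divided by its dataset proportion, and the most *enriched* type
is predicted (ties: larger raw count, then type order). Enrichment rather
than raw abundance is the default so that rare types are predictable at
all; `mode = "abundance"` restores the naive rule. The result is a
confusion matrix, per-class sensitivity and false-positive rate, and their
macro averages — a single operating point per method, not a threshold
sweep, because the classifier has no score to threshold.

## Enrichment metaprofiles

For visual assessment, signal around peaks is averaged after merging peaks
closer than 50 kb, sampling up to 1 000 of them, extracting binned coverage
in ±0.5 Mb around the peak center (point-source marks) or start (broad
domains), and dividing each region by its own mean coverage. Per-region
normalization makes the profile scale-free: uniform coverage yields the
constant profile 1 (tested to 1e-9), and any global rescaling leaves the
profile unchanged. Regions with zero mean are dropped and counted.

## Embedding grid search

Where a 2-D embedding is wanted, parameters are chosen by silhouette:
fraction of most variable bins (90 %/95 %), number of principal components
(5–50), and UMAP neighborhood size (10/15/20) are grid-searched, each
configuration scored by the mean silhouette width of the known labels in
UMAP space, and the argmax returned. Grid points whose input rank cannot
support the requested components are skipped and reported. UMAP runs
single-threaded under a fixed seed so the search is reproducible. This
function exists for visualization only; no ranking metric depends on it.

# Scoring and ranking

Within a scenario, each metric's summary is min-max scaled across the
algorithm pool (the non-imputed input counts as one more algorithm, as in
the figures such benchmarks print). Failed runs — technical error, memory,
timeout — score 0 on every metric of that scenario; they are *excluded*
from the min/max pool so one crash cannot compress everyone else's range.
If all non-failed values coincide, all receive 0.5: with no dynamic range
there is no evidence to crown a winner. Task scores are the scaled metrics
(correlation → $S_{correlation}$, SIMIC → $S_{similarity}$, SiP →
$S_{enrichment}$); $S_{scenario}$ is their unweighted mean and
$S_{overall}$ the median of $S_{scenario}$ across scenarios, ranked
descending with ties sharing the better rank.

Min-max scaling is idempotent and invariant under positive affine
transforms of a metric within a scenario, but it is *relative*: scores are
comparable only within the same algorithm pool, and adding or removing a
(non-failed) algorithm rescales everyone.

# Numerical choices and degenerate inputs

- **Coordinates.** In memory, intervals are `GRanges` (1-based closed,
  the Bioconductor convention); on disk all formats are BED-style 0-based
  half-open. Edge-to-edge gaps are identical in both conventions, so the
  50 kb/5 kb rules translate directly.
- **Promoter windows** span $[\mathrm{TSS} - 500, \mathrm{TSS} + 2000)$ in
  transcription direction (BED coordinates), with the minus strand the
  literal mirror $[\mathrm{TSS} - 2000, \mathrm{TSS} + 500)$; both offsets
  are parameters, and windows are clipped at chromosome bounds.
- **Ties** are always broken deterministically by position/order (variable
  bins by bin index, neighbors by cell order, predictions by type order),
  so results are invariant to re-running but not to permuting the input
  order — permute and re-run to assess that sensitivity.
- **Undefined values** (zero-total cells in SiP or normalization, constant
  profiles in correlations, zero-mean regions in profiles, zero clusters in
  RPKM) are excluded and counted, never silently replaced.
- **Zero-fraction cell filter**: the threshold
  $\bar{z} - 2\,\mathrm{sd}(z)$ is computed on the depth-filtered cells; a
  zero or undefined standard deviation disables the rule rather than
  dropping everything.
- **Seeds** are plain R integers; every stochastic function takes one, and
  the CLI derives all randomness from `--seed`.

# Problem sizes

The test suite and the calibration script run at desk scale by design:
fixtures of 60–400 cells × 80–2 000 bins, 200–1 000 permutations for nulls,
20 replicate fixtures for the SIMIC calibration. These sizes keep the full
suite under a minute of compute for the simulator and metrics while leaving
every statistical check comfortably powered; the same code paths scale to
real matrices (thousands of cells × ~50 000 genome-wide bins) limited
mainly by the dense $m \times m$ correlation matrix in the KNN graph.

# Known limitations

- Only uniform background noise is modeled; type-correlated background and
  batch effects are not.
- SIMIC requires at least two cell types and more cells than $k$; its null
  calibration assumes non-degenerate pseudobulks.
- The peak filter is not idempotent on pathological peak configurations
  (see above).
- `pseudobulk_spearman` compares methods on concatenated per-cluster RPKM
  vectors; clusters with zero totals fall back to pairwise-complete
  handling, which can make correlations non-comparable across method pairs
  when failures differ.
- The embedding grid search optimizes silhouette of *known* labels; it is a
  visualization aid and would overfit if used as a benchmark metric.
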