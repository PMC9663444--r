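# mist

Molecular region detection and region-specific denoising for spatially
resolved transcriptomics (ST).

## What problem this solves, and for whom

Spot-based ST platforms (10x Visium and the older ST arrays) measure a
spot-by-gene count matrix **Y** ∈ ℝ₊^(M×N) on a lattice, but dropout
leaves many transcripts unobserved: a large share of the zeros are
technical, not biological.  Naive smoothing borrows signal across
functionally different tissue, blurring exactly the boundaries a spatial
assay exists to resolve.

`mist` is for analysts who want dropout repaired *within* tissue
structure:

1. **Region detection** — spots are embedded by PCA of the top 80% most
   variable genes (p = 30 components); lattice-adjacent spots are joined
   by edges weighted with the Pearson correlation of their PC vectors;
   edges below a threshold ε are pruned and connected components larger
   than q spots become regions.  ε is selected automatically by
   maximising

   `mean intra-region similarity − mean inter-region similarity + σ · coverage`

   over a grid ε ∈ {0.10, 0.15, …, 0.90} (σ = 0.1).  Spots outside all
   regions are *isolated* — typically boundary spots with mixed cell
   content.

2. **Region-specific denoising** — each region's sub-matrix is completed
   under a low-rank assumption by solving
   `min ‖Y_r − A(X)‖² + λ‖X‖_nuc` with iterative singular-value
   soft-thresholding (threshold λ/2), descending a warm-started λ ladder
   from 2σ_max until the observed entries are reproduced to a total
   absolute error ≤ 1e-12.  Imputation is ensembled over k = 5
   region-centred mini-batches; every isolated spot receives one
   estimate per region.

A spatial-neighbour baseline (`impute_spknn`), holdout benchmarking
(RMSE / PCC / Spearman), silhouette (TSC / SSC / CSC) and adjusted-Rand
evaluation, Wilcoxon rank-sum marker detection, a synthetic-data
generator with planted ground truth, and a CLI are included.

## Worked example

```r
library(mist)

sim  <- generate_synthetic_st(seed = 1)   # 20x20 lattice, 200 genes,
data <- normalize_cpm(sim$data)           # 4 quadrants, 30% dropout
sim$data
#> STData: 400 spots x 200 genes (raw counts)
#>   x range [1, 20], y range [1, 20]
#>   zero fraction: 0.298

assignment <- detect_regions(data)
assignment
#> RegionAssignment: 4 region(s), 25 isolated spot(s), threshold 0.7
#>   sizes: 95, 95, 95, 90
```

The four planted quadrants are recovered as four pure regions (95 + 95 +
95 + 90 = 375 of 400 spots assigned); the 25 isolated spots sit on the
noisy margin.  Agreement with the planted labels on assigned,
non-boundary spots:

```r
sel <- !is.na(assignment$labels) & !sim$truth$boundary
adjusted_rand_index(assignment$labels[sel], sim$truth$region_labels[sel])
#> [1] 1
silhouette_scores(assignment, assignment$embedding, data$coords)
#> TSC 0.563  SSC 0.412  CSC 0.975
```

Holdout benchmark (fold 1 of 5: one fifth of every gene's non-zero
values zeroed, then imputed; RMSE is on the CPM scale):

```r
folds <- make_holdout_folds(data, seed = 1)
held  <- apply_holdout(data, folds, 1)
a1    <- detect_regions(held)
mist_fit <- impute_mist(held, a1, rng_seed = 1)
spknn    <- impute_spknn(held, a1$graph)
idx <- folds$folds[[1]]
#> MIST  RMSE  558.5   PCC 0.997
#> spKNN RMSE 5219.7   PCC 0.799
```

The ensemble recovers held-out values an order of magnitude more
accurately than neighbour averaging.  Regional markers:

```r
head(regional_markers(data, assignment), 3)
#>   region  gene fold_change log_diff    raw_p adjusted_p direction
#> 1      1 g0126        6.64     2.33 1.98e-24   3.97e-22        up
#> 2      1 g0042        6.76     2.47 8.67e-24   8.67e-22        up
#> 3      1 g0082        6.49     2.17 2.93e-22   1.96e-20        up
```

(The generator plants a 6-fold marker block per region; the reported
fold changes recover it.)

## Command line

```sh
inst/cli/mist simulate --out fixture --seed 1
inst/cli/mist detect   --input fixture/counts.csv --out det
inst/cli/mist impute   --input fixture/counts.csv --out imp --k 5 --seed 1
inst/cli/mist benchmark --input fixture/counts.csv --out bench --seed 1
```

Subcommands mirror the library (`run_simulate`, `run_detect`,
`run_impute`, `run_benchmark`); every run writes a JSON report with the
full configuration, and all randomness flows from `--seed`.

## Documentation

See the methods vignette (`vignettes/mist-methods.Rmd`) for the model,
the λ-continuation numerics, the design choices that were genuinely
open, and what the synthetic world does and does not establish.
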