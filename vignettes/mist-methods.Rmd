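---
title: "Molecular region detection and region-specific denoising: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular region detection and region-specific denoising: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mist)
```

## The problem

Spot-based spatial transcriptomics (ST) measures a counts matrix
$\mathbf{Y} \in \mathbb{R}_{\ge 0}^{M \times N}$ over $M$ barcoded spots
arranged on a lattice and $N$ genes.  Two features of these data drive the
design of this package:

* **dropout** — transcripts present in the tissue are frequently missed,
  so the matrix contains *technical* zeros alongside biological ones;
* **spatial organisation** — tissues are built from functional regions,
  and within one region the number of cell types (hence the number of
  independent expression programs) is small, so the region's dense
  expression sub-matrix should be approximately **low-rank**.

The pipeline exploits the second feature to repair the first: detect
molecular regions in silico, then estimate the dropout zeros of each
region by nuclear-norm matrix completion, region by region.

## Region detection

Spots are normalised to counts per million (CPM), the top 80% most
variable genes (dispersion = variance/mean) are kept, and spots are
embedded with mean-centred PCA into $p = 30$ components.  Each pair of
lattice-adjacent spots $(u, v)$ is joined by an edge weighted with the
Pearson correlation of their $p$-dimensional PC score vectors.  Edges
with weight below a threshold $\varepsilon$ are pruned; connected
components (depth-first search) with more than $q$ spots become regions
($q = 40$ for slides with $\ge 500$ spots, $q = 20$ otherwise), and all
remaining spots are **isolated** — typically boundary spots whose mixed
cell content makes their membership ambiguous.

$\varepsilon$ is chosen by grid search over $0.10, 0.15, \dots, 0.90$,
maximising

$$
\frac{1}{|R|}\sum_{r \in R}
  \overline{\mathrm{sim}}_{\text{intra}}(r)
\;-\;
\frac{1}{\binom{|R|}{2}}\sum_{r \ne r'}
  \overline{\mathrm{sim}}_{\text{inter}}(r, r')
\;+\;
\sigma \cdot \frac{\sum_{r \in R} |r|}{M},
$$

where $\overline{\mathrm{sim}}$ denotes the mean pairwise PC-vector
correlation over *all* pairs (not only adjacent ones), and the coverage
term is weighted by $\sigma = 0.1$.  With a single region the
inter-region term is 0; with zero regions the score is $-\infty$ and the
threshold is discarded.  Ties break toward the smaller $\varepsilon$,
keeping regions maximal.

**A scale caveat worth knowing.**  A spot whose mean correlation with its
region falls short by more than roughly $\sigma K n_r / (2M)$ is always
profitably shed to the isolated pool (the intra-region gain beats the
coverage penalty).  On desk-scale fixtures (hundreds of spots, hundreds
of genes, heavy uniform dropout) this bound is small (~0.05), so the
optimiser deliberately sheds a noisy margin of spots and the detected
regions are *pure cores* rather than full partitions.  On slide-scale
data the bound is similar but spot-level noise is far smaller, so
coverage is high.  Evaluation therefore treats isolated spots as having
no cluster membership (they are excluded from silhouette and
agreement scoring), and the imputer guarantees them an estimate from
every region (below).

### Log-transform or not

Whether expression should be log1p-transformed before PCA is left open
by the method's sources; this package defaults to PCA **on the CPM
scale**.  The reason is the behaviour under dropout: zeroing an entry
with CPM value $c$ is a perturbation of magnitude $\log(1+c) \approx 8$
in log space — comparable for every gene, independent of its biological
variance — and at realistic dropout rates these perturbations dominate
the PC subspace, driving adjacent-spot correlations toward zero.  On the
CPM scale the same dropout caps the correlation of two spots at roughly
$1 - p_{\text{drop}}$ but preserves the separation between regions.  On
real Visium data, where dropout concentrates on low-expression genes,
the log transform is mild and either choice works; `log1p = TRUE` is a
flag on `detect_regions()` and the CLI.

## Matrix completion

For each region the observed sub-matrix $\mathbf{Y}_r$ (zeros = missing)
is completed by solving

$$
\min_{\mathbf{X}} \; \lVert \mathbf{Y}_r - A(\mathbf{X}) \rVert^2
 + \lambda \lVert \mathbf{X} \rVert_{\mathrm{nuc}},
$$

where $A$ projects onto the observed entries and the nuclear norm is the
convex surrogate for rank.  The solver is proximal-gradient iteration:
a data-consistency step
$\mathbf{B} \leftarrow \mathbf{X} + \tfrac1\alpha A^T(\mathbf{Y}_r -
A(\mathbf{X}))$
followed by soft-thresholding the singular values of $\mathbf{B}$ at
$\lambda/2$; with $\alpha = 1$ (the sampling projector has unit operator
norm) each iteration is non-increasing in the objective, which the test
suite asserts.

### The continuation ladder and the choice of $\lambda$

$\lambda$ trades observed-entry fidelity against rank.  The selection
rule is: *the largest $\lambda$ whose converged solution reproduces the
observed entries to within a total absolute error of $10^{-12}$*.  Two
numerical facts shape the implementation:

1. A cold start at a small $\lambda$ stalls: the first iterate is the
   zero-filled matrix, which is already a fixed point to within
   tolerance, and nothing is imputed.  The solver therefore descends a
   **warm-started geometric ladder** from $\lambda_0 = 2\sigma_{\max}$
   (ratio 0.7), tracking the solution path — the standard way this
   family of algorithms is run, and the same device glmnet uses for its
   regularisation path.  Intermediate rungs are solved to a path
   tolerance of $10^{-4}$ (relative Frobenius change); the final rung is
   always solved to the contract tolerance of $10^{-6}$ (at most 500
   iterations per rung).
2. The converged observed-entry error scales essentially linearly with
   $\lambda$, down to a floor set by floating-point round-off of the
   SVD.  An absolute target of $10^{-12}$ is reached exactly when
   $\lambda/2$ falls below the representable perturbation of the
   spectrum ($\varepsilon_{\text{mach}}\,\sigma_{\max}$), at which point
   the proximal operator is computed as the exact identity rather than
   through a round-off-contaminated SVD: observed entries then pin to
   their inputs bitwise and the error is exactly zero.  This makes the
   selection rule well-defined: the ladder always terminates, and
   doubling the selected $\lambda$ demonstrably violates the rule.

`select_lambda()` refines the crossing with one geometric bisection step
and validates every candidate by replaying it through the same ladder
used by `svt_complete()`, so the returned value reproduces its error on
re-run.

### Mini-batch ensemble

Completing each region alone ignores two useful pools: isolated spots
(which must be imputed *somehow*) and the other regions (whose shared
genes stabilise gene-side factors).  For each region $r$, $k = 5$
mini-batches are built containing the whole core of $r$, a chunk of the
shuffled isolated pool — partitioned across the $k$ batches so that
**every isolated spot is processed exactly once per region** — and
$\lceil n_{\text{extra}}/2 \rceil$ spots sampled from the other regions
($n_{\text{extra}} = \min(100, M/5)$ by default).  Region spots receive
the mean of their $k$ batch estimates; isolated spots average one
contribution per region, i.e. $|R|$ results in total.  Negative values
are clipped to zero and observed non-zero entries are restored exactly.
The batch size both caps the SVD cost (the dominant operation) and, for
isolated spots, pools enough of them per batch that their mutual
structure is recoverable even when region detection was conservative.

The baseline used for comparison, **spKNN**, replaces each zero with the
mean of the same gene over the spot's lattice neighbours (zeros
included; a nonzero-only variant would change the bias, not the
ranking observed in the tests).

## Evaluation machinery

Holdout experiments follow a 5-fold scheme per gene: genes expressed in
at least 50% of the spots are eligible; each gene's non-zero entries are
randomly partitioned into five groups of near-equal size; one group is
zeroed, imputation runs on the rest, and recovery of the held-out values
is scored by RMSE, Pearson correlation, and Spearman correlation (with
the t-approximation p-value).  Region assignments are scored by mean
silhouette width on PC scores (TSC), on spatial coordinates (SSC), and
their sum (CSC), always excluding isolated spots, plus the adjusted Rand
index against reference labels.

Regional markers use the two-sided Wilcoxon rank-sum test (normal
approximation with tie correction) of each region against all other
regions' spots, Benjamini–Hochberg adjustment within region, and a
fold-change filter.  "Fold change > 50%" is interpreted as a ratio of
group means above 1.5 on the expression scale; the log1p mean difference
is reported alongside because the phrase "difference of average gene
expression" admits both readings.

## The synthetic world

`generate_synthetic_st()` emulates the features the method relies on and
nothing more:

* a rectangular (`square4`) or hexagonal (`hex6`, axial coordinates)
  lattice partitioned into contiguous planted regions (quadrants or
  stripes), with a boundary ring flagged in the truth object;
* per region, dense expression $U_r V_r^\top$ from strictly positive
  factors: one shared log-normal baseline profile (spread 0.1) with the
  region's disjoint marker block elevated 6-fold, plus `rank - 1` weak
  perturbation factors (weight 0.02) — exactly rank-`rank` per region
  when `noise_sd = 0`;
* multiplicative log-normal entry noise (default sd 0.05), a per-spot
  library-size factor (sd 0.2), and uniform Bernoulli dropout (default
  rate 0.3).

Defaults were fixed once, as the "strong between-region separation"
world the acceptance properties assume.  The marker-block design (rather
than fully independent region factors) is what real regional expression
looks like — programs spread over many genes — and is also what makes
detection statistically possible at 200 genes under 30% uniform dropout:
correlations concentrate as $1/\sqrt{n_{\text{eff}}}$ in the number of
effectively contributing genes.

What the generator does **not** model: negative-binomial counting noise,
expression-dependent dropout (real dropout favours low-expression
genes — uniform dropout is deliberately *harsher* on the embedding),
cell-type deconvolution ground truth, or smooth within-region spatial
gradients.  A green test on this world therefore establishes the
algorithmic properties (recovery, ordering against the baseline,
calibration), not slide-level biological accuracy.

## Known limitations

* The threshold objective's shedding bias (above) means coverage can be
  low on small noisy slides; inspect `print()` of the assignment and the
  isolated count before interpreting regions biologically.
* Completion cost is dominated by one SVD per iteration per batch;
  slides with thousands of spots are feasible but minutes-scale on one
  core.
* The pipeline assumes one slide; no cross-sample joint detection.
* CPM is the only normalisation offered, and completion runs on the CPM
  scale.

```{r example, eval = FALSE}
sim <- generate_synthetic_st(seed = 1)
data <- normalize_cpm(sim$data)
assignment <- detect_regions(data)
result <- impute_mist(data, assignment, rng_seed = 1)
markers <- regional_markers(data, assignment)
```
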