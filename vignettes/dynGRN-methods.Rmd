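---
title: "Inferring stage-specific regulatory networks with dynGRN"
author: "dynGRN maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring stage-specific regulatory networks with dynGRN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynGRN)
```

## The problem

During a differentiation time course (for example embryonic stem cells
progressing through mesoderm and cardiac progenitors to cardiomyocytes) the
gene regulatory network is not static: the set of active regulator-target
relationships rewires between stages.  Reconstructing those stage-specific
networks from expression data alone is badly under-determined — with $p$
genes and $T$ stages there are $(T-1)p^2$ candidate edges and only
$(T-1)p$ observations.  dynGRN implements a two-step strategy that makes
the problem tractable by bringing sequence, chromatin and perturbation
information to bear:

1. **A per-base occupancy probability (the LR score).**  A logistic
   regression is trained on candidate transcription-factor binding sites
   (PWM hits in the cis-region around each gene's TSS), labeled by whether
   the hit falls inside a ChIP-seq peak of the same TF.  Its 69 features
   describe the base's sequence context (conservation, CpG, repeat and
   gene structure, GC content, distance to the TSS), the expression of the
   nearest gene at the flanking stages, and the asinh-transformed
   intensity of five chromatin marks (H3K27ac, H3K4me1, H3K4me3, H3K27me3
   and RNA polymerase II) in centered windows of 1000/500/100/50/10 nt at
   stage $t$ together with their change to stage $t+1$.  Because none of
   the features mention a specific motif, the fitted model scores *any*
   base for *any* TF with a known PWM at *any* stage transition — that is
   the point: ChIP data for a handful of TFs generalizes to the full PWM
   compendium.

2. **A time-varying dynamic Bayesian network.**  Expression on the
   $\log(\mathrm{FPKM}+1)$ scale is modeled as a linear dynamical system
   $X^{t+1} = A^t X^t + \varepsilon$.  Each row of $A^t$ factorizes
   through the gene's cis-segments: $A^t_{i\cdot} = (u^{i,t})^\top
   B^{i,t}$, where the binding matrix $B$ has one row per 50-bp segment
   (step 5 bp) and one column per abundantly expressed TF, with entries
   equal to the segment-mean LR score times a perturbation adjustment
   $\pi_{ij}$ ($1$ when target $i$ responded in a perturbation experiment
   of regulator $j$, $0.25$ otherwise) wherever the TF has a surviving PWM
   hit.  The segment weights solve, per gene,
   $$\min_{u^{i,1..T-1}} \sum_t \left(X_i^{t+1} - (u^{i,t})^\top B^{i,t}
   X^t\right)^2 + \lambda_1 \sum_t \lVert u^{i,t}\rVert_1 + \lambda_2
   \sum_t \lVert (u^{i,t})^\top B^{i,t} - (u^{i,t+1})^\top
   B^{i,t+1}\rVert_1 .$$
   The L1 term selects few segments (most cis-DNA is inert); the fused-L1
   term encourages adjacent transitions to share edge weights, which is
   what couples the per-transition equations and makes the per-gene
   problem identifiable.  A positive entry of $A^t$ is reported as a
   regulator-to-target edge, and segments with non-zero weight are the
   predicted binding sites that mediate it.

The data term is the squared residual against the full expression vector
$X^t$ — the form consistent with reporting explained variance — and an
absolute-value loss is available through `dbnConfig(loss = "abs")` for
robustness to outlying stages.

## Conventions and containers

Sequences, intervals and annotations live in Biostrings/GenomicRanges
containers, hence 1-based closed coordinates internally; BED, bedGraph and
the other half-open formats are converted at the boundary.  Abutting
half-open intervals (e.g. `[0,5)` and `[5,9)`) therefore do not overlap,
and a hit is labeled positive only on a true one-base overlap with a peak.

Ties in the nearest-gene assignment of cis-region bases (a base exactly
equidistant between two TSSs) go to the gene with the smaller TSS
coordinate; regions are clipped, not shifted, at chromosome ends.  PWM
count matrices receive a pseudocount of 0.01 per cell before column
normalization; scanning uses the min-max normalized score
$(s - s_{\min})/(s_{\max} - s_{\min}) \ge 0.9$ on both strands, with
ambiguous bases contributing the column minimum (conservative), even-length
motif centers rounded left, and overlap resolution keeping the
highest-scoring hit (5'-most on ties).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| cis-region width | 40,000 nt | window centered on the TSS (toy runs use the generator's region length) |
| scan threshold | 0.90 | min-max normalized PWM score cutoff |
| gene FPKM filter | 1 | a gene enters the universe if it exceeds this in any stage |
| TF FPKM filter | 25 | only abundantly expressed TFs enter the binding matrix at a stage |
| segment width / step | 50 / 5 nt | cis-segment tiling (adjacent overlap 45 nt) |
| $\pi$ default | 0.25 | binding-potential discount without perturbation support |
| $\lambda_1, \lambda_2$ | CV-selected | sparsity and temporal-smoothing penalties |
| bootstrap $N$ | 100 | resampling replicates; the attainable p-value floor is $1/(N+1)$ |
| edge tolerance | 1e-8 | solver noise floor below which a weight is not an edge |

Hyperparameters are selected by leave-one-transition-out cross-validation
on a seeded gene subsample: the weights are refitted without one
transition's data term (the smoothing term restricted to adjacent fitted
pairs), the held-out transition is predicted with the temporally nearest
fitted weight vector (the earlier one when both neighbors are equally
close), and the squared prediction error is averaged; ties in the arg-min
go to the lexicographically smaller $(\lambda_1, \lambda_2)$.

## The solver

Each per-gene problem is a generalized lasso: a low-rank quadratic (one
residual per transition) plus two L1 terms, one on the coordinates and one
on a linear map $D u$ built from the $B$ matrices of adjacent transitions.
It is solved by ADMM with the splitting $z = [u; Du]$ (for the absolute
loss the data rows join the splitting as well).  The $u$-update solves a
ridge-plus-low-rank system through the Woodbury identity, so one iteration
costs $O(n \cdot \mathrm{rank})$ rather than $O(n^2)$; the penalty
parameter $\rho$ is rebalanced from the primal/dual residuals, and
iteration stops on the standard residual criteria (defaults
`epsAbs = 1e-9`, `epsRel = 1e-7`).  The reported weights are the
soft-thresholded ADMM copy, which is exactly sparse at the optimum — that
is what makes the 1e-8 edge tolerance meaningful.  The test suite certifies
the solver against an independent interior-point quadratic-programming
solve of the same objective on a panel of random small instances, against
the closed form of the unpenalized one-segment problem, and against the
monotonicity laws an exact solver must obey (optimal value non-decreasing
in either penalty, total weight mass non-increasing in $\lambda_1$).

Under perfect separation the unregularized logistic likelihood has no
finite maximizer; the IRLS fit detects the runaway-coefficient signature,
flags non-convergence, and `trainOccupancyModel()` then falls back to the
LASSO path (the paper-scale fit, with millions of candidate bases, is not
separable — but a desk-scale table with dozens of rows against 69 features
routinely is, and the penalized fit is the principled estimator there).

## Significance and perturbation

Bootstrap p-values for a segment weight resample the cis-region's per-base
LR values with replacement (positions keep their identity; values are
drawn from the region's empirical distribution — segment-level block
resampling is available), rebuild $B$, re-solve with the point-estimate
hyperparameters, and report $p = (\sum_n H({}^n u > u) + 1)/(N+1)$.
Because only the segment means of the LR track enter $B$, replicates reuse
the precomputed hit-coverage structure and merely rescale rows, which is
what makes $200 \times 101$ re-solves affordable.  A replicate whose solve
fails is retried once and then counted as an exceedance (conservative).

In-silico perturbation multiplies one TF's FPKM by a fold (default 5),
re-logs, and propagates the change one step through $A^t$; genes are
called up/down/unchanged by the sign of the change, unchanged genes are
excluded, and agreement with experimental calls is tested two-sided by
Fisher's exact test.

## What the synthetic data emulates — and what it does not

`simulateGrnDataset()` generates the complete study conditions from one
seed: a toy genome (default 20 genes, 1-kb cis-regions — chosen so a full
inference run takes minutes on one CPU; the vignette-scale numbers in the
test suite state the sizes they use), five TF genes with distinct 8-mer
motifs and near-unit self-loops (so they stay above the FPKM-25 filter at
every stage), one or two TF regulators per target gene with positive
weights (two-regulator genes may carry one repressive edge, keeping
trajectories positive while giving perturbation responses in both
directions), consensus motif instances planted at ChIP-confirmed sites
plus unbound decoy instances elsewhere (the negative training examples),
flat-topped H3K27ac/H3K4me1 bumps with a centered dip at bound sites plus
Poisson noise, conservation elevated at bound sites, expression simulated
from the true network with noise sd 0.05 over four stages, and a
perturbation matrix observing 60% of the true edges (the rest exercise the
$\pi = 0.25$ path).  The true segment weights are constructed so that
$A^\ast = (u^\ast)^\top B^\ast$ holds exactly.

This emulates the statistical *structure* the method assumes — localized
high-LR islands at bound sites, binding-site dips, temporally consistent
dynamics — but not the texture of real data: mammalian cis-regions are 40
kb with overlapping genes, motif hits are vastly more degenerate, signal
tracks carry fragment-length and mappability artifacts, expression noise
is not Gaussian, and true networks have indirect and combinatorial
regulation.  Passing the recovery tests therefore demonstrates the
correctness of the machinery under the model's own assumptions; what the
method achieves on genome-scale mammalian data is a separate, empirical
question that desk-scale benchmarks cannot answer.

A note on the bootstrap calibration check: the p-value is approximately
uniform under a null gene (i.i.d. LR values, no signal) only when the
segment is a small window of the region — the segment mean is then nearly
exchangeable with its resamples.  The calibration test uses a 100-nt
region (11 segments) with the unpenalized fit so the statistic is
continuous; with sparsity active, a null weight sits exactly at zero in
point estimate and replicates alike and its p-value is degenerate at 1,
which is the correct behavior for selection, not a calibration defect.

## Numerical choices and degenerate inputs

* Signal re-binning is a coverage-weighted mean with gaps as zero; the
  last chromosome bin averages only its real bases.
* Standardization uses the sample (n−1) standard deviation; constant
  columns are zeroed, flagged, and excluded from the fit (coefficient 0,
  NA standard error); prediction reuses the training scaler.
* Predicted probabilities are clamped to (1e-12, 1−1e-12) so LR tracks
  remain strictly inside (0,1) even for saturated fits.
* Regions shorter than one segment yield zero-length weights with the
  data term at $u = 0$ as the objective; TFs below the abundance filter
  or without a PWM simply contribute no column.
* The Wilcoxon comparison of enhancer versus random scores uses the exact
  distribution when both samples have at most 10 untied observations and
  the tie-corrected normal approximation otherwise; fully tied samples
  return p = 1.
* The enrichment test for high-LR regions is a one-sided binomial test of
  hit centers against the genome-wide fraction of high-LR bases (the
  base-resolution background is well defined here), with the lowest p per
  TF over its PWMs and Benjamini–Hochberg correction across TFs.

## Known limitations

* The one-step perturbation propagates direct effects only; indirect
  cascades require iterating the map and are out of scope.
* Positive-edge counting is at the gene-pair level ($A^t_{ij}$ above the
  tolerance); segment-level counting ($u > 0$) is exported in the TFBS
  table for comparison.
* The CV scheme fixes one $(\lambda_1, \lambda_2)$ pair shared across
  genes; per-gene penalties would add flexibility at the cost of
  exchangeability across the network.
* With only $T-1$ observations per gene, edges of TFs with nearly
  collinear expression trajectories are not separable in principle; the
  perturbation prior ($\pi$) is what breaks most of those ties.
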