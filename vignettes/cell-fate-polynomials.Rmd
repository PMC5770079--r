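---
title: "Polynomial cell-fate prediction: model, evaluation and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polynomial cell-fate prediction: model, evaluation and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyfate)
```

## The problem and the model

`polyfate` predicts the fate of single cells — specifically the probability
that a cell dies by apoptosis — from its gene expression profile. The
executioner caspases CASP3, CASP6 and CASP7 carry out apoptosis, so their
combined expression is used as the death readout: for each cell the three
marker values are summed and divided by the maximum combined value over all
cells, giving a death probability $P \in [0, 1]$. A cell with $P \ge 0.5$ is
classed as likely to die; the intervals are $[0, 0.5)$ and $[0.5, 1]$, so
the boundary value belongs to the high class.

Any sufficiently smooth relationship between expression and fate can be
approximated by a truncated power series, which motivates a polynomial
regression in $l$ predictor genes $x_1, \dots, x_l$:

$$P = b + \sum_{m=1}^{l} \sum_{p=1}^{n} k_{mp}\, x_m^{p}
      \;+\; \sum_{(i,j)} k'_{ij}\, x_i x_j ,$$

where $n \in \{1,2,3\}$ is the degree and the optional cross terms are plain
products of gene pairs, representing synergistic regulation. The design
matrix is fully determined by the spec: an intercept column, then for each
power $p = 1..n$ the genes in importance order raised to $p$, then the
cross-product columns, for $1 + l\,n + M$ parameters. On the 32-gene
apoptosis list this gives 33, 65 and 97 parameters for degrees 1–3, and 71
for degree 2 with six cross terms. Coefficients are estimated by ordinary
least squares — no regularisation; collinearity among high powers is
reported through the rank, not penalised.

## Scales and conventions

RPKM-like expression is strongly right-skewed, and a log transform makes it
roughly symmetric, so predictors enter the model as $\log_2(x + 1)$ (base
and offset configurable). The death-probability label, in contrast, is
computed on the raw scale, because the readout is the literal combined
caspase expression. Both choices are exposed as flags; the maximum used for
normalisation is taken over exactly the cells passed in.

Predictions are **not** clipped to $[0,1]$: classification applies the 0.5
threshold, which is unaffected by values outside the unit interval, and
clipping would hide fit pathologies from the stability analysis.

## Feature selection

Two modes are supported.

* **Correlation mode** ranks genes by the absolute Spearman rank correlation
  $\rho$ between each gene's expression and $P$, and keeps the top $k$
  (default 30). Ties in the underlying ranks get average ranks (standard
  Spearman); ties in $|\rho|$ are broken by input gene order so selection is
  deterministic. Cross-term pairs, when requested, are ranked the same way
  by the pairwise $|\rho|$ among the selected genes. Requesting more pairs
  than $\binom{k}{2}$ is an error — such grid cells are reported as not
  applicable. Selection always runs on the training cells of each
  cross-validation fold only, including pair ranking, so no information
  leaks from held-out cells.
* **Pathway mode** uses a fixed list of 32 common apoptosis-pathway genes
  (APAF1 … XIAP) in every fold, with cross terms supplied by known
  regulatory relationships rather than data. Only the TP53–MDM2 pair is
  fixed by the method's definition; the package's default of six pairs
  (TP53–MDM2, FADD–CASP8, TNFRSF1A–TRADD, BAX–BCL2, CYCS–APAF1,
  DIABLO–XIAP) is a documented repository choice — literature-standard
  regulatory or binding partners inside the list — and is fully
  configurable. Cross terms are simple products $x_i x_j$ ($p = q = 1$):
  one parameter per pair, which is what makes the degree-2-plus-six-pairs
  model carry $65 + 6 = 71$ parameters.

## Evaluation

Repeated $k$-fold cross-validation (default $10 \times 10$): each repeat
draws a fresh random partition into ten nearly equal folds (sizes differ by
at most one; no stratification), yielding 100 fitted models. Accuracy is
interval agreement: a prediction is correct when predicted and actual
probabilities fall on the same side of 0.5. The reported accuracy is the
arithmetic mean of the 100 fold accuracies. One master seed drives
everything; repeat $r$ partitions with sub-seed `seed + r`, so any single
repeat can be audited in isolation and a rerun is bit-identical.

## Stability and MVAV

Accuracy alone does not distinguish models that change drastically when the
training data change slightly. Two complementary stability measures are
computed over the 100 refits:

* **Parameter ranges** — the min–max envelope of each coefficient position,
  ordered intercept first, then the per-power gene blocks in importance
  order, then cross terms. Across correlation-mode folds the selected genes
  differ, so positions are aligned by importance rank; dimension $i$ of a
  sampled point likewise maps to the $i$-th ranked gene of each model. This
  rank-based alignment is an interpretation choice, documented here.
* **MVAV** — 10,000 points are sampled in expression space, each coordinate
  independently and uniformly within that gene's observed [min, max] (the
  least-assumption reading of "randomly selected"; empirical resampling of
  observed cells is available as an alternative by passing observed rows).
  Each of the 100 models predicts at each point; the per-point sample
  variance (denominator $n-1$; unspecified upstream, chosen as the standard
  unbiased form) is averaged to give the mean value of all variances.
  Smaller MVAV = more stable. The same seeded point set must be reused for
  every model setting with the same gene count, otherwise MVAVs are not
  comparable — `sample_stability_points()` is deterministic given its seed
  precisely for this reason.

The distribution of the 10,000 variances is summarised by a maximum
likelihood gamma fit with a one-sample Kolmogorov–Smirnov check at
$\alpha = 0.05$. Fitting and testing on the same data makes the test
anti-conservative; the p-value is reported as an informal check, not
corrected.

## The synthetic generator

No real pancreas dataset ships with the package, so a seeded generator
provides data with the structure the analysis assumes:

* raw expression drawn log-normal (`meanlog = 1.5`, `sdlog = 0.5`),
  emulating RPKM-like skew; predictors are then used on the log scale;
* a latent death probability computed from a polynomial (default: linear,
  ten informative genes with alternating-sign weights from 0.15 down to
  0.05, intercept centring the latent mean near 0.5) plus Gaussian noise
  (`noise_sd = 0.02`), clipped to $[0,1]$. Clipping rather than a logistic
  squash keeps the generating model exactly linear in the interior, which
  is what makes clean coefficient-recovery experiments possible; with the
  default weights clipping touches on the order of a percent of cells;
* an optional additive shift of the latent probability in a disease donor
  group (emulating the direction reported for T2D β-cells);
* three marker columns whose raw sum equals `latent * marker_scale`
  (default 400, an RPKM-like combined level), split across CASP3/6/7 by a
  symmetric Dirichlet draw — individual markers are noisy but the sum, and
  hence the recovered label, is exact.

Because labels divide by the maximum combined value, the coefficients
realized in the labels are the generating ones divided by
`max(labels_truth)`; `simulate_dataset()` reports both. What the generator
does **not** emulate: dropout and library-size effects, counts, cell-type
structure. Tests passing on this generator therefore certify the pipeline's
statistical machinery, not performance on real single-cell data.

## Numerical choices

* OLS is solved by SVD with singular values below
  `max(dim) * eps * max(sv)` treated as zero — a rank-revealing solve.
  Rank-deficient systems return the minimum-norm solution with a warning;
  under-determined systems additionally warn about shape.
* Constant genes have undefined correlation with the label; their $\rho$ is
  treated as 0 so they can never be selected. A constant label vector is an
  error.
* Degenerate stability dimensions (constant genes) sample at the constant
  value with a warning.
* Fold sizes: `n %% k` folds of size `n %/% k + 1`, the rest `n %/% k`.

## Problem sizes

The test suite and examples run the full design at 2,000 cells × 100 genes
(ten informative) with $10\times10$ cross-validation and 10,000 stability
points — the package's reference simulation conditions — and smaller grids
(~100–200 cells) for orchestration checks. The central qualitative property
reproduced there: with a linear ground truth and modest noise, the linear
model's MVAV is decisively below the cubic's on the same genes, folds and
point set, while their accuracies are close.

## Limitations

Degrees above 3 and three-way interaction terms are out of scope, as are
AUROC-style metrics, class rebalancing, nested tuning, and multiple-testing
correction in the group comparisons. The gamma goodness-of-fit flag is
informal (see above). Real-data accuracies depend on properties (dropout,
depth effects) the generator does not model.
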