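# polyfate

Polynomial regression models for predicting cell fate — the probability of
apoptotic death — from single-cell gene expression, with repeated
cross-validation and a quantitative stability analysis of the fitted
models. Intended for computational biologists who want a fate readout
derived from the data itself (no external viability assay) and who care not
only whether a model predicts well, but whether it stays the same model
when the training cells change.

## The method

Each cell's death probability is its combined expression of the executioner
caspases CASP3, CASP6 and CASP7, divided by the maximum combined value over
all cells:

$$P_c = \frac{x_{\mathrm{CASP3},c} + x_{\mathrm{CASP6},c} + x_{\mathrm{CASP7},c}}
             {\max_{c'}\,(x_{\mathrm{CASP3},c'} + x_{\mathrm{CASP6},c'} + x_{\mathrm{CASP7},c'})}$$

Cells with $P \ge 0.5$ are classed as likely to die. $P$ is then modelled
as a polynomial in $l$ predictor genes (log₂-scale expression), optionally
with product cross terms for gene pairs:

$$P = b + \sum_{m=1}^{l}\sum_{p=1}^{n} k_{mp}\,x_m^p + \sum_{(i,j)} k'_{ij}\,x_i x_j$$

fitted by ordinary least squares. Predictor genes come either from Spearman
correlation with $P$ (top-k per training fold) or from a fixed 32-gene
apoptosis-pathway list with regulatory cross-term pairs. Models are scored
by 10×10-fold cross-validation with interval-agreement accuracy (predicted
and actual $P$ on the same side of 0.5), and their stability by coefficient
min–max ranges across the 100 refits and by **MVAV** — the mean of the
prediction variances at 10,000 points sampled in expression space, smaller
meaning more stable. The variance distribution is checked against a gamma
fit. A seeded synthetic-data generator with caspase-encoded latent labels
makes the whole pipeline testable end to end.

## Worked example

```r
library(polyfate)

ds         <- simulate_dataset(simulation_config(seed = 1, group_shift = 0.1))
labels     <- compute_death_probability(ds$matrix)
predictors <- log_transform(exclude_marker_genes(ds$matrix))

labels
#> fate_labels: 2000 cells, 1195 high (p >= 0.5), 805 low

sel <- select_top_correlated(predictors, labels, k = 10)
cv  <- run_repeated_cv(predictors, labels,
                       cv_config(seed = 1, degree = 1,
                                 mode = "correlation", top_k = 10))
cv
#> Repeated CV: 10 repeats x 10 folds (correlation mode, degree 1)
#>   mean interval accuracy: 0.9007 (fold range 0.8500 - 0.9450)

pts <- sample_stability_points(predictors, sel$genes, 10000, seed = 1)
stability_report(cv$models, pts)
#> Stability report over 100 models, 10000 sampled points
#>   MVAV: 0.0301717
#>   widest parameter range: 0.2875 (IG01)
#>   gamma fit: shape 2.124, scale 0.0142, KS p = 0.0174 (fail)
```

The mean interval accuracy (0.9007) is the average over the 100 fold-level
accuracies; the MVAV (0.030) quantifies how much the 100 refitted linear
models disagree across expression space — compare it across degrees on the
same point set to rank model stability. The simulated disease group's
caspase shift is recovered by the group comparison:

```r
compare_groups(ds$matrix, group_a = "healthy", group_b = "T2D")
#>      label    mean_a    mean_b t_statistic      p_value significant    extent
#> 1    CASP3  66.15630  80.53638   -6.631249 4.270714e-11        TRUE 0.1785538
#> ...
#> 4 combined 201.49147 238.58516  -10.645560 8.845003e-26        TRUE 0.1554736
```

`extent` is $1 - \mathrm{mean}_{\mathrm{healthy}}/\mathrm{mean}_{\mathrm{disease}}$:
positive when the disease group expresses more caspase. For a whole
settings grid (degrees × gene counts, pathway mode, cross-term grids) use
`run_full_analysis()`, which writes accuracy/MVAV tables and a run
manifest.

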