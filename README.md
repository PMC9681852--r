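# screq

Self-consistent recovery of dropout-affected gene expression matrices by
adaptive histogram equalization.

## What it is for

Low capture efficiency leaves single-cell RNA-seq count matrices dominated
by dropout zeros and compresses their value distribution toward zero.
`screq` recovers the expression scale of such matrices by distribution
matching rather than by cell–cell similarity: it learns one target
distribution for the denoised data and remaps every rectangular block of
the matrix onto it.  Because the whole computation is histograms and lookup
tables, it runs in seconds on matrices where similarity-based imputation
methods take hours.

The intended users are analysts of droplet/UMI count matrices (or
normalized expression) who want a fast, deterministic imputation step with
an auditable statistical model behind it.

## The model

Let $S$ be the cells × genes matrix.  A random subsample of cells is
denoised by a three-layer autoencoder
($\mathbf h = \sigma(W \mathbf x + \mathbf b)$ with latent dimension
$P = 2$, linear decoder), and the histogram $p(n) = N(n)/N$ of the
reconstruction is fitted by one of three single-parameter densities on the
normalized value range — half-Gaussian
$f_g(x) = \frac{2}{\lambda\sqrt{\pi}} e^{-(x/\lambda)^2}$, Rayleigh
$f_r(x) = \frac{2x}{\lambda^2} e^{-(x/\lambda)^2}$, or exponential
$f_e(x) = \lambda e^{-\lambda x}$ — choosing the minimum-RMSE fit.

The matrix is then tiled into regions of interest (by default the four
half-size quadrants).  Within each ROI the level CDF
$F(k) = \sum_{j \le k} p(j)$ is pushed through the target's quantile
function — for the exponential target
$t(k) = -\tfrac{1}{\lambda}\ln\!\big(1 - \min(F(k), 1-\varepsilon)\big)$ —
and discretized back onto the level range: discrete inverse-transform
sampling, applied as a monotone lookup table to every value in the ROI.
A bilinear resampling along the window seams reconciles adjacent tiles.

The package also ships the matching synthetic benchmark (Splat-style
five-group count simulation plus gamma–Poisson efficiency loss,
$\tau_c \sim \Gamma(10, \text{rate})$, observed
$\sim \text{Poisson}(\tau_c \lambda_{gc})$) and the evaluation stack
(per-cell Pearson correlation, percent change over observed, k-means++
clustering accuracy, NMI, adjusted Rand and Hubert indices with optimal
label mapping).

## Worked example

```r
library(screq)

# five groups x 500 cells x 1200 genes, observed at 1% capture efficiency
d   <- simulate_benchmark(group_sim_params(), efficiency = 1, seed = 7)
fit <- screq(d$observed, seed = 1)
fit
#> Self-consistent expression recovery
#>   matrix: 2500 cells x 1200 genes
#>   target distribution: rayleigh (lambda = 0.5832, fit rmse = 0.005392)
#>   ROI grid: 4 region(s)

summary(fit)
#> screq imputation of a 2500 x 1200 matrix
#> Fitted expression distribution: rayleigh (lambda = 0.5832, rmse = 0.005392)
#>   ROIs: 4
#>   zero fraction: 0.705 observed -> 0.000 imputed

ev <- evaluate_imputation(d$reference, fitted(fit), observed = d$observed,
                          labels = d$labels, n_init = 50, seed = 3)
round(c(rho_observed = ev$mean_pearson_observed,
        rho_imputed  = ev$mean_pearson_imputed,
        pct_change   = ev$percent_change), 3)
#> rho_observed  rho_imputed   pct_change
#>        0.689        0.657       -4.596
```

The printed fit says the learned target density was a Rayleigh with
$\lambda = 0.58$ on the normalized value range, that the matrix was
processed as four independent quadrants, and that the 70% dropout zeros of
the observed matrix were remapped to nonzero values.  The evaluation
reports the mean per-cell Pearson correlation with the dropout-free
reference for the observed and the imputed matrix, and the percent change
of the latter over the former: on this gamma–Poisson benchmark the
imputed matrix tracks the observed correlation closely (monotone
per-value remapping cannot exceed it — see the vignette's *Known
limitations*), while the value distribution is restored to the learned
target scale.

`screq()` objects support `print`, `summary`, `coef` (the fitted
$\lambda$), `fitted`, `residuals`, `plot` (histogram with the fitted
density) and `predict(fit, newdata)` for applying a learned distribution
to further batches; `batch_impute()` wraps the multi-batch workflow.
A command-line front end lives in `inst/cli/screq`
(`screq impute | simulate | evaluate`).

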