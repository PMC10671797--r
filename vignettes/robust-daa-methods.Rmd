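---
title: "Robust M-estimation for CLR-based differential abundance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust M-estimation for CLR-based differential abundance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robustdaa)
```

## The statistical problem

Sequencing yields counts `Y_is` for taxon `i = 1..m` in sample `s = 1..n`
whose column totals `N_s` (library sizes) are technical, not biological:
only the composition is informative. Modelling the counts as multinomial
draws from latent absolute abundances `X_is`, and the abundances as
log-linear in a variable of interest `u_s` and covariates `c_s`, the
centred log-ratio values

$$W_{is} = \log Y_{is} - \tfrac1m \sum_j \log Y_{js}$$

follow, up to a vanishing multinomial estimation error, the linear model

$$W_{is} = u_s(\alpha_i - \bar\alpha) + c_s^\top\beta_i + \varepsilon_{is},$$

where $\bar\alpha = m^{-1}\sum_i \alpha_i$ is the compositional mean
effect, unidentifiable from relative data. The null hypothesis of interest
per taxon is $\alpha_i = 0$.

Squared-error fits of this model are efficient when
$\varepsilon_{is}$ is normal, but real microbiome residuals are
heavy-tailed and contaminated by isolated extreme counts. This package
estimates $(\alpha_i - \bar\alpha, \beta_i)$ by minimizing an empirical
loss $n^{-1}\sum_s L(W_{is} - z_s^\top\theta)$ with a user-chosen $L$, and
recovers $\bar\alpha$ by a mode correction.

## Loss families, tuning constants and scale

Four families are supported; $\psi = L'$ is the influence curve and
$r$ denotes a residual standardized by the robust scale
$\hat s = \mathrm{MAD}(\text{residuals})/0.6745$:

| family    | loss                                   | default | role |
|-----------|----------------------------------------|---------|------|
| `l2`      | $r^2$                                  | —       | efficiency baseline (LinDA recipe) |
| `huber`   | quadratic inside $|r|\le c$, linear outside | $c = 1.345$ | bounded influence, convex |
| `bisquare`| Tukey biweight, zero influence beyond $c_0$ | $c_0 = 4.685$ | redescending, rejects gross outliers |
| `quantile`| check loss $\rho_\tau$                 | $\tau = 0.5$ | distribution-free location |

The Huber and bisquare constants carry their familiar 95%-efficiency
calibration only for *unit-scale* residuals, so the solver re-estimates
$\hat s$ at every iteration and applies $\psi$ to $r/\hat s$; this is the
same convention as mature robust-regression implementations (the suite
cross-checks coefficients against `MASS::rlm` to $10^{-4}$). The
Monte Carlo benchmark `mc_relative_efficiency()` confirms both defaults at
$\approx 95\%$ (2000 replicates, $n = 500$).

Solvers: `l2` is closed-form QR; Huber and bisquare use iteratively
reweighted least squares (IRLS) from an OLS start, converged when
$\max|\Delta\theta| < 10^{-8}$ (cap 200 iterations, non-convergence is
flagged, not fatal). The bisquare objective is non-convex, so it is
warm-started from the converged Huber fit — standard practice for
redescending losses. The quantile fit uses the classical IRLS scheme for
the check loss with weights
$(\tau\,1\{r\ge 0\} + (1-\tau)\,1\{r<0\})/\max(|r|, 10^{-6})$; the
$10^{-6}$ floor bounds the weights and limits accuracy to about that
order, ample for inference on CLR data.

At kinks the weak derivative is fixed by the left limit
($\psi'(c) = 1$ for Huber, $\psi'(c_0) = 0$ for bisquare) — measure-zero
choices made explicit for determinism.

## Variance estimation

The asymptotic covariance of an M-estimator has the sandwich form
$(\sum_s z_s z_s^\top)^{-1}\, E[\psi^2] / E[\psi']^2$. The plug-in
estimator evaluates the two moments on scale-standardized residuals and
maps back to response units by $\hat s^2$; for `l2` every scale factor and
the constant in $\psi(r) = 2r$ cancels exactly, reproducing
$(Z^\top Z)^{-1}\cdot n^{-1}\sum \tilde r_s^2$. If every residual is
clipped (mean $\psi' = 0$) the estimate is undefined and the fit errors
with advice to enlarge the tuning constant. Degenerate all-zero residual
vectors return a zero covariance through a $10^{-12}$ scale guard.

The check loss has $\psi'$ zero almost everywhere, so the quantile family
uses the sparsity route instead:
$\hat\Sigma = \tau(1-\tau)\hat f(0)^{-2} (\sum_s z_s z_s^\top)^{-1}$ with
$\hat f(0)$ a Gaussian-kernel density estimate of the residual density at
zero (Silverman bandwidth). Kernel sparsity estimates are noisy at small
$n$, which is the known reason quantile-loss DAA shows FDR inflation in
small samples; we do not attempt to repair this.

## Mode correction, testing, and hyperparameter aggregation

Assuming most taxa are non-differential, the raw estimates
$\tilde\alpha_i$ pile up at $-\bar\alpha$, so
$\hat\alpha_i = \tilde\alpha_i - \widehat{\mathrm{mode}}(\{\sqrt n\,
\tilde\alpha_j\})/\sqrt n$. The mode estimator is fixed precisely: exact
Gaussian-kernel density evaluation with Silverman bandwidth
$h = 0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,m^{-1/5}$ on a 512-point
grid spanning $[\min - 3h, \max + 3h]$, argmax with ties to the smallest
abscissa. The choice is recorded in the run metadata so alternative mode
estimators can be compared.

Tests are two-sided t with $n - d - 2$ degrees of freedom ($d$ = number of
covariates excluding intercept and the variable of interest); the t
reference gives better small-sample FDR behaviour than the normal limit.
When a grid of tuning constants is supplied (defaults: 10 log-spaced
Huber constants on $[1.345, 5]$, 10 bisquare constants on $[4.685, 20]$,
11 quantile levels $0.25, 0.30, \dots, 0.75$), each grid member runs the
complete fit-and-correct procedure, the per-taxon p-values are combined by
the Cauchy rule $p = 1/2 - \arctan\{K^{-1}\sum_k \tan((1/2 - p_k)\pi)\}/\pi$
(valid under arbitrary dependence), and a single BH pass follows. We
combine *before* BH because per-grid adjustment would distort ranks; the
reported point estimates come from the first (default) grid member.
The `reject` flag defaults to FDR 0.05; 0.1 is a common alternative in
real-data analyses.

## Preprocessing choices

Order: depth filter (default 1000 reads) → prevalence filter (default
10%; a taxon at exactly the threshold is kept — the rule removes taxa in
*less than* that fraction) → optional winsorization → zero handling → CLR.

* **Zero-strategy rule.** `log N_s` is regressed on `[1, u, C]`
  (covariates included); if the two-sided t p-value for `u` is below 0.1
  the depth-proportional imputation
  $0.5\,N_s/\max\{N_k : Y_{ik} = 0\}$ replaces zeros, otherwise a uniform
  pseudo-count 0.5 is added. The test uses library sizes computed before
  the taxa filter and before winsorization, because depth is a property of
  the sequenced sample, not of the retained taxa. A flag
  (`impute_half = FALSE`) drops the 0.5 factor from the imputation
  fraction for users who prefer the bare depth ratio.
* **Winsorization** clips each taxon at its type-7 (linear-interpolation)
  $\tau$-quantile; 0.97 and 0.90 reproduce the conventional LinDA97 /
  LinDA90 variants. Winsorizing precedes zero replacement so pseudo-counts
  are never clipped; clipped values stay fractional. Note that with
  interpolated quantiles clipping is only idempotent when $(n-1)\tau$ is
  an integer; re-winsorizing can otherwise lower the threshold slightly.
* **Degenerate samples.** A sample can lose its entire retained depth to
  the prevalence filter (one dominant rare taxon removed). Such samples
  carry no information about the retained composition and are dropped with
  a message.

## The simulation engine

`build_dataset()` reproduces the log-linear generative process used in the
package's power/FDR studies:

1. baselines $\log X^*_{is} \sim N(\beta_i^*, \sigma_i^{*2})$ with
   $\beta_i^* \sim N(0, 2^2)$, $\sigma_i^* \sim U(0.5, 2)$ — chosen to
   give a realistic rank-abundance skew; all overridable so parameters
   estimated from a real study can be plugged in;
2. signals $\gamma_i \sim \mathrm{Bern}(p_\gamma)$ with
   abundance-weighted sizes $\mu_i = \log(f\mu)$ for mean proportion
   $\bar\pi_i^* > 5\times10^{-3}$ and
   $\log(f\mu(5\times10^{-3}/\bar\pi_i^*)^{1/3})$ below it, $f = 2$ for
   $n < 100$ else 1 (rare taxa get larger effects to offset their lower
   power);
3. designs $u_s \sim \mathrm{Bern}(0.5)$, or with confounders
   $c_1 \sim \mathrm{Bern}(0.5)$, $c_2 \sim N(0,1)$,
   $u_s \sim \mathrm{Bern}(\mathrm{logit}^{-1}(0.5c_1 + 0.5c_2))$ and
   taxon coefficients $\beta_{i1} \sim N(1,1)$, $\beta_{i2} \sim N(2,1)$;
4. errors from one of: $N(0, \sigma_i^{*2})$; Student $t_3$;
   $\mathrm{LogNormal}(0, 0.8)$ recentred by its theoretical mean
   $e^{0.32}$; $\mathrm{Weibull}(0.5, 0.3)$ recentred by $0.6$.
   Theoretical (not sample) means keep draws i.i.d.;
5. depths $N_s \sim \mathrm{round}(\mathrm{LogNormal}(\log 10^4, 0.5))$
   and multinomial counts;
6. outliers: $k = \mathrm{round}(\rho m)$ nonzero cells inflated 20-fold.
   The cells are the first $k$ entries of one random permutation of the
   nonzero cells, so at a fixed seed contamination sets are *nested* in
   $\rho$ — matched-seed comparisons across contamination levels then
   reflect the injection itself rather than resampling noise. Library
   sizes are recomputed, so each outlier perturbs the CLR of every taxon
   in its sample: exactly the mechanism under study.

What the generator does *not* emulate: taxon–taxon ecological
correlation, overdispersion beyond the log-normal/multinomial hierarchy,
batch structure, and longitudinal designs. Passing simulation-based tests
therefore demonstrates correctness of the machinery under the stated
model, not performance guarantees on arbitrary real data.

Per-replicate seeds derive deterministically from a master seed
(`child_seed()`), so different methods can be compared on identical data.

## Problem sizes used by the test suite

The packaged experiments are sized for a desk-scale run: efficiency
benchmarks use 2000 replicates at $n = 500$; null-calibration uses 200
replicates at $n = 50$, $m = 100$; FDR control uses 50 replicates at
$n = 200$, $m = 500$; the contamination and heavy-tail comparisons use 12
matched replicates per setting at $m = 500$. Directional Monte Carlo
claims are asserted against their matched-pairs standard errors rather
than as strict inequalities between noisy point estimates.

One calibration caveat the suite documents honestly: with only
$m = 100$ taxa the kernel-mode shift is itself noticeably noisy, and that
common noise inflates the null tail probability of the corrected
statistics (measured $\approx 0.064$ at nominal 0.05; removing the mode
step restores 0.050). The effect shrinks with $m$; at the $m = 500$ scale
of the main experiments FDR control holds at the nominal level. Users
analysing tables with few taxa should treat borderline discoveries
accordingly.

## Known limitations

* Mixed-effects/longitudinal extensions are out of scope.
* The quantile family's sparsity-based variance is anti-conservative in
  small samples (documented above).
* The imputation zero rule assumes positive library sizes for all retained
  samples; degenerate samples are dropped rather than imputed.
* No taxonomy-aware aggregation, rarefaction, or alternative
  normalizations (TMM/RLE/CSS/GMPR) — CLR is the only transform offered.
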