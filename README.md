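# powderavg

Estimation of the orientationally-averaged ("powder-averaged")
diffusion-weighted MRI signal from single-diffusion-encoding data, and a
simulation harness to compare the available estimators under controlled
noise.

Many tissue-microstructure analyses use the powder average
$\bar S(b)$ — the mean of the diffusion-weighted signal over all gradient
directions at fixed b — to factor out macroscopic fiber orientation.  How
accurately $\bar S(b)$ can be estimated depends on the gradient sampling
scheme and on the estimator.  This package is for researchers who want to
choose (or stress-test) that combination.  It implements:

* **Shell-by-shell estimators**: arithmetic mean; weighted mean
  $\sum_i w_i S_i/\sum_i w_i$ with Lebedev-quadrature weights (6/38/86-point
  octahedral grids reduced to 3/19/43 antipodal pairs), optimal
  rotation-invariance weights $w_0=(B^\top VB)^{-1}(VB)^\top g_0$ with
  $V=\mathrm{diag}(1+k^2/36)^{-1}$, the spherical-harmonic isotropic
  component $\bar S=a_0/\sqrt{4\pi}$ at order $L\in\{2,4,6\}$, and the
  Cartesian-tensor trace $\mathrm{Tr}(M)/3$.
* **Full-3D estimators**: the spherical-coordinate MAP-MRI
  (Hermite–Laguerre) representation at $N_{\max}\in\{6,8\}$, fit
  unconstrained, with propagator-positivity constraints (MAP), or with an
  analytic Laplacian penalty selected by generalized cross-validation
  (MAPL); its isotropic part gives $\bar S(b)$ at *arbitrary* b,
  including off-shell.
* **Simulator**: Watson-dispersed axisymmetric tensors
  ($D_\parallel=1$, $D_\perp=0.14$ µm²/ms by default; $\kappa\in\{1,9,\infty\}$;
  crossing configurations), Gaussian and Rician noise, and the exact
  closed form
  $\bar S_{gt}(b)=\tfrac{\sqrt\pi}{2}e^{-bD_\perp}\,
  \mathrm{erf}(\sqrt{b\Delta D})/\sqrt{b\Delta D}$, which holds for any
  orientation distribution.
* **Evaluation harness**: Monte-Carlo experiments scoring each method by
  $d_1$ (mean absolute error over the b × dispersion grid) and $d_2$
  (correlation of the signed bias with b), plus Anderson–Darling
  normality screening of the averaged signals.

Gradient schemes read/write FSL-style `bvec`/`bval` tables (s/mm² on
disk, ms/µm² in memory) and a CSV serialization; a thin command-line
interface lives in `inst/cli/powderavg.R`.

## Worked example

```r
library(powderavg)

scheme <- build_scheme("shelled_lebedev", 43, b_shells = seq(1.5, 12, 1.5))
signal <- simulate_signal(scheme, tissue_model(kappa = 9))
noisy  <- add_noise(signal, 0.0283, model = "gaussian", seed = 1)

average_all_shells(scheme, noisy, method = "lebedev")
#> powder average (lebedev):
#>     b      s_bar
#>   1.5 0.56539001
#>   3.0 0.35671355
#>   4.5 0.23271209
#>   6.0 0.17222821
#>   7.5 0.11792581
#>   9.0 0.09364269
#>  10.5 0.07092047
#>  12.0 0.04990575
```

These quadrature-weighted shell averages sit within ~0.003 of the exact
values `0.5640 0.3541 0.2386 0.1682 0.1221 0.0903 0.0678 0.0514`
(`round(ground_truth_average(seq(1.5, 12, 1.5)), 4)`) at this noise
level.  A MAPL fit of the same data interpolates the average off-shell:

```r
vals <- noisy$values / mean(noisy$values[scheme$b_values == 0])
fit  <- fit_map(scheme, vals, n_max = 6, mode = "laplacian")
map_powder_average(fit, c(2.25, 6, 9.75))
#> powder average (mapl6):
#>     b      s_bar
#>  2.25 0.44168397
#>  6.00 0.16960032
#>  9.75 0.07881037
```

A small Monte-Carlo comparison (25 realizations) shows the regularized
3D fit beating arithmetic averaging in mean absolute error at high
noise, at the price of a b-correlated bias:

```r
cfg <- experiment_config(scheme,
                         list(method_spec("arithmetic"),
                              method_spec("mapl", n_max = 6)),
                         sigma_list = c(0.1414, 0.0283),
                         n_realizations = 25, master_seed = 1)
run_experiment(cfg, keep_samples = FALSE)$aggregates
#>       method  sigma mean_d1    sd_d1 mean_d2 sd_d2  n
#> 1 arithmetic 0.0283 0.00368 0.000520  0.0665 0.393 25
#> 2      mapl6 0.0283 0.00310 0.000511 -0.3248 0.290 25
#> 3 arithmetic 0.1414 0.01772 0.002553 -0.0951 0.351 25
#> 4      mapl6 0.1414 0.01275 0.002460 -0.5748 0.241 25
```

## Package layout

| path | contents |
|---|---|
| `R/lebedev.R`, `R/spherical.R` | quadrature grids, real spherical harmonics |
| `R/directions.R`, `R/scheme.R` | repulsion direction sets, scheme generators, b perturbation |
| `R/signal.R` | Watson simulator, ground truth, noise models |
| `R/average.R` | shell-by-shell estimators |
| `R/mapmri.R` | MAP-MRI basis, fits (ls / constrained / MAPL), propagator |
| `R/evaluation.R` | d1/d2 metrics, experiment driver, normality screening |
| `R/io.R` | bvec/bval and CSV I/O, fixture generator |
| `vignettes/powder-averaging.Rmd` | methods and design notes |
| `inst/cli/powderavg.R` | command-line subcommands |
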