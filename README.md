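# robustbg

Robust background estimation for X-ray diffraction reflection
shoeboxes.

When integrating Bragg reflections, the background under the peak is
estimated from the surrounding pixels and subtracted ("summation
integration").  On photon-counting detectors the background pixels are
Poisson counts, frequently 0 or 1 per pixel, contaminated occasionally
by hot pixels and zingers.  Classical outlier rejection (sigma
clipping, Tukey fences, trimmed means, normality trimming) assumes
symmetric data: on weak Poisson backgrounds it biases the estimate low
and, at the extreme, rejects every nonzero pixel and reports a
background of exactly zero.  Biased backgrounds inflate intensities and
can fake twinning signatures downstream.

`robustbg` implements a robust Poisson generalized linear model for the
background, for audiences working on integration software, detector
diagnostics, or robust estimation for counting data.  The
log-background is a constant or a plane, `mu_i = exp(x_i beta)`, and
the coefficients solve the Huber-weighted quasi-likelihood score
equations

    sum_i [ psi_c(r_i) - a(mu_i) ] sqrt(mu_i) x_i = 0

with `r_i = (y_i - mu_i)/sqrt(mu_i)` the Pearson residual,
`psi_c(r) = max(-c, min(c, r))` the Huber function, and
`a(mu) = E[psi_c(R)]` the Fisher-consistency correction (exact Poisson
expectation), solved by iteratively reweighted least squares.  The
default tuning constant `c ≈ 1.345` is derived by root-finding 95%
efficiency at the normal distribution; `c = Inf` recovers the classical
GLM.  Coefficient uncertainty comes from a sandwich covariance with
exact Poisson moments.  The package also ships the six traditional
strategies (`null`, `truncated`, `nsigma`, `tukey`, `plane`,
`normal`), a synthetic shoebox simulator with ground truth (Poisson
backgrounds, Gaussian peaks, hot pixels, zingers), and the diagnostic
battery used to compare the methods.

## Worked example

A 24-pixel background with true level ~1 count/pixel and one zinger at
50 counts:

```r
library(robustbg)
y <- c(1,0,2,1,0,1,1,2,0,1,1,0,2,1,1,0,1,2,1,0,1,1,50,1)
mean(y)                 # 2.958  -- raw mean, dragged up by the zinger
fit <- robust_glm_fit(y)
fit
#> Robust Poisson GLM background fit (constant model)
#>   beta: 0.0542531
#>   background at origin: 1.05575 counts/pixel
#>   iterations: 8 (converged)
```

The robust estimate is 1.056 ± 0.218 counts/pixel — consistent with the
clean level, while the raw mean (2.96) is nearly tripled by the single
corrupted pixel.  `fit$weights` shows the zinger down-weighted to
~0.03.

Comparing methods on 2000 simulated 5×5 shoeboxes at a very weak
background (0.15 counts/pixel):

```r
run_comparison(shoebox_spec(5, 5, background = 0.15),
               c("null", "truncated", "nsigma", "tukey", "normal", "glm"),
               n_replicates = 2000, seed = 1)
#>      method mean_normalized_difference zero_background_pct mean_bias
#>        null                     0.0000                0.00   0.00100
#>   truncated                    -0.5565                9.66  -0.03904
#>      nsigma                    -0.5056               27.08  -0.03191
#>       tukey                    -1.7045               94.50  -0.13278
#>      normal                    -0.2266               11.15  -0.01405
#>         glm                     0.0373                0.00   0.00381
```

Every rejection-based method is biased low (negative normalized
differences) and collapses a sizeable share of shoeboxes to a
background of exactly zero — Tukey fences fail on 94% of them — while
the GLM tracks the no-rejection estimate and never collapses.

## Command line

```sh
inst/exec/robustbg simulate n=1000 lambda=0.15 seed=7 out=sb.jsonl
inst/exec/robustbg fit input=sb.jsonl background.algorithm=glm out=fits.csv
inst/exec/robustbg compare lambda=0.15,1,2.5 n=2000 seed=7 out=summary.csv
```

Parameters follow the dotted-path vocabulary of integration pipelines
(`background.algorithm=glm` or `background.algorithm=simple` plus
`background.simple.outlier.algorithm=tukey`, ...).  Every output gets a
`.meta.json` sidecar recording the package version, resolved
configuration and seed; repeated runs are byte-identical.

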