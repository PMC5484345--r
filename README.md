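# ctufit

Linear and nonlinear fitting of the compartmental tissue uptake (CTU)
model for dynamic contrast-enhanced MRI (DCE-MRI).

## The problem

DCE-MRI records the passage of a gadolinium contrast agent through tissue
at high temporal resolution. Tracer-kinetic models turn the measured
tissue concentration curve C(t) and the arterial input function ca(t)
into hemodynamic parameters. The CTU model is the three-parameter special
case of the two-compartment exchange model that applies when the
acquisition is shorter than the extravascular transit time (typical for
2–5 min oncology protocols): contrast enters the plasma compartment
(fractional volume *v*<sub>p</sub>) at plasma flow *F*<sub>p</sub>
(min⁻¹) and leaks irreversibly into the interstitium at
permeability–surface-area product *PS* (min⁻¹). Its analytical solution
is

> C(t) = ca(t) ⊗ \[ *F*<sub>p</sub> e^(−t/*T*<sub>p</sub>) +
> *K*<sup>trans</sup> (1 − e^(−t/*T*<sub>p</sub>)) \]

with plasma transit time *T*<sub>p</sub> = *v*<sub>p</sub>/(*F*<sub>p</sub> + *PS*),
extraction fraction *E* = *PS*/(*PS* + *F*<sub>p</sub>) and
*K*<sup>trans</sup> = *E·F*<sub>p</sub>.

Fitting this nonlinearly (bounded least squares, `fit_ctu_nlls()`) is
slow at voxel scale and needs a starting guess. Differentiating the model
equations twice and integrating back turns the model into a relation that
is *linear* in three coefficients,

> C = −α C̄ + β c̄a + γ c̄̄a,  α = (*PS*+*F*<sub>p</sub>)/*v*<sub>p</sub>,
> β = *F*<sub>p</sub>, γ = *F*<sub>p</sub>·*PS*/*v*<sub>p</sub>,

(overbars are running time integrals), which `fit_ctu_lls()` solves in
closed form by analytic inversion of the 3×3 normal matrix — no
iteration, no initial guess — and maps back to
(*F*<sub>p</sub>, *v*<sub>p</sub>, *PS*) exactly. The package also
provides the Parker population AIF, an exact exponential-convolution
forward model, a Monte Carlo harness quantifying bias and precision of
both estimators under controlled contrast-to-noise ratio (CNR) and
temporal sampling, and the voxel QC rules used for clinical parameter
maps (negative distribution volume, flat enhancement, out-of-domain
linear solutions).

It is written for imaging scientists who need fast voxelwise CTU
parameter maps, and for methodologists studying when the linear and
nonlinear estimators can be used interchangeably.

## Worked example

Simulate one cervix-tumour acquisition (2-s sampling, CNR 10), fit it
linearly, and run a small Monte Carlo:

```r
library(ctufit)

cfg <- sim_config("cervix_k", dt_s = 2, cnr = 10, seed = 42)
nl  <- sim_noiseless(cfg)          # Parker AIF + CTU curve on a 10-ms grid
set.seed(42)
sigma <- sigma_from_cnr(nl$C, 10)
t0 <- runif(1, 0, 2)               # acquisition-clock jitter
ca <- add_noise(downsample_jitter(nl$ca, 2, t0_s = t0), sigma)
C  <- add_noise(downsample_jitter(nl$C,  2, t0_s = t0), sigma)

fit <- fit_ctu_lls(C, ca)
tidy(fit)
#> # A tibble: 6 × 3
#>   term   estimate unit
#>   <chr>     <dbl> <chr>
#> 1 fp        0.473 "1/min"
#> 2 vp        0.337 ""
#> 3 ps        0.196 "1/min"
#> 4 tp        0.504 "min"
#> 5 e         0.294 ""
#> 6 ktrans    0.139 "1/min"
```

One noisy replicate scatters around the generating values
(*F*<sub>p</sub> = 0.57, *v*<sub>p</sub> = 0.28, *PS* = 0.2); the Monte
Carlo summary quantifies that scatter. `error_pct` is the systematic
deviation 100·(mean − truth)/truth and `precision_pct` the spread
100·SD/truth over replicates:

```r
mc <- run_monte_carlo(sim_config("cervix_k", n_reps = 100, seed = 42))
tidy(mc)
#> # A tibble: 6 × 8
#>   method parameter truth  mean     sd error_pct precision_pct n_used
#>   <chr>  <chr>     <dbl> <dbl>  <dbl>     <dbl>         <dbl>  <int>
#> 1 lls    fp         0.57 0.561 0.0664    -1.59          11.7     100
#> 2 lls    vp         0.28 0.295 0.0365     5.18          13.0     100
#> 3 lls    ps         0.2  0.199 0.0132    -0.570          6.62    100
#> 4 nlls   fp         0.57 0.583 0.0653     2.29          11.5     100
#> 5 nlls   vp         0.28 0.281 0.0340     0.201         12.1     100
#> 6 nlls   ps         0.2  0.198 0.0108    -0.870          5.41    100
```

At this clinically realistic noise level the two estimators perform
comparably; the linear one is a single matrix solve per voxel.

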