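---
title: "The compartmental tissue uptake model: linear and nonlinear estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The compartmental tissue uptake model: linear and nonlinear estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctufit)
```

## The model and its assumptions

The compartmental tissue uptake (CTU) model describes the early passage of
an MRI contrast agent through tissue with two coupled compartments: plasma
(fractional volume $v_p$), fed by the arterial concentration $c_a(t)$ at
plasma flow $F_p$ (min$^{-1}$ per unit tissue volume), and an extravascular
space into which contrast leaks at the permeability–surface-area product
$PS$ (min$^{-1}$) and from which it does **not** return within the
acquisition. That one-way assumption is what distinguishes the CTU model
from the full two-compartment exchange model: it is appropriate when the
scan is shorter than the extravascular transit time (a few minutes in most
tumours, longer where contrast is trapped, e.g. necrosis). The measured
tissue concentration is the convolution of $c_a$ with the impulse response

$$h(t) = F_p\,e^{-t/T_p} + K^{trans}\left(1 - e^{-t/T_p}\right),$$

a vascular washout decaying from $F_p$ at $t=0$ to the steady uptake
plateau $K^{trans}$, with

$$T_p = \frac{v_p}{F_p + PS}, \qquad
  E = \frac{PS}{PS + F_p}, \qquad K^{trans} = E\,F_p .$$

For physical parameters $0 \le E \le 1$, so $h$ decreases monotonically
(`ctu_irf()`); setting $PS = 0$ collapses the model to the one-compartment
vascular model (`one_compartment_forward()`), which the package keeps as
the simpler comparison model for slowly enhancing voxels.

## The linear estimator

Differentiating the compartmental mass-balance equations twice and
integrating back in time yields a relation that is linear in three
coefficients,

$$C(t) = -\alpha \bar C(t) + \beta \bar c_a(t) + \gamma \bar{\bar c}_a(t),
\qquad
\alpha = \frac{PS + F_p}{v_p},\;
\beta = F_p,\;
\gamma = \frac{F_p\,PS}{v_p},$$

where $\bar x$ denotes the running time integral from the first sample and
$\bar{\bar c}_a$ the double integral. Stacking one row per time point gives
an $N \times 3$ least-squares system (`build_design_matrix()`); its normal
equations are solved by analytic inversion of the $3\times 3$ matrix
$A^\top A$ (`fit_ctu_lls()`). The coefficient-to-parameter map

$$v_p = \frac{\beta^2}{\alpha\beta - \gamma},\quad F_p = \beta,\quad
PS = \frac{\gamma\beta}{\alpha\beta - \gamma},\quad
T_p = \frac1\alpha,\quad E = \frac{\gamma}{\alpha\beta}$$

is exact and applied without clipping: negative $v_p$ or $E \notin [0,1]$
are preserved and categorised (`valid`, `vp_negative`, `E_negative`,
`E_above_one`), because out-of-domain solutions carry diagnostic meaning —
$\gamma \approx 0$ indicates a one-compartment state, and invalid
categories drive the voxel QC below. Because $E$ estimated from data can
take any sign, the round-trip $({F_p,v_p,PS}) \to (\alpha,\beta,\gamma)
\to ({F_p,v_p,PS})$ is tested to $10^{-10}$ relative over random valid
parameter sets.

The nonlinear estimator (`fit_ctu_nlls()`) minimises the residual of the
analytical solution directly, by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with positivity bounds. Its goodness-of-fit is the
L2 norm of the analytical-model misfit, while the linear fit reports the
misfit of the linear relation itself; the two residuals are therefore only
comparable like-for-like.

## Numerical choices

* **Convolution.** `exp_convolve()` computes $c_a \otimes e^{-t/\tau}$
  exactly under a piecewise-linear interpolation of $c_a$: on each
  sampling interval the integral has a closed form, giving a first-order
  recursion with no quadrature error beyond the interpolant. On uniform
  grids the recursion runs through a compiled recursive filter. The
  $1-e^{-h/\tau}$ terms use `expm1` so the $\tau \gg$ window limit (where
  the convolution degenerates to a running integral) stays accurate. A
  brute-force fine-grid convolution oracle lives only in the test suite.
* **Integrals.** All running integrals — design-matrix columns, the
  plateau term of the forward model, the distribution volume — use the
  same cumulative trapezoidal rule anchored at zero at the first sample,
  so the linear and nonlinear paths see identical quadrature. Trapezoid
  integration is second-order on smooth curves; on the Parker input
  function it is first-order because that functional form steps from zero
  at onset (its Gaussian tails are truncated), which the tests assert
  explicitly.
* **Degeneracy.** When $\det(A^\top A)$ falls below $10^{-12}$ of its
  scale (e.g. an all-zero AIF), the linear fit returns a flagged
  `degenerate` result instead of inverting noise. Monte Carlo summaries
  count such replicates rather than dropping them silently.
* **Bounds.** The nonlinear fit constrains $F_p, v_p \ge 10^{-8}$
  (a tiny floor keeps $T_p$ defined at the boundary) and $PS \ge 0$
  (the one-compartment limit is legitimate), unbounded above. Function
  and parameter tolerances default to $10^{-8}$, at most 200 iterations;
  the defaults are ordinary least-squares practice, not fitted to data.
* **Initialisation.** On measured data `default_init()` seeds the
  nonlinear fit from the linear solution (projected onto a small positive
  floor where invalid), exploiting that the linear problem is solved
  globally. In the simulation harness the nonlinear fit is instead
  initialised at the generating values — its best-case configuration —
  so the Monte Carlo compares the linear estimator against the best the
  nonlinear one can do.

## What the simulator emulates

`sim_config()` fixes one acquisition condition. Its defaults are the
simulation study's conditions: a 20-s pre-contrast baseline followed by
4 min of enhancement (260 s of samples in total), a 10-ms master grid, the
Parker population arterial input function with onset at the end of the
baseline, target sampling period `dt_s = 2` s, and `cnr = 10`. Three
literature tissue parameter sets are built in (`tissue_presets()`): a
brain-tumour set ($F_p{=}0.23$, $v_p{=}0.05$, $PS{=}0.02$) and two
cervix-tumour sets ($0.57/0.28/0.2$ and $0.65/0.22/0.14$).

Each Monte Carlo replicate (`run_monte_carlo()`):

1. draws an acquisition-clock jitter $t_0 \sim U[0, \Delta t)$ and samples
   both master-grid curves at $t_0 + k\Delta t$ by nearest-sample lookup —
   the scanner clock is not synchronised to the bolus, and the same draw
   applies to $c_a$ and $C$ of one replicate;
2. adds i.i.d. Gaussian noise to both curves. The noise SD is set by the
   contrast-to-noise ratio, defined as the maximum concentration
   difference of the *noiseless* tissue curve divided by the baseline
   noise SD, so $\sigma$ is deterministic per condition. There is no
   equally canonical convention for the arterial noise level; the package
   uses the same absolute $\sigma$ on both curves, with an
   `aif_noise_mult` knob to explore other conventions;
3. fits with the requested methods and summarises percentage error
   $100(\bar x - \mu)/\mu$ and precision $100\,\mathrm{sd}(x)/\mu$.

A seeded run is bit-identical across invocations.

What the generator does **not** emulate: signal-to-concentration
conversion and $T_1$ mapping errors, $B_1$ inhomogeneity, partial-volume
and inflow effects in the AIF, temporal autocorrelation of physiological
noise, motion, and Rician noise floors at low SNR. Passing the simulation
checks therefore demonstrates correctness of the estimators under the
stated noise model, not robustness to everything a scanner does.

## Voxel quality control

Clinical parameter maps are filtered in a fixed precedence
(`classify_voxel()`): a voxel is excluded first if its distribution volume
$v_d = \int C\,dt / \int c_a\,dt$ is negative (noise-dominated), then if
the fitted model curve lies entirely within the 95% band of the baseline
noise, operationalised as every fitted sample inside
$\text{mean} \pm 1.96\,\text{SD}$ of the first $n$ baseline samples — the
plain reading of "indistinguishable from no enhancement"; the band
construction is a package choice since no formal definition exists for it.
Surviving voxels are then classified by the validity of the linear
solution ($v_p \le 0$, $E < 0$, $E > 1$). The flatness test uses the
fitted curve of whichever fit is being QC'd.

## Design choices at genuinely open points

* The 20-s baseline samples are **included** in the fitted window; the
  integrals are anchored at the first acquired sample. Trimming the
  baseline is a defensible alternative, but anchoring at acquisition start
  uses all data and needs no onset detection.
* Curve files declare their time unit through the time column name
  (`time_s` / `time_min`) rather than a side-channel header, making the
  unit impossible to omit. Internally everything is minutes, matching the
  min$^{-1}$ parameter units.
* Rows of the linear system are equally weighted. Weighted variants can
  reduce the noise-model mismatch of linearisation but choosing weights
  well is its own research question; they are out of scope.
* Upper bounds for the nonlinear fit default to $+\infty$; clinical
  pipelines sometimes cap $v_p$, so the bounds are configurable.

## Problem sizes

The shipped test-and-reproduction workloads use 1000-replicate Monte Carlo
runs per condition at $\Delta t = 2$ s (130 samples per replicate), a
six-point CNR sweep from 40 down to 5, three-replicate noiseless checks at
$\Delta t = 0.05$ s, and 60–100-voxel simulated populations for the
method-agreement and QC checks. These sizes give Monte Carlo standard
errors a few times smaller than the effects being checked.

## Known limitations

* The CTU model itself is misspecified once back-flux becomes visible;
  fitting longer acquisitions requires the full exchange model.
* When the plasma transit time approaches the sampling period
  ($T_p \lesssim \Delta t$) the linear and nonlinear estimators diverge
  systematically and neither is trustworthy for $F_p$; the
  method-agreement checks deliberately stay out of that regime.
* The linear estimator's noise model is misspecified by construction
  (noise enters the integrated regressors), which costs precision at low
  CNR relative to the nonlinear fit — visible in the CNR sweep.
* Percentage error and precision are undefined for a zero true value;
  the summary functions refuse $\mu = 0$ rather than guessing.
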