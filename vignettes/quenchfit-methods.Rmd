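---
title: "Models and methods behind quenchfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quenchfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchfit)
```

# The two-state quenching model

Metal-ion probes built from a dye and a chelating bipyridine show strong
negative curvature in Stern–Volmer plots. quenchfit models this as a
reversible transition between two emissive states: the free probe `L`
(bright) and the 1:1 metal complex `ML` (dim, with residual relative quantum
yield `f` rather than zero). Two forms are provided.

**Approximate model.** When the probe is dilute enough that the free
quencher concentration equals the total quencher concentration `c`,

$$\frac{F_0}{F} = \frac{1 + K c}{1 + f K c},$$

which rises with initial slope $K(1-f)$ and saturates at $1/f$. The limits
are informative: $f = 1$ gives a flat line at 1 (complexation without
quenching), and $f \to 0$ recovers the static Stern–Volmer form $1 + Kc$ —
the linear law is *nested* in the two-state model at the lower boundary of
`f`. This is why, on truly linear data, `fit_two_state()` returns `f` pinned
at its lower bound with `K` equal to the Stern–Volmer constant.

**Exact model.** `solve_equilibrium()` solves the full 1:1 mass balance
$K(L_0 - ML)(M_0 - ML) = ML$ and `precise_ratio()` converts the bound
fraction $x = ML/L_0$ into $F_0/F = 1/(1 - (1-f)x)$. The physically
admissible root is the smaller root of the quadratic, evaluated in the
cancellation-free form $2c/(b + \sqrt{b^2 - 4ac})$ because stability
constants span $10^4$–$10^8\,\mathrm{M^{-1}}$ and the naive quadratic
formula loses digits at the upper end. The two models agree to better than
$10^{-3}$ relative whenever $K L_0 < 10^{-3}$ — smaller than photometric
error — which is why the approximate model is the default fitting target at
sub-micromolar probe concentrations. At $K L_0 \gtrsim 10^{-1}$ quencher
depletion by the probe becomes visible and the precise fitter
(`use_precise = TRUE`) removes the resulting bias.

Concentrations are mol/L internally; the CSV readers accept µM (the natural
bench unit) and convert. `log K` always means base-10.

# Ensemble fitting

Quantum yields are estimated per quencher concentration as the OLS slope of
fluorescence on absorbance over several probe concentrations
(`relative_quantum_yield()`), which cancels probe-concentration errors. The
intercept is left free by default — it absorbs baseline offsets, and a
through-origin switch exists for instruments with a trusted zero. With the
usual three probe concentrations the slope's standard error has one residual
degree of freedom, so "±3 SE" intervals cover the truth at the Student-t
rate (about 80%), not the Gaussian 99.7% — the test suite asserts exactly
this.

`build_quench_curve()` divides the zero-quencher slope by each slope and
propagates both standard errors to a per-point sigma,
$\sigma = \sqrt{(\sigma_0/\varphi)^2 + (\varphi_0\sigma/\varphi^2)^2}$.
The zero-concentration ratio is fixed at 1 by construction.

`fit_two_state()` minimises the weighted residual sum of squares over
$(\log_{10} K, f)$ with bounds $\log K \in [0, 14]$, $f \in (10^{-6}, 1]$.
The objective can be multi-modal for weak binders, so the optimiser runs
from a deterministic 15-point start grid ($\log K \in \{4..8\}$,
$f \in \{0.05, 0.3, 0.7\}$) and the best result is polished with
Levenberg–Marquardt, which brings noiseless synthetic data back to machine
precision. Standard errors come from the local quadratic approximation
(covariance $= 2 H^{-1}$ with $H$ the Hessian of the $\chi^2$ objective).
$\chi^2$ is reported *reduced* (per degree of freedom, $n - 2$); with
correctly specified per-point sigmas it averages 1 in simulation, the
calibration the test suite checks over 500 replicates. If sigmas are
miscalibrated by a common factor the parameter estimates are unchanged and
only $\chi^2_{red}$ shifts.

# Benesi–Hildebrand analysis

For 1:1 binding followed in absorbance at a wavelength on one wing of the
isosbestic point, the transform $y = d L_0 [M]/(A - A_0)$ is linear in
$[M]$ in the excess-metal regime with $K = \text{slope}/\text{intercept}$;
the unknown extinction difference cancels in the ratio, which the tests
assert numerically. The fit is unweighted, matching the conventional
straight-line analysis; rows with $|A - A_0|$ below a configurable floor are
excluded because the transform diverges there (3× the absorbance noise is a
sensible floor). A non-positive intercept would imply a negative constant
and is returned as a flagged failure.

The synthetic generator deliberately uses the *full* mass balance, not the
excess-metal approximation. Applying the BH linearisation to such data bends
the plot away from the line at low metal concentration; `bh_fit()` exposes
this as a curvature diagnostic (RSS reduction from an added quadratic term,
as a fraction of the total variation — below $10^{-12}$ it is round-off,
i.e. no curvature). At a probe concentration of 0.5 µM and metal 1–50 µM the
depletion bias on a true $\log K = 5.16$ is about $-0.02$ — real, visible in
the diagnostic, and small compared with typical reporting precision.

# Single-molecule trace analysis

Blinking traces of immobilised probes are binned photon counts with three
intensity levels: bright (free probe), dim (metal-bound) and background
(after single-step photobleaching, clearly below the dim level). The
analysis accumulates each trace into an intensity histogram (one bin per
integer count while the maximum count is below 200, Freedman–Diaconis
above), fits the sum of three Gaussians to the occupancies by least squares,
and estimates the per-trace dim-state quantum yield as the
background-corrected brightness ratio
$f = (\mu_1 - \mu_b)/(\mu_2 - \mu_b)$. Per-sample results are the mean and
standard deviation over traces.

Numerical choices:

* **Label switching** is eliminated structurally: the dim and bright means
  are parameterised as cumulative positive increments above the background
  mean, so the ordering $\mu_b < \mu_1 < \mu_2$ holds by construction.
* **Starts** come from occupancy-weighted quantiles of the histogram
  (several deterministic seed sets); Levenberg–Marquardt from each, best RSS
  wins. No randomness is involved, so a given histogram always yields the
  same decomposition.
* **Resolution flag.** A decomposition is only trusted when neighbouring
  components are separated by more than the sum of their fitted widths.
  Traces that never photobleach during the record contribute no background
  population, and traces that bleach almost immediately barely populate the
  emissive states; in both cases a three-Gaussian fit will happily split one
  of the remaining peaks and return a plausible-looking but wrong ratio. In
  simulations this inflated the aggregate by ~0.08. `analyze_traces()`
  therefore excludes unresolved traces by default — the computational
  analogue of an experimenter evaluating only traces that show all three
  levels — and reports how many were dropped. Per-trace values outside
  $[0,1]$ by more than 0.1 are likewise excluded from aggregation as fit
  failures.
* The Gaussian least-squares fit on occupancies (rather than a Poisson
  mixture likelihood on raw counts) is the deliberate default: it matches
  the histogram-decomposition practice in this field. Its known cost is a
  slight downward pull on the dim mean when an intense, right-skewed
  background peak sits nearby; the aggregate recovery stays well inside the
  per-sample spread.

# Förster radius

`overlap_integral()` computes $J = \int \bar F_D(\lambda)\,
\varepsilon_A(\lambda)\, \lambda^4\, d\lambda$ with the donor emission
area-normalised on the common wavelength window, both spectra linearly
interpolated onto the union grid restricted to that window (no
extrapolation), and trapezoidal quadrature. `forster_radius()` applies
$R_0 = 0.02108\,(\kappa^2 n^{-4} \Phi_D J)^{1/6}$ nm, the standard
nanometre-units constant with $J$ in $\mathrm{M^{-1} cm^{-1} nm^4}$;
defaults $\kappa^2 = 2/3$, $n = 1.33$, $\Phi_D = 0.1$ suit a freely
rotating dye on DNA in aqueous buffer. Halving the grid spacing of smooth
spectra moves $J$ by well under 0.1%. Radii for measured metal-complex
spectra are data-dependent and require those spectra as input; the package
validates the computation against analytic box-spectrum values instead.

# What the synthetic generators emulate — and what they do not

The generators define the benchmark conditions for every recovery test:

* **Ensemble titrations**: 21 concentrations, 0–20 µM quencher;
  sub-micromolar probe (0.34/0.47/0.68 µM) with quencher-independent
  absorbance; 2% multiplicative Gaussian (photometric) noise on
  fluorescence. Curve-level simulation (`gen_quench_curve()`) uses the same
  grid and noise with the known per-point sigma attached.
* **Absorbance titrations**: full mass-balance binding curve, additive
  absorbance noise; probe 0.5 µM, metal 1–50 µM, path 0.3 cm.
* **Blinking traces**: two-state continuous-time Markov chain started from
  its stationary distribution (bright dwell $1/k_{on}$, dim dwell
  $1/k_{off}$, defaults 0.5 s each), exponential bleach time (mean 20 s),
  1 ms bins over 30 s, expected counts per bin formed as the time-weighted
  mixture of state rates within the bin (correct when dwells are comparable
  to the bin width), Poisson counts; bright 40, background 2 counts/bin,
  dim level set by the target ratio.
* **Spectra**: sums of Gaussian bands on a nm grid.

Passing recovery tests on these inputs demonstrates that the estimators are
unbiased and correctly calibrated *under the stated noise models*. Real
data add effects deliberately not simulated: inner-filter and re-absorption
(avoided experimentally by working below $10^{-4}$ M), probe impurities and
incomplete hybridisation (which bias apparent constants), triplet shelving
and spectral diffusion in single-molecule traces, detector afterpulsing and
drift. Recovery here therefore validates the analysis chain, not the
instrument.

Simulation sizes used by the tests and the acceptance script — 200
replicates per ensemble operating point, 500 for the $\chi^2$ calibration,
100 experiments × 15 traces for the single-molecule pipeline — were chosen
so Monte-Carlo error on the reported medians/means is an order of magnitude
below the tolerances being checked.

# Known limitations

* The ensemble fitters assume per-point sigmas are supplied; without them
  unit weights are used and the χ² loses its absolute calibration.
* The Benesi–Hildebrand estimate inherits the classical linearisation bias
  when the excess-metal assumption is violated; the curvature diagnostic
  flags it but the fit does not correct it (use the two-state mass-balance
  machinery when that matters).
* The trace analysis estimates brightness levels only; dwell-time kinetics
  ($k_{on}$, $k_{off}$ estimation) and lifetime analysis are out of scope.
* Only 1:1 stoichiometry is modelled throughout; isosbestic behaviour in
  absorbance supports exactly two components, but systems forming 2:1
  complexes at high metal concentration need different models.
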