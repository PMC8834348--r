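---
title: "Quantifying nanodomain confinement: svFCS diffusion laws and FRAP with raftdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanodomain confinement: svFCS diffusion laws and FRAP with raftdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(raftdyn)
```

## The measurement problem

Raft nanodomains are small (below 100 nm), short-lived sterol- and
sphingolipid-dependent assemblies in the plasma membrane. They are far below
the diffraction limit, so their effect on a fluorescent probe is only visible
indirectly, through the probe's lateral dynamics. Two classic read-outs are
used:

* **Spot-variation FCS (svFCS).** Fluorescence correlation spectroscopy is
  repeated at several sizes of the confocal observation spot (waist
  $\omega$, the $1/e^2$ beam radius). For each waist the autocorrelation
  function (ACF) of the intensity fluctuations is fitted with the
  two-dimensional lateral diffusion model
  $$G(\tau) = G_\infty + \frac{G_0}{1 + \tau/\tau_d},$$
  giving the mean dwell time $\tau_d$ of the probe in the spot. Plotting
  $\tau_d$ against $\omega^2$ yields the *diffusion law*
  $$\tau_d(\omega^2) = t_0 + \frac{\omega^2}{4\,D_{\mathrm{eff}}}.$$
  For free Brownian motion the law passes through the origin ($t_0 = 0$).
  Transient trapping in nanodomains adds a spot-size-independent delay and
  pushes the intercept positive; a cytoskeletal meshwork pushes it
  negative. The slope gives an effective long-range diffusion coefficient
  $D_{\mathrm{eff}}$.

* **FRAP.** A circular region of interest (ROI) is photobleached and the
  recovery of its mean fluorescence is quantified by the half-time of
  recovery $t_{1/2}$ and the mobile fraction $M$.

raftdyn implements both quantification chains end to end and couples them to
a particle-level Monte Carlo model of a membrane with trapping nanodomains,
so that every estimator can be exercised on data whose ground truth is
known exactly.

## The Monte Carlo membrane

`simulate_membrane()` propagates point particles on a periodic square of
side $L$ (default 2 µm, 3 µm for the free-diffusion presets). Each step is
an isotropic Gaussian displacement with per-axis standard deviation
$\sqrt{2 D_{\mathrm{local}}\,\Delta t}$, with $D_{\mathrm{local}} = D_{in}$
inside a trapping disk and $D_{out}$ outside. Trapping disks (radius 40 nm
by default, area fraction 0.1, placed without overlap by rejection
sampling) exchange particles through probabilistic boundary crossings: a
step that would cross a boundary is accepted with probability `p_enter`
(outward-in) or `p_escape` (inward-out) and otherwise reflected off the
circle. This disk-plus-crossing-probability mechanism is the simplest one
that produces positive diffusion-law intercepts and is standard in the
svFCS methodological literature; the underlying biology (scaffold proteins
such as MPP1 capturing flotillin nanoclusters and thereby concentrating
raft lipids) enters only through the preset parameter values.

Numerical choices:

* **Time step.** $\Delta t$ is chosen per preset so the free step is at
  most a quarter of the domain radius
  ($\sqrt{2 D_{out} \Delta t} \le r/4$); larger steps would tunnel through
  domains. A hard validity bound $\sqrt{2 D_{out} \Delta t} \le L/10$ is
  enforced by `sim_config()`.
* **Refused crossings are reflected**, not resampled, preserving detailed
  balance approximately at small steps. A reflected point that would land
  on the wrong side (possible only when two disks nearly touch) leaves the
  particle in place for that step.
* **Periodic wrapping** uses the minimum-image convention everywhere,
  including the detector distances below.

Two scalings summarize the trapping kinetics and were used to calibrate
the presets: the equilibrium in/out concentration ratio
$K \approx (p_{enter}/p_{escape})\sqrt{D_{out}/D_{in}}$, and the mean
domain residence time, measured at $D_{in} = 0.1$ µm²/s and $r = 40$ nm as
$\tau_{res} \approx 0.5\,\mathrm{ms}/p_{escape}$. A positive intercept
requires residence times comparable to the spot crossing time
($\tau_{res} \gtrsim 10$ ms here); much shorter residence merely rescales
the slope (the "well-mixed" regime), which is why the presets use small
crossing probabilities rather than strong interior slowdown alone.

## The virtual detector and correlator

`intensity_trace()` integrates a Gaussian detection profile
$\exp(-2 r^2/\omega^2)$ over all particles per sampling bin (default
100 µs) and draws Poisson counts around the expected signal (brightness 3
counts/bin/molecule at the spot centre, background 0.1 counts/bin).
`multitau_acf()` then emulates a hardware multi-tau correlator: 16 linear
channels at full resolution, then 8 channels per stage with the trace
re-binned by 2 between stages, each lag normalized symmetrically (left and
right means) so slow drifts do not bias the estimate. The brute-force
`direct_acf()` computes the same quantity lag by lag and serves as the
independent cross-check; at the unbinned stage the two agree to machine
precision, and within 1% once re-binning starts.

`fit_acf()` performs weighted least squares of the 2D model with
derivative-free initialization (baseline from the median of the last
decade of lags, amplitude from the maximum above it, $\tau_d$ from the
half-amplitude crossing). Lags below three sampling bins are excluded to
stay clear of shot-noise artifacts, and lags above a tenth of the run
duration are dropped as too poorly sampled. The model contains no triplet
term and no anomalous exponent — it is the minimal model the measurement
chain needs. Per cell, the 20 runs are correlated individually, averaged
with `average_acf()` (which supplies per-lag standard errors), and fitted
once; fitting the run-averaged ACF rather than averaging per-run fits has
lower variance, which is why the pipeline adopts it.

`calibrate_waist()` converts a reference dwell time into a waist via
$\omega = \sqrt{4 D_{ref} \tau_{d,ref}}$. The reference coefficient
defaults to 414 µm²/s, a literature value for Rhodamine 6G at room
temperature, and is exposed as an argument because calibration dyes and
temperatures vary.

## The diffusion law

`fit_diffusion_law()` regresses the per-waist mean dwell times (in ms) on
$\omega^2$ (in µm²). When every waist carries a positive SEM the fit is
weighted by $1/\mathrm{SEM}^2$ and the parameter covariance is the
known-variance (generalized least squares) form $(X^TWX)^{-1}$; with only
four waists, a residual-based dispersion estimate would have two degrees
of freedom and make the intercept's confidence region uselessly noisy,
so the cell-to-cell SEMs are treated as known. Unweighted fits (no SEMs
available) fall back to ordinary least squares with residual-based errors.
The slope converts as $D_{\mathrm{eff}} = 1000/(4\,\mathrm{slope})$
(ms and µm² to µm²/s); the factor 1000 lives only inside this function.

`classify_regime()` applies a two-sided 2-SEM rule: trapped if
$t_0 > 2\,\mathrm{SEM}$, meshwork if $t_0 < -2\,\mathrm{SEM}$, free
otherwise. The underlying sign criterion is standard; the 2-SEM
significance multiple is this package's choice (exposed as `threshold`)
since the field states the criterion without a test.

The four waists default to 0.20, 0.25, 0.30 and 0.35 µm — a plausible
span for 488-nm illumination, covering the diffraction-limited range used
in spot-variation work; the exact values used in any given study are
rarely printed, so they are configurable everywhere.

## Law-level round trips and what they show

`simulate_law_points()` draws per-cell dwell times directly from a known
law, $\tau_d \sim \mathcal{N}(t_0 + 1000\omega^2/(4 D_{\mathrm{eff}}),
(cv\,\mu)^2)$ truncated at zero, and aggregates them like real per-cell
fits. With the published condition parameters as ground truth
(`condition_preset()`), 15 cells per waist and a 15% cell-to-cell CV —
chosen so that the regression's intercept SEM reproduces the printed SEMs
of a few ms — the estimator chain recovers every published intercept
within its printed SEM on 100-replicate averages.

These round trips validate the inference chain, not the biology: they
show the estimators are unbiased and correctly weighted under the stated
noise model (Gaussian cell-to-cell scatter, independent cells, exact
waists). Features of real data they deliberately omit include waist
miscalibration, photobleaching during runs, triplet blinking, membrane
undulations, and cell-to-cell correlations in probe expression.

The particle tier (`run_svfcs_experiment(..., mode = "particle")`)
additionally validates the physics: a free-diffusion preset must come out
"free" with $D_{\mathrm{eff}}$ within 15% of the simulator's $D_{out}$,
trapped presets must produce significantly positive intercepts, and the
intercept must respond monotonically to the escape probability. The
acquisition sizes used in the tests (10 cells × 20 runs × 5 s for the
free preset, 6 cells × 10 runs for the trapped one, 3 cells × 8 runs per
grid point of the monotonicity check) are the package's compromise
between statistical resolution and a test suite that runs in minutes;
they match the study's design at the free-preset end and scale it down
where only a sign or an ordering is being checked.

## FRAP

`simulate_frap()` produces a pre-bleach plateau at 1, an instantaneous
bleach at $t = 0$ of depth $b$, and a post-bleach signal
$F(t) = (1 - b) + b\,(M/100)\,f(t)$, where $f$ is the closed-form
uniform-disk diffusion recovery
$$f(t) = e^{-2\tau_D/t}\left[I_0(2\tau_D/t) + I_1(2\tau_D/t)\right],
\qquad \tau_D = \frac{r^2}{4D},$$
with $r$ the ROI radius (1.25 µm by default, matching a 2.5-µm bleach
spot). The closed form is evaluated with exponentially-scaled Bessel
functions for numerical stability and is cross-checked in the tests
against an independent spectral (FFT) solution of the diffusion equation
on a 256² grid, agreeing within 2%.

`normalize_frap()` anchors the curve between the mean pre-bleach level
and the first post-bleach frame, so $F_n(0) = 0$ and full recovery is 1;
no acquisition-bleaching correction is applied. `fit_frap()` fits
$F_n(t) = M' f(t;\tau)$ with $M' \in [0,1]$, and reports
$t_{1/2} = c\,\tau$ with $c$ solved numerically from $f(c) = 1/2$
($c \approx 0.8946$; $\log 2$ for the selectable single-exponential
fallback). Defining $t_{1/2}$ on the fitted curve rather than the raw
trace makes it noise-robust and invariant to the bleach depth. The
vendor software used for the original quantification documents neither
its normalization nor its half-time definition, so recovered values are
interpreted as round-trip targets rather than re-derivations of the
instrument's numbers. A default frame interval of 1.5 s puts 100
post-bleach frames at ≈150 s, an order of magnitude beyond the
half-times of interest.

## Degenerate inputs and edge cases

Constant intensity traces (no fluctuations) raise an error from the
correlators rather than returning NaNs; FRAP curves with no detectable
bleach raise a degenerate-normalization error; a post-bleach curve that
never recovers above 2% is reported as fully immobile with an undefined
half-time; a diffusion law with non-positive slope (dwell times
decreasing with spot size) is rejected as unphysical rather than
reported with a negative coefficient. Optimizer failures in `fit_acf()`
and `fit_frap()` are reported through `converged = FALSE`, never as
exceptions, so batch pipelines keep running.

## Known limitations

* The membrane is flat, two-dimensional and periodic; no curvature,
  no interleaflet coupling, no cytoskeletal meshwork (negative
  intercepts are classified but never generated).
* Photophysics is limited to Poisson shot noise: no triplet state, no
  photobleaching inside FCS runs, no detector afterpulsing.
* All spot sizes observe the same simulated membrane per cell; real
  spot-variation series acquire waists sequentially.
* The preset condition parameters are calibrated, not measured: domain
  density, size and probe diffusion coefficients for these cells are not
  published, so presets reproduce published *law parameters* and their
  ordering, not an independently known microscopic truth.

## A complete example

```{r example, eval = FALSE}
# law-level round trip for the sphingomyelin control condition
report <- run_svfcs_experiment("SM_control", mode = "law_level", seed = 1)
report
plot(report$law)

# contrast control and MPP1-knockdown conditions
knd <- run_svfcs_experiment("SM_KnD", mode = "law_level", seed = 2)
compare_conditions(list(report, knd))

# FRAP: 37 virtual cells of the flotillin-2 control condition
frap <- run_frap_experiment("Flot2_control", n_cells = 37, seed = 3)
frap
```
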