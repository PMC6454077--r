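---
title: "Temporal sampling bias in dynamic CT myocardial perfusion: models and methods"
author: "ctmpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal sampling bias in dynamic CT myocardial perfusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmpi)
```

## The problem

Dynamic CT myocardial perfusion imaging (CTMPI) quantifies myocardial blood
flow (MBF, mL/g/min) from the passage of an iodine contrast bolus: a tissue
attenuation curve (TAC) is measured in each myocardial segment and an
arterial input function (AIF) in the aorta, and the widely used
maximum-upslope model computes

$$\mathrm{MBF} \;=\; \frac{\max_t \, \dot{C}_\mathrm{tissue}(t)}
  {\max_t \, c_a(t)} \cdot \frac{60}{\rho},$$

with enhancements in HU, time in seconds and tissue density
$\rho$ in g/mL. Clinical dual-source scanners acquire the analyzed slab only
every 2–3 s (ECG-triggered "shuttle" mode), so both the numerator (a
derivative) and the denominator (a curve maximum) are estimated from a
handful of points on a fast-evolving curve. `ctmpi` simulates an ex-vivo
perfused-heart experiment with fully known ground truth to measure how much
of the well-documented underestimation of CT-derived MBF is attributable to
the temporal sampling rate alone, comparing three acquisition schemes:
shuttle (slab revisited every 4th beat), non-shuttle (every beat) and
continuous (16 frames/s, no ECG).

## Ground-truth contrast kinetics

**Arterial input.** The AIF enhancement is a normalized gamma-variate,

$$c_a(t) = A\left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
  \exp\!\left(\alpha - \frac{t - t_0}{\beta}\right),\qquad t \ge t_0,$$

which peaks at exactly $A$ HU, $\alpha\beta$ seconds after contrast arrival
$t_0$. The exact normalization makes every peak-dependent contract testable
without numerical slack. Defaults ($A$ = 250 HU over a 40 HU baseline,
arrival 4 s after injection, $\alpha$ = 3, $\beta$ = 2.5 s) emulate a 15 mL
bolus at 3 mL/s into a perfusion circuit whose scan starts 5 s before
injection and lasts 60 s. Recirculation is deliberately absent: the emulated
rig drew from a 20 L reservoir that suppresses it.

**Tissue model.** Each segment follows a one-compartment model with
extraction,

$$\frac{dC_t}{dt} = k_{in}\, c_a(t) - \frac{k_{in}}{v_d}\, C_t(t), \qquad
  k_{in} = \frac{E\,F\,\rho}{60}, \quad v_d = V_d\,\rho,$$

with perfusion $F$ (mL/g/min), extraction fraction $E \in (0,1]$ and
distribution volume $V_d$ (mL/g). The transfer constant is $K_1 = E F$. The
washout term is included so that Patlak back-flux bias is a real,
exercisable effect; defaults are $E = 0.6$, $V_d = 0.3$ mL/g,
$\rho = 1.05$ g/mL. The unit chain is designed to be exactly invertible: the
estimator's $\times 60 / \rho$ conversion undoes the simulator's
$E F \rho / 60$, so in the ideal limit ($E = 1$, negligible washout, dense
noise-free sampling) the upslope estimate equals $F$ identically — the
package's primary internal calibration, tested at $F \in \{0.5, 1, 2, 4\}$.

**Integrator.** Curves are simulated on a 10 ms grid. The compartment is
advanced with the exact exponential-integrator step for a piecewise-linear
input, vectorized through the linear recursion (`stats::filter`), so the
solver is exact up to the piecewise-linear representation of the AIF;
agreement with boxcar and exponential closed forms is held to 0.5%. Coarser
grids are rejected rather than silently interpolated, because a coarse
forward grid would masquerade as sampling bias.

**Hearts, grades, territory.** Three phantom hearts (560 g / 1000 mL/min,
430 g / 1200, 580 g / 1100) keep pump flow inside the rig's 1.0–1.2 L/min
operating range and span weight-based true MBF of roughly 1.8–2.8 mL/g/min;
the source experiment did not publish heart weights, so these are chosen to
span the plausible range, not to match any particular heart. Stenosis is an
experiment factor: FFR grades 0.9, 0.8, 0.7, 0.6, 0.5 and total occlusion.
The rig holds pressure constant, so input flow only falls from FFR 0.7
onward; the default factors are 1.0, 1.0, 0.9, 0.8, 0.7, 0.7. The circumflex
territory (AHA segments 5, 6, 11, 12, 16) is additionally scaled by the FFR
value at partial grades and receives zero flow at occlusion; occlusion runs
serve only to mark the territory and are excluded from summaries, leaving 11
non-ischemic segments per heart and grade — 165 analyzed cells per scan
mode under the default 3 hearts × 5 grades design.

## Acquisition timing

RR intervals are drawn i.i.d. uniformly from [60/115, 60/107] s. ECG-
triggered frames fire a fixed end-systolic delay after the R wave, equal to
0.35 of the *nominal* RR interval (60 / mean heart rate). Using a constant
delay rather than a per-beat RR fraction is both closer to physiology (end
systole is a near-constant electromechanical delay) and makes the
inter-acquisition gaps exactly sums of RR intervals, so shuttle gaps are
provably inside $[4 \cdot 60/115,\; 4 \cdot 60/107]$ s — within the
protocol's "one image every 2–3 s".

The shuttle protocol fires every other heartbeat while alternating between
two table positions; the slab under analysis is therefore revisited every
4th beat. Non-shuttle images every beat (one acquisition per 0.5–1 s at
these heart rates). Continuous mode ignores the ECG: frames at
$0, h, 2h, \dots$ with $h = 1/16$ s taken as the exact value behind the
printed 0.06 s — 960 frames over 60 s. Gantry rotation (250 ms) is exposed
as an optional window-averaging of the sampled values but is off by
default: point sampling isolates the timing effect under study. Z-coverage
differences between modes are not modeled; analysis is per-segment on a
shared slab.

## Estimators

**Maximum upslope.** The literal estimator — the maximum over windows of
`slopeWindow` consecutive samples of the least-squares slope — is provided
(`smoothing = "none"` or `"ma"`) and is the reference for all noise-free
contracts. It is, however, the maximum of many noisy slope estimates, and
with 10 HU of frame noise its noise term (standard error 3–9 HU/s depending
on mode) rivals the true maximum slopes (4–7 HU/s), which would let noise
rather than sampling dominate the comparison. Real perfusion software fits
a curve through the measured points before differentiating, so the default
(`smoothing = "spline"`) fits a smoothing spline and reports the maximum
derivative of the fit; the AIF peak is likewise the fitted maximum over the
pre-injection baseline (mean of samples before 5 s), floored at zero.

The spline's flexibility follows $df = \sqrt{n}$ (bounded to $[4, n-2]$):
flexibility must grow with sampling density — denser curves resolve sharper
features — but sublinearly, so each basis function keeps averaging several
samples and per-sample noise cannot dominate the derivative. Per-curve GCV
is deliberately not used: on the few dozen samples an ECG-triggered scan
yields it oscillates between near-interpolation (noise-dominated
derivatives) and gross oversmoothing, inflating estimator variance. On
dense noise-free curves the rule is conservative and recovers the true
maximum slope to well under 1%. Negative fitted maxima are floored at zero
with a warning rather than propagated into negative flows.

**Patlak.** With $x(T) = \int_0^T c_a\,dt / c_a(T)$ and
$y(T) = C_t(T)/c_a(T)$, the early Patlak slope estimates $K_1$, and
$F = K_1/E$ corrects for incomplete extraction. Two fit windows are
provided. The default runs from contrast arrival (5% of peak enhancement)
to the AIF peak — robust for noisy, sparsely sampled curves, at the price
of a back-flux bias of order $\lambda (T - \bar{t})$ with
$\lambda = k_{in}/v_d$ (about 10–15% at the default kinetics). The
`"early"` window (first 0.5 s after arrival at a 0.2% cutoff) is for dense
noise-free data, where back-flux must be negligible for the Patlak premise
to hold; there $K_1$ is recovered within 5% across $E \in [0.4, 1]$.
Samples enter the fit only when arterial enhancement exceeds a small
fraction of the peak, keeping the ratios stable under noise; sparse schemes
whose early window contains fewer than 3 samples extend it forward to the
first 3 usable samples. In the factorial experiment the Patlak rows store
the corrected flow $K_1/E$ (the simulator's $E$ is known), so upslope and
Patlak rows are directly comparable against true flow.

## The factorial experiment and statistics

`runExperiment()` crosses hearts × analyzed grades × modes × 16 segments ×
replicates (default 10). Dense ground truth is computed once per heart and
grade and cached; every (cell, replicate) gets independent sub-seeds for
the beat schedule and for AIF/TAC noise, fanned out deterministically from
one master seed, so runs are exactly reproducible. Summaries use
linear-interpolation quantiles (`quantile(..., type = 7)`), declared so
IQRs reproduce bit-for-bit, and report underestimation as
$100\,(1 - \mathrm{median}/\overline{F_\mathrm{true}})$.

Scan modes are compared with a paired Wilcoxon signed-rank test on
per-segment differences, pairing by (heart, grade, segment, replicate).
This replaces the mixed linear model a clinical analysis would fit: the
pairing absorbs the repeated-measures structure the random effects would
model, the package then owns its statistic end-to-end, and the
nonparametric test makes no distributional claim about the skewed MBF
estimates. Zero differences are dropped (standard signed-rank convention,
recorded in the output); an all-zero contrast reports p = 1. Pearson
correlation between per-row true flow and estimated MBF is computed per
mode; constant inputs are reported as undefined rather than silently NA.

## The image phantom

An optional image-level fixture renders the experiment as a 4D short-axis
stack: a myocardial annulus split into AHA sectors over three slices
(6 basal, 6 mid, 4 apical; equal angular sectors from the anterior RV
insertion), plus an aorta-surrogate tube looped through the field of view,
with per-voxel Gaussian noise. The label map has 18 labels (background, 16
segments, tube). Rendering then extracting per-label means is lossless at
zero noise and reduces noise by $\sqrt{n}$ voxels otherwise, so image-level
estimates are a strictly lower-variance path to the same curves — this is a
fixture for end-to-end validation, not a CT simulator: no beam hardening,
motion, partial volume or reconstruction physics, and the geometric sectors
stand in for the manual segment drawing a human reader would do. Stacks
export to NIfTI with HU voxel units.

## What the simulation does and does not establish

The generator reproduces the *structure* of the ex-vivo experiment — its
timing protocols, factorial design, noise scale and kinetic regime — not
any measured curve. Passing tests therefore demonstrate properties of the
estimators under known kinetics (ordering and magnitude-ordering of the
sampling bias, recovery in analytic limits, direction of the Patlak
correction), and say nothing about absolute MBF accuracy in vivo, where
extraction, dispersion, motion and beam hardening all intervene. The
default conditions are fixed study conditions, not tuning knobs; every
default is config-overridable for sensitivity work.

Problem sizes were chosen so the full suite runs in a few minutes on one
core: the default factorial (3 hearts × 5 grades × 3 modes × 16 segments ×
10 replicates, with independent per-cell seeds — 150 seeded realizations
per mode pooling 1650 analyzed rows) backs the ordering, correlation and
summary tests; analytic-limit checks run on single dense curves.

## Known limitations

* The AIF does not scale with input flow or grade; in the rig the bolus
  profile varies somewhat with pump flow. The flow–MBF correlation here is
  therefore driven purely by the tissue side.
* A single AIF/TAC noise level stands in for the dose/kVp-dependent noise
  of the three protocols.
* Whether the real shuttle protocol measured the AIF at one or both table
  positions is unknown; here AIF and TAC share acquisition times per mode.
* The mL/100 mL/min ↔ mL/g/min conversion used by commercial software is
  not public; this package declares its own exact unit chain
  ($\times 60/\rho$, $\rho$ = 1.05 g/mL) rather than inferring one.
* Heart weights of the source preparation are unpublished; phantom hearts
  span, not match, its true-MBF range.
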