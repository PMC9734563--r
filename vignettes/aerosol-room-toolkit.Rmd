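---
title: "Methods: the virtual aerosol room and its analysis layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the virtual aerosol room and its analysis layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerotest)
```

## What this package models

Assessing how well face masks and other countermeasures reduce inhaled
aerosol requires many repeated, tightly controlled room experiments: an
aerosol generator fills a sealed laboratory room with a stable test
aerosol, laser aerosol spectrometers (optical particle counters) sample
the air every 6 s — some behind masks on manikin heads, some bare — and an
air purifier resets the room between repetitions. `aerotest` reproduces
that workflow entirely in software: a declarative protocol engine, a
virtual room with simulated instruments, and the statistical layer used to
turn the logs into efficacy numbers. The simulator makes the analysis
code fully testable (every estimator can be checked against known ground
truth), and the same analysis functions apply unchanged to replayed CSV
logs from real instruments.

## The room model

The room is treated as well mixed apart from explicit transport delays —
a standard approximation for fine aerosol in small rooms, where
convection homogenizes concentrations on minute time scales.

**Purifier decay.** With the purifier running, the above-background
concentration decays exponentially. We parameterize it decadically,

$$C(t) = a \cdot 10^{-b t} + c,$$

so that $1/b$ is directly the time (seconds) to cut the removable
component tenfold and $c$ is the lowest concentration the room can reach.
The package's reference parameterization, `decay_model()`, uses
$a = 100$, $b = 0.0035\,\mathrm{s^{-1}}$, $c = 0.04\,\mu g/m^3$: a
clearance time of $1/b \approx 286$ s, and $0.046\,\mu g/m^3$ (99.95% of
the PM$_{2.5}$ removed) after 20 minutes. The simulator implements the
decay as a per-step multiplication by $10^{-b\,\Delta t}$, which is exact
under composition: a noise-free simulated decay reproduces the closed
form to machine precision, and `fit_decay()` must invert it to $10^{-6}$
relative error — one of the package's acceptance properties.

**Background rise.** With the purifier off, ambient infiltration slowly
raises the background. For windows up to about 30 minutes this is modeled
linearly (`rise_model()`: intercept $0.04\,\mu g/m^3$, slope
$1.5\times10^{-4}\,\mu g\,m^{-3}\,s^{-1}$); `fit_rise()` records a
warning on the result when asked to fit a longer window, where the linear
approximation degrades.

**Transport delay.** A plume released at the emitter does not reach a
sensor instantly. Measured onsets are about three minutes at 1 m and
about four minutes at 2–2.5 m, so the default delay model is linear,
$\tau(d) = 180\,\mathrm{s/m} \times d$, halved when the fan blows the
plume across the room. Each sensor relaxes toward the well-mixed level as
it stood one delay ago with a mixing time constant of 60 s. These three
numbers (180 s/m, 0.5, 60 s) are phenomenological and configurable in
`room_spec()`; they reproduce the qualitative onset/peak behaviour of
multi-sensor runs without a CFD model. After the generator stops, a
sensor keeps relaxing toward its delayed target for one further delay
(aerosol already in transit), then its plume is frozen apart from
purifier losses — which keeps the purifier-decay closed form exact.

**Size distribution and mass.** The generated aerosol is polydisperse
with a number-distribution peak near 250 nm and essentially nothing above
2.5 µm. `aerosol_source()` uses a lognormal in diameter with mode
0.25 µm, truncated at 2.5 µm and renormalized. The geometric standard
deviation is not dictated by the measurements we emulate; the default
1.40 was chosen so that, on the default geometric channel grid, the modal
number fraction falls in the first (0.25 µm) channel, matching where real
spectrometers report the peak. The default grid (`default_bin_grid()`)
has 31 log-spaced edges spanning 0.25–35 µm with one edge pinned at
2.53 µm so the PM$_{2.5}$-style cutoff used throughout is exact.
Mass concentrations are spherical-particle sums over bins,
$\mathrm{PM} = \sum_b N_b \cdot 10^3 \cdot \frac{\pi}{6} d_b^3 \rho$,
with the representative diameter $d_b$ the geometric mean of the bin
edges and the density fixed at 0.914 g/cm³ (diethylhexyl sebacate, the
standard test oil). Whether real instrument firmware applies additional
per-channel weighting is unknown; this package documents its own
convention and applies it consistently to simulated and replayed data.

## Instruments, masks, noise

A simulated spectrometer (`spectrometer_model()`) applies, in order: mask
attenuation by the realized efficacy, a fixed multiplicative device bias,
and Poisson counting noise on the expected number of particles in the
per-tick sample volume (1.2 L/min × 6 s = 0.12 L). Poisson counting is
the natural noise model for an optical particle counter; no electronic
noise floor is modeled. Biases default to one draw per run from ±6%
uniform — the maximum disagreement observed between co-located real
units — and are seedable; the calibration machinery exists to remove
exactly this kind of bias.

Mask fit varies every time a mask is donned. `mask_model()` represents
this as an additive per-donning offset in percentage points, drawn from a
centred normal with SD 5 by default: across 20 donnings the realized
efficacy then spans roughly ±10 points around nominal, the spread
reported for repeated manual donning. The offset is a pure
donning effect here; inter-mask (manufacturing) variation is not
separately modeled and would be confounded with it.

Every stochastic element is owned by the backend and seeded once at
construction; `sim_backend()` refuses to run a stochastic configuration
without a seed rather than produce silently irreproducible logs.

## Protocols and acquisition

Experiment protocols are declarative YAML: `id`, `pre`, `repeats`,
`protocol`, `post`, with steps `[minutes, ACTION, comment]` and actions
`AEROSOL`, `CLEAN`, `PAUSE`, `FAN_ON`, `FAN_OFF`. The action-to-device
mapping is defined here once: `AEROSOL` runs the generator (purifier
off), `CLEAN` the purifier (generator off), `PAUSE` nothing; the fan
toggles persist across subsequent segments, and `AEROSOL` never touches
the fan. Sampling ticks fall at exact multiples of the 6-s tick, the
first at $t = 6$ s (a log entry *every* 6 s, not one at $t=0$). The clock
is virtual: simulations run as fast as possible, and wall-clock pacing is
deliberately not reproduced since it cannot affect results. Imaging is
treated as independent of the protocol (a `CLEAN` step does not reset the
reference still frame).

Logs are long-format CSV (one row per sensor per tick: per-bin counts/L,
total, PM$_{2.5}$, PM$_{10}$, phase comment, repeat index) with a JSON
manifest. If a backend fails mid-run the partial log is flushed and the
manifest flagged incomplete; summaries refuse incomplete runs unless
explicitly allowed.

## The analysis layer

**Efficacy.** $e = (1 - c_i/c_o) \times 100\%$, with $c_i$ behind the
mask and $c_o$ ambient. `efficacy_series()` uses windowed means and a
percentile bootstrap over paired ticks (2000 resamples by default) for
the CI. Negative efficacies are reported, never clamped: a masked sensor
reading above ambient is a setup problem the analyst must see. The
statistic is scale invariant, which is why measuring at high
concentration (for signal-to-noise) is legitimate;
`efficacy_by_concentration()` verifies the flatness empirically by
stratifying ticks into ambient-concentration bins.

**Calibration.** Co-located instruments are reconciled by the median
ratio: device $d$'s factor is $\mathrm{median(ref)}/\mathrm{median}(d)$
over the first $n$ aligned samples (default $n = 450$), with a paired
bootstrap CI. Factors multiply, so factor(A→B)·factor(B→A) = 1 exactly,
and applying the factors equalizes medians by construction. Note that a
device reading 6% low has an exact factor $1/0.94 \approx 1.064$, i.e.
"+6%" only to rounding; the package always uses the exact ratio. An
uncorrected ambient-side bias $\beta$ perturbs the efficacy by
$(1-e/100)(1/\beta-1)\cdot100$ points — vanishing as $e \to 100$ — which
the test suite verifies on simulated data. The achieved CI is always
reported rather than asserting any particular accuracy for a given $n$,
since that accuracy depends on the instrument noise level.

**Model fits.** `fit_decay()` fits $a\cdot10^{-bt}+c$ by
Levenberg–Marquardt least squares on linear concentration (not log
space — the tail would otherwise dominate), with self-starting values:
$c_0$ from the trailing-window minimum, $b_0$ from a log-linear
regression of the excess, $a_0 = C(0)-c_0$; $b$ is bounded positive and
$c$ non-negative. Flat input is flagged non-identifiable and
non-convergence is flagged, never raised. `fit_rise()` is ordinary least
squares.

**Repetition statistics.** Per-repetition mean concentrations are the
unit of analysis; `summarize_repetitions()` reports their grand mean, SD,
95% t-interval and a Shapiro–Wilk statistic. Normality is information,
not a gate. Condition comparisons (`compare_conditions()`) report a
Wilcoxon signed-rank test and a Kruskal–Wallis test with no significance
gating. Zero differences are handled by the Pratt convention (ranked,
then dropped from the statistic) with a normal approximation and tie
correction; identical arms therefore give $p = 1$ rather than an error.
`distance_reduction()` computes the percentage reduction in inhaled
aerosol between two distances with a t-interval over per-repetition
ratios.

CI method choices — bootstrap for efficacy and calibration, t-intervals
for repetition means — reflect what each statistic is: ratios of means
or medians with no convenient exact distribution versus means of
approximately normal per-repetition summaries.

## The imaging chain

Laser-sheet footage is processed by subtracting a pre-experiment still
from every frame (clipped at zero: darker-than-still pixels are flicker
or shadow artifacts, not aerosol) and compositing Canny edges of the
still over the result so the geometry stays visible. Edges are drawn into
the difference frame at a fixed intensity (a composited single image, not
a side-by-side); pixels without an edge pass through untouched. The Canny
implementation (Gaussian smoothing, Sobel gradients, non-maximum
suppression, hysteresis) is in-package with configurable thresholds
(defaults: sigma 1.4, hysteresis 0.1/0.2 on unit-scaled intensities).
Frame cadence is metadata only; the pipeline is cadence-agnostic.
`synth_frames()` generates test sequences with known plume support and
centroids, which serve as ground-truth oracles.

## What the simulator does and does not show

The generator's defaults are the study conditions: a 3×3×3 m room,
decay rate 0.0035 s⁻¹, floor 0.04 µg/m³, rise slope 1.5×10⁻⁴ µg/m³/s,
6-s ticks, 1.2 L/min flow, ±6% biases, 5-point donning spread, 250 nm
lognormal mode truncated at 2.5 µm. Passing tests demonstrate that the
estimators recover known parameters under these idealized conditions —
well-mixed transport, Poisson-only noise, time-invariant biases, masks
whose true efficacy is concentration-independent. They do not
demonstrate anything about real masks: the efficacy of a physical
surgical mask or respirator is a measurement only hardware can make;
nominal efficacies here merely parameterize demonstrations.
Deliberately out of scope: spatially resolved (CFD) transport, ballistic
droplets above ~2.5 µm, evaporation and hygroscopic growth (the DEHS
test oil is chosen precisely because it barely evaporates), breathing
flow dynamics, and temperature/humidity effects.

## Problem sizes and reproducibility

The test suite simulates deliberately small problems: 20-minute decay
runs (200 ticks), 450-sample calibrations, 1000-tick efficacy
recoveries, 200-replicate bootstrap-coverage checks at 400 resamples,
and 64×48-pixel image fixtures. These sizes were chosen to keep the full
suite fast while leaving every statistical check comfortably powered;
all scale linearly if larger studies are wanted. All randomness flows
from explicit seeds: same config and seed, byte-identical logs.

`scripts/acceptance.R` recomputes the headline quantities end to end —
the fitted clearance time (286 s), the 20-minute residual concentration
(0.046 µg/m³), and the recovered background-rise slope — from freshly
simulated data under a caller-supplied seed.
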