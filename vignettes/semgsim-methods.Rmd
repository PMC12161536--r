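---
title: "Simulating surface EMG fiber by fiber: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating surface EMG fiber by fiber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgsim)
```

## Overview

`semgsim` simulates surface electromyography (sEMG) and muscle force from a
desired force--time profile, taking the **single muscle fiber** as the unit
of activation. Most sEMG simulators activate whole motor units; treating
fibers independently lets low firing rates recruit only the low-threshold
fibers of a unit, which matters for the short, low-intensity contractions
that dominate daily activity. The chain has five stages:

1. **Motor control** -- translates the reference force into per-sample
   recruitment (how many motor units, at what mean firing rate) using a
   precomputed cumulative force-response table under Henneman's size
   principle.
2. **Motor neurons** -- convert spike trains into acetylcholine (ACh)
   release profiles that summate at the neuromuscular junction (NMJ).
3. **Muscle fibers** -- innervate when the ACh trace crosses their
   threshold, then propagate a mirrored pair of balanced tripole current
   sources along their 3D path and produce a twitch force.
4. **Volume conductor** -- a voxel finite-element model maps every traveling
   point charge to voltages at skin electrodes.
5. **Electrodes** -- monopolar channels and their bipolar differences.

## Membrane model and tripole decomposition

The intracellular action potential along the fiber follows Rosenfalck's
form
$$V_m(z) = A\,(\alpha z)^3 e^{-\alpha z} - B,$$
with amplitude $A = 96$ mV, resting potential $B = 90$ mV, and spatial
scale $\alpha = 550\,\mathrm{mm}^{-1}$. The transmembrane current is
proportional to its second derivative,
$$I_m(z) = C\,\sigma_{ic}\,\pi r^2\, V_m''(z),$$
where $r$ is the fiber radius ($\mu$m), $\sigma_{ic}$ the intracellular
conductivity (S/m), and $C = 1500$ a dimensionless amplitude constant that
absorbs the mixed units of the expression; amplitudes are therefore "model
units" calibrated against recorded data rather than absolute volts. The
current is triphasic with analytic sign changes at $\alpha z = 0$,
$3-\sqrt3$, $3+\sqrt3$. Each lobe is integrated in closed form to a point
charge at the lobe's charge centroid, and the middle charge is set to
$-(q_1+q_3)$ so the net charge is exactly zero. In dimensionless
$u = \alpha z$ space the lobe charges are $(+0.784, -1.126, +0.342)$ at
centroids $(0.536, 2.640, 7.462)$.

On innervation two mirrored tripoles leave the NMJ and advance
$c_v \Delta t$ of arc length per sample toward opposite tendons along the
fiber polyline. Within a *generation region* around the NMJ the three pole
amplitudes scale jointly and linearly from 0 to full; within an
*extinction region* ending at each tendon they scale back to 0, and a
train is removed when its wavefront reaches the tendon. Joint scaling
keeps each train balanced at every step, which is what suppresses end
effects when thousands of potentials overlap. The region length defaults
to the tripole span $(3+\sqrt3)/\alpha$ mm and is configurable
(`ramp_length_mm`); offsets follow arc length across polyline vertices,
and trailing poles never cross back over the junction.

## Twitch force

A single innervation produces
$$F(t) = F_{base}\,\bigl(1 - e^{-t/\tau_{up}}\bigr)\,d^2\,e^{-t/\tau_{down}},$$
with $d = 2r$ in $\mu$m and time constants in ms; force is exactly zero
for $t<0$ (causality). The peak sits at
$t^\* = \tau_{up}\ln(1+\tau_{down}/\tau_{up})$. Fiber force is the linear
superposition of twitches at the innervation instants; series are
truncated where the decay envelope falls below $e^{-12}$ ($\approx$
$6\times10^{-6}$ of full amplitude), and window averages in the
recruitment calibration use the closed-form integral, so no truncation
enters the force-response table.

## Acetylcholine release and triggering

Each impulse releases
$$\mathrm{ACh}(t) = A_m\bigl(1-e^{-k_r (t-t_p)}\bigr)e^{-k_d (t-t_p)},$$
with $A_m = 1$ mM, $k_r = 0.45\,\mathrm{s}^{-1}$,
$k_d = 30\,\mathrm{s}^{-1}$; impulses summate linearly. A fiber innervates
at the first sample its summed trace reaches its threshold (no sub-sample
interpolation); reuptake then zeroes that fiber's trace, so fresh releases
are needed before it can fire again. The reset is per-fiber by default; a
shared-cleft variant (`shared_cleft = TRUE`) resets all member fibers of
the unit together.

**Units caveat.** With the tabulated constants taken verbatim, a single
impulse peaks near $5.5\times10^{-3}$ mM and even maximal-rate summation
stays below $2.2\times10^{-2}$ mM -- far under the tabulated thresholds of
0.45--0.9 mM, so no fiber would ever innervate. The formula and constants
are implemented verbatim and never silently rescaled; instead the package
exposes one global threshold multiplier (`thr_scale`) and a calibration
helper, `ach_threshold_scale()`, that derives it from the model itself: it
simulates a maximal-rate train, takes the peak summed trace $P$, and
returns $P/(\mu_{IIx} + 2\sigma_{IIx})$ so the printed threshold hierarchy
maps onto the achievable trace range. Under this scale slow fibers are
recruitable at low drive and fast fibers only near maximal drive, which is
the intended physiology. The default configuration keeps `thr_scale = 1`
(verbatim constants); every simulation in this package's tests and
reproduction script applies the calibrated scale.

## Motor control

For every motor unit and every rate on the firing-rate grid (8--42 Hz), a
steady periodic train is run through triggering and twitch summation over
a 2 s calibration window, and the mean force over the final 1.5 s is
recorded (by then ACh summation and twitch summation have settled; the
window is configurable). Units are sorted ascending by size and rows are
cumulatively summed into `M_ref`: entry $(n, m)$ is the steady force of
the $n$ smallest units all firing at rate $m$.

Per reference sample with target $f$, the candidate set is every entry
inside the one-percent window $0.99f < M_{ref} < 1.01f$ (the printed
inequality chain in the source material is inverted as written; it is
implemented as a window). Among candidates the entry nearest the diagonal
from $(0,0)$ to $(N_{max}, R_{max})$ -- perpendicular distance in the
normalized index space $(n/N, m/M)$ -- is selected; ties prefer fewer
units, then lower rates. An empty window falls back to the nearest-force
entry, forces above the model maximum saturate at $(N_{max}, R_{max})$,
and $f \le 0$ recruits nothing. Two desk-scale realities deserve note:

* **Hysteresis.** Resampling ripple on a plateau would otherwise flap the
  selection between equivalent entries every few samples, resetting spike
  phases and inflating ACh summation; the previous entry is therefore kept
  while it still satisfies the window. Tracking always has priority.
* **Monotonicity.** On a dense full-scale table ($1000 \times 35$) the
  near-diagonal selection progresses monotonically in both coordinates
  with increasing force. On a coarse desk-scale table the one-percent
  windows are sparse stripes and adjacent windows trade units against
  rate, so only the *trend* of $n(t)$ and $m(t)$ is monotone (tested via
  bin means), while within a fixed unit count the rate index is exactly
  monotone.

At each change of the selected entry, every active unit draws its rate
from a Gaussian with mean $m(t)$ and standard deviation
$10\,\mathrm{Hz}\cdot n(t)/N_{max}$ (clamped to the grid) and fires
periodically from a random phase. Because of this prescribed dispersion
the *realized* plateau force of a single run is stochastic around the
tracked `M_ref` value; the one-percent tracking guarantee is a property of
the selection, and the reproduction script reports the realized ratio
alongside it.

Reference profiles (e.g. 100 Hz recorded torque) are resampled to the
2000 Hz simulation clock by polyphase band-limited resampling (linear
interpolation behind a flag), normalized by the participant's maximum
voluntary contraction (MVC) and rescaled by the model's MVC
(`M_ref[N, M]`).

## Volume conductor and electrodes

The tissue grid holds labels (air, fat/skin, muscle, cortical and
cancellous bone) on a regular voxel lattice with tabulated conductivities
(0.30 S/m muscle, $4.07\times10^{-2}$ fat/skin, $2.00\times10^{-2}$
cortical, $7.56\times10^{-2}$ cancellous). The potential obeys
$\nabla\!\cdot\sigma\nabla V = 0$ with natural no-flux conditions on the
skin--air interface and grounded ($V=0$) truncation planes at both ends of
the z-axis. By reciprocity, injecting unit current at an electrode node
and solving once per electrode yields the response field $h_{elec}(l)$;
the voltage of a charge $Q$ at $l$ is then $Q\,h_{elec}(l)$, and
superposition over all active poles gives each channel.

Numerical choices: trilinear hexahedral elements on the voxel lattice;
per-element conductivity by majority vote of the eight corner labels (ties
toward air), which keeps the discrete domain mirror-symmetric; geometry
converted mm$\to$m inside the solver so S/m units are consistent; direct
sparse Cholesky up to $2\times10^4$ unknowns and Jacobi-preconditioned
conjugate gradients beyond, both at relative residual $\le 10^{-8}$;
trilinear interpolation of $h$ between nodes, with out-of-domain pole
positions clamped to the grid (or rejected, configurable).

Validation uses a homogeneous muscle cylinder (radius 60 mm, length
150 mm) with an interior source far from the boundaries: at 4 mm voxels
the field matches the infinite-medium law $1/(4\pi\sigma d)$ within
$\sim$6% on the shell $d \in [6, 10)$ mm, improving to $\sim$4% at 2 mm
voxels. The shell is chosen so discretization error dominates the
(refinement-invariant) finite-boundary error: closer than ~1.5 voxels the
nodal source dominates; much farther, wall confinement does.

Electrodes form an $M \times N$ cylindrical grid (default $2 \times 3$,
15 mm spacing, centered at 30% of the z-axis per SENIAM-style placement
over the muscle belly); each electrode's segment toward the section
centroid is ray-cast against the tissue surface and the electrode snaps to
the first intersection, refined by bisection. Bipolar channels pair
z-neighbors within each angular column.

## Synthetic phantom and reference tasks

The phantom is a layered cylinder inside the reference arm box ($x, y \in
[-50, 50]$ mm, $z \in [0, 150]$ mm): cancellous core (7 mm), cortical
shell (12 mm), muscle (40 mm), fat/skin (45 mm). The biceps region is an
annular sector (radial band 16--36 mm, $40^\circ$--$140^\circ$) filled
with `n_fib` deterministic, near-uniform points (golden-angle spiral) per
slice; slices taper slightly toward the ends (fusiform belly), which also
exercises genuinely 3D fiber paths. Reference tasks mirror the recorded
protocols: smoothed isometric trapezoids (10/40% MVC) and bell-shaped
isotonic bursts (20/30% MVC), at 100 Hz like the recorded torque.

Fiber paths connect consecutive slices by recursive bisection pairing:
each subset splits along its larger bounding-box extent (ties split
vertically) into lower $\lceil n/2\rceil$ / upper $\lfloor n/2\rfloor$
halves until singletons pair. Motor-unit layouts draw unit counts and
sizes from the configured Gaussians, repair the total by single-fiber
adjustments at random units, disperse each unit as $R\cdot
\mathcal N_2(0,\lambda)$ (with $R$, $\lambda$ means scaling linearly with
unit size across 4--40% of the section area and 20--50% of $R$; the
Gaussian spread around those means is 1/20 of each range, a choice the
source material leaves open), and greedily match dispersed fibers to
unassigned section points. Fiber types start uniform-random and convert
one fiber per iteration through three equal-spread Gaussians over the
unit-size range (spread = range/6, tolerance 1 percentage point, zero
targets drained exactly), concentrating slow fibers in small units.
Conduction velocity maps the realized population's $r\,\sigma_{ic}$ range
affinely onto 3--5 m/s (a constant population maps to the midpoint), and
NMJs sit where each path crosses the z-plane at a Gaussian fraction
($40\pm5$% from the upper tendon) of its length.

## Scales

Two configurations ship with the package. `default_config("full")` is the
literature-scale biceps (200k fibers, $1000\pm250$ units of $300\pm100$
fibers, rate grid 8--42 Hz in 1 Hz steps). `default_config()`
(`"desk"`) preserves every per-fiber distribution and the unit-size
coefficient of variation but shrinks the population to 2,000 fibers in
$\sim$50 units with a 2 Hz rate grid, so a full contraction simulates in
about two minutes on one CPU; the test suite shrinks further (300 fibers,
$\sim$8 units, 5 mm voxels) to keep the whole suite in minutes. The
directional fiber-type comparison in the reproduction script uses 800
fibers in $\sim$20 units, five seeds per composition.

## Similarity metrics

Per repetition: RMS, and median frequency (MF) -- the smallest frequency
at which the cumulative one-sided FFT power reaches half the total.
Envelopes: rectified signal under a 0.5 s centered moving average (edges
truncated), and the magnitude spectrum under a 10 Hz moving average; the
whole repetition enters one FFT (no Welch averaging). Feature similarity
$$\mathrm{FeatSimi} = 1 - \tfrac12(\mathrm{avgSimi} + \mathrm{stdSimi}),
\qquad \mathrm{avgSimi} = \frac{|\overline{f_R} - \overline{f_S}|}
{\overline{f_R} + \overline{f_S}},$$
with stdSimi analogous on standard deviations; envelope pairs are
linearly resampled to the shorter length and scored by Pearson
correlation clamped below at zero. The General Similarity Index is the
mean of RMS, MF, temporal and spectral indices; all lie in $[0,1]$, a
degenerate zero-sum denominator is reported as `NA` rather than guessed.

## What the synthetic tests do and do not show

Everything here is validated against closed forms, independent brute-force
oracles, and the phantom -- not against human recordings. The headline
similarity levels of the original study (indices above 85--90%) are
defined against participants' recorded sEMG and torque, which no synthetic
fixture can stand in for; what the package's checks establish is that each
stage implements its stated model exactly, that the assembled system is
linear and causal, and that the fiber-type composition moves the median
frequency in the physiological direction (slow-dominant below
fast-dominant, checked across seeds). The phantom also omits realistic
anatomy (a perfectly layered cylinder), fiber shortening during
contraction, fatigue, electrode--skin impedance, and measurement noise, so
absolute amplitudes and spectra should be read as model units, not
microvolts.

## Worked example

```{r example, eval = FALSE}
cfg <- default_config()                 # desk scale: 2000 fibers
cfg$rate_grid <- seq(8, 42, by = 2)
cfg$thr_scale <- ach_threshold_scale(cfg)

ph   <- make_phantom(phantom_spec(n_fib = cfg$table1$n_fib), cfg)
anat <- build_anatomy(ph$stack, cfg, seed = 1)
lead <- solve_lead_field(ph$grid, place_electrodes(ph$grid))
mref <- build_mref(anat, cfg, thr_scale = cfg$thr_scale)

raw <- make_force_profile(force_profile_spec("isometric", level = 30), 100)
ref <- prepare_reference_force(raw, 100, mref$model_mvc)
res <- simulate_contraction(anat, mref, lead, ref, cfg, seed = 1)

compute_features(res$semg_bipolar[1, 2600:7200], res$fs)
```
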