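---
title: "Simulating motor unit loss: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating motor unit loss: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mupool` simulates a pool of motor units — motor neurons plus the muscle
fibers they innervate — to ask how different *patterns* of motor unit
loss change muscle strength, force steadiness, and the relation between
surface EMG amplitude and force. This vignette explains the model, the
parameters that matter, and the design decisions behind the
implementation; the README shows a worked example.

## The motor neuron pool

A pool of $n$ units (default 120) is built from four exponential /
power-law assignments indexed by unit $i$:

* **Recruitment threshold** $\mathrm{RTE}_i = e^{(\ln \mathrm{RR}/n)\,i}$,
  in % of maximum excitation, with $\mathrm{RR} = 40$: most units are
  recruited at low drive (74 of 120 below 10%), and the last unit joins
  at exactly 40% excitation.
* **Peak twitch force** $P_i = e^{(\ln \mathrm{RP}/n)\,i}$ over an
  $\mathrm{RP} = 100$-fold range (arbitrary units), so late-recruited
  units are the strong ones.
* **Contraction time** $T_i = T_L (1/P_i)^{\ln \mathrm{RT}/\ln
  \mathrm{RP}}$ over an $\mathrm{RT} = 3$-fold range below $T_L$: strong
  units are fast.
* **Innervation number** proportional to the same exponential as $P_i$,
  rounded by largest remainder so the counts sum exactly to the fiber
  total (70,000): 28 fibers for the smallest unit, about 2,661 for the
  largest.

Above its threshold a unit discharges at
$\mathrm{FR}_i(t) = \mathrm{gain}\,(E(t) - \mathrm{RTE}_i) + \mathrm{MFR}$,
clamped at its peak firing rate (PFR), with $\mathrm{MFR} = 8$ Hz.
Discharges are a Gaussian renewal process: each interspike interval has
mean $1/\mathrm{FR}$ at the previous spike and SD equal to `isi_cv`
(default 0.20) times the mean; negative draws are resampled, which at
CV 0.2 touches about $3\times10^{-7}$ of draws and cannot bias the
moments meaningfully.

Two firing strategies are compared. Under the **onion skin** scheme PFR
falls linearly with recruitment threshold from `pfr_hi` (35 Hz, first
unit) to `pfr_lo` (25 Hz, last unit); the **reverse onion skin** scheme
mirrors this. The endpoints, the gain (1 Hz per % excitation) and $T_L$
(90 ms) are not quantities with canonical published values; we adopt the
conventional values above and expose all of them in
`mu_pool_config()` — the headline *relative* results are driven by the
ratios RR, RP, RT and by which units are removed, not by these scales.
The linear PFR map is anchored so that both stated endpoints hold
exactly: the lowest-threshold unit gets `pfr_hi` and a unit at
threshold RR gets `pfr_lo` ("inversely proportional" read as the linear
fan the two endpoints define).

## Force generation

Each discharge $j$ of unit $i$ produces a critically damped twitch
$f_{i,j}(t) = g_{i,j} P_i (t/T_i) e^{1 - t/T_i}$, peaking at
$g_{i,j} P_i$ at $t = T_i$. The nonlinear **fusion gain** captures
tetanic summation: with $x = T_i/\mathrm{ISI}_j$ and
$S(x) = (1 - e^{-2x^3})/x$,

$$ g_{i,j} = \begin{cases} 1 & x \le 0.4 \\ S(x)/S(0.4) & x > 0.4.
\end{cases} $$

The normalization by $S(0.4)$ makes the gain continuous at the
boundary; the unnormalized form would jump by a factor ~3.3 there,
contradicting the unfused regime having gain 1. The gain peaks near
$x = 1$ (ISI equal to the contraction time) and falls at higher rates
such that the steady mean force of a unit, proportional to
$f\,g(Tf)$, plateaus once $Tf \gtrsim 2$ — force saturates at fusion.
The first discharge of a train has no preceding ISI and takes gain 1,
so a lone twitch equals the unloaded twitch. Whole-muscle force is the
linear sum of unit forces. Spike times stay continuous; forces are
sampled on a 1 ms grid, and each twitch is truncated 30 contraction
times after its discharge, where it has decayed below $10^{-11}$ of its
peak.

## Surface EMG

The muscle is a cylinder of radius 8 mm under 2.5 mm of fat and skin.
Each unit owns a circular territory sized to 20 fibers/mm², placed
uniformly at random wholly inside the cross-section; its fibers scatter
uniformly within the territory. Fiber diameters are Gaussian (55 ± 5 µm,
truncated at 3 SD, the same mean for every unit), and conduction
velocity is linear in diameter, $v = 2.2 + 0.05\,(d - 25)$ m/s.

A discharge launches two current tripoles at the fiber's innervation
zone (scattered ±2.5 mm about the muscle midpoint). They propagate in
opposite directions at the fiber's conduction velocity and extinguish at
the fiber-tendon endings. Pole offsets are 2 and 4 mm behind the lead
pole with charges $(+q, -(q+q'), +q')$, $q'/q = 1/9$; trailing poles
emerge from the innervation zone sequentially (so all six poles coincide
and cancel at the discharge instant), and each pole's charge ramps
linearly to zero over its final 2 mm of travel. The monopolar electrode
potential is $\sum \mathrm{charge}/(4\pi\sigma r)$ in a homogeneous
isotropic volume conductor with the fat layer entering as pure distance;
$\sigma$ only sets the (arbitrary) amplitude scale, which is fine
because every analysis here uses amplitudes *relative* to their own
maximum. During onset and extinction the source carries a transient net
charge — this is what produces the non-propagating terminal phases — so
zero-net-charge (faster-than-monopole) far-field decay holds only for
the fully formed tripole, and that is how the package tests it.

The unit's MUAP template is the sum of its fibers' action potentials,
computed once per anatomy (`build_emg_system()`); the trial EMG is the
sparse superposition of templates at the discharge times at 4 kHz, which
comfortably covers the MUAP spectrum at these velocities. Loss scenarios
simply index into the intact pool's templates.

## The experiment

Excitation ramps linearly from zero for 2 s, then holds for 5 s at a
level from 10% to 100% in 10% steps. Only the 5 s steady window is
analyzed: mean force, force COV (population SD over the window divided
by the mean, computed per repetition and then averaged over
repetitions), and EMG averaged rectified value (ARV). Loss scenarios
remove 20/40/60% of units: the highest-indexed (largest), the
lowest-indexed (smallest), or a uniformly random subset redrawn for
each repetition from that trial's seeded stream ("unrestricted" read as a
random pattern, so repetitions average over subsets). Survivors keep all
their properties — no reinnervation, synchronization, fatigue, or
central-drive impairment is modeled. For the EMG–force relation the
per-level mean force and ARV are each normalized to their maximum over
the ten levels and fit by ordinary least squares; the fit's $R^2$
summarizes linearity, and the mean residual at the 30–70% levels
(`mid_residual`) diagnoses the characteristic departure where force
saturates while rate coding still drives EMG up. That residual form, not
a pointwise EMG-minus-force comparison, is the meaningful diagnostic
here: once force has saturated, normalized EMG *lags* normalized force
pointwise in level while still rising faster per unit of force.

Every trial derives its RNG seed from a master seed and the condition
labels (`trial_seed()`), so any cell of a grid is reproducible in
isolation and the EMG synthesis consumes no randomness (force results
are bit-identical with and without EMG).

## Numerical and scale choices

* Force grid 1 ms; EMG grid 4 kHz; trial length 7 s (2 s ramp + 5 s
  hold); 10 repetitions for the headline capacity/COV comparisons.
* The EMG analyses run the full 120-unit pool over a 7,000-fiber muscle
  (identical per-unit proportions to the 70,000-fiber pool); EMG
  amplitudes are relative, so only the fiber sample size changes, and
  three repetitions per level are averaged.
* The test suite exercises small 12-unit/700-fiber pools built by the
  same generative rules (`make_fixture_pool()`) wherever pool scale is
  irrelevant to the property under test.

## What the simulation does and does not show

The generator *is* the study: all inputs are model parameters, and the
synthetic pools emulate an idealized, healthy-architecture muscle with
independent units, linear force summation, a single fiber-diameter
distribution, and full excitation capacity. Passing tests therefore
demonstrate internal consistency of the model and reproducibility of
its comparative claims — largest-unit loss dominates weakness and breaks
EMG-force linearity; smallest-unit loss dominates force variability —
not quantitative fidelity to any particular human muscle.

Two behaviors deserve explicit note. First, with the common gain of
1 Hz/% excitation, every unit reaches its peak rate by about 62% drive,
so steady-state discharge statistics — and hence force COV — are
level-independent above that point: COV falls steeply over the lower
levels and is flat thereafter. A strict rank-monotone COV-level trend
across the entire 10–100% range is therefore not attainable under these
parameters, and the corresponding test documents that. Second, absolute
force values (in au) and EMG amplitudes depend directly on the
unprinted scale parameters (PFR endpoints, gain, $T_L$, $\sigma$); only
relative comparisons — percent changes, normalized curves, orderings —
are meaningful model outputs.
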