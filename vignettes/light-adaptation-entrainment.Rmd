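---
title: "Light adaptation and the stability of circadian entrainment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light adaptation and the stability of circadian entrainment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circadapt)
```

## The model

`circadapt` analyses a minimal transcription–translation clock: a single
clock gene whose mRNA (M) is translated into cytosolic protein (P~C~), which
shuttles into the nucleus (P~N~) and represses its own transcription through
a steep Hill term,

$$
\begin{aligned}
\dot M &= v_s\,(1+X(t))\,\frac{K_I^n}{K_I^n + P_N^n} - v_m\,\frac{M}{K_M + M},\\
\dot P_C &= k_s M - v_d\,\frac{P_C}{K_d + P_C} - k_1 P_C + k_2 P_N,\\
\dot P_N &= k_1 P_C - k_2 P_N.
\end{aligned}
$$

Both mRNA and cytosolic protein are removed by saturable (Michaelis–Menten)
degradation; nuclear import/export is linear; nuclear protein is lost only by
export. With the default constants (`clock_params("neurospora_21p5h")`:
n = 4, K~I~ = 1 nM, v~s~ = 1.6 nM/h, v~m~ = 0.505 nM/h, K~M~ = 0.5 nM,
k~s~ = 0.5 /h, v~d~ = 1.4 nM/h, K~d~ = 0.13 nM, k~1~ = 0.5 /h,
k~2~ = 0.6 /h) the free-running (constant-darkness, DD) period is 21.51 h,
the wild-type Neurospora period; raising v~s~ to 2.5 nM/h
(`"mammal_25h"`) gives 25.19 h, a mammalian free-running period. Across
v~s~ ∈ [1.3, 3.2] nM/h the period grows monotonically from 20.1 to 27.4 h.
We quote the two periods to their conventional rounded values (21.5 h, 25 h)
throughout; the package always reports the computed values.

Light acts only on transcription: the dimensionless response X(t) scales the
synthesis rate by (1 + X). Three waveform families describe how induction
unfolds across the light phase of an LD cycle
(lights-on at t ≡ 0 mod T, photoperiod T/2 by default):

* **adaptation** — X jumps to X^max^ at lights-on, holds for T~s~ hours,
  then decays linearly over T~d~ hours (transient induction, as for
  Neurospora *frq* and mouse *Per1*);
* **slow response** — X ramps up over T~r~ hours and plateaus until
  lights-off (*Per2*-like); the plateau ends exactly at the light–dark
  transition, so the constructor enforces T~r~ + T~s~ = photoperiod;
* **square** — constant X^max^ through the light phase (no adaptation).

All segments are half-open `[start, end)`, making X right-continuous; the
value at the light–dark transition itself is the dark value. This fixes the
stroboscopic section unambiguously.

## Numerics

Integration is fixed-step 4th-order Runge–Kutta (default step 0.01 h),
implemented in C++. The forcing is piecewise linear with discontinuities and
kinks at state-independent times, so every integration interval is split at
those breakpoints: no RK4 stage ever straddles a discontinuity, and stage
evaluations at a segment's right endpoint use the left limit of X. This
preserves 4th-order convergence (the suite checks the ~16× error contraction
under step halving and agreement with an adaptive `lsoda` reference to
1e-5 nM).

The limit cycle is measured after discarding 500 h of transient; the period
is the mean spacing of successive minima of M over ≥ 10 cycles, each minimum
refined by quadratic interpolation of its three bracketing grid points.
Phase 0 on the cycle is the minimum of M. "No sustained oscillation" is
declared when the post-transient peak-to-trough amplitude of M falls below
1e-4 nM. The default initial state is (0.1, 0.1, 0.1) nM; the measured
period is invariant to the start (checked to 1e-3 h).

## Stroboscopic-map analysis

Entrained oscillations are fixed points of the stroboscopic (Poincaré) map:
the state sampled once per forcing period T. The map Jacobian (monodromy
matrix) is obtained by integrating the variational equations alongside the
state; because forcing discontinuities occur at fixed times, segment
Jacobians compose by plain matrix products with no saltation corrections.
Its eigenvalues are the characteristic multipliers: a stable entrained orbit
has all three inside the unit circle, and boundaries of entrainment appear
as a real multiplier crossing +1 (saddle-node, SN), −1 (period doubling,
PD), or a complex pair crossing the circle (Neimark–Sacker, NS).

Fixed points are located by damped Newton iteration on map(s) − s with the
monodromy as Jacobian (residual tolerance 1e-10 nM), falling back to long
brute-force map iteration (stable orbits only) when Newton diverges.
Bifurcations are located by marching the amplitude X^max^ with continuation
(each fixed point seeds the next Newton solve) and bisecting the relevant
multiplier test function to a bracket width of 1e-4. Attractors are
classified from post-transient map iterates (defaults: 500 transient, 1000
sampled): a repeat after k iterates within 1e-4 nM in every coordinate is
period-k; otherwise the tangent-map Lyapunov exponent separates
quasi-periodic motion (|λ| ≤ 0.01 per iterate) from chaos (λ > 0.01);
anything else is reported as "undetermined" rather than silently labelled.

For 12:12 square-wave forcing of the 21.5-h clock this machinery locates the
SN at X^max^ ≈ 0.199 and the PD at ≈ 0.647, with the period-1 → 2 → 4
cascade beyond it (period-4 at X^max^ = 0.75). Transient induction widens
the region dramatically: with T~s~ + T~d~ fixed at 12 h, the upper limit
rises from 0.65 (square) to 2.4 (T~s~ = 6) and ≈ 30 (T~s~ = 3) — a roughly
fifty-fold expansion once the plateau is shorter than about 6 h. The
"about fifty times" acceptance check is evaluated at T~s~ = 3 h, the
adaptation waveform (T~s~ = 3T/24, T~d~ = 9T/24) used for the
two-parameter scans, where the computed ratio is ≈ 47.

## Phase response curves and the analytic criteria

The PRC is computed by applying one light pulse to the free-running
oscillator at a grid of phases (default spacing 0.25 h) and measuring the
*asymptotic* phase shift: the perturbed trajectory is integrated 15
free-running cycles past pulse end, and the shift is the offset of its late
M-minima from the unperturbed schedule, averaged over the last 5 cycles and
wrapped to (−τ/2, τ/2]. Advances are positive, delays negative. The
asymptotic definition removes amplitude-relaxation transients; estimates are
unchanged from 8 to 60 post-pulse cycles, and are independent of the marker
variable used.

A 24-h pulse train defines the circle map
φ~k+1~ = (φ~k~ + Δφ(φ~k~) + T) mod τ. Locking requires a phase with
Δφ = τ − T (−2.49 h for the 21.5-h clock under 24-h cycles, conventionally
−2.5 h), and the lock is stable iff the PRC slope there lies in (−2, 0);
slope 0 is the tangency (SN) condition and slope −2 the period-doubling
condition. Roots are found on a monotone (Fritsch–Carlson) interpolant of
the PRC; sign changes across wrap discontinuities (the ~τ jumps that appear
under strong, type-0 resetting) are not roots and are filtered by a
jump test (|Δshift| > τ/4 across one grid interval). Slopes are central
differences of freshly computed shifts with 0.1-h spacing.

Two limits of this 1-D reduction deserve emphasis. First, it is exact only
when amplitude relaxation between pulses is fast; here the entrained orbit's
second multiplier is ≈ 0.75, so relaxation is slow and the criterion is
quantitatively approximate. The tangency route reproduces the map SN
almost exactly (0.201 vs 0.199), but at the map-located PD the measured
PRC slope is ≈ −1.3 rather than −2, and published slope values at fixed
amplitudes are reproducible only to a few tenths, depending on the
differencing convention. Second, because the criterion is approximate, the
map and PRC verdicts are compared in the suite only away from decision
boundaries: cells within 25% of a located bifurcation amplitude, or whose
lock slope lies within 0.25 of −2, are excluded. On the remaining cells of
a 5×5 (T~s~, X^max^) grid the two routes agree everywhere.

## Reconstructing the transcription rate

Given sparse relative series of mRNA and total protein P~t~ = P~C~ + P~N~,
the estimation stage recovers v~s~(t) and X(t) = v~s~(t)/v~s~^dark^ − 1:

1. kinetic parameters other than v~s~ are fitted to DD data
   (`fit_dark_parameters()`): the free-running cycle is matched in shape,
   period and M-vs-P~t~ phase, with two multiplicative scale factors
   (relative units → nM) and the phase offset profiled out; the free
   parameter set is a user-controlled mask (default v~s~, v~m~, v~d~);
2. adding the two protein equations eliminates transport:
   dP~t~/dt = k~s~M − v~d~P~C~/(K~d~+P~C~), which is inverted pointwise for
   P~C~ on a dense grid, with derivatives taken from GCV smoothing splines;
   P~C~ is clamped to [0, P~t~] and clamped points are flagged;
3. M, and P~N~ = P~t~ − P~C~ are substituted into the transcription
   equation, giving v~s~(t) = (dM/dt + v~m~M/(K~M~+M))(K~I~^n^+P~N~^n^)/K~I~^n^;
   negative excursions are clipped and flagged, and clipping on > 20% of
   the grid flags model misfit;
4. the dark baseline is the mean rate over the last 6 h of darkness, and the
   light-phase X(t) is classified against the three waveform templates by a
   penalized (AIC-like) least-squares fit, with a robust median-residual
   guard that returns "other" when no template explains the curve.

The inversion in step 3 multiplies derivative error by the Hill factor
(K~I~^n^+P~N~^n^)/K~I~^n^, which reaches 10^2^–10^3^ whenever nuclear
protein is high: v~s~ is well determined only where P~N~ is low. The
returned grid therefore carries a per-point conditioning weight
(inverse squared amplification; zero where the inversion clamped) as a
reliability diagnostic. In practice the pointwise route resolves the
bundled scenarios at 0.5-h sampling and degrades sharply at 2 h.

Because the published wording ("the time series of P~C~ that most perfectly
fitted the data") also admits a trajectory-level reading, both are
implemented behind one interface: `estimate_response(method = "trajectory")`
fits each waveform template by simulating the entrained orbit it produces
(warm-up run to stroboscopic convergence; candidates that fail to entrain
are penalized by their non-convergence residual) and least-squares matching
the sampled observations. This route involves no derivatives, so it handles
the sparse 2-h designs, at the cost of assuming the data lie on a 1:1
entrained attractor and that the response belongs to one of the template
families. The closure tests run it at the scenarios' native 2-h density.

## The synthetic-data generator

`clock_scenario()` produces ground-truthed series with the sampling
structure of the source experiments: sparse grids (every 2 h across two
24-h cycles), unit-free abundances rescaled to max 1, and multiplicative
log-normal noise (observed = truth·e^ε^, ε ~ N(0, log(1+cv²)), default
cv = 0.1), deterministic given the seed. Truths are sampled after 50 warm-up
cycles; some entrained scenarios need ~40 cycles to relax onto their
attractor, and a truth still on its transient (or worse, on a quasi-periodic
or chaotic attractor) cannot stand in for entrained experimental data. Each
preset's amplitude was therefore chosen inside its waveform family's
entrained band, verified by attractor classification:

* `neurospora_frq_LD` — 21.5-h clock, adaptation with X^max^ = 9
  (induction ≈ 10× the dark rate), T~s~ = 1 h, decay completing at
  lights-off (T~d~ = 11 h): response maximal within 1 h of lights-on;
* `mouse_per1_LD` — 25-h clock, adaptation X^max^ = 3, T~s~ = 4 h,
  T~d~ = 8 h: plateau ends 4 h after lights-on;
* `mouse_per2_LD` — 25-h clock, slow response X^max^ = 0.25, T~r~ = 9 h
  (the slow family entrains this oscillator only on a narrow band,
  ≈ [0.17, 0.34]): response maximal at the light–dark transition;
* `dd_fit` — unforced 21.5-h clock sampled every 2 h over two cycles.

What the generator does *not* emulate: measurement error structure beyond a
single multiplicative log-normal term (no replicate/count noise, no
baseline offsets), dark-phase modulation of the transcription rate by
unmodelled post-translational regulation (real *Per* estimates are not flat
in the dark; classification therefore uses the light phase only), and any
cell-population or behavioural-level averaging. Passing closure tests show
the estimator is consistent for data generated by this model under these
designs — not that the model is identifiable from any particular published
dataset.

## Problem sizes and runtime choices

The test suite measures periods over 400-h windows, classifies attractors
from 300–500 transient plus 100–1000 sampled map iterates, scans the
verdict-consistency grid at 5×5 conditions, and runs 20 noisy replicate
seeds for the sparse-recovery check (Nelder–Mead effort reduced to
`maxit = 120`, two starts for those replicates). The stability cross-check
perturbs located orbits and iterates a few hundred cycles — convergence
is geometric, so longer brute-force runs add runtime, not information.

## Known limitations

* The package analyses the three-variable single-gene clock only; detailed
  multi-gene mammalian models are out of scope, and conclusions about the
  stabilizing role of adaptation transfer to them only partially.
* PRC-based criteria are approximate for this weakly contracting oscillator
  (see above); the stroboscopic map is the authority for bifurcation
  locations.
* The trajectory estimation route assumes 1:1 entrainment and a template
  waveform; it will misfit relative-coordination (quasi-periodic) data,
  which the non-convergence penalty reports as a poor fit rather than
  repairing.
* Continuation is a simple parameter march with bisection; there is no
  branch switching or pseudo-arclength continuation, so bifurcation curves
  that fold in the scanned parameter would need manual bracketing.
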