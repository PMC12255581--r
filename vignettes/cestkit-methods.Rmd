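---
title: "Simulating and evaluating CEST saturation experiments with cestkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating CEST saturation experiments with cestkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

cestkit simulates the *saturation block* of a CEST experiment and the
evaluation that follows it. A voxel is a Bloch–McConnell system: water,
up to N dilute CEST pools, and optionally one semisolid MT pool. The state
vector holds (Mx, My, Mz) for water and each CEST pool and a single Mz for
the MT pool, all in units of the equilibrium water polarization. For one
constant RF segment the dynamics are the affine ODE dM/dt = A M + C, with

* transverse and longitudinal relaxation (1/T2, 1/T1), recovery towards
  Mz = f per pool;
* rotating-frame precession of pool i at
  (dw_i + dB0) * w0 * 1e-6 - offset, so a static field error dB0 (ppm)
  shifts every resonance together;
* RF nutation at w1 = 2*pi*gamma * B1 * relB1 (gamma = 42.5764 MHz/T), with
  the segment phase selecting the rotation axis;
* two-site exchange between water and each CEST pool with detailed
  balance, k_water->i = k_i * f_i, acting on all three components;
* MT saturation of the semisolid Mz at R_rf = pi * w1^2 * g(offset) with a
  Lorentzian lineshape g(x) = (T2m/pi) / (1 + (x*T2m)^2). A
  super-Lorentzian is deliberately not offered: the package's phantom MT
  source is agarose gel, for which the Lorentzian is the customary model,
  and the validity range of the super-Lorentzian near resonance would
  demand extra handling.

The readout is *not* modelled. An ideal crusher zeroes all transverse
components between saturation and "acquisition", and the recorded signal
is water Mz. A Z-spectrum is S_sat(offset)/S0.

## Assumptions worth knowing

* **Offsets are independent.** Each offset starts from the same
  recovery-attenuated equilibrium, Mz_i(0) = f_i (1 - exp(-Trec/T1_i)),
  transverse zero; no magnetization is carried across offsets. This models
  a sequence whose recovery delay (3.5 s for the APTw protocol, 12 s for
  WASABI) dominates the post-readout state. Consequently the order of the
  offset list is irrelevant, and the package guarantees it.
* **S0 policy.** The default reference is a dedicated RF-off scan of
  identical timing (recovery plus free evolution over t_sat), so Z is
  exactly 1 when the RF amplitude is zero. A far-offset saturated scan can
  be selected per sequence instead.
* **Noise** in the phantom module is additive Gaussian on the normalized
  signal, not Rician. At the SNR regimes of interest (Z near 1, noise sd
  of order 1e-2) the difference is negligible; the choice is recorded in
  the stack provenance and trivially switchable at the call site.

# Numerical scheme

Shaped pulses are discretized into piecewise-constant segments.
`discretize()` groups raster samples into blocks no longer than `maxDt`
(default 100 us), *splitting additionally at phase discontinuities* so
that a sinc lobe sign flip never falls inside a segment. Each segment
carries the RMS amplitude of its samples — preserving RF power, the
quantity that governs saturation — and the power-weighted mean phase.
Segment durations sum exactly to the pulse duration.

Each segment is advanced by the matrix exponential of the one-dimensional
affine augmentation [[A, C], [0, 0]], computed by `Matrix::expm`
(scaling-and-squaring Padé), which is exact for the piecewise-constant
problem to near machine precision. Two optimizations make desk-scale
simulation fast without changing results:

* runs of identical (amplitude, phase) segments are merged into one
  exponential (exp(A dt1) exp(A dt2) = exp(A (dt1+dt2))), which collapses
  a long rectangular pulse to a single segment;
* exponentials are cached by (amplitude, phase, offset, dt), so the 36
  identical pulses of an APTw train cost one pulse propagator per offset.

The only approximation is the piecewise-constancy itself. Its error is
second order in the segment length: in the package's convergence test a
further halving of a 10 us step changes Z by less than 1e-6, and the
default 100 us step is converged to about 1e-5 for the 50 ms sinc-Gauss
pulse — ample for Z values of order 0.1-1. The propagator itself is
verified against an independent fine-step Runge–Kutta integration of the
same ODE (agreement to 1e-5 across random multi-pool environments, and to
1e-12 on single trajectories).

Degenerate inputs are handled explicitly: zero-duration propagation is the
identity; zero-amplitude RF reproduces the reference scan exactly; a
non-finite state aborts with the offending offset named.

# Sequences and their parameters

`buildAPTw3T()` constructs the amide-proton-transfer-weighted 3 T
protocol: 36 sinc-Gauss pulses of t_p = 50 ms separated by t_d = 5 ms
(t_sat = 1.975 s, duty cycle 91%), B1rms = 2 uT, 3.5 s recovery.
`buildWASABI()` is a single 5 ms, 3.7 uT rectangular pulse with 12 s
recovery. Parameters the protocol descriptions leave open were fixed once:

* **B1 convention.** "B1 = 2 uT" for the shaped pulse is the
  root-mean-square amplitude over the pulse, the power-equivalent
  convention of APTw protocol reporting. For a rectangular pulse RMS and
  peak coincide.
* **Sinc-Gauss definition.** Sinc with 2 side lobes per side, apodized by
  a Gaussian with sigma = duration/4, sampled on a 10 us raster, rescaled
  to the target RMS. Negative lobes are stored as positive amplitude at
  phase pi. The resulting peak amplitude is about 2.6x the RMS, which
  matters for the spillover discussion below.
* **Offset grids.** APTw: -4 to +4 ppm in 0.25 ppm steps, resolving the
  +-3 ppm guanidinium peak; WASABI: -2 to +2 ppm in 0.1 ppm steps,
  several samples per Rabi fringe at 3.7 uT and 5 ms.
* **Phase cycling.** Per-pulse phase offsets exist in the data model
  (`PulseTrain@phases`) but default to zero, i.e. a phase-coherent train
  in the frame rotating at the RF frequency.

Sequences serialize to a flat text format (a `[DEFINITIONS]` key-value
section plus a `[SHAPE]` sample table at 12 significant digits), which
round-trips all timings and samples to 1e-9 and is byte-stable. It is a
deliberate miniature: gradient and readout events of full scanner formats
are out of scope.

# Environments

Pool fractions follow f = n_H * c / 111000 mM — labile protons per
molecule over the 2 x 55.5 M water proton concentration. L-arginine at
concentration c contributes one guanidinium pool (n_H = 3) at +3.0 ppm
exchanging at 350 Hz (the rate of the acidic pH ~4 preparation), with
water T1 = 1500 ms / T2 = 1000 ms as in the doped phantom solutions. The
pool's own relaxation (T1 = 1.5 s, T2 = 0.1 s) is a package default; the
simulated spectra are insensitive to it because k dominates T2-broadening
of the dilute pool.

The five-tube phantom maps Table-style tube compositions to environments:
20/27/40/60/70 mM L-arginine, tubes 3-5 adding a semisolid MT pool for
their 2% agarose (f = 0.05, T1 = 1 s, T2 = 10 us, k = 30 Hz, Lorentzian,
centred on water). Two remarks on realism:

* The MT fraction 0.05 is a convention for "gel-like MT background", on
  the high side of quantitative-MT estimates for 2% agarose; it is
  overridable via yaml and its main effect is a uniform far-off-resonance
  baseline depression in tubes 3-5.
* Water T2 is kept at 1 s in *all* tubes, although agarose shortens water
  T2 substantially in reality. This isolates the designed contrast
  mechanism — exchange scaling with concentration plus an MT baseline —
  and keeps the 3-ppm MTRasym strictly increasing across tubes 1-5.
  With a realistic gel water T2 (~100 ms) the extra direct-saturation
  spillover in tube 3 would push its 3-ppm asymmetry *below* tube 2's
  despite the higher concentration; users studying that competition can
  set the water pool per environment.

Environments load from and save to a yaml dialect with `water_pool`,
`cest_pool` (named pools), `mt_pool` blocks and `b0`, `gamma`, `rel_b1`,
`db0` scalars, mirroring publicly shared simulation-parameter files.
Numbers are written with shortest-round-trip precision, key order is
canonical (serialization is byte-idempotent), unknown keys survive round
trips, and validation errors name the missing field.

# Evaluation

* **MTRasym sign.** MTRasym = Z(-dw) - Z(+dw), so a pool at positive ppm
  gives a positive peak. Mirrored offsets are looked up by linear
  interpolation regardless of any display interpolation choice.
* **Interpolation.** `"linear"` is exact at nodes;
  `"smoothing_spline"` is a cubic smoothing spline whose node residual sum
  of squares is kept within n * s^2, with s a noise scale estimated from
  second differences. (A much tighter budget — a quarter of the noise
  scale — was considered and rejected: it forces near-interpolation,
  defeating the smoother; the n*s^2 budget recovers a noisy parabola to
  within 2 noise standard deviations in the package tests.) Smoothing can
  still distort sharp features such as the direct-saturation dip; linear
  evaluation is the conservative choice for quantitative asymmetry
  readouts.
* **WASABI fit.** The Rabi model |c - d (w1^2/weff^2) sin^2(weff tp/2)|
  is fit by bounded least squares (c in [0.5, 1.5], d in [0.1, 3]) with a
  5 x 5 multi-start grid over (B1, dB0) — the objective is oscillatory in
  B1, and single starts routinely land in the wrong Rabi branch. On
  noiseless model spectra the median recovery error is far below 1% in B1
  and 0.01 ppm in dB0; through the full simulator the 3.7 uT amplitude and
  an imposed 0.1 ppm shift are recovered within 2% and 0.02 ppm.
* **B0 correction** re-interpolates measured values at offsets + dB0 and
  returns them on the nominal grid (restricted to where the shifted lookup
  stays in range), preserving the value range under linear interpolation.
* **Maps.** `parametricMap()` applies the asymmetry or WASABI evaluation
  voxelwise; identical voxel spectra (noiseless phantom tubes) share one
  computation, and background voxels (s0 <= 0 or non-finite spectra)
  come back NA.

# Where the MTRasym peak lands — and why

With the APTw protocol on 20 mM L-arginine the package's asymmetry curve
is broad and its maximum falls at 2.5 ppm on the 0.25 ppm grid — below
the 3.0 ppm pool resonance. This is reproducible physics, not a numerical
artifact (it survives propagator cross-validation, step refinement, pool
T2 variation and phase cycling): at 2 uT RMS the exchange-broadened label
dip (k = 350 Hz) is already ~0.8 ppm wide, and the shaped pulse's ~5.2 uT
peak amplitude transiently broadens it much further while spillover
weights the asymmetry towards water. In continuous-wave steady state the
same environment peaks at 2.75 ppm at 2 uT and at 3.0 ppm at 1 uT or a
rectangular train. The broad "approximately +3 ppm" description of such
curves is accurate; a grid-argmax statistic, however, reports the 2.5 ppm
plateau point. Users who need the pool position rather than the curve
argmax should fit the asymmetry peak or lower B1.

# Phantom generator: what it does and does not emulate

`makeDigitalPhantom()` arranges five equal discs on a ring in a 64 x 64
grid (tube radius 7 voxels by default) — a synthetic layout, not a model
of any measured phantom's geometry. Optional linear dB0/relB1 field maps
emulate smooth scanner inhomogeneity. `simulateStack()` runs one
simulation per distinct (environment, dB0, relB1) combination, with field
maps quantized to 0.005 ppm and 0.5% so homogeneous regions share work,
then adds seeded Gaussian noise.

Passing phantom tests therefore demonstrates the pipeline's correctness
and sensitivity ordering on idealized data; they say nothing about
partial-volume effects, readout-induced saturation, motion, fat/blood
artifacts, Rician noise floors, or realistic B0 texture, none of which are
modelled.

# Problem sizes and runtime choices

The test suite and the reproduction script run single-threaded in a few
minutes: Z-spectra use the full 33-offset APTw protocol where the claim
demands it and 3-9 offsets elsewhere; the Runge–Kutta cross-check uses
short two-pulse rectangular trains at a 20 us integration step across 20
random environments; phantom tests use a 24 x 24 grid with the full
64 x 64 phantom reserved for the tube-monotonicity check. These sizes are
stated here as the package's chosen operating points; all tolerances
quoted above are asserted in `tests/testthat/`.

# Known limitations

* Prep-only scope: no gradients, diffusion, flow, or readout physics
  beyond the ideal crusher.
* Lorentzian MT only; no super-Lorentzian, hence no in vivo white-matter
  quantitation.
* The WASABI model neglects relaxation during the 5 ms pulse — excellent
  for phantom T1/T2, increasingly approximate for short-T2 systems.
* Exchange rates are inputs; no pH or temperature model is provided.
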