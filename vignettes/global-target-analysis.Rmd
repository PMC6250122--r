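---
title: "Global and target analysis of flavoprotein photoactivation"
author: "PhotoTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global and target analysis of flavoprotein photoactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhotoTA)
```

## The problem

Blue-light photoreceptors of the cryptochrome family reduce their
protein-bound FAD chromophore through a cascade of electron transfers along
a conserved tryptophan tetrad. The observable is transient absorption: a
difference-absorption surface $\Delta A(\lambda, t)$ spanning femtoseconds
(electron transfer), microseconds (proton release), milliseconds (radical
decay) and minutes (reoxidation). PhotoTA implements the standard analysis
chain for such data — preprocessing, model-free global fitting, model-based
target analysis, basis-spectrum decomposition, anisotropy analysis — plus a
compartmental simulator of the full branched photocycle, and a seeded
synthetic-data generator so that every estimator in the chain can be tested
against known ground truth.

## Global fitting: variable projection

The central model is bilinear,
$$\chi^2 = \lVert \Delta A - F\,B \rVert^2 \to \min,$$
where the columns of $F$ are exponential decays convolved with a Gaussian
instrument response (IRF) and the rows of $B$ are the decay-associated
difference spectra (DADS). For fixed rate constants, $B$ has a closed-form
least-squares solution (`solveDads()`); the nonlinear parameters — the
logarithms of the rate constants and optionally the IRF center — are
optimized by Levenberg–Marquardt on the projected residual (`fitGlobal()`).
This *variable projection* is exactly equivalent to the full joint
optimization over $(k, B)$, which the test suite verifies against a
brute-force joint fit ($\chi^2$ agreement below $10^{-10}$).

Numerical choices:

* The IRF-convolved exponential
  $\tfrac12 e^{-k(t-\mu)+k^2\sigma^2/2}\,\mathrm{erfc}\!\big(\tfrac{\mu + k\sigma^2 - t}{\sigma\sqrt2}\big)$
  is evaluated through `pnorm(log.p = TRUE)`, so it stays finite for
  $k\sigma$ far beyond $10^3$ — necessary because the rates span
  $10^{12}\,\mathrm{s^{-1}}$ to $10^{-2}\,\mathrm{s^{-1}}$ while IRF widths
  range from 40 fs to milliseconds.
* Rates are optimized as $\log_{10} k$: positivity is automatic and the
  fs-to-s dynamic range becomes well scaled.
* Components that do not decay inside the observation window are encoded
  exactly as $k = 0$ (an IRF-broadened step), not as a tiny rate; this
  removes spurious curvature in the optimization.
* Exponential fitting is multimodal, so `fitGlobal()` multistarts (default
  5) with log-uniform jitter by a factor in $[0.2, 5]$ around the initial
  rates, under a fixed seed; ties break by the lower iteration count.
* $\chi^2$ is unweighted over grid points. The quasi-logarithmic delay axis
  (`buildTimeAxis()`, linear to the switch time, then equal point counts
  per decade) itself balances the timescales.
* The number of components comes from SVD rank analysis (`svdRank()`): a
  component counts when its singular value exceeds a noise floor (3x the
  median of the trailing half of the spectrum) *and* both its singular
  vectors have first-lag autocorrelation at or above 0.8. The rule for the
  rank criterion is not fixed by the literature this implementation
  follows; these are conventional, configurable defaults, and ties resolve
  to the smaller rank because parsimony protects the nonlinear fit.
* All internal times are seconds; constructors accept unit-suffixed
  strings (`"848fs"`, `"46ps"`, `"187ms"`) because a fs-to-minute range in
  bare floats invites unit bugs.

## Target analysis: from DADS to species

A compartmental scheme $\dot C = K C$ with IRF-shaped excitation turns the
model-free fit into species-associated spectra (SAS). Because the
compartment concentrations are linear combinations of the same
IRF-convolved exponentials (eigenmodes of $K$), the map $C = F A$ is an
invertible matrix $A$, and $\mathrm{SAS} = (A^{-1}B)^{\!\top}$ leaves the
reconstruction $F B$ — and hence $\chi^2$ — *identical*. `sasFromDads()`
asserts that identity rather than assuming it. Model rates are fixed to the
fitted rates (two-stage workflow) rather than refit, keeping the fit
quality comparable across candidate models; a mismatch beyond tolerance is
an error listing both rate sets.

Two spectral-arithmetic steps carry the mechanistic conclusions:

* `addGroundState()` adds back the scaled ground-state spectrum to the DADS
  sum to recover the pure excited-state spectrum; the scale is the amount
  of ground state contributing to the data, which normalizes quantum-yield
  estimates. If not given, the fraction is the smallest one that leaves no
  bleach in the ground-state band.
* `stripFlavin()` removes the (radical minus oxidized) flavin difference
  spectrum from the persistent DADS until the flavin features disappear.
  This is operationalized as a least-squares projection inside a
  flavin-dominated window with a low-order polynomial nuisance baseline,
  plus a residual decorrelation check. The default window is **445–500
  nm** with a cubic baseline: the window must exclude the tryptophanyl
  radical cation's own band at ~405–410 nm (its tail reaches ~440 nm;
  inside it, no projection can separate the two species) while staying
  blue of the broad 490–700 nm radical band. On noise-free synthetic
  truth this recovers the mixing coefficient to ±0.002 for every
  counter-radical variant; windows starting at 430 nm are biased by
  several points whatever the baseline order. The complement of the
  stripping coefficient is the radical-pair recombination fraction
  (`estimateRpr()`).

## Decomposition and the pocket pH

`decomposeSpectra()` expresses measured spectra as combinations of known
species basis spectra — ordinary least squares by default, with the
species sum monitored (never silently renormalized) as the physical
plausibility diagnostic; a nonnegative mode (Lawson–Hanson) is available.
Fractions are normalized to the fitted dark-state total; species on an
arbitrary scale, such as the unidentified Trp photoproduct, can be
excluded from the conservation check. The ratio of the flavin anion
radical to its protonated neutral form, with
$\mathrm{p}K_a(\mathrm{FAD^{\bullet-}/FADH^{\bullet}}) = 8$, gives the
binding-pocket pH through Henderson–Hasselbalch (`pocketPH()`); the
absorption-to-concentration conversion behind the ratio is not part of the
package, so the ratio itself is the input.

## Anisotropy

`anisotropySurface()` computes
$r = (\Delta A_\parallel - \Delta A_\perp)/(\Delta A_\parallel + 2\Delta A_\perp)$
with cells masked where the isotropic denominator falls below 1 mOD —
anisotropy diverges at isosbestic and bleach-cancellation points, and the
default threshold reflects typical noise floors of supercontinuum probes.
Theoretical photoselection values $r = 0.4\,P_2(\cos\theta)$ take pairwise
dipole angles as input (extracting dipoles from structures or quantum
chemistry is out of scope), and `averagedAnisotropy()` forms the
population-and-extinction weighted mean used to assign equilibrated
radical-pair mixtures. Rotational-diffusion depolarization is not
modelled; per-species anisotropies are taken time-independent, which is
adequate within the sub-ns interpretation window of a protein this size.

## The photocycle simulator

`simulateSingleShot()` propagates unit excited population through the
branched scheme: primary electron transfer (848 fs), primary radical-pair
decay (46 ps) splitting between recombination ($\varphi_{rec} = 0.2$) and
onward transfer, terminal radical-pair formation in the ns gap,
deprotonation (1 us), neutral-radical decay (187 ms) and O2-dependent
reoxidation (default time constant 180 s at the aerobic reference). The
terminal-pair formation time is only bounded (between the end of the ps
window and ~100 ns) by the data this models; the default, 30 ns, is the
geometric middle of that interval and configurable. Every compartment
population is an analytic sum of IRF-convolved exponentials, and the two
ground-state returns (recombination with intact Trp; reoxidation after Trp
decomposition) use the closed-form flux integral
$\int k\,c_k\,dt = \mathrm{step} - c_k$, so flavin and Trp positional mass
are conserved to machine precision on any grid from fs to minutes — no
stiff ODE integration, no regime stitching error.

`simulateIllumination()` does the ensemble bookkeeping of repeated
illumination: each absorbed photon of a protein with intact sacrificial
Trp positions completes a photocycle with probability $1-\varphi_{rec}$
and decomposes one position (the photoreaction is irreversible — the
protein is a different molecule afterwards); a protein with all three
sacrificial positions decomposed releases its FAD with probability
$\varphi_{release}$ per absorbed photon. The pulse-resolved state follows
a small linear generator in the dose domain, solved by matrix exponential.
Full dark reoxidation between pulses is assumed, matching the measurement
protocol the generator emulates. DTT chemistry is reduced to an optional
rate modifier; single-molecule stochasticity is not modelled because all
observables here are ensemble quantities.

**Dose and release-yield defaults.** The observables this module must
reproduce are: bound FAD falling to ~50% over the 13-pulse schedule
(10x1 s, 2x5 s, 1x10 s) and a cumulative free-FAD release yield of 6% per
absorbed photon. Together these fix the mean dose:
$0.5 / 0.06 / 30\,\mathrm{s} \approx 0.28$ excitations per flavin per
second of illumination. The microscopic per-photon release probability of
a Trp-depleted protein is then calibrated so the schedule-level yield
equals 6% (`calibrateReleaseYield()`, default 0.161). A naive
Beer–Lambert estimate from the stated optical density and pulse power
(`excitationRate()`) gives a several-fold larger dose; it is provided for
dosimetry but is not the default, because it is inconsistent with the
observed endpoint — photon delivery to the cuvette is not photon
absorption by photoactive protein.

## The synthetic generator, and what passing tests do not show

`generateRegime()` builds $\Delta A = C\,S^\top$ for each instrument
regime (ps: quasi-log axis −1 ps to 3 ns, 500 points, 100 fs FWHM IRF,
340–820 nm; us: 10 us window, 100 ns IRF; ms: 400–700 nm in 10 nm steps at
12.5 ms over 10 s), with species spectra as Gaussian-band sums placed at
the observed band positions (flavin anion maxima 472/403/367 nm,
excited-state absorption 360/505/700/775 nm, stimulated emission 545 nm,
radical-cation bands 410 and 490–700 nm, the neutral flavin radical
redshifted by 39 nm, the Trp photoproduct below 400 nm). Bound FAD carries
sharp vibronic sub-bands (FWHM 20–22 nm), as protein-bound flavin does;
this fine structure is what the stripping procedure keys on, and the free
FAD preset is deliberately structureless so the two are separable in
decompositions. Noise is additive i.i.d. Gaussian with SNR 30 against the
peak signal — achievable but non-trivial for the 10% lifetime and ±3-point
fraction recovery targets; polarized pairs encode per-species
anisotropies so that $(\parallel + 2\perp)/3$ reproduces the population
signal identically; chirp and pre-t0 scatter are optional raw-data
features. Every generator stores the truth needed for bit-identical
regeneration.

What the generator does *not* emulate: vibronic structure beyond Gaussian
sums, shot noise and detector nonlinearity, wavelength-dependent IRF
width, rotational diffusion, sample degradation within a scan. Recovery
tests therefore certify the estimators, not instrument realism: a passing
suite means the analysis chain is unbiased and correctly propagates known
inputs to conclusions under the stated noise model, not that every
systematic error of a real spectrometer is survivable.

## Degenerate inputs and edge behaviour

Streak-camera cells with nonpositive intensities are masked, never
imputed; masked cells are excluded from every fit (verified by poisoning
them). Duplicate rate constants are rejected naming the offending pair;
models whose eigenrates disagree with the fitted rates list both sets.
Constant matrices yield rank 0 with a warning. Chirp-corrected points
shifted outside the measured axis are masked. Anisotropy is undefined, and
masked, below the denominator threshold. A time grid too coarse for the
fastest process in its span is refused rather than silently aliased.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run the ps regime at 121
wavelengths x 500 delays, the us regime at 121 x 211, the ms regime at 31
x 800, and the illumination sequence at 13 pulses — the instrument grids
of the emulated experiments — with 5-start global fits; the whole suite
completes in a few seconds on one core.
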