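---
title: "Methods: acoustic analysis and insulation modelling for venous pulsatile tinnitus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic analysis and insulation modelling for venous pulsatile tinnitus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptinsulate)
```

## The problem

Venous pulsatile tinnitus (PT) is a pulse-synchronous somatosound of sigmoid
sinus origin, usually heard through a dehiscent or thinned sigmoid plate of
the temporal bone. Surgical treatment resurfaces the plate with layered
grafts and biomaterials (temporalis fascia, auricular cartilage, gelatin
sponge, bone wax, ...), whose task is sound insulation. The package
implements the desk-scale measurement-and-model chain for this problem:
characterising sensor traces of the vibrating vessel wall and the airborne
sound, reducing impedance-tube and porosimetry measurements of the
candidate materials, simulating the pulsatile flow and the flow-borne
(hydroacoustic) source it creates, and computing whether a given multilayer
reconstruction should resolve the tinnitus.

All inputs are synthesised by the package's own generators; no patient data
are used or reproduced. Every generator takes an explicit seed and is
deterministic under it.

## Synthetic study conditions

The generators' defaults are the study conditions throughout:

* cardiac period **1.46 s** (fundamental 0.685 Hz); displacement sensor at
  **1 kHz** (1 ms sampling cycle); audio at 8 kHz;
* wall-displacement median excursion **0.012 mm** (wall attached to the
  plate) vs **0.092 mm** (after separation), used in the pre/post rank-sum
  comparison;
* PT-like audio with all spectral energy **below 2 kHz**, calibrated so the
  peak pressure equals a target dB SPL re 20 µPa (64.0 dB is the
  pre-reconstruction peak used in examples);
* venous Doppler waveform: raised-cosine pulse on a baseline,
  `v(t) = v̄ (1 − p + p (1 − cos 2πt/T))`, which has cycle mean `v̄`,
  minimum `v̄(1 − p)` and maximum `v̄(1 + p)`. The inlet velocity and
  vessel diameter are never reported clinically in the source setting; we
  adopt the pair **0.5 m/s and 7 mm** because it reproduces the quoted
  Reynolds number of about 1065 with blood properties ρ = 1050 kg/m³ and
  µ = 0.00345 Pa·s. This pair is an inference, not a measurement.

The displacement waveform is a sum of 3–5 harmonics of the cardiac
fundamental with geometrically decaying amplitudes — the simplest form that
is pulse-synchronous with most of its power below the audible range. The
audio generator shapes broadband noise plus a low-frequency harmonic stack
with a raised-cosine FFT roll-off over the top 10% of the band, so the
out-of-band/in-band energy ratio is below 1e-4 by construction.

What the generators deliberately do not emulate: patient-specific vessel
morphology, the measured surgical audio, microphone room acoustics, or
sensor nonlinearity. Passing round-trip tests therefore demonstrates the
*analysis chain* is correct, not that real recordings look like the
synthetic ones.

## Signal analysis

`rms()`, `to_db_spl()` (20 log₁₀ p/p₀, p₀ = 20 µPa) and
`calibrate_pressure()` (microphone sensitivity −34 dB re 1 V/Pa, flat
response assumed — the anechoic calibration transfer curve is not
available) are the calibration layer.

**STFT.** `stft()` frames, windows (Hann or rectangular) and returns
one-sided amplitude spectra in dB with a −120 dB floor so silence never
yields −Inf. With a rectangular window, `frame_energies()` inverts the
scaling and satisfies Parseval's theorem exactly, which the suite checks.

**VMD.** `vmd()` is the frequency-domain ADMM scheme that minimises the
summed bandwidth of K analytic modes about adaptive center frequencies
ω_k, subject to the modes summing to the input. Defaults: bandwidth penalty
α = 2000 (cyclic-frequency scale), tolerance 1e-7, center frequencies
initialised uniformly over [0, rate/4], Lagrangian step τ = 1. Two boundary
extensions are used in sequence — a detail worth recording because it is a
genuine design choice:

* an **even mirror** extension keeps the extended signal's spectrum free of
  a wrap discontinuity, so the spectral power centroids (the ω_k updates)
  are unbiased; but its derivative kink at the junctions makes the
  narrowband filters ring into the retained segment;
* a **point-reflected (odd) extension** is continuous in value and slope,
  so the mode filters do not ring at the boundaries; but its wrap
  discontinuity biases the lowest ω_k.

`vmd()` therefore estimates ω_k on the even mirror, then recomputes the
modes with ω_k fixed on the odd extension. With τ = 1 the dual update
enforces in-band reconstruction; on a 10 s two-tone (5 + 50 Hz, 1 kHz) the
center frequencies are recovered within 1% and the relative L2
reconstruction error is about 0.05%. For noisy data set `tau = 0`, which
drops the exact-reconstruction constraint (the classical noise-robust
variant). Non-convergence at `max_iter` is flagged on the result, not
raised.

**CWT.** `cwt()` uses the analytic complex Morlet wavelet (ω₀ = 6),
computed per scale by FFT convolution, with the pseudo-frequency map
f = f_c/(a·Δt). The wavelet choice is ours; the measurement literature the
package follows names none.

**Rank-sum.** `compare_segments()` computes the two-sided Mann–Whitney U
test: exact enumeration of all rank assignments when both groups have ≤ 8
observations (ties handled naturally by enumerating midranks), otherwise
the normal approximation with tie correction. The exact path is written
here because the standard R implementation cannot produce exact p-values
under ties; the suite cross-checks the tie-free exact path against
`stats::wilcox.test()` and the tied path against an independently coded
enumeration oracle. Five-second windows from the trace start are the
comparison convention.

## Material acoustics

**Transmission loss.** The four-microphone impedance tube is reduced by the
transfer-matrix method:

TL = 20 log₁₀{ ½ |A + B/(ρc) + ρc·C + D| } + 10 log₁₀(S_i/S_o).

The four per-frequency coefficients are read as the elements of one 2×2
plane-wave transfer matrix relating upstream (pressure, particle velocity)
to downstream; with equal tube areas the area term vanishes. The
`gen_tube_signals()` fixture simulates the four microphone spectra with an
anechoic termination, and `tube_transfer_matrix()` reduces them under the
symmetric-reciprocal-specimen assumption (A = D, AD − BC = 1), giving the
closed form A = (p_b·u_b + p_f·u_f)/(p_f·u_b + p_b·u_f). The exact
microphone spacings of the physical tube are not published; the fixture's
spacing (5 cm) only has to avoid the half-wavelength singularities, which
sit above 2 kHz for the 13-band set.

**Absorption.** α = 1 − r with r treated as an energy (power) reflection
coefficient, so α ∈ [0, 1]. Band reductions use arithmetic means over the
named center-frequency sets: 6 octave bands (125–4000 Hz) for absorption,
13 one-third-octave bands (125–2000 Hz) for TL; fine-grid spectra are
interpolated linearly on a log-frequency axis. Unweighted band values are
averaged (whether the measured averages were A-weighted is unstated; we
assume not).

**Mass law and density estimation.** The normal-incidence mass law
TL = 10 log₁₀(1 + (πfm/ρc)²) with m the areal density (density ×
thickness). `estimate_density_from_tl()` inverts it by 1-D least squares
over the 13-band curve; a fit residual above 3 dB RMS or a near-zero
estimate flags low confidence. Note the shipped bone-wax measurement
(45.3 dB average) far exceeds its mass-law prediction (~28 dB at 1 kHz for
3.12 kg/m²): that specimen is stiffness-controlled, which is exactly the
situation the low-confidence flag exists for.

**Composite stacks.** `composite_stack_tl()` cascades per-layer 2×2
matrices (solid layers plus air gaps). Layer sound speed comes from the
thin-solid longitudinal formula c = √(E(1−ν)/(ρ(1+ν)(1−2ν))) unless
configured directly; a limp-mass model (B = jωm) is also available. A
noteworthy physical consequence of the shipped property table: with the
measured moduli, a bone-wax + solidified-gelatin-sponge elastic cascade has
a mass–spring–mass resonance near 500 Hz (the sponge acts as a soft
spring), locally *reducing* TL there, whereas the limp-mass idealisation
shows the expected monotone mass-law gain of the added layer. The suite
checks the composite direction in the limp regime, below the mass–air–mass
resonance. Plate bending, diffuse-field incidence and the measured
first-order resonance dip of cartilage are out of scope.

## Porosimetry

Mercury intrusion is reduced by the Washburn relation d = −4σcosθ/P
(diameter convention, matching the instrument's 4V/A output). Mercury
parameters default to σ = 0.485 N/m and θ = 130°; only θ > 90° and the
400 MPa ceiling are documented for the instrument, and these defaults
reproduce its stated 0.003 µm detection floor at 400 MPa. Porosity is total
intruded volume × bulk density (the identity matches the published
gelatin-sponge figures exactly); the alternative skeletal-density
definition is not used. The log-differential distribution dV/dlogD uses
central differences. "Interstitial porosity" has no documented formula, so
`interstitial_porosity()` requires an explicit interparticle cutoff
diameter and is never reported by default.

## Flow model

The patient-specific transverse–sigmoid geometry is unreleased, so the flow
stage is a straight rigid circular tube (radius default 3.5 mm — a typical
sigmoid sinus calibre, a configuration choice, not a fact), with blood
ρ = 1050 kg/m³, µ = 0.00345 Pa·s, time step 5e-5 s, two 1.46 s cycles with
the second one representative, on a 41 × 101 (radial × axial) grid. In this
geometry fully developed axisymmetric flow has u = u(r, t) only, so the
convective term vanishes identically and mass conservation along the axis
is exact by construction. The wall is rigid: wall elasticity
(0.3 mm, E = 1.26 MPa in the source setting) is out of desk scale and
enters only as a documented limitation of the acoustic stage. Gravity is
set to zero (no orientation is specified anywhere).

Two routes cross-validate each other:

* `womersley_solution()` — the classical analytic profile per harmonic of
  the driving pressure gradient, with the Bessel function J₀ of complex
  argument evaluated by power series (accurate to ~1e-12 for the Womersley
  numbers involved, α ≈ 4 at the fundamental);
* `solve_transient_laminar()` — an explicit finite-difference integration
  of ρ∂u/∂t = G(t) + µ∇²u with a per-step uniform pressure-gradient
  correction enforcing the prescribed inlet mean-velocity waveform
  (flow-rate-driven formulation). The diffusive stability bound
  ν·dt/dr² ≤ 0.25 is checked and a compliant dt suggested on violation.
  The integration starts from the analytic periodic profile implied by the
  inlet waveform's Fourier harmonics, so the start-up transient is already
  small and the last-two-cycle L2 difference lands well below 1%.

At the default grid the solver matches the analytic solution to ~0.2% L2
over a cycle and is insensitive (≤ 0.1%) to halving dt.

## Acoustic source

`lighthill_tensor()` evaluates T_ij = ρu_iu_j + p′δ_ij per cell on the
axisymmetric grid (incompressible flow: the c₀²∇²ρ term vanishes; p′ is the
fluctuation about the spatial mean; the viscous shear's Cartesian
components average to zero over each azimuthal ring, so the ring-cell
representation carries no net viscous term). `radiate()` applies the
compact-quadrupole far-field solution of the Lighthill equation,

p′(x, t) = x_i x_j / (4π c₀² |x|³) · d²/dt² ∫ T_ij(y, t − |x|/c₀) dV,

with the double time derivative outside the integral, central-difference
second derivatives at the stored sampling step and linearly interpolated
retarded time. Air properties are 1.139 kg/m³ and 340 m/s; spectra are
reported in dB SPL re 20 µPa with the standard IEC A-weighting (poles at
20.6, 107.7, 737.9 and 12194 Hz, 0 dB at 1 kHz). Peak extraction breaks
ties toward the lower frequency.

This free-field surrogate deliberately omits the mastoid-cavity modal
acoustics and the wall-vibration (vibroacoustic) branch of the full
coupled computation, so it cannot and does not claim to reproduce the
published patient-specific spectra (e.g. the 42 Hz peak); those enter the
efficacy stage as configured inputs instead.

## Efficacy

`apply_insertion_loss()` subtracts a stack's per-band TL from a
pre-operative spectrum, floored at 0 dB SPL — an audibility floor, not
physical silence. `technique_comparison()` reproduces the published
three-technique arithmetic when fed the published pre/post peaks (shipped
as a YAML fixture), or derives post peaks from a stack in predictive mode;
both paths share one report schema because the full coupled-simulation
post values cannot be recomputed at desk scale. `resolution_decision()`
implements the decision rule that the total transmission loss must reach
the tinnitus loudness above the hearing threshold (default 17.7 dB, a
cohort mean from prior loudness matching; the boundary case counts as
resolved). Where published summaries disagree internally on the
solidified-gelatin-sponge post peaks, the values consistent with the
printed reductions are adopted.

## Worked example

```{r example}
# three-technique comparison from the shipped fixture
technique_comparison(read_efficacy_cases())

# porosimetry of a synthetic gelatin-sponge-like record
curve <- gen_intrusion_curve(list(median_um = 100, sdlog = 0.5, weights = 1),
                             porosity = 0.967, bulk_density = 34.2)
porosity(curve)
mean_pore_diameter_4v_a(28.28, 0.773) * 1000  # mm
```

## Problem sizes and numerical choices

The shipped tests use 10 s signals at 1 kHz for decomposition checks, a
single 1.46 s representative cycle at dt = 5e-5 s on the 41 × 101 grid for
the flow oracle, 20-replicate Monte-Carlo for noisy density recovery, and
exhaustive rank-sum enumeration up to group sizes of 6 — sizes chosen so
the whole chain (including the analytic cross-validations) runs in well
under a minute while leaving every tolerance meaningfully tight.
Spectrogram and scalogram floors are clamped at −120 dB; tie-breaks in
peak extraction always prefer the lower frequency; degenerate inputs
(constant traces, zero porosity, zero TL curves) return flagged or absent
values rather than erroring where the contract says so.

## Known limitations

No psychoacoustic loudness or masking model; no FEM propagation through
the mastoid air cells; no fluid–structure interaction; no mercury
compressibility or extrusion hysteresis; single-frequency-set band
conventions. The decision rule operates within its published framework and
is not a predictor of individual surgical outcomes.
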