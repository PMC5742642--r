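---
title: "Square-wave SFDI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Square-wave SFDI: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement and its model

Spatial frequency domain imaging (SFDI) projects spatially modulated light
onto a turbid medium and measures how strongly the medium attenuates each
spatial frequency of the backscattered image. Because scattering and
absorption attenuate the planar (fx = 0) and modulated (fx > 0) components
differently, a measurement at two spatial frequencies separates the
absorption coefficient `mua` from the reduced scattering coefficient `musp`
per pixel. With three wavelengths (655, 730, 850 nm), the per-wavelength
absorption maps unmix into oxy- and deoxyhemoglobin concentrations and the
oxygen saturation `StO2 = ctHbO2 / (ctHbO2 + ctHb)`.

The speed trick this package models: binary square-wave stripe patterns
refresh far faster on a digital projector than grayscale sinusoids. Tissue is
a spatial low-pass filter, so the odd harmonics of a square wave
(amplitude `2/(n*pi)` at `n*fx`) return strongly attenuated, and — crucially —
the three-phase demodulator cancels every harmonic whose order is a multiple
of 3 exactly, because stepping the base phase by 120 degrees steps the 3rd
harmonic by full turns. What survives demodulation is, to a very good
approximation, the base-frequency sinusoidal response. The 12-frame sequence
(per wavelength: one planar frame, then three square-wave phases at
0.3 cycles/mm) at a 167 Hz camera rate yields optical-property maps at
167/12 ≈ 14 Hz, and a heart-rate ceiling of (14/2)·60 = 420 bpm for
optically sampled pulsation.

# Forward models

Two forward models coexist deliberately:

* **Diffusion closed form** (`rd_diffusion()`): the standard semi-infinite
  spatial-frequency-domain solution
  `Rd = 3*A*a' / ((mueff'/mutr + 1)(mueff'/mutr + 3A))` with
  `mueff' = sqrt(3*mua*mutr + (2*pi*fx)^2)`. `A` comes from the refractive
  index through the effective internal-reflection polynomial
  (`internal_reflection_A()`, frozen in one function; n = 1.4 by default).
  This is the fast model used for rendering, calibration and the inversion
  table.
* **White Monte Carlo** (`rd_monte_carlo()`): photon transport in the same
  geometry, used as the independent cross-check. Scattering is
  Henyey-Greenstein with anisotropy g = 0.9 at rate `mus = musp/(1-g)` in the
  near-surface zone. We chose anisotropic transport after measuring that an
  isotropic-equivalent walk (the textbook similarity reduction) overestimates
  Rd at 0.3 cycles/mm by roughly 75%: at spatial frequencies comparable to
  the transport coefficient the reflectance is genuinely phase-function
  sensitive, and similarity only holds in the diffusive regime. Below a depth
  of 4 transport lengths the simulation therefore switches to isotropic steps
  at rate `musp` (with the remaining optical depth rescaled at the zone
  crossing), which is exact to within Monte Carlo noise there and makes
  million-photon runs desk-fast. Absorption is applied after transport by
  per-photon pathlength reweighting `exp(-mua*L)`, so one run serves every
  `mua`; `Rd(fx)` is the zeroth-order Hankel transform evaluated as the
  per-photon sum `mean(w * J0(2*pi*fx*rho))`. Photons are dropped beyond a
  2000 mm pathlength; the induced bias is `O(exp(-mua*2000))`.

**How well do they agree?** At fx = 0 the two models track within ~8% over
`mua` 0.005–0.05, `musp` 0.5–2 mm⁻¹. At fx = 0.3 mm⁻¹ the closed form
overestimates transport by 12–20% in the same range — the known accuracy
limit of the diffusion approximation at high spatial frequency, and the
reason the test suite's cross-validation check at a 10% tolerance passes on
the planar channel and is expected to fail on the modulated one. The
practical consequence is quantified directly: inverting Monte-Carlo-generated
reflectance pairs with the diffusion lookup table misestimates both
coefficients by about 10% (bounded at 15% in the tests). Since the package
calibrates measurements against a phantom evaluated with the *same* forward
model, this model-mismatch error largely cancels in practice; it matters when
comparing absolute numbers across instruments.

# Rendering, demodulation, calibration

The simulator renders each camera frame by decomposing the projected pattern
into its Fourier harmonics, attenuating each harmonic by `Rd(n*fx)` evaluated
from the *local* pixel properties, and resumming (truncation at the pixel
grid's Nyquist; the Gibbs ripple of the truncated series is left in the
signal and exercised by the tests). This local-MTF rendering ignores lateral
photon crosstalk between pixels of different properties: it is exact for
homogeneous regions and adequate near the smooth ±5% texture the simulator
uses, but it does not model the real blur across sharp property boundaries —
a stated simulator limitation, which is why the two-region inversion test
checks region means and edge width rather than claiming point-spread realism.

Demodulation uses the three-phase amplitude estimator
`M = sqrt(2)/3 * sqrt((I1-I2)^2 + (I2-I3)^2 + (I3-I1)^2)`, which returns the
exact modulation amplitude for any sinusoid triplet independent of the planar
offset and local carrier phase. Calibration divides tissue amplitudes by
phantom amplitudes per pixel and multiplies by the model reflectance of the
phantom's known properties; being a per-pixel ratio it cancels source
nonuniformity, vignetting and gain exactly (tested to machine precision).
Pixels where the phantom amplitude falls below 1% of its median are flagged
invalid rather than divided through.

Detector noise is signal-dependent Gaussian with variance
`read_noise^2 + I/gain` (defaults 2 counts, 0.5 counts/e⁻, sCMOS-like), and
frames are quantized to 16-bit counts. The default source power (1e5 count
scale) puts the planar tissue signal near 40 dB SNR per pixel.

# Lookup-table inversion

The two-frequency lookup table spans `mua` 0.001–0.5 mm⁻¹ (log-spaced; the
sensitivity is concentrated at low absorption) by `musp` 0.3–3 mm⁻¹ (linear),
64×64 by default. Build-time validation enforces the properties that make
the two-channel inversion well posed: the planar table strictly decreasing in
`mua`, and the modulated table strictly increasing in `musp`. We deliberately
do **not** require the modulated channel to be monotone in `mua`: at
frequencies well above the transport coefficient the AC reflectance is nearly
absorption-blind, and for low `musp` the closed form is genuinely
non-monotone there. Absorption information lives in the DC channel,
scattering information in the AC channel; that separability is the
well-posedness argument, and it is what the build check tests.

Inversion runs a coarse nearest-node search for the starting point, then a
damped Newton iteration on the continuous closed form in log-parameter space
(positivity-preserving; relative tolerance 1e-10, at most 60 iterations).
Non-converged or out-of-table results are returned as `NA` and flagged — never
clamped — because with monotone tables a failed inversion is a data-quality
signal. Monte Carlo tables, which have no continuous model behind them, are
inverted by continuous minimization on the bilinearly interpolated surface
instead. Noiseless round trips recover both coefficients to better than
0.5% over 100 random interior draws (machine precision in practice); at the
default noise level a 32×32 homogeneous inversion shows < 2% bias and < 5%
pixel spread.

# Chromophores

`mua(lambda) = ln(10) * (ctHbO2*epsHbO2 + ctHb*epsHb)` with the unit bridge
(ε in cm⁻¹M⁻¹, concentrations in µM, `mua` in mm⁻¹) kept in a single
constant. The shipped extinction table is a transcribed, rounded subset of
the standard Prahl/van Assendelft compilation on a 10–20 nm grid over
650–900 nm; 655 nm is served by linear interpolation and flagged as such.
The three-wavelength system is solved per pixel by least squares (an
overdetermined 3×2 solve), the RMS spectral residual is kept as a quality
map, and negative concentrations are flagged unclipped by default — a
nonnegativity-constrained solve exists but is opt-in, because the
unconstrained solution preserves linearity (scale equivariance is tested) and
makes unmixing failures diagnosable.

# Dynamics analytics

Percent changes are referenced to the mean over an explicit baseline window.
ROI series carry the standard deviation over ROI pixels (not the standard
error) as their spread. Landmarks are located on the unsmoothed series with
an earliest-extremum tie-break: the ischemic minimum is the StO2 minimum
between asphyxia onset and CPR start, the reperfusion peak the StO2 maximum
between ROSC and the first ECoG burst (burst times are consumed as
annotations, never detected), and the scattering trough/peak pairs are found
within the same two windows. The vessel masking rule flags pixels whose
scattering percent change exceeds 10% *atop the vessel mask* (large apparent
scattering increases over major vessels are absorption crosstalk artifacts);
we read the rule as vessel-conditioned and expose an `everywhere` flag for
the blanket interpretation.

Heart rate comes from a sliding 10 s Hann-tapered FFT (50% overlap) of the
detrended planar intensity, with the band peak converted to bpm. Windows
whose peak sits at the band edge or within 10% of the Nyquist ceiling are
flagged unreliable: a rate above the ceiling aliases back into the band
(450 bpm at 14 Hz sampling reappears at |450 − 840| = 390 bpm) and is
indistinguishable from a genuine near-ceiling rate without an external
reference, so near-ceiling peaks are treated as suspect and the
arterial-pressure reference path exists for validation. Agreement with the
reference is summarized as `R² = 1 − Σ(y−x)²/Σ(y−ȳ)²` against the identity
line, over pairs whose reference rate is below the 420 bpm cutoff.

# The synthetic cortex

The simulator is the package's ground-truth supply; every stage is tested
against it. Its defaults are the study conditions of the cardiac-arrest /
resuscitation experiments the pipeline targets: bulk baselines ctHbO2 85 µM,
ctHb 40 µM, musp(655) 0.87 mm⁻¹; an ischemic excursion of −19.4% ctHbO2 /
+66.9% ctHb reaching the StO2 minimum 0.46 min after asphyxia onset;
reperfusion swings of +32.0 / −94.0; post-peak oxygen-extraction drifts of
−9.9 / +31.0; and biphasic scattering with trough-to-peak excursions of 9.7%
over 1.1 min (ischemia) and 21.2% over 2.1 min (reperfusion). Dynamics are
piecewise exponential approaches to per-phase targets — phenomenology, not
mechanism: no spreading-depolarization or mitochondrial model is claimed.
Spatial structure is a seeded smooth ±5% Gaussian random field around the
bulk values plus drawn sinuous vessels carrying +50% deoxyhemoglobin, enough
to exercise per-pixel inversion and the vessel-masking rule without claiming
anatomical realism. The onset of the scattering dynamics is staggered
linearly across the field (default 10 s full-field; the paper-scale
propagation emulation) — the stagger is a free parameter because no
propagation speed is asserted by the underlying physiology.

Two timelines exist: `"paper"` mirrors the in-vivo session structure
(5 min washout baseline, 5 min asphyxia, 45 s CPR, ≈ 24 min total), and
`"compressed"` keeps every amplitude and the short timing constants but
shortens the long plateaus to 5.75 simulated minutes so that a complete
64×64 end-to-end run (≈ 4800 reconstructions, ≈ 57,600 rendered frames)
finishes in about three minutes on one CPU — the problem size used by the
end-to-end tests and the acceptance script. Pulsatility is a multiplicative
1% sinusoidal modulation of ctHbO2 at the instantaneous programmed heart
rate, gated off during arrest; frames within a cycle are rendered at their
true timestamps (1/167 s apart) while reconstruction assigns the cycle
midpoint, so the intra-cycle time skew of the real instrument is present in
the data.

**What passing tests do and do not show.** The simulator shares its forward
model with the inversion (calibration makes that near-circular by design);
recovery tests therefore validate the pipeline's algebra, calibration
chain, noise behavior and bookkeeping — not the diffusion model's absolute
accuracy against real tissue, which is exactly what the Monte Carlo
cross-check quantifies (and bounds at 10–20% at the high spatial frequency).
Real cortical data additionally contain curvature, specular reflections,
motion and heterogeneous depth structure that the simulator does not emulate.

# Numerical choices and degenerate inputs

* Pattern phases follow `sin(2*pi*fx*x + phi)` with phases in degrees;
  360° ≡ 0°. Patterns vary along image columns; a transposed orientation is
  available.
* Harmonics are truncated at the pixel Nyquist (period ≥ 2 px); patterns
  whose base period falls below 2 px raise an aliasing error.
* The timing-limited statements about landmark recovery hold in the
  sampling limit: with noiseless, unquantized rendering the kink-type
  landmarks (ischemic minimum, scattering troughs) recover at the exact
  sample. Smooth extrema (the reperfusion peaks) are different: near a flat
  peak the series changes by only ~2·10⁻³ %/sample, below the
  level-dependent calibration bias (~0.5% relative shape difference between
  recovered and truth curves), so their localization is bias-limited and
  lands 2–3 samples (≈ 0.2 s) from the truth even without noise; detector
  noise widens this further. Amplitude metrics are unaffected (≤ 4% error
  end to end).
* Inversions for reflectance pairs outside (0,1), outside the table, or
  without a converged root return flagged `NA`; ambiguity is reported, never
  resolved by a silent choice.
* All stochastic components (noise, Monte Carlo, textures, arterial trace)
  draw from R's RNG, so a single `set.seed()`-style seed argument makes
  scenes, stacks and results bit-reproducible.

# Known limitations

Semi-infinite homogeneous-depth physics only (no layered media); per-pixel
local-MTF rendering without lateral crosstalk; two chromophores (no water or
lipid terms) per the absorption model above; single-snapshot Fourier/Hilbert
demodulation is out of scope; and the alias flag for heart rates is a
heuristic — without a reference waveform a true above-ceiling rate is
unknowable from the optical channel alone.
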