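# rapidsfdi

Processing pipeline for **rapid square-wave spatial frequency domain imaging
(SFDI)** of dynamic tissue — built for the regime where cerebral hemodynamics
and scattering change on sub-second time scales (cardiac arrest and
resuscitation, stroke, spreading depolarization, functional activation) and
the field of view is too small for single-snapshot demodulation.

SFDI projects striped illumination onto tissue and measures how strongly each
spatial frequency of the backscattered image is attenuated. Two frequencies
(planar fx = 0 and fx = 0.3 mm⁻¹) separate the absorption coefficient μa from
the reduced scattering coefficient μs′ in every pixel via a lookup-table
inversion of the diffuse-reflectance forward model

    Rd(fx) = 3·A·a′ / ((μeff′/μtr + 1)(μeff′/μtr + 3A)),
    μtr = μa + μs′,  a′ = μs′/μtr,  μeff′ = sqrt(3·μa·μtr + (2π·fx)²),

with A the internal-reflection parameter of the tissue–air boundary. Three
wavelengths (655/730/850 nm) then unmix the absorption maps through
μa(λ) = 2.303·(ctHbO₂·εHbO₂ + ctHb·εHb) into oxy-/deoxyhemoglobin
concentrations and the oxygen saturation StO₂ = ctHbO₂/(ctHbO₂ + ctHb).

Speed comes from **binary square-wave projection**: binary patterns refresh
much faster than grayscale sinusoids, tissue low-pass filters away the higher
odd harmonics, and the three-phase demodulator
M = (√2/3)·√((I₁−I₂)² + (I₂−I₃)² + (I₃−I₁)²) cancels every 3rd-order harmonic
exactly. A 12-frame sequence (per wavelength: planar + three phases) at a
167 Hz camera gives property maps at 167/12 ≈ 14 Hz and an optical heart-rate
ceiling of (14/2)·60 = 420 bpm.

The package covers the full chain — acquisition-sequence modeling, frame
rendering, three-phase demodulation, phantom calibration, LUT inversion
(diffusion closed form, cross-checked against a white Monte Carlo transport
simulation), hemoglobin unmixing, and dynamics analytics (baseline-referenced
percent changes, phase-landmark metrics, vessel masking, FFT heart-rate
extraction) — plus a **ground-truthed synthetic cortex simulator** that
renders complete cardiac-arrest/CPR experiments into raw 16-bit frame stacks,
so every stage is testable end to end without any instrument data.

## Worked example

```r
library(rapidsfdi)

# forward model: cortical baseline optics at 655 nm
cortex <- optical_props(mua = 0.02, musp = 0.87)
rd_diffusion(cortex, fx = c(0, 0.3))
#> [1] 0.4966029 0.0554626

# acquisition arithmetic for the default 3-wavelength, 3-phase sequence
effective_rates(acq_config())
#>   frames_per_cycle reconstruction_rate_hz nyquist_hr_bpm
#> 1               12                   13.9           418.

# invert a reflectance pair back to optical properties
lut <- build_lut()
invert_pixel(rd_diffusion(cortex, 0), rd_diffusion(cortex, 0.3), lut)
#> $mua  0.02
#> $musp 0.87

# unmix a three-wavelength absorption spectrum into hemoglobin maps
eps <- extinction_at(extinction_table(), c(655, 730, 850))
mua_maps <- lapply(mua_from_chromophores(85, 40, eps), function(m) matrix(m, 2, 2))
unmix(mua_maps, c(655, 730, 850))
#> <chromophore_maps> 2x2 px, median ctHbO2 85 uM, ctHb 40 uM, StO2 0.680
```

Reading the numbers: the medium returns 49.7% of the injected diffuse light
in the planar channel but only 5.5% at 0.3 cycles/mm (scattering media are
spatial low-pass filters); the 12-frame sequence reconstructs at 13.9 Hz,
putting the aliasing ceiling for optically sampled pulsation near 420 bpm;
the inversion recovers exactly the (μa, μs′) that generated the pair; and a
spectrum composed from 85 µM HbO₂ / 40 µM Hb unmixes back to those
concentrations with StO₂ = 85/125 = 0.68.

For a full synthetic experiment, `scene_truth()` + `process_experiment()`
render and process a complete arrest/resuscitation run (64×64 px at 14 Hz)
and return recovered and ground-truth ROI series side by side;
`phase_metrics()` then extracts the landmark excursions (ischemic StO₂
minimum, reperfusion peak, biphasic scattering trough-to-peak amplitudes and
durations) and `heart_rate_fft()` the pulse rate from the planar intensity.

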