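# holocount

Off-axis digital holographic microscopy (DHM) processing in R: reconstruct
the complex object wavefield from a single off-axis hologram, numerically
refocus it through a microfluidic chamber into a 3D phase stack, and
segment and count the suspended particles — silica microspheres or model
bacteria — in one exposure.  The package also implements the analytic
phase-noise model that predicts the signal-to-noise ratio (SNR) of such a
measurement, and ships a seeded synthetic hologram generator with full
ground truth, so the whole chain is testable end to end without an
instrument.

Who it is for: developers of DHM-based counting assays (e.g. single-cell
antimicrobial susceptibility testing in microfluidic cartridges) who need
a reference implementation of the numerical pipeline and a quantitative
way to dimension chamber height, concentration range and optics before
building hardware.

## The models at the core

**Reconstruction.** An off-axis hologram `I = |U_O + U_R|²` carries the
object wave on a spatial carrier. The pipeline demodulates the +1 order
with a super-Gaussian Fourier window, unwraps the phase (least-squares /
DCT with congruence restoration), subtracts a Zernike aberration mask
(Noll terms, default 15), and propagates the corrected field with the
angular spectrum method to a z-stack of phase maps `φ_z` spanning the
chamber (±125 µm for a 200 µm chamber, 0.5 µm steps), with Nagahama-style
ringing-artifact extraction available for hard-edged apertures.  The stack
is thresholded, opened with a shape-matched 3D structuring element,
26-connected-labelled, volume-filtered, and converted to particles/mL.

**SNR model.** With per-plane RMS noise averaged over planes,
`⟨φ_N⟩(c, L) = L(k₁c² + k₂c) + φ_N0`, the phase signal of a thin particle
`⟨φ_S⟩ = 2πd(n_S − n_M)/λ`, and `SNR = ⟨φ_S⟩/⟨φ_N⟩`, with shipped
constants `k₁ = −55 rad µm⁵/particles²`, `k₂ = 0.78 rad µm²/particle`,
`φ_N0 = 0.1 rad` (c in particles/µm³, L in µm).  `fit_noise_params()`
estimates `(k₁, k₂)` from measured dilution series by linear least
squares and returns a classed model object with `coef`/`predict`/`print`
methods.

## Worked example

```r
library(holocount)

# predicted SNR for a 1 µm bacterium at 5e7 cells/mL in a 200 µm chamber
p <- noise_params()            # k1 = -55, k2 = 0.78, phi_N0 = 0.1
q <- predict_snr(d = 1, n_s = 1.388, c = 5e7 / 1e12, L = 200, params = p)
q$snr
#> [1] 6.17
q$attenuation_db
#> [1] -0.65

# simulate a microsphere suspension and count it back
cfg   <- holo_config(chamber_height = 200, particle = "microsphere",
                     grid = 256L, seed = 1)
fov   <- cfg$grid * cfg$pitch                      # ~30 µm sub-field
scene <- generate_scene(6.76e7 / 1e12, fov, fov, 200,
                        particle_preset("microsphere"), seed = 1)
scene
#> <holo_scene> 9 sphere(s) in 30 x 30 x 200 um^3 (c = 5.02e-05/um^3 = 5.02e+07/mL), phiN0 0.1 rad
holo   <- simulate_hologram(scene, acquisition_spec(grid = cfg$grid))
report <- run_count_pipeline(holo, cfg)
report
#> <count_report> 1 frame(s) (0 excluded): mean count 9, CV 0%, 6.195e+07 /mL
```

The scene drew 9 particles (Poisson at the requested density, i.e. a true
realized concentration of 5.0×10⁷/mL in this sub-field); the full
reconstruct → refocus → segment → count chain recovers all 9 and reports
6.2×10⁷/mL over the guarded measurement volume, with the frame's measured
mean phase noise (0.102 rad, against the injected 0.1 rad base level) and
its estimated SNR (10.1) attached for quality gating.

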