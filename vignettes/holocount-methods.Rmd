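---
title: "Counting suspended particles with off-axis digital holographic microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting suspended particles with off-axis DHM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

holocount implements the numerical side of a single-shot workflow for
counting micrometre-scale particles — silica microspheres and model
bacteria — suspended in microfluidic chambers, imaged with an off-axis
digital holographic microscope (DHM).  One hologram encodes the complex
object wavefield; numerical refocusing turns that one exposure into a 3D
phase stack spanning the whole chamber height, which is then segmented and
counted.  The package also implements the analytic phase-noise model that
predicts when this measurement stops working: the signal-to-noise ratio of
a particle's phase as a function of its size and refractive index, the
suspension concentration, and the chamber height.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the known limitations.  It states no
empirical result beyond what the package's tests and acceptance script
themselves compute.

## 1. The reconstruction chain

An off-axis hologram is the interference intensity
$I = |U_O + U_R|^2$ between the object wavefield $U_O$ and a tilted
reference wave $U_R$.  The tilt moves the information-bearing cross term
onto a spatial carrier, so a single Fourier transform separates the real
image from its twin and from the autocorrelation (DC) term.

`isolate_real_image()` performs that separation: FFT, a super-Gaussian
window $\exp\{-[(x-c_x)^2/\sigma_x^2+(y-c_y)^2/\sigma_y^2]^n\}$ centred on
the +1 order, an integer spectral shift of the order to DC, inverse FFT.
The soft window (default order 6, $\sigma$ = 45% of the DC-to-carrier
distance) avoids the ringing a hard aperture would cause.  The carrier is
auto-detected as the spectral maximum in the $+f_y$ half-plane outside a DC
exclusion disk (radius 5% of the spectral half-width); a hologram with no
such peak raises a carrier-not-found error.

**Carrier parameterisation.**  The instrument images through a 50x
objective, so the reference tilt recorded in camera space corresponds, in
object-space coordinates, to carrier frequencies that may exceed
$1/\lambda$ — an "equivalent tilt" with $\sin\theta > 1$, which no physical
object-space plane wave could produce.  `acquisition_spec()` therefore
accepts the carrier directly as a spatial frequency in cycles/µm (default
$0.3/\text{pitch}$, i.e. 60% of Nyquist, along $+y$), and uses
$\sin(\theta_y)/\lambda$ only when a physical tilt is supplied.  The only
hard constraint is sampling: the carrier must stay below the Nyquist
frequency $1/(2\,\text{pitch})$.  By default the simulator snaps the
carrier to the nearest DFT bin so that demodulation by an integer spectral
shift is exact; any residual (sub-pixel) tilt is absorbed by the Zernike
tilt terms in the aberration mask.

`correct_aberrations()` then unwraps the phase and subtracts a Zernike
aberration mask: a least-squares projection onto the first `n_terms` Noll
polynomials (default 15, through primary spherical aberration — the
reference instrument needs only "sufficiently many" low orders).  Piston is
included in the mask, so the corrected background has mean ≈ 0, which the
downstream fixed threshold relies on.  Two numerical points:

* **Fit disk.**  The mask is fitted and evaluated over a disk that
  *circumscribes* the grid.  Noll polynomials extrapolated beyond their fit
  disk grow like $\rho^n$; fitting on an inscribed disk and evaluating at
  the corners ($\rho = \sqrt 2$) turns coefficients of a few hundredths of
  a radian into ~0.5 rad corner artifacts.  With the circumscribed mapping
  every pixel satisfies $\rho \le 1$ and the mask stays bounded.
* **Unwrapping.**  2D unwrapping is the unweighted least-squares (discrete
  Poisson) solution computed with DCTs, then snapped back to the lattice
  congruent with the wrapped input (the snap is centred with the circular
  mean of the residual so rounding never sits on a half-cycle boundary).
  The contract is modest by design: output ≡ input (mod 2π) everywhere,
  and no spurious 2π jumps over smooth regions.  A residual-wrap score
  (fraction of neighbour differences exceeding π) is attached to every
  corrected field; dense suspensions with unresolvable wraps are flagged
  rather than silently processed.

## 2. Refocusing and ringing suppression

`propagate_angular_spectrum()` is the exact scalar propagator: multiply the
spectrum by $\exp(i 2\pi z \sqrt{(n_M/\lambda)^2 - f_x^2 - f_y^2})$, with
evanescent frequencies zeroed (hard zeroing — the imaging regime never
relies on them) and in-medium wavelength $\lambda/n_M$, since the chamber
contents are aqueous ($n_M = 1.333$).  Band-limited fields conserve energy
to machine precision and propagation composes over distances; an optional
anti-aliasing band-limit factor exists but defaults to off, as the default
geometry shows no wrap-around artifacts over the ±225 µm range.

`refocus_stack()` propagates the corrected field to a uniform z-grid and
stores the piston-removed wrapped phase per plane.  The chamber occupies
$[-L/2, +L/2]$ around the hologram plane (the exposure is captured near the
chamber mid-height); the standard presets refocus over ±125 µm (200 µm
chamber) and ±225 µm (400 µm chamber) at 0.5 µm steps.  Per-slice 2D
unwrapping is available but off by default: particle phases of ≤ 2 rad on a
~0.1 rad background essentially never wrap, and 500 unwraps per stack are
pure overhead.

**Ringing artifact extraction.**  Numerical refocusing drags edge
diffraction through the stack.  The correction propagates an idealized
constant-phase field with the same aperture envelope to each plane and
subtracts its phase from the measured slice (on the wrapped phase, before
any unwrapping; subtracting before keeps the reference and the measurement
on the same branch).  The reference envelope defaults to uniform over the
grid — under periodic DFT boundary conditions a uniform field propagates
into itself, so the default correction reduces to piston removal and costs
nothing; supplying the true aperture (e.g. a hard-edged window embedded in
padding) cancels its diffraction ringing exactly for the empty field, by
construction.  References are cached per (grid, pitch, wavelength, medium,
z, envelope).

## 3. Segmentation and counting

The phase volume is thresholded at $\tau$, morphologically opened with a
volumetric structuring element, and 26-connected components are labelled
(compiled code; the element is built in physical units, so the lateral
pitch / axial step anisotropy is handled explicitly).

* **Threshold.**  Default $\tau = 0.5\,\langle\phi_S\rangle$, half the
  predicted phase signal of the configured particle (below).
* **Element.**  Spherical for spheres, cube-shaped for rods, sized to
  *half* the particle diameter by default.  At $\tau$ = half the peak, a
  spherical phase profile exceeds threshold over a diameter of
  $\sqrt{3}/2\,d \approx 0.87\,d$; an element of a full diameter $d$ can
  never fit inside that core and erases every true particle, while $d/2$
  fits at any sub-pixel alignment and still removes single-voxel speckle.
* **Physical culls.**  Components whose centroid lies outside the chamber
  ($|z| > L/2$) cannot be particles — the refocus margin exists only to
  capture focus curves — and components inside a 1.5 µm lateral guard band
  sit where the periodic spectral processing corrupts the reconstruction.
  Both are removed, and the measurement volume shrinks to the guarded
  field, keeping the concentration unbiased.
* **Statistical filter.**  Components below $f_\text{low}$ (default 0.3)
  times the median volume are debris; components above $f_\text{high}$
  times the median are kept and flagged as clusters.  The default
  $f_\text{high} = 3$ is deliberately loose: under a coherent background
  the supra-threshold footprint of identical particles varies severalfold,
  and a tight gate misclassifies ordinary singles as clusters, which the
  splitting step then multiplies.  A peak gate (default 75% of
  $\langle\phi_S\rangle$) removes regions whose maximum never approaches
  the signal a real particle must produce.
* **Cluster splitting.**  Each structure contributes
  $\max(1, \text{round}(V/V_\text{avg}))$ particles, $V_\text{avg}$ being
  the mean volume of the non-cluster components, so touching cells are
  divided by the average single-cell volume.  Particles elongate axially in
  the stack (the focus curve spans several slices); no de-elongation is
  attempted because only the ratio $V/V_\text{avg}$ enters, which cancels
  the elongation factor.

Counts divide by the measurement volume — $w \times h \times L$, e.g.
120 × 120 × 200 µm³ = 2.88 nL — to give particles/mL.  Replicate statistics
report the coefficient of variation as the population standard deviation
over the mean, in percent.

**Frame quality gating.**  Two per-frame gates mirror the practice of
discarding unusable acquisitions of dense suspensions: the residual-wrap
score (default limit 1%) and a Rose-criterion SNR gate — frames whose
estimated SNR $\langle\phi_S\rangle / \langle\phi_N\rangle_\text{measured}$
falls below 5 are excluded from replicate statistics (the classic threshold
for reliable detection of a feature against background fluctuations).
Excluded frames remain in the per-frame table, and their noise statistic
still feeds the noise-model fit, which needs exactly those dense levels.

## 4. The phase-noise / SNR model

The mean phase noise of a stack is
$\langle\phi_N\rangle = \frac{1}{N_z}\sum_z s_z$ with
$s_z = \sqrt{\sum_{x,y} (\phi_z - \langle\phi_z\rangle)^2 / N_{xy}}$ — the
per-plane RMS deviation averaged over planes.  We adopt the RMS reading
(rather than a mean of variances) because the base level carries units of
radians and the SNR divides a radian-valued signal by it; the mean-variance
variant is available behind `variance = TRUE`.

The noise model and its companions are

$$\hat{\langle\phi_N\rangle}(c, L) = L\,(k_1 c^2 + k_2 c) + \phi_{N0},
\qquad
\langle\phi_S\rangle = \frac{2\pi d (n_S - n_M)}{\lambda},
\qquad
\langle SNR\rangle = \frac{\langle\phi_S\rangle}{\hat{\langle\phi_N\rangle}},$$

with $c$ in particles/µm³ and $L$ in µm.  The shipped constants are the
microsphere-fitted values $k_1 = -55$ rad µm⁵/particles²,
$k_2 = 0.78$ rad µm²/particle and $\phi_{N0} = 0.1$ rad (the base level
measured on an empty chamber).  `noise_params()` verifies at construction
that the prediction stays positive over the declared validity range; the
quadratic's vertex sits near $7 \times 10^{-3}$ particles/µm³, far above
every concentration of interest.  Public interfaces accept cells/mL and
divide by $10^{12}$ internally.  Attenuation helpers report
$20\log_{10}(SNR(c)/SNR(0))$ in dB — the convention under which a −1.5 dB
drop pairs with ≈ 15% — and $100\,(1 - SNR(c)/SNR(0))$ in percent.

`fit_noise_params()` is the package's one classical model fit: the model is
linear in $(k_1, k_2)$ given $\phi_{N0}$, so it is an ordinary least-squares
fit (via `lm`) of $\langle\phi_N\rangle - \phi_{N0}$ on $(L c^2, L c)$, with
$\phi_{N0}$ held fixed at its empty-chamber value by default and jointly
estimable behind `fit_phi_n0 = TRUE`.  Heights enter as a regressor, so
series at several chamber heights are fitted jointly.  The returned object
follows the standard modelling idiom (`print`, `coef`, `predict`,
`summary`, `residuals`).  A design with fewer than two distinct non-zero
concentrations is refused as underdetermined.

Suspension arithmetic: a 5% w/v suspension of 0.985 µm silica spheres at
1.85 g/cm³ contains $0.05 / (\rho \frac{\pi}{6} d^3) \approx 5.4\times
10^{10}$ particles/mL (`stock_concentration()`); OD600 conversion constants
for the two model organisms (7 and 5 × 10⁸ cells/mL at OD600 = 1) are
shipped as documented approximations for labelling simulated bacterial
series.

## 5. The synthetic-data generator

`generate_scene()` draws a Poisson number of particles at the target
density, uniformly in the chamber box, with rod orientations uniform on the
sphere unless fixed; everything is reproducible from the seed.
`simulate_hologram()` is a multislice thin-object forward model: particles
are binned to axial slabs at the refocus step, each slab multiplies the
object wave by its projected phase mask
$\phi(x,y) = 2\pi (n_S - n_M)\, t(x,y)/\lambda$ ($t$ = chord thickness:
analytic for spheres and for rods perpendicular or parallel to the axis,
midpoint quadrature for oblique rods; rods are capsules — cylinders with
hemispherical caps, the standard E. coli approximation), and the angular
spectrum method propagates between slabs and to the focus plane.  A tilted
plane reference is added and $|\cdot|^2$ recorded; Poisson shot noise is
available behind a flag but off by default, since the reference camera's
noise was never quantified.

The base-level noise $\phi_{N0}$ is emulated as a single smoothed
Gaussian phase screen at the chamber mid-plane (the physical sources —
surface roughness, material inhomogeneity — are chamber-bound, but no
axial distribution is documented, so one thin screen is the simplest
faithful choice).  Its correlation length defaults to 1 µm, the
diffraction scale of the imaging system, which is where roughness-induced
speckle lives.  The screen is injected with RMS $\sqrt 2 \times$ the
target: away from its own plane a thin phase screen's fluctuation power
divides evenly between the phase and amplitude quadratures, so the
volume-averaged phase-noise statistic of an empty-chamber reconstruction
then matches the configured $\phi_{N0}$ (0.1 rad by default).

Default acquisition is a 256² grid at 0.117 µm/pixel — a ~30 µm sub-field
of the instrument's 120 × 120 µm area, keeping a full 501-slice stack at
desk scale; `grid = 1024` reproduces the full field.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: partial coherence (the real source's ~200 µm
coherence length attenuates interference from distant scatterers and the
fringe contrast towards the field edges — the fully coherent model
*overestimates* the speckle background of dense suspensions), the
objective's NA-limited pupil (an optional low-pass is exposed but not
calibrated), multiple scattering and Mie effects, and camera noise beyond
optional Poisson statistics.  Because the single-scatter coherent model
need not reproduce the empirically fitted noise curve, the in-silico
dilution study asserts only that its own fitted noise curve is monotone
increasing over the measured range — it makes no claim of regenerating
$k_1$ and $k_2$.

## 6. Problem sizes and test design

The test suite runs everything at desk scale, chosen once: unit tests use
48–128² grids; the reconstruction round-trip, focal localization
(±125 µm at 0.5 µm steps) and empty-chamber noise checks use the default
256² sub-field; the dilution study simulates the series
1:10 … 1:8000 of the 5.4 × 10¹⁰/mL stock at 200 µm chamber height, 256²
grid, 0.5 µm steps, with three replicates per level and six at the two
sparsest levels (the pooled Poisson statistics at ≲ 3 expected
particles/field need them).  Under the Rose gate the two densest levels
(estimated SNR ≈ 1.9 and 4.4 under this fully coherent forward model) are
excluded from counting statistics, exactly as unusable dense acquisitions
are discarded in practice; the log-log recovery regression runs on the
retained levels, and the noise-model fit uses all frames with resolvable
wraps.

## 7. Known limitations

* Counting accuracy degrades continuously as the measured SNR approaches
  the Rose limit; below it, thresholding counts coherent speckle grains
  and no volume statistic distinguishes them from particles.  The SNR
  model exists precisely to predict this boundary in advance.
* Cluster splitting by $V/V_\text{avg}$ assumes volumes add; under
  coherent interference merged particles swell super-linearly, so split
  counts at high density are upper estimates.
* Axial localization is accurate to about the slice spacing (±1 µm at
  0.5 µm steps for a 1 µm sphere); no sub-step super-resolution is
  attempted.
* The least-squares unwrapper guarantees congruence, not correctness, in
  regions of genuine phase aliasing; such frames are meant to be caught by
  the residual-wrap gate, not repaired.
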