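---
title: "Holographic FD-DCS signal processing: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holographic FD-DCS signal processing: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Fourier-domain diffuse correlation spectroscopy (FD-DCS) measures blood-flow
surrogates by sampling the first-order power spectral density (PSD) of
multiply scattered coherent light instead of its temporal autocorrelation.
The instrument this package models is a heterodyne off-axis holographic
camera system: light returning from a turbid sample through a circular
collection aperture interferes, on a camera, with a strong reference beam
that has been frequency shifted by a detuning $\Delta f$. By the
Wiener–Khinchin theorem the PSD $s_1(\omega)$ of the field fluctuations is
the Fourier transform of the field autocorrelation $g_1(\tau)$, so scanning
$\Delta f$ samples the same physical information as a correlator — but with
an inexpensive, slow, massively parallel detector.

Processing proceeds per camera frame stack:

1. **Temporal filtering** forms camera-plane holograms $H_C$: sliding
   differences of successive frames (`dc_pair`, $I_n - I_{n+1}$), the
   difference against the first frame (`first_frame`), or the identity
   (`single_frame`, used after SVD decluttering).
2. **Reconstruction**: $H_R = |\mathcal{F}_{2D}(H_C)|^2$ with the
   unnormalised forward DFT and the zero-frequency bin moved to the grid
   centre. The off-axis geometry separates the two conjugate heterodyne
   twin images from the homodyne terms around DC.
3. **Shot-noise normalisation**: with $\bar N$ the mean of $H_R$ over a
   mask in a quiet corner (pure photon noise), the per-pixel signal is
   $S_1 = (H_R/\bar N - 1)/\mathrm{MTF}(k_x,k_y)$ and $\bar S_1(\Delta\omega)$
   is the mean of $S_1$ over the heterodyne masks. The MTF of the pixel
   aperture, $\mathrm{MTF} = |\mathrm{sinc}(\alpha \Delta_x k_x)\,
   \mathrm{sinc}(\alpha \Delta_y k_y)|^2$ with fill factor $\alpha$, is not
   applied to the shot-noise estimate because photon noise is white.
4. Optional **SVD decluttering** of the space–time matrix (frames as
   columns), **sort–median–unsort denoising** of the masked $S_1$ values,
   and a **Lorentzian fit** of $\bar S_1$ across detunings.

All masks are closed discs on the integer lattice
($x^2+y^2 \le r^2$): a radius-80 disc contains 20081 pixels, the signal
mask size used throughout at the reference 512 px scale. The conjugate
twin mask is the exact point reflection of the signal mask through the
origin. The default carrier sits at $5N/16$ on the diagonal: intensity
holograms contain a sample-sample self-beating term occupying a disc of
radius $2 r_f$ around DC, so the off-axis separation must satisfy
$|k_c| \ge 3 r_f$ for the heterodyne band to stay clean (the
configuration validator warns when it does not).

## The synthetic-data generator

No public raw data exist for instruments of this type, so the package
ships a physics-level simulator that every claim is validated against.

**Field model.** The sample field at the camera is synthesised directly in
the spatial-frequency domain: independent circular complex Gaussian modes
on a closed disc of radius $r_f$ centred at the off-axis carrier. This
reproduces the statistics of a lensless Fourier geometry (the
reconstruction plane is the aperture plane) without modelling the light
guide. By default $r_f$ is derived from the reference instrument geometry
— wavelength 785 nm, observation distance 76.84 mm, 5.0 mm circular
aperture, 3.45 µm pixels — so that the camera-plane speckle area equals
the optical value $S = (\lambda z)^2 / A_{aperture} = 15.57$ px, i.e.
$r_f = \sqrt{N^2 / (\pi S)}$ (73.2 px at $N = 512$). Each mode evolves as
an AR(1) process whose lag autocorrelation equals $g_1$ at the substep
interval; for the exponential model $g_1(\tau) = e^{-|\tau|/\tau_c}$ the
AR coefficient is $e^{-\delta t/\tau_c}$ and the discrete autocorrelation
is exact at all lags. Plug-in $g_1$ shapes are mapped to a constant lag-1
coefficient $g_1(\delta t)/g_1(0)$; this matches the plug-in exactly only
at lag one (exponential decay is the only shape an AR(1) reproduces at
every lag), which is the accuracy the stand-in fitting model warrants.

**Exposure and substeps.** Frames are acquired back to back with exposure
$T$ (default 5 ms, a 200 Hz camera). Each exposure is integrated over
substeps chosen as
$\max(8,\ \lceil \Delta\omega T / (\pi/4) \rceil,\ \lceil 2T/\tau_c \rceil)$
so both the heterodyne beat and the field decorrelation are resolved; an
explicit substep count below either bound is an error.

**Detector.** Per substep the intensity is
$|R e^{i\Delta\omega t} + E|^2$ with a uniform reference of
`reference_photoelectrons_per_pixel` (default 200 e⁻/frame) and mean
sample intensity `sample_to_reference_ratio` times that (default 0.1).
The finite pixel fill factor is applied in one of two equivalent ways:

* `oversample_factor = 1`: the band-limited intensity spectrum is
  multiplied by $\mathrm{sinc}(\alpha u)\,\mathrm{sinc}(\alpha v)$ —
  *exact* continuous integration over the active pixel area, because the
  configuration invariants keep the whole intensity spectrum inside
  Nyquist. This is what makes full-scale (512×512×501) runs affordable.
* `oversample_factor = m > 1`: the field is synthesised on an $m\times$
  finer grid and averaged over the active $\alpha\times\alpha$ sub-region
  of each pixel, with area weighting of fractional boundary sub-samples.
  The window is centred on the coarse sample point so that both routes
  share the same registration; they agree to within the sub-sample
  discretisation error (3% at $m = 5$, tested).

Then Poisson shot noise, Gaussian read noise (default 2.45 e⁻ RMS) and
ADC quantisation (default 5.73 e⁻/count, 12 bit, floor then clip) — the
read-noise and quantisation figures of the reference camera.

**Clutter.** Three injectable nonidealities:

* *Mode hops* — at a hop frame the laser settles into a new longitudinal
  mode: mode amplitudes are redrawn, the output power takes a persistent
  ±3–8% jump, and the heterodyne term of the hop exposure is suppressed
  entirely (the laser frequency transient is many orders faster than the
  detuning, so the beat integrates to zero). Consecutive frames are
  already mutually incoherent whenever $\tau_c \ll T$, so it is the
  within-exposure washout, not the coherence break, that produces the
  characteristic negative-going $\bar S_1$ outlier under dc-pair
  filtering; the power jump produces the intensity step that first-frame
  filtering reveals.
* *Global power modulation* — frame $t$ multiplied by $1 + w_t$. Worth
  knowing: the per-frame shot-noise normalisation cancels a purely global
  modulation exactly ($\bar S_1$ is scale-invariant), so this clutter is
  visible in the singular spectrum but harmless to dc-pair $\bar S_1$.
* *Coherent beat notes* — a static stray-reflection pattern (band-limited
  like the sample field) beating with the reference at a fixed frequency.
  This is spatially structured, lands inside the heterodyne band, is
  rank-2 in the space–time matrix, and degrades dc-pair SNR when the beat
  is outside the dc-pair stopband — the clutter class that SVD
  decluttering exists to remove.

**Determinism.** All randomness flows from `rng_seed` through two
substreams (field, detector noise), so the fused streaming simulator and
the composed `make_field_stack() |> detector_integrate()` path are
bit-for-bit identical, and identical configurations reproduce identical
stacks.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `grid_size` | 512 | px | reference sensor crop; smaller grids scale the geometry |
| `carrier_offset` | $5N/16$ on the diagonal | cycles/frame | twin images clear of DC, of each other, and of the self-beating disc |
| `aperture_radius_freq` | from geometry (73.2 at 512) | px | sets speckle area 15.57 px |
| `tau_c` | 1e-3 | s | desk-scale phantom correlation time; real tissue values (10–100 µs) would need proportionally more substeps |
| `detuning_hz` | 100 (single); 25–800 (spectra) | Hz | spans the Lorentzian knee $1/2\pi\tau_c \approx 159$ Hz |
| `exposure_time` | 5e-3 | s | 200 Hz camera |
| `fill_factor` | 0.72 | — | the effective fill factor fitted for the reference camera |
| `read_noise` | 2.45 | e⁻ RMS | reference camera |
| `quantisation_gain` | 5.73 | e⁻/count | reference camera quantisation interval |
| `n_frames` | 501 | — | 500 dc-pair holograms per stack |
| denoise window `n` | 3 | frames | smallest window that restores $\sqrt{N}$ SNR scaling; larger `n` trades temporal resolution for SNR |
| SVD `nc` | chosen by inspection (`suggest_nc()` is advisory) | — | number of elevated singular values |

## Fill-factor calibration

On a spatially flat sample the mean reconstructed $S_1$ image should be
flat; the MTF tilts it. `fit_fill_factor()` sweeps $\alpha$ over a
101-point grid, corrects the mean image, and minimises the variance over
the union of the two heterodyne masks (the twin images carry the same
information; outside them $S_1$ is noise), refining the argmin by
golden-section search to $10^{-3}$. Alternative flatness objectives
(radial-profile gradient, symmetry measures) can be supplied as plug-in
functions. Two practical constraints: the calibration masks must lie
inside the illuminated image support (pixels outside the twin image carry
no MTF information and corrupt the variance), and several hundred frames
are needed — with fewer, the noise term of the variance (inflated by the
$1/\mathrm{MTF}^2_\alpha$ correction at high spatial frequency) biases
the argmin low. The estimate is invariant to global intensity rescaling.

## Sort–median–unsort denoising

The masked $S_1$ values of each reconstructed hologram are one random
spatial sample of a fixed distribution. Sorting each column of the
space–time matrix $R$ removes the spatial randomness; a $[1\times n]$
median filter along time then removes detector noise, which after
reconstruction behaves as an extra speckle-like noise; inverting each
column's permutation restores the spatial arrangement of ranks exactly.
Window placement uses offsets $-\lfloor (n-1)/2 \rfloor \ldots$ (centred
for odd $n$); the median of an even window is the mean of the two central
order statistics; edges are replicate-padded (configurable policy slot —
replicate keeps output length equal to input).

Two consequences verified by the test suite:

* sub-mask sampling noise is *preserved* (the ranks a small mask draws are
  untouched), so single-speckle SNR is essentially unchanged, while the
  full-mask series is smoothed — this is precisely what restores the
  $\sqrt{N_{speckles}}$ SNR scaling that detector and normalisation noise
  break;
* the central tendency moves by well under 0.5%, and fitted correlation
  times of control and denoised spectra agree to better than 0.1%.

## SNR accounting

$\mathrm{SNR} = \mu/\sigma$ over the $\bar S_1$ repeats, with the sample
(N−1) standard deviation — the convention is fixed for reproducibility;
at 500 repeats the choice is numerically minor. Speckle counts are
real-valued, `mask pixels / speckle_px`. The single-speckle reference of
the SNR gain is the concentric mask whose pixel count is *closest* to one
speckle area — 13 px (radius 2) against 15.57 px/speckle; the nearest
alternative (21 px) contains 1.35 speckles and would understate the gain
systematically. Reduced masks are concentric with the full signal mask.

At the full scale (512², 501 frames, mask radius 80 = 20081 px ≈ 1290
speckles) the simulated pipeline with dc-pair filtering, MTF correction
and $n=3$ denoising yields an SNR gain of 37–39 across seeds, within a
few percent of the $\sqrt{20081/13} \approx 39$ ideal (the last mask
annulus extends slightly beyond the illuminated disc, which costs a
little); without denoising the gain saturates near 27 because the
shot-mask normalisation noise (a common-mode fluctuation of order
$1/\sqrt{m_{shot}}$ per frame) flattens the curve at high speckle
counts.
The `n = 4` window exceeds the $\sqrt{N}$ line by reducing the
independence of consecutive holograms — gain without a matching loss of
temporal resolution is not free.

## Spectrum fitting

Only the exponential-$g_1$ stand-in ships: the closed-form Lorentzian
$s_1(\omega) = 2\tau_c/(1+\omega^2\tau_c^2)$, with plug-in $g_1$ models
evaluated by adaptive quadrature (rel. tol. $10^{-8}$). The fit profiles
the amplitude out in closed form and optimises $\log \tau_c$ from five
log-spaced starts (deterministic). The mapping to a Brownian flow
parameter is a *labelled placeholder* $D_b = k/\tau_c$: the true mapping
requires the semi-infinite correlation-diffusion detection model, which
is deliberately out of scope; `db_hat` is not interpretable in absolute
units and the model tag says so.

**Finite exposure and the dc-pair transfer.** A camera integrating over
$T$ sees the PSD through a triangular lag window, and dc-pair filtering
of *contiguous* exposures additionally subtracts the cross-frame
covariance $c(\omega) = \mathrm{Re}[(1-E)^2/s^2]/T$ (with
$s = 1/\tau_c - i\omega$, $E = e^{-sT}$), because adjacent exposures
contain field lags all the way down to zero. Both effects suppress the
low-detuning response; ignoring them biases a plain Lorentzian fit low
by roughly 15% at $T = 5\tau_c$ (verified against an exact discrete
oracle). Real-tissue regimes ($T \gtrsim 100\tau_c$) are essentially
unaffected; desk-scale simulations are not. `model_psd()` and `fit_db()`
accept `exposure_time` and `filter = "dc_pair"` to use the closed-form
corrected model; the parameter-recovery validation uses it and recovers
$\tau_c$ to ~1% at 500 frames per detuning.

## Problem sizes used in validation

The packaged checks run at the sizes the science requires and no larger:
the SNR-gain and scaling analysis at the full 512×512×501 configuration
(one detuning); fill-factor recovery at 128×128 with a 25× oversampled
detector and 501 frames; $\tau_c$ recovery at 64×64 with six detunings ×
501 frames and doubled substep resolution; all remaining properties at
48–128 px with 40–400 frames. The 64–128 px configurations keep the same
relative geometry (carrier at $N/4$, mask radius $80N/512$), so mask
pixel counts and mode counts scale by $N^2/512^2$.

## What the simulator does and does not emulate

Captured: off-axis heterodyne geometry and twin-image statistics, correct
speckle area from the instrument optics, fully developed speckle
(contrast ≈ 1), exponential field decorrelation, finite-exposure beat
integration, pixel fill-factor MTF, shot/read/quantisation noise,
mode-hop phenomenology, global and coherent clutter. Not captured: the
liquid-light-guide transfer matrix and its motion sensitivity, laser
cavity dynamics beyond the hop phenomenology, pixel nonuniformity (PRNU),
spatially structured reference beams, ambient light, and the true
correlation-diffusion $g_1$ of a semi-infinite turbid medium. Passing
tests therefore demonstrate the correctness of the *signal-processing
chain* under a faithful statistical model of the detection physics, not
the accuracy of any tissue model.

## Numerical choices and degenerate inputs

DFT convention: forward unnormalised, centre-shifted output
($\sum H_R = N_{pix} \sum H_C^2$). Ties in the denoising sort are broken
by original index; the recorded permutation guarantees exact unsorting
regardless. Singular spectra of tall matrices are computed through the
time-side Gram matrix (identical to a full SVD within $10^{-8}$
relative, verified); singular-vector sign conventions are irrelevant
because only the reconstruction is used. `suggest_nc()` fits its
log-linear noise baseline on the 35–80% index band of the spectrum
because the final singular values of a noise matrix roll off sharply and
would drag a tail fit down. Degenerate inputs error loudly: an all-zero
stack has no shot-noise level to normalise by; a fill factor of zero is
allowed (point sampling) with a warning; saturation beyond 1% of pixels
warns. For noiseless synthetic data the per-frame shot estimate is
meaningless and `reconstruct_s1(nbar = "global")` normalises by the
series mean instead.

## Known limitations

* The AR(1) plug-in path reproduces non-exponential $g_1$ only at lag one.
* The placeholder $\tau_c \to D_b$ scale makes `db_hat` relative, not
  absolute.
* `suggest_nc()` flags any sufficiently structured component, including a
  static term in raw-intensity stacks (which is why the advisory is
  computed on temporally filtered matrices in the examples) — the
  filtering threshold should always be confirmed by inspection.
* Memory, not time, bounds the materialised `make_field_stack()` path;
  full-scale runs must use the streaming `simulate_stack()`.
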