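# fddcs

Signal processing for multispeckle **Fourier-domain diffuse correlation
spectroscopy (FD-DCS)** with off-axis holographic camera detection, plus a
physics-level simulator of the instrument used to validate every step.

## The problem

Diffuse correlation spectroscopy measures blood flow from the temporal
decorrelation of multiply scattered coherent light, but its SNR falls
sharply at the large source–detector separations that deep (cerebral)
measurements require. Multispeckle detection recovers SNR: averaging
`N_speckles` independent speckles should improve the SNR of the spectral
estimate by `sqrt(N_speckles)`. FD-DCS reaches thousands of speckles in
parallel with an ordinary camera by heterodyne off-axis holography: the
sample field interferes with a reference beam detuned by `Δf`, and a 2D
DFT of the camera-plane hologram `H_C` separates the heterodyne signal
from noise,

    H_R = |F2D(H_C)|²,        S̄1(Δω) = S̄(±Δω)/N̄(Δω) − 1,

where `S̄` is the mean of `H_R` over the twin heterodyne masks and `N̄`
over a shot-noise mask in a quiet corner. Per-pixel values are corrected
for the camera pixel MTF, `|sinc(αΔx kx) sinc(αΔy ky)|²`, with fill
factor `α` calibrated by flattening the mean `S1` image of a spatially
uniform phantom. `S̄1(Δω)` sampled across detunings is, by
Wiener–Khinchin, the power spectral density of the field autocorrelation
`g1(τ)`, and a Lorentzian fit yields the correlation time / flow
parameter.

In practice the `sqrt(N)` law is broken by laser mode hops,
spatiotemporally correlated clutter, and detector noise. The package
implements the corresponding counter-measures:

* **temporal filtering** (`dc_pair`, `first_frame`, `single_frame`) and
  mode-hop phenomenology,
* **SVD spatiotemporal decluttering** of the space–time matrix
  (`svd_declutter`, zero the `nc` strongest singular values),
* the **sort–median–unsort multispeckle denoiser**: sort each column of
  the masked `S1` space–time matrix, median-filter each rank along time
  with a `[1×n]` window, unsort exactly (`sort_median_unsort`),
* **SNR analysis**: `SNR = μ/σ` over `S̄1` repeats, mask-radius sweeps,
  speckle counting from the instrument optics
  (`S = (λz)²/A_aperture` = 15.6 px here), and SNR gain against a
  single-speckle reference.

## Worked example

Simulate a small heterodyne stack, reconstruct, denoise and measure SNR:

```r
library(fddcs)

cfg <- simulation_config(grid_size = 128, n_frames = 201, rng_seed = 1)
stack <- simulate_stack(cfg)           # 128x128x201 camera counts
masks <- default_masks(cfg)            # twin + shot-noise masks (radius 20)
rec <- reconstruct_s1(stack, "dc_pair", masks, mtf = cfg$fill_factor)
rec
#> FD-DCS reconstruction: 200 holograms, 1257 mask px, MTF alpha = 0.720
#>   mean S1_bar = 59.11, sd = 2.656

den <- denoise_recon(rec, n = 3)       # sort-median-unsort
spx <- speckle_area()$area_px          # 15.57 px/speckle
radii <- sort(unique(c(single_speckle_mask(spx)$radius, seq(5, 20, 2.5))))
curve <- snr_gain(mask_radius_sweep(den, radii, speckle_px = spx))
tail(as.data.frame(curve), 1)
#>   radius n_pixels n_speckles      snr     gain
#> 8     20     1257   80.74011 31.28791 8.574919
snr_loglog_slope(curve)
#> [1] 0.4784088
```

At this desk scale the denoised SNR gain at the full mask (8.6 at ~81
speckles) sits close to the `sqrt(N_speckles)` line (`sqrt(80.7) = 9.0`
is the ideal; the log-log slope of SNR against speckle count is 0.48). The
full-scale experiment (`experiment_snr_gain()`, 512×512, 501 frames,
~1290 speckles) reproduces the headline behaviour: raw dc-pair data fall
short of the square-root law, `n = 3` denoising restores it with an SNR
gain of ≈36–39, and `n = 4` exceeds it.

Fill-factor calibration and spectrum fitting follow the same pattern —
see `experiment_alpha_recovery()` (variance-minimisation recovery of
`α = 0.72`) and `experiment_tauc_recovery()` (six-detuning spectrum,
finite-exposure dc-pair Lorentzian fit, recovery of `τ_c` to ~1%).

A thin command-line wrapper over these functions is installed at
`inst/cli/fddcs.R` (`simulate`, `reconstruct`, `calibrate-mtf`,
`svd-filter`, `denoise`, `fit`, `snr`, `pipeline`), reading and writing
16-bit multi-frame TIFF stacks with plain-text sidecars and CSV tables.

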