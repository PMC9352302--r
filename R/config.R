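#' Reference instrument geometry
#'
#' Optical geometry of the reference FD-DCS instrument: a 785 nm single-mode
#' laser, light collected through the 5.0 mm circular aperture of a liquid
#' light guide observed at z = 76.84 mm by a camera with 3.45 um pixel pitch.
#' These are the defaults used throughout the package; every field can be
#' overridden.
#'
#' @param wavelength Operating wavelength (m).
#' @param distance Observation distance z from the collection aperture to the
#'   camera sensor (m).
#' @param aperture_diameter Diameter of the circular collection aperture (m).
#'   Mutually exclusive with `aperture_area`.
#' @param aperture_area Area of the collection aperture (m^2). Overrides
#'   `aperture_diameter` when given.
#' @param pixel_pitch Camera pixel pitch (m), assumed square.
#' @return An object of class `fddcs_geometry`.
#' @seealso [speckle_area()]
#' @export
speckle_geometry <- function(wavelength = 785e-9,
                             distance = 76.84e-3,
                             aperture_diameter = 5.0e-3,
                             aperture_area = NULL,
                             pixel_pitch = 3.45e-6) {
  if (is.null(aperture_area)) {
    aperture_area <- pi * (aperture_diameter / 2)^2
  }
  stopifnot(wavelength > 0, distance > 0, aperture_area > 0, pixel_pitch > 0)
  structure(list(wavelength = wavelength, distance = distance,
                 aperture_area = aperture_area, pixel_pitch = pixel_pitch),
            class = "fddcs_geometry")
}

#' Simulation configuration for synthetic heterodyne hologram stacks
#'
#' Bundles every parameter of the synthetic off-axis heterodyne dynamic
#' speckle simulator: the spatial band of the sample field, its temporal
#' statistics, the reference-arm detuning, the exposure model and the
#' detector model (fill factor, shot noise, read noise, quantisation).
#'
#' The sample field is synthesised directly in the camera-plane
#' spatial-frequency domain: independent circular complex Gaussian modes on
#' a disc of radius `aperture_radius_freq` centred at `carrier_offset`, each
#' evolving as an AR(1) process whose autocorrelation equals the configured
#' g1 sampled at the substep interval. By default the disc radius is derived
#' from the instrument geometry so that the camera-plane speckle area equals
#' `speckle_area(geometry)$area_px`.
#'
#' @param grid_size Camera pixels per side (square sensor).
#' @param oversample_factor Integer sub-pixel sampling per dimension used by
#'   the detector model. With `oversample_factor = 1` the finite pixel
#'   aperture is applied as an exact frequency-domain sinc filter on the
#'   band-limited field modes instead of spatial integration.
#' @param carrier_offset Length-2 spatial-frequency offset of the sample band
#'   (cycles/frame in x and y). Default `grid_size/4` on the diagonal.
#' @param aperture_radius_freq Radius of the sample band in reconstruction
#'   pixels. Default derived from `geometry`.
#' @param tau_c Field correlation time (s) of the exponential g1.
#' @param g1_model `"exponential"` or a function `g1(tau)` registered as a
#'   plug-in; plug-ins are mapped to time-varying AR coefficients via their
#'   tabulated autocorrelation at the substep interval.
#' @param detuning_hz Reference-arm detuning frequencies (Hz); one stack is
#'   simulated per detuning.
#' @param exposure_time Camera exposure (s). Frames are acquired back to back
#'   so this is also the frame period.
#' @param substeps_per_exposure `"auto"` or an integer. Automatic selection
#'   uses `max(8, ceiling(dw*T/(pi/4)), ceiling(2*T/tau_c))` so that both the
#'   heterodyne beat and the field decorrelation are resolved within one
#'   exposure. An explicit value that leaves `dw*T/substeps > pi/4` is an
#'   error, as is `tau_c` shorter than twice the substep interval.
#' @param reference_photoelectrons_per_pixel Mean reference-arm
#'   photoelectrons per pixel per frame.
#' @param sample_to_reference_ratio Ratio of mean sample-arm to reference-arm
#'   photoelectrons per pixel.
#' @param fill_factor Linear camera pixel fill factor alpha in [0, 1].
#' @param read_noise Read noise (photoelectrons RMS).
#' @param quantisation_gain ADC gain (photoelectrons per count).
#' @param bit_depth ADC bit depth.
#' @param n_frames Frames per detuning.
#' @param rng_seed Integer seed; all randomness flows from it.
#' @param shot_noise Logical; Poisson-sample the photoelectron counts.
#'   Disabling it (together with `read_noise = 0`) gives a noiseless
#'   detector for oracle tests.
#' @param hop_frames Integer frame indices at which a laser mode hop is
#'   injected (coherence broken from the start of that frame onwards).
#' @param clutter_waveform Optional numeric vector of length `n_frames`;
#'   frame t is multiplied by `1 + clutter_waveform[t]` after detection.
#' @param geometry An [speckle_geometry()] object.
#' @return An object of class `fddcs_config`.
#' @export
simulation_config <- function(grid_size = 512,
                              oversample_factor = 1,
                              carrier_offset = NULL,
                              aperture_radius_freq = NULL,
                              tau_c = 1e-3,
                              g1_model = "exponential",
                              detuning_hz = 100,
                              exposure_time = 5e-3,
                              substeps_per_exposure = "auto",
                              reference_photoelectrons_per_pixel = 200,
                              sample_to_reference_ratio = 0.1,
                              fill_factor = 0.72,
                              read_noise = 2.45,
                              quantisation_gain = 5.73,
                              bit_depth = 12,
                              n_frames = 501,
                              rng_seed = 1,
                              shot_noise = TRUE,
                              hop_frames = integer(0),
                              clutter_waveform = NULL,
                              geometry = speckle_geometry()) {
  grid_size <- as.integer(grid_size)
  oversample_factor <- as.integer(oversample_factor)
  ## carrier at 5N/16 on the diagonal: far enough off axis that the
  ## sample-sample self-beating term (radius 2 r_f around DC) clears the
  ## heterodyne band for the geometry-derived band radius (~0.143 N)
  if (is.null(carrier_offset)) {
    carrier_offset <- c(5 * grid_size / 16, 5 * grid_size / 16)
  }
  if (is.null(aperture_radius_freq)) {
    spx <- speckle_area(geometry)$area_px
    aperture_radius_freq <- sqrt(grid_size^2 / (pi * spx))
  }
  cfg <- structure(list(
    grid_size = grid_size,
    oversample_factor = oversample_factor,
    carrier_offset = carrier_offset,
    aperture_radius_freq = aperture_radius_freq,
    tau_c = tau_c,
    g1_model = g1_model,
    detuning_hz = detuning_hz,
    exposure_time = exposure_time,
    substeps_per_exposure = substeps_per_exposure,
    reference_photoelectrons_per_pixel = reference_photoelectrons_per_pixel,
    sample_to_reference_ratio = sample_to_reference_ratio,
    fill_factor = fill_factor,
    read_noise = read_noise,
    quantisation_gain = quantisation_gain,
    bit_depth = bit_depth,
    n_frames = as.integer(n_frames),
    rng_seed = as.integer(rng_seed),
    shot_noise = isTRUE(shot_noise),
    hop_frames = as.integer(hop_frames),
    clutter_waveform = clutter_waveform,
    geometry = geometry
  ), class = "fddcs_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  n <- cfg$grid_size
  if (n < 8) stop("grid_size must be at least 8")
  if (cfg$oversample_factor < 1) stop("oversample_factor must be >= 1")
  if (cfg$fill_factor < 0 || cfg$fill_factor > 1) {
    stop("fill_factor must lie in [0, 1]")
  }
  if (any(c(cfg$tau_c, cfg$exposure_time, cfg$quantisation_gain) <= 0)) {
    stop("tau_c, exposure_time and quantisation_gain must be positive")
  }
  if (cfg$read_noise < 0) stop("read_noise must be non-negative")
  if (any(cfg$detuning_hz < 0)) stop("detuning frequencies must be >= 0")
  if (cfg$reference_photoelectrons_per_pixel <= 0) {
    stop("reference_photoelectrons_per_pixel must be positive")
  }
  if (cfg$sample_to_reference_ratio < 0) {
    stop("sample_to_reference_ratio must be >= 0")
  }
  c0 <- cfg$carrier_offset
  r <- cfg$aperture_radius_freq
  ## the sample band plus its twin must fit in the Nyquist quadrants without
  ## overlapping each other or the DC term
  if (any(abs(c0) + r > n / 2 - 1)) {
    stop("carrier_offset plus aperture_radius_freq exceeds the Nyquist quadrant")
  }
  if (sqrt(sum(c0^2)) <= r) {
    stop("sample band overlaps the DC term: increase carrier_offset or ",
         "decrease aperture_radius_freq")
  }
  if (2 * sqrt(sum(c0^2)) <= 2 * r) {
    stop("twin sample bands overlap each other")
  }
  if (sqrt(sum(c0^2)) < 3 * r - 0.5) {
    warning("off-axis separation |carrier| < 3 x band radius: the ",
            "sample-sample self-beating term overlaps the heterodyne band")
  }
  if (length(cfg$hop_frames) &&
      (any(cfg$hop_frames < 1) || any(cfg$hop_frames > cfg$n_frames))) {
    stop("hop_frames must lie within 1..n_frames")
  }
  if (!is.null(cfg$clutter_waveform)) {
    if (length(cfg$clutter_waveform) != cfg$n_frames) {
      stop("clutter_waveform must have length n_frames")
    }
    if (any(abs(cfg$clutter_waveform) >= 1)) {
      stop("|clutter_waveform| must be < 1 (negative intensities)")
    }
  }
  invisible(cfg)
}

#' @export
print.fddcs_config <- function(x, ...) {
  cat("FD-DCS simulation config\n")
  cat(sprintf("  grid %dx%d, oversample %d, carrier (%g, %g), band radius %.2f px\n",
              x$grid_size, x$grid_size, x$oversample_factor,
              x$carrier_offset[1], x$carrier_offset[2], x$aperture_radius_freq))
  cat(sprintf("  tau_c %.3g s, detuning %s Hz, exposure %.3g s, %d frames\n",
              x$tau_c, paste(x$detuning_hz, collapse = "/"),
              x$exposure_time, x$n_frames))
  cat(sprintf("  reference %g e-/px, ratio %g, alpha %.2f, read %.2f e-, gain %.2f e-/DN, %d bit\n",
              x$reference_photoelectrons_per_pixel, x$sample_to_reference_ratio,
              x$fill_factor, x$read_noise, x$quantisation_gain, x$bit_depth))
  invisible(x)
}

## Number of substeps needed to resolve both the heterodyne beat (phase
## advance <= pi/4 per substep) and the field dynamics (substep <= tau_c/2)
## within one exposure.
resolve_substeps <- function(cfg, detuning_hz) {
  t_exp <- cfg$exposure_time
  need_beat <- ceiling(2 * pi * detuning_hz * t_exp / (pi / 4))
  need_tau <- ceiling(2 * t_exp / cfg$tau_c)
  if (identical(cfg$substeps_per_exposure, "auto")) {
    return(max(8L, need_beat, need_tau))
  }
  s <- as.integer(cfg$substeps_per_exposure)
  if (2 * pi * detuning_hz * t_exp / s > pi / 4) {
    stop("substeps_per_exposure too small to resolve the heterodyne beat: ",
         "need at least ", need_beat)
  }
  if (cfg$tau_c < 2 * t_exp / s) {
    stop("tau_c shorter than twice the substep interval (aliasing): ",
         "need at least ", need_tau, " substeps")
  }
  s
}

## Two independent RNG substreams derived from one seed, so that the fused
## simulator and the make_field_stack/detector_integrate composition draw
## identical numbers. Streams save and restore .Random.seed around use.
make_rng_streams <- function(seed) {
  streams <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  streams$field <- get(".Random.seed", globalenv())
  set.seed((seed + 777767L) %% .Machine$integer.max)
  streams$noise <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  streams
}

with_stream <- function(streams, which, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", streams[[which]], envir = globalenv())
  on.exit({
    streams[[which]] <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
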