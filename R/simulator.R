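## Synthetic off-axis heterodyne dynamic-speckle hologram simulator.
##
## The sample field is synthesised directly in the camera-plane spatial
## frequency domain: independent circular complex Gaussian modes on a disc
## centred at the carrier offset, each evolving as an AR(1) process whose
## lag autocorrelation equals the configured g1 at the substep interval.
## The detector integrates |R exp(i dw t) + E|^2 over the exposure, applies
## the finite pixel fill factor, Poisson shot noise, Gaussian read noise and
## ADC quantisation.

## complex circular Gaussian draws with E|z|^2 = variance
cnorm <- function(n, variance = 1) {
  s <- sqrt(variance / 2)
  complex(real = rnorm(n, 0, s), imaginary = rnorm(n, 0, s))
}

## AR(1) lag-1 coefficient reproducing g1 at the substep interval
ar_coefficient <- function(cfg, dt) {
  if (is.function(cfg$g1_model)) {
    rho <- cfg$g1_model(dt) / cfg$g1_model(0)
  } else if (identical(cfg$g1_model, "exponential")) {
    rho <- exp(-dt / cfg$tau_c)
  } else {
    stop("unknown g1 model: ", cfg$g1_model)
  }
  if (!is.finite(rho) || rho < 0 || rho > 1) {
    stop("g1 model yields an invalid AR coefficient: ", rho)
  }
  rho
}

## in-band frequency lattice (closed disc at the carrier) and its linear
## indices into an M x M unshifted FFT grid
mode_lattice <- function(cfg, fft_size) {
  c0 <- cfg$carrier_offset
  r <- cfg$aperture_radius_freq
  kx <- seq(floor(c0[1] - r), ceiling(c0[1] + r))
  ky <- seq(floor(c0[2] - r), ceiling(c0[2] + r))
  g <- expand.grid(kx = kx, ky = ky)
  g <- g[(g$kx - c0[1])^2 + (g$ky - c0[2])^2 <= r^2, , drop = FALSE]
  M <- fft_size
  idx <- (g$kx %% M) + 1L + M * (g$ky %% M)
  list(kx = g$kx, ky = g$ky, idx = as.integer(idx), n = nrow(g))
}

## separable pixel-aperture amplitude filter sinc(alpha u) sinc(alpha v) on
## the unshifted n x n intensity-spectrum grid (u, v in cycles/pixel). The
## simulated intensity is band-limited well inside Nyquist (config
## invariants), so filtering the intensity spectrum is exact continuous
## integration over the active pixel area.
pixel_aperture_filter <- function(alpha, n) {
  k <- ((seq_len(n) - 1 + n / 2) %% n) - n / 2
  u <- k / n
  s <- nsinc(alpha * u)
  outer(s, s)
}

#' Normalised sinc function
#'
#' `nsinc(t) = sin(pi t) / (pi t)` with `nsinc(0) = 1`.
#'
#' @param t Numeric vector.
#' @return Numeric vector of the same length.
#' @export
nsinc <- function(t) {
  out <- rep(1, length(t))
  nz <- t != 0
  out[nz] <- sin(pi * t[nz]) / (pi * t[nz])
  out
}

## area weights of the fine-grid sub-samples around one sample point for
## active width alpha (pixels); the window is centred on the sample point
## so that the spatial route and the spectral (sinc) route share the same
## registration. Fractional boundary sub-samples are area weighted;
## weights sum to 1 (average over the active area).
subpixel_weights <- function(alpha, m) {
  if (alpha == 0) return(list(offsets = 0L, weights = 1))
  half <- alpha * m / 2
  o <- seq(-ceiling(half + 0.5), ceiling(half + 0.5))
  w <- pmax(0, pmin(o + 0.5, half) - pmax(o - 0.5, -half))
  keep <- w > 0
  list(offsets = as.integer(o[keep]), weights = w[keep] / sum(w[keep]))
}

## block-downsampling matrix (n x n*m) applying the centred subpixel
## weights around each coarse sample (periodic boundary)
downsample_matrix <- function(alpha, n, m) {
  sw <- subpixel_weights(alpha, m)
  W <- matrix(0, n, n * m)
  for (j in seq_along(sw$offsets)) {
    cols <- ((seq_len(n) - 1) * m + sw$offsets[j]) %% (n * m) + 1
    W[cbind(seq_len(n), cols)] <- W[cbind(seq_len(n), cols)] + sw$weights[j]
  }
  W
}

## fill-factor integration of one expected-intensity image (fine grid in,
## pixel grid out); helpers precomputed by make_integrator()
make_integrator <- function(cfg) {
  N <- cfg$grid_size
  m <- cfg$oversample_factor
  alpha <- cfg$fill_factor
  if (alpha == 0) warning("fill_factor = 0: degenerate point sampling")
  if (m == 1) {
    apfilter <- if (alpha > 0) pixel_aperture_filter(alpha, N) else NULL
    function(Ibar) {
      if (is.null(apfilter)) return(Ibar)
      Re(fft(fft(Ibar) * apfilter, inverse = TRUE)) / (N * N)
    }
  } else {
    W <- downsample_matrix(alpha, N, m)
    Wt <- t(W)
    function(Ibar) W %*% Ibar %*% Wt
  }
}

## Core simulation loop shared by make_field_stack() and simulate_stack().
## collect = "fields" materialises the per-substep complex field plus the
## beat-phase and power-scale series (small grids only); collect = "frames"
## integrates the detector on the fly.
sim_engine <- function(cfg, detuning_hz, collect = c("frames", "fields")) {
  collect <- match.arg(collect)
  N <- cfg$grid_size
  m <- cfg$oversample_factor
  M <- N * m
  S <- resolve_substeps(cfg, detuning_hz)
  dt <- cfg$exposure_time / S
  rho <- ar_coefficient(cfg, dt)
  streams <- make_rng_streams(cfg$rng_seed)

  R2 <- cfg$reference_photoelectrons_per_pixel
  Is <- cfg$sample_to_reference_ratio * R2
  Ramp <- sqrt(R2)
  modes <- mode_lattice(cfg, M)
  mode_var <- Is / modes$n
  evo_sd <- sqrt(1 - rho^2)

  spec <- matrix(0i, M, M)
  power_scale <- rep(1, cfg$n_frames)
  hop_jumps <- numeric(0)
  beat_phase <- numeric(S * cfg$n_frames)
  het_scale <- rep(1, cfg$n_frames)
  beat <- 2 * pi * detuning_hz
  cur_scale <- 1

  if (collect == "frames") {
    integrate_px <- make_integrator(cfg)
    frames <- array(NA_integer_, dim = c(N, N, cfg$n_frames))
    full_well <- (2^cfg$bit_depth - 1) * cfg$quantisation_gain
    n_sat <- 0
  } else {
    fields <- array(NA_complex_, dim = c(M, M, S * cfg$n_frames))
  }

  a <- with_stream(streams, "field", cnorm(modes$n, mode_var))
  for (f in seq_len(cfg$n_frames)) {
    hop_now <- f %in% cfg$hop_frames
    if (hop_now) {
      ## laser settles in a new longitudinal mode: fresh speckle realisation
      ## and a small persistent output-power jump. During the hop exposure
      ## the laser frequency transient is orders of magnitude faster than
      ## the reference detuning, so the reference/sample beat integrates to
      ## zero: the heterodyne term of this frame is suppressed entirely.
      with_stream(streams, "field", {
        a <- cnorm(modes$n, mode_var)
        eps <- runif(1, 0.03, 0.08) * sample(c(-1, 1), 1)
      })
      cur_scale <- cur_scale * (1 + eps)
      hop_jumps <- c(hop_jumps, eps)
      het_scale[f] <- 0
    }
    power_scale[f] <- cur_scale
    acc <- 0
    for (s in seq_len(S)) {
      if (!(f == 1 && s == 1)) {
        a <- with_stream(streams, "field",
                         rho * a + cnorm(modes$n, mode_var) * evo_sd)
      }
      t_mid <- ((f - 1) * S + s - 0.5) * dt
      phase <- -beat * t_mid
      beat_phase[(f - 1) * S + s] <- phase
      spec[modes$idx] <- a
      E <- fft(spec, inverse = TRUE)
      if (collect == "fields") {
        fields[, , (f - 1) * S + s] <- E
      } else {
        acc <- acc + R2 + Mod(E)^2 +
          het_scale[f] * 2 * Ramp * Re(E * exp(1i * phase))
      }
    }
    if (collect == "frames") {
      Ibar <- integrate_px((acc / S) * cur_scale)
      Ibar[Ibar < 0] <- 0
      n_sat <- n_sat + sum(Ibar > full_well)
      frames[, , f] <- with_stream(streams, "noise", detect_counts(Ibar, cfg))
    }
  }

  if (collect == "fields") {
    return(structure(list(fields = fields, beat_phase = beat_phase,
                          power_scale = power_scale, het_scale = het_scale,
                          config = cfg,
                          detuning_hz = detuning_hz,
                          substeps_per_frame = S, dt = dt,
                          hop_jumps = hop_jumps, streams = streams),
                     class = "fddcs_fields"))
  }
  if (n_sat > 0.01 * length(frames)) {
    warning(sprintf("saturation: %.1f%% of pixels exceed the bit depth",
                    100 * n_sat / length(frames)))
  }
  fs <- structure(list(frames = frames, detuning_hz = detuning_hz,
                       config = cfg,
                       ground_truth = ground_truth(cfg, hop_jumps)),
                  class = "fddcs_frames")
  if (!is.null(cfg$clutter_waveform)) {
    fs <- inject_global_clutter(fs, cfg$clutter_waveform)
  }
  fs
}

ground_truth <- function(cfg, hop_jumps = numeric(0)) {
  N <- cfg$grid_size
  list(tau_c = cfg$tau_c, fill_factor = cfg$fill_factor,
       hop_frames = cfg$hop_frames, hop_power_jumps = hop_jumps,
       clutter_waveform = cfg$clutter_waveform,
       speckle_area_px = N^2 / (pi * cfg$aperture_radius_freq^2),
       n_modes = mode_lattice(cfg, N * cfg$oversample_factor)$n)
}

## expected photoelectron image -> quantised counts (uses current RNG state)
detect_counts <- function(Ibar, cfg) {
  x <- if (cfg$shot_noise) rpois(length(Ibar), Ibar) else as.vector(Ibar)
  if (cfg$read_noise > 0) x <- x + rnorm(length(x), 0, cfg$read_noise)
  counts <- floor(x / cfg$quantisation_gain)
  counts <- pmin(pmax(counts, 0), 2^cfg$bit_depth - 1)
  matrix(as.integer(counts), nrow(Ibar), ncol(Ibar))
}

#' Synthesise the time-resolved complex sample field
#'
#' Materialises the camera-grid sample field at every substep for one
#' detuning frequency, together with the beat-phase series and per-frame
#' laser power scale. Intended for small configurations (oracle tests);
#' large stacks should use [simulate_stack()], which integrates the
#' detector on the fly.
#'
#' @param config An [simulation_config()] object.
#' @param detuning_hz Detuning frequency (Hz); defaults to the first entry
#'   of `config$detuning_hz`.
#' @return An object of class `fddcs_fields` with the complex field array
#'   (grid x grid x substeps), the substep interval, the beat-phase series,
#'   and the RNG state for subsequent detector integration.
#' @export
make_field_stack <- function(config, detuning_hz = config$detuning_hz[1]) {
  validate_config(config)
  M <- config$grid_size * config$oversample_factor
  S <- resolve_substeps(config, detuning_hz)
  if (as.double(M)^2 * S * config$n_frames * 16 > 4e9) {
    stop("field stack too large to materialise; use simulate_stack()")
  }
  sim_engine(config, detuning_hz, collect = "fields")
}

#' Integrate a field stack through the detector model
#'
#' Applies the reference interference, exposure integration, pixel
#' fill-factor integration, shot noise, read noise and ADC quantisation to
#' a materialised field stack, yielding integer camera counts.
#'
#' With `oversample_factor = 1` the finite pixel aperture is applied as an
#' exact sinc amplitude filter on the (band-limited) intensity spectrum;
#' with `oversample_factor > 1` the intensity is area-averaged over the
#' active alpha x alpha sub-region of each pixel cell, with area weighting
#' of fractional boundary sub-samples.
#'
#' @param field_stack Result of [make_field_stack()].
#' @param config Configuration; defaults to the one stored in `field_stack`.
#'   Detector fields (fill factor, noise) may be overridden; the grid and
#'   temporal fields must match the field stack.
#' @return An object of class `fddcs_frames` (integer counts array
#'   grid x grid x n_frames plus metadata and ground truth).
#' @export
detector_integrate <- function(field_stack, config = field_stack$config) {
  stopifnot(inherits(field_stack, "fddcs_fields"))
  cfg <- config
  N <- cfg$grid_size
  S <- field_stack$substeps_per_frame
  R2 <- cfg$reference_photoelectrons_per_pixel
  Ramp <- sqrt(R2)
  integrate_px <- make_integrator(cfg)
  streams <- field_stack$streams
  full_well <- (2^cfg$bit_depth - 1) * cfg$quantisation_gain
  n_sat <- 0
  frames <- array(NA_integer_, dim = c(N, N, cfg$n_frames))
  for (f in seq_len(cfg$n_frames)) {
    acc <- 0
    for (s in seq_len(S)) {
      i <- (f - 1) * S + s
      E <- field_stack$fields[, , i]
      acc <- acc + R2 + Mod(E)^2 + field_stack$het_scale[f] *
        2 * Ramp * Re(E * exp(1i * field_stack$beat_phase[i]))
    }
    Ibar <- integrate_px((acc / S) * field_stack$power_scale[f])
    Ibar[Ibar < 0] <- 0
    n_sat <- n_sat + sum(Ibar > full_well)
    frames[, , f] <- with_stream(streams, "noise", detect_counts(Ibar, cfg))
  }
  if (n_sat > 0.01 * length(frames)) {
    warning(sprintf("saturation: %.1f%% of pixels exceed the bit depth",
                    100 * n_sat / length(frames)))
  }
  structure(list(frames = frames, detuning_hz = field_stack$detuning_hz,
                 config = cfg,
                 ground_truth = ground_truth(cfg, field_stack$hop_jumps)),
            class = "fddcs_frames")
}

#' Simulate a camera frame stack for one detuning frequency
#'
#' Fused field synthesis and detector integration; memory use is bounded by
#' the output stack, so full-scale (512 x 512 x 501) runs are possible.
#' Bit-for-bit identical to `detector_integrate(make_field_stack(config))`
#' for configurations small enough to materialise.
#'
#' @inheritParams make_field_stack
#' @return An object of class `fddcs_frames`.
#' @export
simulate_stack <- function(config, detuning_hz = config$detuning_hz[1]) {
  validate_config(config)
  sim_engine(config, detuning_hz, collect = "frames")
}

#' Simulate one frame stack per configured detuning frequency
#'
#' Each detuning uses an independent RNG substream derived from
#' `config$rng_seed`.
#'
#' @param config An [simulation_config()] object.
#' @return A list of `fddcs_frames`, one per entry of `config$detuning_hz`.
#' @export
simulate_all <- function(config) {
  lapply(seq_along(config$detuning_hz), function(i) {
    cfg_i <- config
    cfg_i$rng_seed <- as.integer((config$rng_seed + 104729 * (i - 1)) %%
                                   .Machine$integer.max)
    simulate_stack(cfg_i, config$detuning_hz[i])
  })
}

#' Inject laser mode hops into a simulation
#'
#' Re-synthesises the field stack with mode hops at the given frames. A hop
#' breaks the mutual coherence between reference and sample from the start
#' of the hop frame onwards: all mode amplitudes are redrawn, the
#' heterodyne beat of the hop exposure integrates to zero (the laser
#' frequency transient is far faster than the detuning), and the laser
#' output power takes a small persistent jump. The same field seed is
#' reused, so with `hop_frames` empty the stack is unchanged bit for bit.
#'
#' @param field_stack Result of [make_field_stack()].
#' @param hop_frames Integer frame indices of the hops.
#' @return A new `fddcs_fields` object.
#' @export
inject_mode_hops <- function(field_stack, hop_frames) {
  stopifnot(inherits(field_stack, "fddcs_fields"))
  cfg <- field_stack$config
  hop_frames <- as.integer(hop_frames)
  if (length(hop_frames) &&
      (any(hop_frames < 1) || any(hop_frames > cfg$n_frames))) {
    stop("hop_frames must lie within 1..n_frames")
  }
  cfg$hop_frames <- hop_frames
  make_field_stack(cfg, field_stack$detuning_hz)
}

#' Inject a global intensity modulation into a frame stack
#'
#' Multiplies frame t by `1 + waveform[t]`, emulating clutter that is
#' spatially coherent across the whole sensor (laser power modulation, beat
#' notes, slow drift).
#'
#' @param frame_stack An `fddcs_frames` object.
#' @param waveform Numeric vector, one value per frame, `|waveform| < 1`.
#' @return The modified `fddcs_frames` object; ground truth records the
#'   injected waveform.
#' @export
inject_global_clutter <- function(frame_stack, waveform) {
  stopifnot(inherits(frame_stack, "fddcs_frames"))
  nf <- dim(frame_stack$frames)[3]
  if (length(waveform) != nf) stop("waveform length must equal n_frames")
  if (any(abs(waveform) >= 1)) {
    stop("|waveform| must be < 1 (negative intensities)")
  }
  top <- 2^frame_stack$config$bit_depth - 1
  for (t in seq_len(nf)) {
    if (waveform[t] == 0) next
    v <- round(frame_stack$frames[, , t] * (1 + waveform[t]))
    frame_stack$frames[, , t] <- as.integer(pmin(pmax(v, 0), top))
  }
  frame_stack$ground_truth$clutter_waveform <- waveform
  frame_stack
}

#' Inject a coherent beat-note clutter into a frame stack
#'
#' Emulates a static stray reflection (at an optical interface) beating
#' with the frequency-shifted reference: a fixed band-limited interference
#' pattern multiplied by a sinusoidal temporal vector. Unlike a global
#' power modulation, this clutter is spatially structured (it lands inside
#' the heterodyne band) and rank-2 in the space-time matrix, so it biases
#' the per-frame S1 estimate at its beat frequency, is outside the
#' stopband of DC-pair filtering for fast beats, and is exactly removable
#' by SVD decluttering.
#'
#' @param frame_stack An `fddcs_frames` object.
#' @param strength Peak amplitude of the pattern in ADC counts.
#' @param beat_cycles_per_frame Beat frequency in cycles per frame.
#' @param rng_seed Seed for the static stray-reflection pattern.
#' @return The modified `fddcs_frames`; ground truth records the clutter.
#' @export
inject_coherent_clutter <- function(frame_stack, strength,
                                    beat_cycles_per_frame, rng_seed = 1) {
  stopifnot(inherits(frame_stack, "fddcs_frames"))
  cfg <- frame_stack$config
  nf <- dim(frame_stack$frames)[3]
  N <- cfg$grid_size
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(rng_seed)
  lat <- mode_lattice(cfg, N)
  spec <- matrix(0i, N, N)
  spec[lat$idx] <- cnorm(lat$n, 1)
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  pattern <- Re(fft(spec, inverse = TRUE))
  pattern <- pattern / stats::sd(pattern)
  top <- 2^cfg$bit_depth - 1
  phase <- 2 * pi * beat_cycles_per_frame * seq_len(nf)
  for (t in seq_len(nf)) {
    v <- round(frame_stack$frames[, , t] + strength * pattern * cos(phase[t]))
    frame_stack$frames[, , t] <- as.integer(pmin(pmax(v, 0), top))
  }
  frame_stack$ground_truth$coherent_clutter <-
    list(strength = strength, beat_cycles_per_frame = beat_cycles_per_frame,
         rng_seed = rng_seed)
  frame_stack
}

#' @export
print.fddcs_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("FD-DCS frame stack: %d x %d px, %d frames, detuning %g Hz\n",
              d[1], d[2], d[3], x$detuning_hz))
  invisible(x)
}
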