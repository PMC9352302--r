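## End-to-end orchestration, file formats and the fixture generator.
## Frame stacks travel as multi-frame 16-bit TIFF plus a plain-text
## key = value sidecar; tables as CSV with a header row.

#' Write a frame stack as multi-frame 16-bit TIFF plus sidecar
#'
#' @param frame_stack An `fddcs_frames` object.
#' @param path Output TIFF path; the sidecar is written next to it with
#'   extension `.meta.txt`, and the ground truth (when present) with
#'   `.truth.txt`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frame_stack, path) {
  stopifnot(inherits(frame_stack, "fddcs_frames"))
  f <- frame_stack$frames
  planes <- lapply(seq_len(dim(f)[3]), function(t) f[, , t] / 65535)
  tiff::writeTIFF(planes, path, bits.per.sample = 16, compression = "none")
  cfg <- frame_stack$config
  meta <- c(seed = cfg$rng_seed, grid_size = cfg$grid_size,
            oversample_factor = cfg$oversample_factor,
            alpha = cfg$fill_factor, tau_c = cfg$tau_c,
            detuning_hz = frame_stack$detuning_hz,
            exposure_time = cfg$exposure_time,
            reference_photoelectrons_per_pixel =
              cfg$reference_photoelectrons_per_pixel,
            sample_to_reference_ratio = cfg$sample_to_reference_ratio,
            quantisation_gain = cfg$quantisation_gain,
            read_noise = cfg$read_noise, bit_depth = cfg$bit_depth,
            n_frames = dim(f)[3],
            carrier_x = cfg$carrier_offset[1],
            carrier_y = cfg$carrier_offset[2],
            aperture_radius_freq = cfg$aperture_radius_freq)
  writeLines(paste(names(meta), meta, sep = " = "),
             sub("\\.tiff?$", ".meta.txt", path, ignore.case = TRUE))
  gt <- frame_stack$ground_truth
  if (!is.null(gt)) {
    lines <- c(paste("tau_c =", gt$tau_c),
               paste("fill_factor =", gt$fill_factor),
               paste("speckle_area_px =", gt$speckle_area_px),
               paste("n_modes =", gt$n_modes),
               paste("hop_frames =", paste(gt$hop_frames, collapse = ",")),
               paste("clutter =",
                     if (is.null(gt$clutter_waveform)) "" else
                       paste(signif(gt$clutter_waveform, 6), collapse = ",")))
    writeLines(lines, sub("\\.tiff?$", ".truth.txt", path, ignore.case = TRUE))
  }
  invisible(path)
}

#' Read a frame stack written by [write_frames()]
#'
#' @param path TIFF path.
#' @return An `fddcs_frames` object; the sidecar metadata (when present)
#'   is parsed into a `meta` field and used to rebuild the configuration.
#' @export
read_frames <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  f <- array(NA_integer_, dim = c(dim(planes[[1]]), length(planes)))
  for (t in seq_along(planes)) {
    f[, , t] <- as.integer(round(planes[[t]] * 65535))
  }
  meta_path <- sub("\\.tiff?$", ".meta.txt", path, ignore.case = TRUE)
  meta <- NULL
  cfg <- NULL
  detuning <- NA_real_
  if (file.exists(meta_path)) {
    kv <- read_keyvals(meta_path)
    meta <- kv
    detuning <- as.numeric(kv$detuning_hz)
    cfg <- simulation_config(
      grid_size = as.integer(kv$grid_size),
      oversample_factor = as.integer(kv$oversample_factor),
      carrier_offset = c(as.numeric(kv$carrier_x), as.numeric(kv$carrier_y)),
      aperture_radius_freq = as.numeric(kv$aperture_radius_freq),
      tau_c = as.numeric(kv$tau_c),
      detuning_hz = detuning,
      exposure_time = as.numeric(kv$exposure_time),
      reference_photoelectrons_per_pixel =
        as.numeric(kv$reference_photoelectrons_per_pixel),
      sample_to_reference_ratio = as.numeric(kv$sample_to_reference_ratio),
      fill_factor = as.numeric(kv$alpha),
      read_noise = as.numeric(kv$read_noise),
      quantisation_gain = as.numeric(kv$quantisation_gain),
      bit_depth = as.integer(kv$bit_depth),
      n_frames = as.integer(kv$n_frames),
      rng_seed = as.integer(kv$seed))
  }
  structure(list(frames = f, detuning_hz = detuning, config = cfg,
                 ground_truth = NULL, meta = meta),
            class = "fddcs_frames")
}

read_keyvals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = " = ")),
                  vapply(kv, `[[`, character(1), 1))
}

#' Run the full FD-DCS processing pipeline on simulated data
#'
#' simulate -> temporal filter / SVD declutter -> reconstruct (+ MTF) ->
#' denoise -> spectrum -> fit -> SNR sweep. SVD decluttering implies
#' single-frame temporal filtering downstream (the SVD step has already
#' performed temporal filtering); requesting `svd_nc > 0` together with a
#' different filter mode is rejected.
#'
#' @param config An [simulation_config()] object (the detuning list drives
#'   the spectrum).
#' @param filter_mode Temporal filter for reconstruction.
#' @param mtf_alpha Fill factor used for MTF correction, or `NULL` to skip
#'   correction.
#' @param svd_nc Number of leading singular values to zero before
#'   reconstruction (0 = no SVD step).
#' @param denoise_n Sort-median-unsort window (1 = no denoising).
#' @param signal_radius Heterodyne mask radius (pixels).
#' @param sweep_radii Radii for the SNR sweep on the first detuning;
#'   `NULL` for an automatic grid up to the mask radius.
#' @param model PSD model for the spectrum fit.
#' @param out_dir Optional directory for CSV outputs and a manifest.
#' @return A list with `stacks` metadata, `recons`, `spectrum`, `fit`,
#'   `snr_curve` (with gain), and `manifest`.
#' @export
run_pipeline <- function(config,
                         filter_mode = c("dc_pair", "first_frame", "single_frame"),
                         mtf_alpha = config$fill_factor,
                         svd_nc = 0,
                         denoise_n = 3,
                         signal_radius = 80 * config$grid_size / 512,
                         sweep_radii = NULL,
                         model = "exponential_g1",
                         out_dir = NULL) {
  filter_mode <- match.arg(filter_mode)
  if (svd_nc > 0 && filter_mode != "single_frame") {
    stop("svd_nc > 0 requires filter_mode = 'single_frame': the SVD step ",
         "has already implemented temporal filtering")
  }
  masks <- default_masks(config, signal_radius = signal_radius)
  mtf <- if (!is.null(mtf_alpha)) mtf_map(mtf_alpha, config$grid_size) else NULL
  stacks <- simulate_all(config)
  recons <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    if (svd_nc > 0) {
      q <- stack_to_matrix(st$frames, provenance = "camera_plane_Q")
      qf <- svd_declutter(q, svd_nc)
      st$frames <- matrix_to_stack(qf)
    }
    r <- reconstruct_s1(st, mode = filter_mode, masks = masks, mtf = mtf)
    if (denoise_n > 1) r <- denoise_recon(r, n = denoise_n)
    recons[[i]] <- r
  }
  spec <- make_spectrum(config$detuning_hz,
                        lapply(recons, function(r) r$scalars$s1_bar))
  fit <- if (length(config$detuning_hz) >= 2) fit_db(spec, model = model) else NULL
  spx <- speckle_area(config$geometry)$area_px
  if (is.null(sweep_radii)) {
    rmax <- masks$geometry$signal_radius
    sweep_radii <- sort(unique(c(single_speckle_mask(spx)$radius,
                                 seq(5 * config$grid_size / 512, rmax,
                                     length.out = 16))))
  }
  curve <- mask_radius_sweep(recons[[1]], sweep_radii, speckle_px = spx)
  curve <- tryCatch(snr_gain(curve), error = function(e) curve)
  out <- list(stacks = lapply(stacks, function(s)
                list(detuning_hz = s$detuning_hz,
                     ground_truth = s$ground_truth)),
              recons = recons, spectrum = spec, fit = fit, snr_curve = curve,
              manifest = pipeline_manifest(config, filter_mode, mtf_alpha,
                                           svd_nc, denoise_n, signal_radius,
                                           model))
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  out
}

pipeline_manifest <- function(config, filter_mode, mtf_alpha, svd_nc,
                              denoise_n, signal_radius, model) {
  c(package_version = as.character(utils::packageVersion("fddcs")),
    seed = config$rng_seed, grid_size = config$grid_size,
    oversample_factor = config$oversample_factor,
    carrier_x = config$carrier_offset[1], carrier_y = config$carrier_offset[2],
    aperture_radius_freq = config$aperture_radius_freq,
    tau_c = config$tau_c,
    detuning_hz = paste(config$detuning_hz, collapse = ","),
    exposure_time = config$exposure_time,
    substeps = as.character(config$substeps_per_exposure),
    reference_photoelectrons_per_pixel =
      config$reference_photoelectrons_per_pixel,
    sample_to_reference_ratio = config$sample_to_reference_ratio,
    fill_factor = config$fill_factor, read_noise = config$read_noise,
    quantisation_gain = config$quantisation_gain,
    bit_depth = config$bit_depth, n_frames = config$n_frames,
    shot_noise = config$shot_noise,
    filter_mode = filter_mode,
    mtf_alpha = if (is.null(mtf_alpha)) "none" else mtf_alpha,
    svd_nc = svd_nc, denoise_n = denoise_n,
    signal_radius = signal_radius, model = model)
}

write_pipeline_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(paste(names(out$manifest), unlist(out$manifest), sep = " = "),
             file.path(out_dir, "manifest.txt"))
  scal <- do.call(rbind, lapply(seq_along(out$recons), function(i) {
    s <- out$recons[[i]]$scalars
    data.frame(frame = s$frame, detuning_hz = config$detuning_hz[i],
               s_plus = s$s_plus, s_minus = s$s_minus, n_bar = s$n_bar,
               s1_bar = s$s1_bar)
  }))
  write.csv(scal, file.path(out_dir, "s1_scalars.csv"), row.names = FALSE)
  write.csv(out$spectrum$table, file.path(out_dir, "spectrum.csv"),
            row.names = FALSE)
  if (!is.null(out$fit)) {
    write.csv(data.frame(model = out$fit$model,
                         tau_c_hat = out$fit$tau_c_hat,
                         db_hat = out$fit$db_hat,
                         scale = out$fit$amplitude,
                         residual = out$fit$residual_norm,
                         n_detunings = nrow(out$fit$fitted)),
              file.path(out_dir, "fit.csv"), row.names = FALSE)
  }
  write.csv(as.data.frame(out$snr_curve), file.path(out_dir, "snr_curve.csv"),
            row.names = FALSE)
  invisible(out_dir)
}

#' Miniature test fixtures with machine-readable expectations
#'
#' Emits small (64 x 64, at most 50 frames) simulated stacks for named
#' scenarios together with the values a correct pipeline should recover.
#'
#' @param scenario One of `"flat_field_alpha"`, `"mode_hop"`,
#'   `"beat_clutter"`, `"shot_noise_only"`, `"known_tauc"`.
#' @param seed Integer RNG seed.
#' @return A list with `stacks` (list of `fddcs_frames`), `config`, and
#'   `expected` (named list of expectation values).
#' @export
fixture_generator <- function(scenario = c("flat_field_alpha", "mode_hop",
                                           "beat_clutter", "shot_noise_only",
                                           "known_tauc"),
                              seed = 1) {
  scenario <- match.arg(scenario)
  base <- function(...) {
    defaults <- list(grid_size = 64, n_frames = 50, rng_seed = seed,
                     reference_photoelectrons_per_pixel = 200,
                     sample_to_reference_ratio = 0.1)
    do.call(simulation_config, utils::modifyList(defaults, list(...)))
  }
  switch(scenario,
    flat_field_alpha = {
      cfg <- base(oversample_factor = 3, fill_factor = 0.72,
                  carrier_offset = c(21, 21), aperture_radius_freq = 10)
      list(stacks = list(simulate_stack(cfg)), config = cfg,
           expected = list(alpha = 0.72))
    },
    mode_hop = {
      cfg <- base(hop_frames = 25L)
      list(stacks = list(simulate_stack(cfg)), config = cfg,
           expected = list(hop_frame = 25L))
    },
    beat_clutter = {
      n <- 50
      wav <- 0.05 * sin(2 * pi * 3.2 * seq_len(n) / n)
      cfg <- base(clutter_waveform = wav)
      list(stacks = list(simulate_stack(cfg)), config = cfg,
           expected = list(waveform = wav))
    },
    shot_noise_only = {
      cfg <- base(sample_to_reference_ratio = 0)
      list(stacks = list(simulate_stack(cfg)), config = cfg,
           expected = list(s1_bar = 0))
    },
    known_tauc = {
      cfg <- base(tau_c = 1e-3,
                  detuning_hz = c(25, 50, 100, 200, 400, 800))
      list(stacks = simulate_all(cfg), config = cfg,
           expected = list(tau_c = 1e-3))
    })
}
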