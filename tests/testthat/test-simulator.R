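test_that("configuration invariants are enforced", {
  expect_error(simulation_config(grid_size = 64, carrier_offset = c(30, 30)),
               "Nyquist")
  expect_error(simulation_config(grid_size = 64, carrier_offset = c(4, 4),
                                 aperture_radius_freq = 8),
               "DC term")
  expect_error(simulation_config(fill_factor = 1.2), "fill_factor")
  expect_error(simulation_config(tau_c = -1), "positive")
  expect_error(tiny_config(hop_frames = 99L), "hop_frames")
  expect_error(tiny_config(clutter_waveform = rep(1.5, 40)), "negative intensities")
  expect_error(tiny_config(clutter_waveform = rep(0, 5)), "length")
})

test_that("substep resolution covers beat and field dynamics", {
  cfg <- tiny_config(tau_c = 1e-3, exposure_time = 5e-3)
  # beat: dw*T = 2*pi*100*0.005 ~ 3.1 rad -> 4 substeps; tau_c: 2T/tau = 10
  expect_equal(fddcs:::resolve_substeps(cfg, 100), 10)
  expect_equal(fddcs:::resolve_substeps(cfg, 800), 32)  # beat-limited
  cfg2 <- tiny_config(substeps_per_exposure = 2)
  expect_error(fddcs:::resolve_substeps(cfg2, 800), "beat")
  cfg3 <- tiny_config(substeps_per_exposure = 8, tau_c = 1e-4)
  expect_error(fddcs:::resolve_substeps(cfg3, 10), "aliasing")
})

test_that("a static sample (infinite tau_c) yields an identical field at every substep", {
  cfg <- tiny_config(grid_size = 16, n_frames = 2, tau_c = Inf,
                     carrier_offset = c(4, 4), aperture_radius_freq = 1.3,
                     substeps_per_exposure = 8)
  fld <- make_field_stack(cfg, detuning_hz = 10)
  for (s in 2:dim(fld$fields)[3]) {
    expect_identical(fld$fields[, , s], fld$fields[, , 1])
  }
})

test_that("mode evolution follows the configured g1 at lag one", {
  # sample-autocorrelation oracle on a single spatial-frequency mode
  cfg <- suppressWarnings(
    simulation_config(grid_size = 16, carrier_offset = c(4, 4),
                      aperture_radius_freq = 2.3, n_frames = 400,
                      tau_c = 1e-3, exposure_time = 5e-3,
                      rng_seed = 5, detuning_hz = 100))
  fld <- suppressWarnings(make_field_stack(cfg))
  S <- dim(fld$fields)[3]
  lat <- fddcs:::mode_lattice(cfg, 16)
  a <- vapply(seq_len(S), function(s) fft(fld$fields[, , s])[lat$idx[1]] / 16^2,
              complex(1))
  rho_hat <- Re(sum(a[-1] * Conj(a[-S]))) / sum(Mod(a[-S])^2)
  rho_true <- exp(-fld$dt / cfg$tau_c)
  se <- sqrt((1 - rho_true^2) / S)
  expect_lt(abs(rho_hat - rho_true), 3 * se)
})

test_that("spatial coherence area of the field matches the configured band", {
  # brute-force autocovariance of one frame over a shift window
  cfg <- tiny_config(grid_size = 48, n_frames = 1, rng_seed = 31)
  fld <- make_field_stack(cfg)
  E <- fld$fields[, , 1]
  n <- nrow(E)
  shifts <- -8:8
  gam2 <- 0
  c0 <- mean(Mod(E)^2)
  for (dx in shifts) for (dy in shifts) {
    Es <- E[((seq_len(n) - 1 + dx) %% n) + 1, ((seq_len(n) - 1 + dy) %% n) + 1]
    gam2 <- gam2 + Mod(mean(E * Conj(Es)))^2
  }
  s_est <- gam2 / c0^2
  s_true <- fld$config$grid_size^2 / fddcs:::mode_lattice(cfg, n)$n
  expect_lt(abs(s_est - s_true) / s_true, 0.15)
  # and the ground-truth speckle area agrees with the optical geometry
  fs <- simulate_stack(tiny_config(n_frames = 2))
  expect_equal(fs$ground_truth$speckle_area_px, speckle_area()$area_px,
               tolerance = 1e-6)
})

test_that("speckle contrast of a noiseless sample-only frame is close to 1", {
  cfg <- tiny_config(grid_size = 128, n_frames = 1, rng_seed = 9)
  fld <- make_field_stack(cfg)
  I <- Mod(fld$fields[, , 1])^2
  expect_lt(abs(sd(I) / mean(I) - 1), 0.05)
})

test_that("detector with zero sample light and no noise is exactly constant", {
  cfg <- tiny_config(sample_to_reference_ratio = 0, shot_noise = FALSE,
                     read_noise = 0, fill_factor = 1, n_frames = 3)
  fs <- simulate_stack(cfg)
  expected <- floor(cfg$reference_photoelectrons_per_pixel /
                      cfg$quantisation_gain)
  expect_true(all(fs$frames == expected))
})

test_that("Poisson shot noise has variance equal to the mean", {
  cfg <- tiny_config(grid_size = 64, n_frames = 30,
                     sample_to_reference_ratio = 0, read_noise = 0,
                     quantisation_gain = 1, bit_depth = 16, rng_seed = 77)
  fs <- simulate_stack(cfg)
  x <- as.numeric(fs$frames)           # ~1.2e5 independent Poisson draws
  rel_se <- sqrt(2 / length(x))        # sampling error of a variance ratio
  expect_lt(abs(var(x) / mean(x) - 1), 4 * rel_se + 0.01)
})

test_that("fill factor attenuates the heterodyne band by the MTF", {
  # near-carrier band: compare alpha = 0.72 against the alpha -> 0 limit
  base <- list(grid_size = 64, n_frames = 2, rng_seed = 13,
               aperture_radius_freq = 1.2, shot_noise = FALSE,
               read_noise = 0, quantisation_gain = 1e-3, bit_depth = 30)
  f0 <- suppressWarnings(simulate_stack(do.call(tiny_config, c(base, fill_factor = 0))))
  f1 <- simulate_stack(do.call(tiny_config, c(base, fill_factor = 0.72)))
  masks <- default_masks(f0$config, signal_radius = 4)
  h0 <- reconstruct(temporal_filter(f0, "dc_pair"))
  h1 <- reconstruct(temporal_filter(f1, "dc_pair"))
  ratio <- sum(h1[, , 1][masks$plus$idx]) / sum(h0[, , 1][masks$plus$idx])
  u <- 0.3125                          # carrier at 5N/16
  expect_equal(ratio, nsinc(0.72 * u)^4, tolerance = 0.02)
})

test_that("spectral and oversampled pixel integration agree", {
  base <- list(grid_size = 32, n_frames = 3, rng_seed = 21, shot_noise = FALSE,
               read_noise = 0, quantisation_gain = 1e-3, bit_depth = 30,
               fill_factor = 0.72)
  fa <- simulate_stack(do.call(tiny_config, c(base, oversample_factor = 1)))
  fb <- simulate_stack(do.call(tiny_config, c(base, oversample_factor = 5)))
  rel <- max(abs(fa$frames - fb$frames)) / diff(range(fa$frames))
  expect_lt(rel, 0.03)
})

test_that("all randomness flows from the seed", {
  cfg <- tiny_config(n_frames = 5)
  expect_identical(simulate_stack(cfg)$frames, simulate_stack(cfg)$frames)
  cfg2 <- tiny_config(n_frames = 5, rng_seed = 102)
  expect_false(identical(simulate_stack(cfg)$frames,
                         simulate_stack(cfg2)$frames))
  # fused engine reproduces the field-stack + detector composition exactly
  fld <- make_field_stack(cfg)
  expect_identical(detector_integrate(fld)$frames, simulate_stack(cfg)$frames)
})

test_that("mode-hop injection is the identity when no hops are given", {
  cfg <- tiny_config(grid_size = 16, n_frames = 4,
                     carrier_offset = c(4, 4), aperture_radius_freq = 1.3)
  fld <- make_field_stack(cfg)
  fld2 <- inject_mode_hops(fld, integer(0))
  expect_identical(fld$fields, fld2$fields)
  expect_error(inject_mode_hops(fld, 99L), "hop_frames")
})

test_that("a mode hop produces a negative-going S1_bar outlier under dc-pair filtering", {
  cfg <- tiny_config(n_frames = 250, hop_frames = 125L, rng_seed = 321)
  fs <- simulate_stack(cfg)
  masks <- default_masks(cfg)
  r <- reconstruct_s1(fs, "dc_pair", masks)
  s1 <- r$scalars$s1_bar
  med <- median(s1)
  spread <- mad(s1[-c(124, 125)])
  # holograms 124 (frames 124-125) and 125 (frames 125-126) span the hop;
  # the washed-out hop exposure halves their heterodyne power
  expect_lt(s1[124], med - 4 * spread)
  expect_lt(s1[125], med - 4 * spread)
  # the outlier is a signal loss, visible against the series median
  expect_lt(min(s1[c(124, 125)]), min(s1[-c(124, 125)]))
})

test_that("first-frame filtering reveals an intensity step at a mode hop", {
  cfg <- tiny_config(n_frames = 250, hop_frames = 125L, rng_seed = 321)
  fs <- simulate_stack(cfg)
  masks <- default_masks(cfg)
  r <- reconstruct_s1(fs, "first_frame", masks)
  m <- r$scalars$s_plus              # masked mean intensity per hologram
  # hologram t spans frames (t+1, 1); the step sits between t = 123 and 125
  before <- m[10:123]
  after <- m[126:249]
  tt <- t.test(before, after)
  expect_lt(tt$p.value, 1e-4)
})

test_that("global clutter injection behaves as specified", {
  cfg <- tiny_config(n_frames = 40)
  fs <- simulate_stack(cfg)
  fs0 <- inject_global_clutter(fs, rep(0, 40))
  expect_identical(fs$frames, fs0$frames)
  expect_error(inject_global_clutter(fs, rep(1.1, 40)), "negative intensities")
  wav <- 0.05 * sin(2 * pi * 7 * seq_len(40) / 40)
  fsw <- inject_global_clutter(fs, wav)
  means <- apply(fsw$frames, 3, mean)
  expect_gt(cor(means / apply(fs$frames, 3, mean) - 1, wav), 0.99)
})

test_that("twin-image energy follows the model PSD across detunings", {
  # relative S1_bar shape across detunings ~ Lorentzian s1(dw)
  cfg <- tiny_config(n_frames = 60, rng_seed = 17, tau_c = 5e-4,
                     detuning_hz = c(100, 300, 900), shot_noise = TRUE)
  masks <- default_masks(cfg)
  stacks <- simulate_all(cfg)
  s1 <- vapply(stacks, function(s) {
    mean(reconstruct_s1(s, "dc_pair", masks)$scalars$s1_bar)
  }, numeric(1))
  model <- model_psd(2 * pi * cfg$detuning_hz, cfg$tau_c)
  ratio <- s1 / model
  expect_lt(max(ratio) / min(ratio), 1.35)
})
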