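test_that("temporal filtering follows the three definitions", {
  frames <- array(0, dim = c(4, 4, 3))
  frames[, , 1] <- 1; frames[, , 2] <- 2; frames[, , 3] <- 5
  dc <- temporal_filter(frames, "dc_pair")
  expect_equal(dim(dc$holos)[3], 2)
  expect_true(all(dc$holos[, , 1] == -1) && all(dc$holos[, , 2] == -3))
  ff <- temporal_filter(frames, "first_frame")
  expect_true(all(ff$holos[, , 1] == 1) && all(ff$holos[, , 2] == 4))
  sf <- temporal_filter(frames, "single_frame")
  expect_equal(dim(sf$holos)[3], 3)
  expect_error(temporal_filter(frames[, , 1, drop = FALSE], "dc_pair"),
               "at least 2")
  const <- array(7, dim = c(4, 4, 5))
  expect_true(all(temporal_filter(const, "dc_pair")$holos == 0))
})

test_that("reconstruction matches the closed form for a cosine hologram", {
  n <- 32; q <- 5
  hc <- matrix(cos(2 * pi * q * (seq_len(n) - 1) / n), n, n)
  hr <- reconstruct(hc)
  ctr <- n / 2 + 1
  expect_equal(hr[ctr + q, ctr], n^4 / 4, tolerance = 1e-10)
  expect_equal(hr[ctr - q, ctr], n^4 / 4, tolerance = 1e-10)
  mask <- matrix(TRUE, n, n)
  mask[c(ctr + q, ctr - q), ctr] <- FALSE
  expect_lt(max(hr[mask]), 1e-12 * n^4)
  expect_true(all(reconstruct(matrix(0, 8, 8)) == 0))
  expect_error(reconstruct(matrix(c(NA, rnorm(15)), 4, 4)), "non-finite")
})

test_that("Parseval holds for the unnormalised transform", {
  set.seed(4)
  hc <- matrix(rnorm(64^2), 64, 64)
  hr <- reconstruct(hc)
  expect_equal(sum(hr), 64^2 * sum(hc^2), tolerance = 1e-9)
})

test_that("MTF map has the documented values and symmetries", {
  n <- 512
  m <- mtf_map(0.72, n)
  ctr <- n / 2 + 1
  expect_equal(m[ctr, ctr], 1)
  expect_true(all(mtf_map(0, n) == 1))
  # u = -0.5 row/column: |sinc(0.36)|^2 and |sinc(0.36)|^4
  expect_equal(m[1, ctr], 0.6400684, tolerance = 1e-6)
  expect_equal(m[1, 1], 0.4096876, tolerance = 1e-6)
  expect_true(all(m > 0))
  # fourfold rotational symmetry for square pixels
  expect_equal(m[ctr + 10, ctr + 3], m[ctr - 3, ctr + 10], tolerance = 1e-12)
  expect_error(mtf_map(1.1, 16), "alpha")
})

test_that("mask construction matches lattice enumeration and symmetry", {
  geom <- list(carrier = c(128, 128), signal_radius = 80,
               shot_centre = c(-128, 128), shot_radius = 80)
  masks <- build_masks(geom, 512)
  # independent O(N^2) lattice count of a closed radius-80 disc
  g <- expand.grid(x = -90:90, y = -90:90)
  expect_equal(length(masks$plus$idx), sum(g$x^2 + g$y^2 <= 80^2))
  expect_equal(length(masks$plus$idx), 20081)
  # minus mask is the exact point reflection of the plus mask
  expect_setequal(paste(masks$minus$kx, masks$minus$ky),
                  paste(-masks$plus$kx, -masks$plus$ky))
  expect_length(intersect(masks$plus$idx, masks$minus$idx), 0)

  m0 <- build_masks(list(carrier = c(10, 10), signal_radius = 0,
                         shot_centre = c(-10, 10), shot_radius = 0), 64)
  expect_length(m0$plus$idx, 1)
  expect_error(build_masks(list(carrier = c(5, 5), signal_radius = 8,
                                shot_centre = c(-16, 16), shot_radius = 2), 64),
               "overlap|DC")
  expect_error(build_masks(list(carrier = c(28, 28), signal_radius = 8,
                                shot_centre = c(-16, 16), shot_radius = 2), 64),
               "beyond the grid")
})

test_that("S1 normalisation follows the shot-noise and MTF definitions", {
  cfg <- tiny_config()
  masks <- default_masks(cfg)
  n <- cfg$grid_size
  # constant H_R: S1_bar = 0 in all masks
  hr <- array(3, dim = c(n, n, 2))
  r <- normalize_s1(hr, masks)
  expect_equal(r$scalars$s1_bar, c(0, 0))
  expect_equal(r$scalars$n_bar, c(3, 3))
  # plus mask at twice the shot level: S1_bar(+) = 1
  hr2 <- array(5, dim = c(n, n, 1))
  plane <- hr2[, , 1]; plane[masks$plus$idx] <- 10; hr2[, , 1] <- plane
  r2 <- normalize_s1(hr2, masks, mtf = mtf_map(0, n))
  expect_equal(r2$scalars$s1_plus, 1)
  expect_equal(r2$scalars$s1_minus, 0)
  # degenerate input
  expect_error(normalize_s1(array(0, dim = c(n, n, 1)), masks), "degenerate")
  # non-positive MTF inside a mask is rejected
  bad <- mtf_map(0.72, n)
  bad[masks$plus$idx[1]] <- 0
  expect_error(normalize_s1(hr, masks, mtf = bad), "positive")
})

test_that("streaming reconstruction equals the composed operations", {
  x <- noisy_recon()
  for (mode in c("dc_pair", "first_frame", "single_frame")) {
    a <- reconstruct_s1(x$fs, mode, x$masks, mtf = x$cfg$fill_factor)
    b <- normalize_s1(reconstruct(temporal_filter(x$fs, mode)), x$masks,
                      mtf = mtf_map(x$cfg$fill_factor, x$cfg$grid_size))
    expect_equal(a$s1_plus, b$s1_plus, tolerance = 1e-12)
    expect_equal(a$scalars$s1_bar, b$scalars$s1_bar, tolerance = 1e-12)
  }
})

test_that("twin masks agree for every frame", {
  r <- noisy_recon()$recon
  # H_R of a real hologram is exactly conjugate-symmetric, so the twin
  # S1_bar values agree to numerical round-off
  expect_equal(r$scalars$s1_plus, r$scalars$s1_minus, tolerance = 1e-9)
})

test_that("shot-noise-only data give S1_bar consistent with zero", {
  cfg <- tiny_config(sample_to_reference_ratio = 0, n_frames = 150,
                     rng_seed = 55)
  fs <- simulate_stack(cfg)
  masks <- default_masks(cfg)
  r <- reconstruct_s1(fs, "dc_pair", masks)
  s1 <- r$scalars$s1_bar
  # per-frame mask-size standard error: per-pixel S1 has unit relative
  # spread (exponential H_R statistics), plus the shot-mask estimate
  se <- sqrt(1 / length(masks$plus$idx) + 1 / length(masks$shot$idx))
  expect_gt(mean(abs(s1) < 3 * se), 0.95)
  expect_lt(abs(mean(s1)), 4 * se / sqrt(length(s1)))
})

test_that("dc-pair filtering of a static noiseless stack yields S1 = 0", {
  cfg <- tiny_config(tau_c = Inf, shot_noise = FALSE, read_noise = 0,
                     n_frames = 5, substeps_per_exposure = 8,
                     detuning_hz = 0)
  fs <- simulate_stack(cfg)
  masks <- default_masks(cfg)
  h <- temporal_filter(fs, "dc_pair")
  expect_true(all(h$holos == 0))
})

test_that("MTF correction flattens the mean S1 image", {
  cfg <- tiny_config(grid_size = 128, n_frames = 150, rng_seed = 7,
                     carrier_offset = c(41, 41),
                     aperture_radius_freq = 19)  # disc covers the mask,
                                                 # self-beating term clear
  fs <- simulate_stack(cfg)
  masks <- default_masks(cfg, signal_radius = 16)
  raw <- reconstruct_s1(fs, "dc_pair", masks)
  cor_ok <- reconstruct_s1(fs, "dc_pair", masks, mtf = cfg$fill_factor)
  prof <- function(r) rowMeans(r$s1_plus)
  d2 <- masks$plus$kx^2 + masks$plus$ky^2        # radius^2 from DC
  slope_raw <- coef(lm(prof(raw) ~ d2))[2]
  fit_cor <- summary(lm(prof(cor_ok) ~ d2))
  # uncorrected: radial profile decreases away from the reference
  expect_lt(slope_raw, 0)
  expect_gt(abs(slope_raw) / fit_cor$coefficients[2, 2], 5)
  # corrected with the true alpha: residual slope is a small fraction of
  # the uncorrected distortion
  expect_lt(abs(fit_cor$coefficients[2, 1]), abs(slope_raw) / 3)
})
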