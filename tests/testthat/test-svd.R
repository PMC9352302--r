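test_that("space-time reshaping round-trips exactly", {
  st <- array(rnorm(2 * 2 * 3), dim = c(2, 2, 3))
  q <- stack_to_matrix(st)
  expect_equal(dim(q), c(4, 3))
  expect_identical(matrix_to_stack(q), st)
  # general dimension bookkeeping: n_x n_y x n_t
  st2 <- array(rnorm(6 * 5 * 7), dim = c(6, 5, 7))
  expect_equal(dim(stack_to_matrix(st2)), c(30, 7))
  expect_error(matrix_to_stack(build_R(matrix(1, 2, 2))), "spatial_dim")
})

test_that("singular spectrum matches closed forms and the full SVD", {
  expect_equal(singular_spectrum(diag(c(2, 1))), c(2, 1))
  u <- c(1, 2, 3); v <- c(2, 1)
  d <- singular_spectrum(u %*% t(v))
  expect_equal(d, c(sqrt(sum(u^2) * sum(v^2)), 0), tolerance = 1e-12)
  set.seed(8)
  m <- matrix(rnorm(400), 50, 8)
  expect_equal(singular_spectrum(m), svd(m)$d, tolerance = 1e-8)
  # energy accounting
  expect_equal(sum(singular_spectrum(m)^2), sum(m^2), tolerance = 1e-8)
  expect_error(singular_spectrum(matrix(c(NA, 1, 2, 3), 2)), "non-finite")
})

test_that("decluttering is a projection with the stated identities", {
  set.seed(9)
  m <- matrix(rnorm(50 * 6), 50, 6)
  expect_equal(svd_declutter(m, 0), m)
  r1 <- outer(rnorm(50), rnorm(6))
  expect_lt(max(abs(svd_declutter(r1, 1))), 1e-10 * max(abs(r1)))
  # orthogonal projection: removed components stay removed, the remaining
  # spectrum is the tail of the original
  f1 <- svd_declutter(m, 2)
  d0 <- singular_spectrum(m)
  expect_equal(singular_spectrum(f1)[1:4], d0[3:6], tolerance = 1e-8)
  v2 <- eigen(crossprod(m), symmetric = TRUE)$vectors[, 1:2]
  expect_lt(max(abs(f1 %*% v2)), 1e-8 * d0[1])
  # a matrix of rank <= nc is annihilated, hence idempotent
  r2 <- outer(rnorm(50), rnorm(6)) + outer(rnorm(50), rnorm(6))
  expect_equal(svd_declutter(svd_declutter(r2, 2), 2),
               svd_declutter(r2, 2), tolerance = 1e-8)
  expect_error(svd_declutter(m, 6), "nc")
  # wide-matrix fallback agrees with the Gram route on its transpose
  expect_equal(t(svd_declutter(t(m), 2)), f1, tolerance = 1e-8)
})

test_that("injected global clutter elevates leading singular values and is removed", {
  # fine quantisation, so that the injected modulation stays exactly
  # multiplicative (coarse ADC rounding adds a nonlinear clutter residual
  # that no small-nc filter can represent)
  cfg <- tiny_config(grid_size = 64, n_frames = 400, rng_seed = 250,
                     quantisation_gain = 0.05, bit_depth = 20)
  fs <- simulate_stack(cfg)
  nf <- dim(fs$frames)[3]
  wav <- 0.05 * sin(2 * pi * 0.41 * nf * seq_len(nf) / nf)  # near-Nyquist beat
  fsw <- inject_global_clutter(fs, wav)
  # dc-pair filtering leaves (and even amplifies) the beat note, which
  # lies far outside its DC stopband
  d_clean <- singular_spectrum(stack_to_matrix(temporal_filter(fs, "dc_pair")))
  d_clut <- singular_spectrum(stack_to_matrix(temporal_filter(fsw, "dc_pair")))
  expect_equal(suggest_nc(d_clean), 0)
  expect_gte(suggest_nc(d_clut), 1)
  floor_clean <- median(d_clean[1:10])
  expect_gt(d_clut[1] / floor_clean, 2)

  # decluttering the raw stack kills the correlation with the waveform
  q <- stack_to_matrix(fsw$frames)
  raw_means <- colMeans(q)
  expect_gt(abs(cor(raw_means, wav)), 0.5)
  qf <- svd_declutter(q, 2)
  expect_lt(abs(cor(colMeans(qf), wav)), 0.05)
})

test_that("nc suggestion reads elevation above a log-linear tail", {
  d <- 10 * 0.9^(0:49)
  expect_equal(suggest_nc(d), 0)
  d2 <- c(rep(10 * 10, 3), 10 * 0.9^(3:49))
  expect_equal(suggest_nc(d2), 3)
  expect_error(suggest_nc(1:5), "length")
})

test_that("speckle-only stacks rarely trigger a clutter suggestion", {
  hits <- vapply(1:10, function(s) {
    cfg <- tiny_config(n_frames = 40, rng_seed = 400 + s)
    fs <- simulate_stack(cfg)
    d <- singular_spectrum(stack_to_matrix(temporal_filter(fs, "dc_pair")))
    suggest_nc(d)
  }, integer(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("SVD filtering matches dc-pair SNR on clean data and beats it on cluttered data", {
  cfg <- tiny_config(n_frames = 120, rng_seed = 88)
  fs <- simulate_stack(cfg)
  masks <- default_masks(cfg)
  snr_of <- function(stack, mode, nc = 0) {
    if (nc > 0) {
      q <- svd_declutter(stack_to_matrix(stack$frames), nc)
      stack$frames <- matrix_to_stack(q)
    }
    r <- reconstruct_s1(stack, mode, masks, mtf = cfg$fill_factor)
    snr(r$scalars$s1_bar)
  }
  s_dc <- snr_of(fs, "dc_pair")
  s_svd <- snr_of(fs, "single_frame", nc = 10)
  expect_gt(s_svd / s_dc, 0.6)
  expect_lt(s_svd / s_dc, 1.67)

  # a stray-reflection beat note is spatially structured and outside the
  # dc-pair stopband: it degrades dc-pair S1 but is low-rank in space-time
  fsw <- inject_coherent_clutter(fs, strength = 4,
                                 beat_cycles_per_frame = 0.41, rng_seed = 9)
  s_dc_w <- snr_of(fsw, "dc_pair")
  s_svd_w <- snr_of(fsw, "single_frame", nc = 10)
  expect_lt(s_dc_w, 0.75 * s_dc)          # the clutter hurts dc-pair
  expect_gte(s_svd_w, s_dc_w)             # decluttering recovers the SNR
  d <- singular_spectrum(stack_to_matrix(temporal_filter(fsw, "dc_pair")))
  expect_gte(suggest_nc(d), 1)
})
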