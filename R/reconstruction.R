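## Holographic reconstruction: temporal filtering of camera frames,
## 2D-DFT reconstruction, frequency masks, MTF maps, and shot-noise
## normalised S1 estimation.

#' Temporal filtering of a camera frame stack
#'
#' Forms camera-plane holograms H_C from raw frames. `dc_pair` takes
#' sliding differences of successive frames (`I_n - I_(n+1)`), a high-pass
#' filter that removes the static reference contribution; `first_frame`
#' subtracts the first recorded frame (`I_(n+1) - I_1`); `single_frame`
#' passes frames through unchanged (used after SVD decluttering, which has
#' already performed temporal filtering).
#'
#' @param frame_stack An `fddcs_frames` object or a numeric/integer 3-D
#'   array (x, y, frame).
#' @param mode One of `"dc_pair"`, `"first_frame"`, `"single_frame"`.
#' @return An object of class `fddcs_holograms`: signed hologram array
#'   `holos`, the `mode`, and `source_frames` (the raw frame indices each
#'   hologram was formed from).
#' @export
temporal_filter <- function(frame_stack,
                            mode = c("dc_pair", "first_frame", "single_frame")) {
  mode <- match.arg(mode)
  frames <- if (inherits(frame_stack, "fddcs_frames")) frame_stack$frames else frame_stack
  stopifnot(length(dim(frames)) == 3)
  nf <- dim(frames)[3]
  if (mode != "single_frame" && nf < 2) {
    stop("need at least 2 frames for ", mode, " filtering")
  }
  storage.mode(frames) <- "double"
  out <- switch(mode,
    dc_pair = {
      h <- frames[, , -nf, drop = FALSE] - frames[, , -1, drop = FALSE]
      attr(h, "source") <- lapply(seq_len(nf - 1), function(n) c(n, n + 1))
      h
    },
    first_frame = {
      h <- frames[, , -1, drop = FALSE] - c(frames[, , 1])
      attr(h, "source") <- lapply(seq_len(nf - 1) + 1, function(n) c(n, 1))
      h
    },
    single_frame = {
      attr(frames, "source") <- as.list(seq_len(nf))
      frames
    })
  structure(list(holos = unname(out), mode = mode,
                 source_frames = attr(out, "source")),
            class = "fddcs_holograms")
}

## quadrant swap moving the zero-frequency bin to the grid centre
## (index N/2 + 1 for even N)
fftshift2 <- function(x) {
  n1 <- dim(x)[1]; n2 <- dim(x)[2]
  s1 <- c(seq(n1 / 2 + 1, n1), seq(1, n1 / 2))
  s2 <- c(seq(n2 / 2 + 1, n2), seq(1, n2 / 2))
  x[s1, s2]
}

#' Reconstruct intensity holograms by 2D DFT
#'
#' `H_R = |F2D(H_C)|^2` with the forward unnormalised transform and the
#' zero-frequency bin shifted to the grid centre. Parseval:
#' `sum(H_R) = N_pix * sum(H_C^2)`.
#'
#' @param holo_stack An `fddcs_holograms` object, a single matrix, or a 3-D
#'   array of camera-plane holograms (square grids).
#' @return A 3-D array of non-negative reconstructed intensities in
#'   centre-shifted frequency coordinates (or a matrix if a matrix was
#'   given).
#' @export
reconstruct <- function(holo_stack) {
  h <- if (inherits(holo_stack, "fddcs_holograms")) holo_stack$holos else holo_stack
  if (is.matrix(h)) {
    if (nrow(h) != ncol(h)) stop("holograms must be square")
    if (any(!is.finite(h))) stop("non-finite values in hologram")
    return(fftshift2(Mod(fft(h))^2))
  }
  stopifnot(length(dim(h)) == 3)
  if (dim(h)[1] != dim(h)[2]) stop("holograms must be square")
  out <- array(NA_real_, dim = dim(h))
  for (t in seq_len(dim(h)[3])) {
    ht <- h[, , t]
    if (any(!is.finite(ht))) stop("non-finite values in hologram ", t)
    out[, , t] <- fftshift2(Mod(fft(ht))^2)
  }
  out
}

#' Modulation transfer function map of the camera pixel aperture
#'
#' `MTF(kx, ky) = |sinc(alpha u) sinc(alpha v)|^2` where `(u, v)` run
#' linearly over `[-0.5, +0.5]` across the centre-shifted grid; `alpha` is
#' the linear pixel fill factor. The map is 1 at the origin and strictly
#' positive over the sampled range.
#'
#' @param alpha Fill factor in `[0, 1]`.
#' @param grid_size Grid side length (pixels).
#' @return A `grid_size x grid_size` matrix in shifted coordinates, with
#'   attribute `alpha`.
#' @export
mtf_map <- function(alpha, grid_size) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  k <- seq_len(grid_size) - (grid_size / 2 + 1)
  u <- k / grid_size
  s <- nsinc(alpha * u)^2
  structure(outer(s, s), alpha = alpha)
}

## closed-disc pixel set around a centre in signed shifted coordinates
disc_pixels <- function(centre, radius, grid_size) {
  cx <- centre[1]; cy <- centre[2]
  kx <- seq(floor(cx - radius), ceiling(cx + radius))
  ky <- seq(floor(cy - radius), ceiling(cy + radius))
  g <- expand.grid(kx = kx, ky = ky)
  g <- g[(g$kx - cx)^2 + (g$ky - cy)^2 <= radius^2, , drop = FALSE]
  g
}

## signed shifted coordinates -> linear index into the shifted N x N grid
shifted_index <- function(kx, ky, n) {
  half <- n / 2
  ## wrap to the representable range [-n/2, n/2 - 1]
  kx <- ((kx + half) %% n) - half
  ky <- ((ky + half) %% n) - half
  (kx + half) + 1 + n * (ky + half)
}

#' Build the heterodyne and shot-noise masks
#'
#' Pixel-index sets over the centre-shifted reconstruction grid: a closed
#' disc (`x^2 + y^2 <= r^2` on the integer lattice) around the positive
#' heterodyne image, its exact point reflection through the origin for the
#' conjugate twin, and a disc in a quiet corner for the shot-noise
#' estimate. The three masks must be pairwise disjoint, inside the grid,
#' and must avoid the DC pixel.
#'
#' @param geometry List with `carrier` (length-2 centre of the positive
#'   heterodyne image in shifted coordinates), `signal_radius`,
#'   `shot_centre` and `shot_radius` (pixels).
#' @param grid_size Grid side length.
#' @return An object of class `fddcs_masks`: for each of `plus`, `minus`,
#'   `shot`, the linear indices `idx` into the shifted grid and the signed
#'   coordinates `kx`, `ky`.
#' @export
build_masks <- function(geometry, grid_size) {
  stopifnot(all(c("carrier", "signal_radius", "shot_centre", "shot_radius")
                %in% names(geometry)))
  n <- grid_size
  plus <- disc_pixels(geometry$carrier, geometry$signal_radius, n)
  minus <- data.frame(kx = -plus$kx, ky = -plus$ky)
  shot <- disc_pixels(geometry$shot_centre, geometry$shot_radius, n)
  sets <- list(plus = plus, minus = minus, shot = shot)
  out <- lapply(sets, function(g) {
    if (any(g$kx < -n / 2 | g$kx > n / 2 - 1 | g$ky < -n / 2 | g$ky > n / 2 - 1)) {
      stop("mask extends beyond the grid")
    }
    list(idx = as.integer(shifted_index(g$kx, g$ky, n)), kx = g$kx, ky = g$ky)
  })
  bad <- c(
    if (length(intersect(out$plus$idx, out$minus$idx))) "plus/minus",
    if (length(intersect(out$plus$idx, out$shot$idx))) "plus/shot",
    if (length(intersect(out$minus$idx, out$shot$idx))) "minus/shot")
  if (length(bad)) stop("masks overlap: ", paste(bad, collapse = ", "))
  dc <- shifted_index(0, 0, n)
  if (any(vapply(out, function(m) dc %in% m$idx, logical(1)))) {
    stop("masks must avoid the DC pixel")
  }
  structure(c(out, list(grid_size = n, geometry = geometry)),
            class = "fddcs_masks")
}

#' Default mask geometry for a simulation configuration
#'
#' Signal masks centred on the configured carrier offset; the shot-noise
#' mask sits in the quiet corner obtained by reflecting the carrier in x.
#'
#' @param config An [simulation_config()] object.
#' @param signal_radius Radius of the heterodyne masks (pixels); default 80
#'   scaled with grid size relative to 512.
#' @param shot_radius Radius of the shot-noise mask; defaults to
#'   `signal_radius`.
#' @return An `fddcs_masks` object.
#' @export
default_masks <- function(config,
                          signal_radius = 80 * config$grid_size / 512,
                          shot_radius = signal_radius) {
  build_masks(list(carrier = config$carrier_offset,
                   signal_radius = signal_radius,
                   shot_centre = c(-config$carrier_offset[1],
                                   config$carrier_offset[2]),
                   shot_radius = shot_radius),
              config$grid_size)
}

#' Shot-noise-normalised S1 estimation
#'
#' For every reconstructed hologram, the shot-noise level `N_bar` is the
#' mean of H_R over the shot-noise mask; per-pixel
#' `S1 = (H_R / N_bar - 1)`, additionally divided by the MTF value at that
#' pixel when a map is supplied (the shot-noise component is homodyne and
#' is not MTF-corrected); `S1_bar(+/-dw)` is the mean of per-pixel S1 over
#' each heterodyne mask, and `S1_bar(dw)` the mean of the two (the twin
#' images are identical up to noise).
#'
#' @param hr 3-D array of reconstructed intensities in shifted coordinates
#'   (or a single matrix).
#' @param masks An `fddcs_masks` object.
#' @param mtf Optional [mtf_map()] output.
#' @return An object of class `fddcs_recon`: `scalars` (data frame with
#'   columns frame, s_plus, s_minus, n_bar, s1_plus, s1_minus, s1_bar),
#'   per-pixel matrices `s1_plus`, `s1_minus` (mask pixels x frames),
#'   `masks`, `mtf_applied`, `alpha`.
#' @export
normalize_s1 <- function(hr, masks, mtf = NULL) {
  if (is.matrix(hr)) hr <- array(hr, dim = c(dim(hr), 1))
  stopifnot(inherits(masks, "fddcs_masks"), length(dim(hr)) == 3)
  nt <- dim(hr)[3]
  mtf_plus <- mtf_minus <- NULL
  if (!is.null(mtf)) {
    mtf_plus <- mtf[masks$plus$idx]
    mtf_minus <- mtf[masks$minus$idx]
    if (any(mtf_plus <= 0) || any(mtf_minus <= 0)) {
      stop("MTF values inside the heterodyne masks must be positive")
    }
  }
  np <- length(masks$plus$idx)
  s1p <- matrix(NA_real_, np, nt)
  s1m <- matrix(NA_real_, np, nt)
  sc <- data.frame(frame = seq_len(nt), s_plus = NA_real_, s_minus = NA_real_,
                   n_bar = NA_real_, s1_plus = NA_real_, s1_minus = NA_real_,
                   s1_bar = NA_real_)
  for (t in seq_len(nt)) {
    plane <- hr[, , t]
    nbar <- mean(plane[masks$shot$idx])
    if (!is.finite(nbar) || nbar <= 0) {
      stop("degenerate input: shot-noise level N_bar is not positive ",
           "(frame ", t, ")")
    }
    vp <- plane[masks$plus$idx] / nbar - 1
    vm <- plane[masks$minus$idx] / nbar - 1
    if (!is.null(mtf)) {
      vp <- vp / mtf_plus
      vm <- vm / mtf_minus
    }
    s1p[, t] <- vp
    s1m[, t] <- vm
    sc$s_plus[t] <- mean(plane[masks$plus$idx])
    sc$s_minus[t] <- mean(plane[masks$minus$idx])
    sc$n_bar[t] <- nbar
    sc$s1_plus[t] <- mean(vp)
    sc$s1_minus[t] <- mean(vm)
  }
  sc$s1_bar <- (sc$s1_plus + sc$s1_minus) / 2
  structure(list(scalars = sc, s1_plus = s1p, s1_minus = s1m, masks = masks,
                 mtf_applied = !is.null(mtf),
                 alpha = if (!is.null(mtf)) attr(mtf, "alpha") else NA_real_),
            class = "fddcs_recon")
}

#' Temporal filter, reconstruct and normalise in one streaming pass
#'
#' Equivalent to `normalize_s1(reconstruct(temporal_filter(frames, mode)),
#' masks, mtf)` but never materialises the full H_R stack, so full-scale
#' (512 x 512 x 501) runs stay within memory.
#'
#' @inheritParams temporal_filter
#' @inheritParams normalize_s1
#' @param mtf Optional [mtf_map()] output, or a fill factor `alpha` given
#'   as a single number.
#' @param nbar `"per_frame"` (default: normalise by each
#'   hologram's own shot-noise level) or `"global"` (normalise every
#'   hologram by the mean shot-noise level over the whole series; useful
#'   for noiseless synthetic data, where a per-hologram shot estimate is
#'   degenerate).
#' @param keep_mean_hr If `TRUE`, also accumulate the mean over frames of
#'   `H_R / N_bar` (full grid), used for fill-factor calibration displays.
#' @return An `fddcs_recon` object (plus `mean_hr_ratio` if requested).
#' @export
reconstruct_s1 <- function(frame_stack,
                           mode = c("dc_pair", "first_frame", "single_frame"),
                           masks, mtf = NULL,
                           nbar = c("per_frame", "global"),
                           keep_mean_hr = FALSE) {
  mode <- match.arg(mode)
  nbar <- match.arg(nbar)
  frames <- if (inherits(frame_stack, "fddcs_frames")) frame_stack$frames else frame_stack
  stopifnot(length(dim(frames)) == 3)
  if (is.numeric(mtf) && length(mtf) == 1) {
    mtf <- mtf_map(mtf, dim(frames)[1])
  }
  nf <- dim(frames)[3]
  n <- dim(frames)[1]
  if (mode != "single_frame" && nf < 2) stop("need at least 2 frames")
  nt <- if (mode == "single_frame") nf else nf - 1
  mtf_plus <- mtf_minus <- NULL
  if (!is.null(mtf)) {
    mtf_plus <- mtf[masks$plus$idx]
    mtf_minus <- mtf[masks$minus$idx]
    if (any(mtf_plus <= 0) || any(mtf_minus <= 0)) {
      stop("MTF values inside the heterodyne masks must be positive")
    }
  }
  np <- length(masks$plus$idx)
  s1p <- matrix(NA_real_, np, nt)
  s1m <- matrix(NA_real_, np, nt)
  nbar_t <- numeric(nt)
  sc <- data.frame(frame = seq_len(nt), s_plus = NA_real_, s_minus = NA_real_,
                   n_bar = NA_real_, s1_plus = NA_real_, s1_minus = NA_real_,
                   s1_bar = NA_real_)
  mean_hr <- if (keep_mean_hr) matrix(0, n, n) else NULL
  first <- if (mode == "first_frame") frames[, , 1] else NULL
  for (t in seq_len(nt)) {
    hc <- switch(mode,
                 dc_pair = frames[, , t] - frames[, , t + 1],
                 first_frame = frames[, , t + 1] - first,
                 single_frame = frames[, , t])
    plane <- fftshift2(Mod(fft(hc))^2)
    nbar_t[t] <- mean(plane[masks$shot$idx])
    s1p[, t] <- plane[masks$plus$idx]
    s1m[, t] <- plane[masks$minus$idx]
    sc$s_plus[t] <- mean(plane[masks$plus$idx])
    sc$s_minus[t] <- mean(plane[masks$minus$idx])
    if (keep_mean_hr) mean_hr <- mean_hr + plane
  }
  if (nbar == "global") nbar_t <- rep(mean(nbar_t), nt)
  if (any(!is.finite(nbar_t)) || any(nbar_t <= 0)) {
    stop("degenerate input: shot-noise level N_bar is not positive")
  }
  sc$n_bar <- nbar_t
  s1p <- sweep(s1p, 2, nbar_t, "/") - 1
  s1m <- sweep(s1m, 2, nbar_t, "/") - 1
  if (!is.null(mtf)) {
    s1p <- s1p / mtf_plus
    s1m <- s1m / mtf_minus
  }
  sc$s1_plus <- colMeans(s1p)
  sc$s1_minus <- colMeans(s1m)
  sc$s1_bar <- (sc$s1_plus + sc$s1_minus) / 2
  if (keep_mean_hr) mean_hr <- mean_hr / nt / mean(nbar_t)
  out <- structure(list(scalars = sc, s1_plus = s1p, s1_minus = s1m,
                        masks = masks, mtf_applied = !is.null(mtf),
                        alpha = if (!is.null(mtf)) attr(mtf, "alpha") else NA_real_,
                        filter_mode = mode),
                   class = "fddcs_recon")
  if (keep_mean_hr) out$mean_hr_ratio <- mean_hr
  out
}

#' @export
print.fddcs_recon <- function(x, ...) {
  cat(sprintf("FD-DCS reconstruction: %d holograms, %d mask px, MTF %s\n",
              nrow(x$scalars), nrow(x$s1_plus),
              if (x$mtf_applied) sprintf("alpha = %.3f", x$alpha) else "off"))
  cat(sprintf("  mean S1_bar = %.4g, sd = %.4g\n",
              mean(x$scalars$s1_bar), sd(x$scalars$s1_bar)))
  invisible(x)
}
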