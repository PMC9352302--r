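## SNR, speckle-count and SNR-gain analysis. The SNR of an S1_bar series
## is mean/sd over repeats; for a speckle detection instrument it should
## scale with the square root of the number of detected speckles, and the
## SNR gain of multispeckle over single-speckle detection is measured as
## the ratio of the two SNRs at the same detuning.

#' Signal-to-noise ratio of an S1_bar series
#'
#' Ratio of the mean to the sample standard deviation (N-1 denominator).
#'
#' @param x Numeric vector, length >= 3.
#' @return A single number.
#' @export
snr <- function(x) {
  if (length(x) < 3) stop("need at least 3 repeats for an SNR estimate")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("undefined SNR: series has zero spread")
  mean(x) / s
}

#' Speckle area on the camera sensor
#'
#' `S = (lambda z)^2 / A_aperture`, also expressed in camera pixels.
#'
#' @param geometry An [speckle_geometry()] object.
#' @return List with `area_m2` and `area_px`.
#' @export
speckle_area <- function(geometry = speckle_geometry()) {
  stopifnot(inherits(geometry, "fddcs_geometry"))
  S <- (geometry$wavelength * geometry$distance)^2 / geometry$aperture_area
  list(area_m2 = S, area_px = S / geometry$pixel_pitch^2)
}

#' Concentric mask closest to one speckle area
#'
#' Searches closed-disc lattice masks for the pixel count closest to one
#' speckle area; this defines the single-speckle reference of the SNR-gain
#' analysis.
#'
#' @param speckle_px Speckle area in pixels.
#' @return List with `radius` (the smallest radius attaining the count)
#'   and `n_pixels`.
#' @export
single_speckle_mask <- function(speckle_px) {
  stopifnot(speckle_px >= 1)
  r2max <- ceiling(4 * speckle_px)
  span <- ceiling(sqrt(r2max))
  g <- expand.grid(x = -span:span, y = -span:span)
  d2 <- g$x^2 + g$y^2
  counts <- vapply(0:r2max, function(t) sum(d2 <= t), integer(1))
  best <- which.min(abs(counts - speckle_px))
  list(radius = sqrt(best - 1), n_pixels = counts[best])
}

#' SNR versus mask radius
#'
#' Recomputes the per-frame S1_bar over concentric reduced masks and the
#' SNR of each series. The number of detected speckles is
#' `mask pixels / speckle_px` (real-valued). Frames series with undefined
#' SNR (zero spread) propagate as `NA` gaps.
#'
#' @param recon An `fddcs_recon` object (per-pixel S1 values and masks).
#' @param radii Mask radii (pixels), strictly increasing, each at most the
#'   recorded mask radius.
#' @param speckle_px Speckle area in pixels; default from the reference
#'   instrument geometry.
#' @param use `"both"` (average the twin masks, default), `"plus"` or
#'   `"minus"`.
#' @return An object of class `fddcs_snr_curve`: data frame with columns
#'   radius, n_pixels, n_speckles, snr.
#' @export
mask_radius_sweep <- function(recon, radii,
                              speckle_px = speckle_area()$area_px,
                              use = c("both", "plus", "minus")) {
  use <- match.arg(use)
  stopifnot(inherits(recon, "fddcs_recon"))
  if (is.unsorted(radii, strictly = TRUE)) {
    stop("radii must be strictly increasing")
  }
  masks <- recon$masks
  if (max(radii) > masks$geometry$signal_radius) {
    stop("radius beyond the recorded mask")
  }
  cp <- masks$geometry$carrier
  d2p <- (masks$plus$kx - cp[1])^2 + (masks$plus$ky - cp[2])^2
  d2m <- (masks$minus$kx + cp[1])^2 + (masks$minus$ky + cp[2])^2
  out <- data.frame(radius = radii, n_pixels = NA_integer_,
                    n_speckles = NA_real_, snr = NA_real_)
  for (i in seq_along(radii)) {
    subp <- d2p <= radii[i]^2
    out$n_pixels[i] <- sum(subp)
    out$n_speckles[i] <- sum(subp) / speckle_px
    if (!any(subp)) next
    series <- switch(use,
      plus = colMeans(recon$s1_plus[subp, , drop = FALSE]),
      minus = colMeans(recon$s1_minus[d2m <= radii[i]^2, , drop = FALSE]),
      both = (colMeans(recon$s1_plus[subp, , drop = FALSE]) +
              colMeans(recon$s1_minus[d2m <= radii[i]^2, , drop = FALSE])) / 2)
    out$snr[i] <- tryCatch(snr(series), error = function(e) NA_real_)
  }
  structure(out, class = c("fddcs_snr_curve", "data.frame"),
            speckle_px = speckle_px, use = use)
}

#' SNR gain over the single-speckle reference
#'
#' `gain(r) = SNR(r) / SNR_single`, with the single-speckle SNR measured
#' on the concentric mask whose pixel count is closest to one speckle area
#' ([single_speckle_mask()]), at the same detuning.
#'
#' @param curve An [mask_radius_sweep()] result.
#' @param snr_single Single-speckle SNR; if missing, it is taken from the
#'   curve row at the single-speckle radius (which must be present).
#' @return The curve with an added `gain` column; attribute `snr_single`.
#' @export
snr_gain <- function(curve, snr_single = NULL) {
  stopifnot(inherits(curve, "fddcs_snr_curve"))
  if (is.null(snr_single)) {
    ref <- single_speckle_mask(attr(curve, "speckle_px"))
    i <- which(abs(curve$radius - ref$radius) < 1e-9)
    if (!length(i)) {
      stop("single-speckle reference radius ", signif(ref$radius, 4),
           " not present in the sweep; pass snr_single explicitly")
    }
    snr_single <- curve$snr[i[1]]
  }
  if (!is.finite(snr_single) || snr_single <= 0) {
    stop("missing or invalid single-speckle reference SNR")
  }
  curve$gain <- curve$snr / snr_single
  attr(curve, "snr_single") <- snr_single
  curve
}

#' Log-log slope of SNR versus speckle count
#'
#' Least-squares slope of `log(snr)` on `log(n_speckles)`; 0.5 is the
#' multispeckle scaling target (SNR proportional to the square root of the
#' number of detected speckles).
#'
#' @param curve An [mask_radius_sweep()] result.
#' @return The fitted slope.
#' @export
snr_loglog_slope <- function(curve) {
  ok <- is.finite(curve$snr) & curve$snr > 0
  if (sum(ok) < 3) stop("need at least 3 usable radii for a slope")
  unname(coef(lm(log(curve$snr[ok]) ~ log(curve$n_speckles[ok])))[2])
}
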