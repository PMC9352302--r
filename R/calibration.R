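## Fill-factor calibration: the camera MTF attenuates high heterodyne
## spatial frequencies; on a spatially flat sample the mean reconstructed
## S1 image should be flat, so the effective fill factor alpha is the value
## whose MTF correction minimises the variance of the mean S1 image over
## the heterodyne masks.

#' Estimate the effective pixel fill factor
#'
#' Sweeps `alpha` over a grid; for each value the per-pixel mean-over-frames
#' S1 image is corrected with `mtf_map(alpha)` and the variance over the
#' union of the two heterodyne masks is computed. The minimising `alpha` is
#' refined by golden-section search between the best grid neighbours.
#'
#' Expects data from a spatially flat sample (the objective is meaningless
#' otherwise) reconstructed *without* MTF correction.
#'
#' @param recon An `fddcs_recon` object with `mtf_applied = FALSE`, or a
#'   3-D H_R array (then `masks` is required and normalisation is applied
#'   here).
#' @param masks Masks; default taken from `recon`.
#' @param alpha_grid Search grid on `[0, 1]`; default 101 points.
#' @param objective `"variance"` (default) or a function
#'   `f(s1_values, kx, ky)` returning the scalar to minimise; alternative
#'   flatness targets (radial-profile gradient, asymmetry) can be plugged
#'   in this way.
#' @param refine_tol Absolute tolerance of the golden-section refinement.
#' @param min_frames Minimum number of frames required.
#' @return An object of class `fddcs_fillfactor`: `alpha_hat`, the
#'   variance-vs-alpha `curve` (data frame), `sigma2_min`, `n_frames`, and
#'   `boundary` (TRUE when the optimum sits on the grid edge, with a
#'   warning).
#' @export
fit_fill_factor <- function(recon, masks = NULL,
                            alpha_grid = seq(0, 1, length.out = 101),
                            objective = "variance",
                            refine_tol = 1e-3,
                            min_frames = 10) {
  if (inherits(recon, "fddcs_recon")) {
    if (recon$mtf_applied) {
      stop("fit_fill_factor needs an uncorrected reconstruction ",
           "(mtf_applied must be FALSE)")
    }
    masks <- recon$masks
    nfr <- ncol(recon$s1_plus)
    ## mean over frames of the raw per-pixel S1 on each mask
    mean_raw <- c(rowMeans(recon$s1_plus), rowMeans(recon$s1_minus))
  } else {
    stopifnot(length(dim(recon)) == 3, !is.null(masks))
    nfr <- dim(recon)[3]
    nr <- normalize_s1(recon, masks)
    mean_raw <- c(rowMeans(nr$s1_plus), rowMeans(nr$s1_minus))
  }
  if (nfr < min_frames) {
    stop("fill-factor calibration needs at least ", min_frames,
         " frames (got ", nfr, ")")
  }
  n <- masks$grid_size
  kx <- c(masks$plus$kx, masks$minus$kx)
  ky <- c(masks$plus$ky, masks$minus$ky)
  u <- kx / n
  v <- ky / n
  obj_fun <- if (is.function(objective)) {
    function(alpha) {
      corr <- mean_raw / (nsinc(alpha * u)^2 * nsinc(alpha * v)^2)
      objective(corr, kx, ky)
    }
  } else if (identical(objective, "variance")) {
    function(alpha) {
      corr <- mean_raw / (nsinc(alpha * u)^2 * nsinc(alpha * v)^2)
      var(corr)
    }
  } else {
    stop("unknown objective: ", objective)
  }
  sig2 <- vapply(alpha_grid, obj_fun, numeric(1))
  i <- which.min(sig2)
  boundary <- i == 1 || i == length(alpha_grid)
  if (boundary) {
    warning("fill-factor optimum at the boundary of the search grid")
    alpha_hat <- alpha_grid[i]
    s2min <- sig2[i]
  } else {
    opt <- optimize(obj_fun, lower = alpha_grid[i - 1],
                    upper = alpha_grid[i + 1], tol = refine_tol)
    alpha_hat <- opt$minimum
    s2min <- opt$objective
  }
  structure(list(alpha_hat = alpha_hat,
                 curve = data.frame(alpha = alpha_grid, sigma2 = sig2),
                 sigma2_min = s2min, n_frames = nfr, boundary = boundary),
            class = "fddcs_fillfactor")
}

#' @export
print.fddcs_fillfactor <- function(x, ...) {
  cat(sprintf("Fill-factor fit: alpha_hat = %.3f (sigma2_min = %.4g, %d frames%s)\n",
              x$alpha_hat, x$sigma2_min, x$n_frames,
              if (x$boundary) ", boundary optimum" else ""))
  invisible(x)
}
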