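## SVD spatiotemporal clutter filtering. Frames are flattened into a
## space-time matrix Q (n_space x n_time); the largest singular values
## capture variations with the strongest spatiotemporal correlation
## (clutter), which fully developed speckle lacks, so zeroing the first
## n_c singular values and rebuilding Q removes the clutter.

#' Reshape a stack into a space-time matrix
#'
#' Column t is frame t flattened in a fixed (column-major) order; the
#' round trip through [matrix_to_stack()] is the identity.
#'
#' @param stack A 3-D array (x, y, frame), an `fddcs_frames` /
#'   `fddcs_holograms` object, or a matrix of already-masked values
#'   (space x time; kept as is).
#' @param provenance Label recorded on the result: `"camera_plane_Q"` for
#'   camera-plane holograms, `"reconstructed_R"` for masked reconstructed
#'   values.
#' @return An object of class `fddcs_stm`: numeric matrix
#'   (n_space x n_time) with attributes `spatial_dim` (or `mask_size`) and
#'   `provenance`.
#' @export
stack_to_matrix <- function(stack, provenance = "camera_plane_Q") {
  if (inherits(stack, "fddcs_frames")) stack <- stack$frames
  if (inherits(stack, "fddcs_holograms")) stack <- stack$holos
  if (is.matrix(stack)) {
    m <- stack
    attr(m, "spatial_dim") <- NULL
    attr(m, "mask_size") <- nrow(stack)
  } else {
    stopifnot(length(dim(stack)) == 3)
    d <- dim(stack)
    m <- matrix(as.numeric(stack), d[1] * d[2], d[3])
    attr(m, "spatial_dim") <- d[1:2]
  }
  attr(m, "provenance") <- provenance
  class(m) <- c("fddcs_stm", class(m))
  m
}

#' Inverse of [stack_to_matrix()]
#'
#' @param m An `fddcs_stm` matrix with a `spatial_dim` attribute.
#' @return The 3-D array (x, y, frame).
#' @export
matrix_to_stack <- function(m) {
  d <- attr(m, "spatial_dim")
  if (is.null(d)) stop("matrix has no spatial_dim; it came from masked values")
  array(as.numeric(m), dim = c(d, ncol(m)))
}

## singular values and right (time) singular vectors via the time-side
## Gram matrix; identical to a full decomposition for tall matrices
time_side_svd <- function(m) {
  g <- crossprod(m)                      # n_time x n_time
  e <- eigen(g, symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  list(d = d, v = e$vectors)
}

#' Singular spectrum of a space-time matrix
#'
#' All `n_time` singular values in non-increasing order, computed through
#' the `n_time x n_time` Gram matrix for tall inputs (identical to a full
#' decomposition to within 1e-8 relative).
#'
#' @param m A matrix or `fddcs_stm` object (n_space x n_time,
#'   n_space >= n_time).
#' @return Numeric vector of singular values.
#' @export
singular_spectrum <- function(m) {
  if (any(!is.finite(m))) stop("non-finite entries in space-time matrix")
  if (nrow(m) < ncol(m)) return(svd(m, nu = 0, nv = 0)$d)
  time_side_svd(m)$d
}

#' Remove the strongest spatiotemporal components
#'
#' Rebuilds the space-time matrix with its first `nc` singular values set
#' to zero; the result is the orthogonal projection of the data away from
#' the `nc` leading spatiotemporal components. Downstream reconstruction
#' should use `single_frame` temporal filtering, since the SVD step has
#' already removed the static (and any slowly varying) contribution.
#'
#' @param m A matrix or `fddcs_stm` object (n_space x n_time).
#' @param nc Number of leading singular values to zero, `0 <= nc < n_time`.
#' @return The filtered matrix, same shape and attributes as the input.
#' @export
svd_declutter <- function(m, nc) {
  nt <- ncol(m)
  if (nc < 0 || nc >= nt) stop("nc must satisfy 0 <= nc < n_time")
  if (nc == 0) return(m)
  if (any(!is.finite(m))) stop("non-finite entries in space-time matrix")
  att <- attributes(m)
  if (nrow(m) >= nt) {
    v <- time_side_svd(m)$v[, seq_len(nc), drop = FALSE]
    out <- m - (m %*% v) %*% t(v)
  } else {
    s <- svd(m)
    keep <- seq_len(length(s$d))[-seq_len(nc)]
    out <- s$u[, keep, drop = FALSE] %*%
      (s$d[keep] * t(s$v[, keep, drop = FALSE]))
  }
  attributes(out) <- att
  out
}

#' Suggest a clutter-component count from a singular spectrum
#'
#' Fits a log-linear baseline to the body of the spectrum (indices between
#' 35% and 80% of the range, avoiding both any elevated head and the sharp
#' roll-off of the last singular values of a noise matrix) and returns the
#' number of leading values elevated above `factor` times the extrapolated
#' baseline; 0 when no elevation is detected. Advisory only: the threshold
#' used for filtering should be chosen by inspection.
#'
#' @param d Singular values, non-increasing, length >= 20.
#' @param factor Elevation factor over the baseline (default 1.25).
#' @return Integer suggested `nc`.
#' @export
suggest_nc <- function(d, factor = 1.25) {
  stopifnot(length(d) >= 20)
  n <- length(d)
  tail_idx <- seq(max(2, ceiling(0.35 * n)), floor(0.8 * n))
  pos <- d[tail_idx] > 0
  ti <- tail_idx[pos]
  fit <- lm(log(d[ti]) ~ ti)
  base <- exp(coef(fit)[1] + coef(fit)[2] * seq_len(n))
  elevated <- d > factor * base
  ## count the contiguous run of elevated values from the top
  nc <- 0L
  for (i in seq_len(n)) {
    if (!elevated[i]) break
    nc <- i
  }
  as.integer(nc)
}
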