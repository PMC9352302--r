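## Multispeckle denoising: each column of the space-time matrix R of
## masked S1 values is an independently randomised sample of the same S1
## distribution. Sorting each column into ascending order removes the
## random spatial arrangement; a median filter along time then removes
## detector noise (which behaves as additional speckle-like noise in each
## reconstructed hologram); reversing the per-column sort restores the
## spatial arrangement of ranks exactly.

#' Build the space-time matrix R of masked S1 values
#'
#' Column t holds the S1 values of frame t at the mask pixels; the values
#' are copied bit-exactly.
#'
#' @param s1_stack A 3-D array of per-pixel S1 frames, or a matrix already
#'   in space x time form (returned unchanged apart from attributes).
#' @param mask Integer linear pixel indices (e.g. `masks$plus$idx`);
#'   required for array input.
#' @return An `fddcs_stm` matrix (mask pixels x frames) with provenance
#'   `"reconstructed_R"` and the mask stored in attribute `mask_idx`.
#' @export
build_R <- function(s1_stack, mask = NULL) {
  if (is.matrix(s1_stack) && length(dim(s1_stack)) == 2) {
    m <- s1_stack
  } else {
    stopifnot(length(dim(s1_stack)) == 3, !is.null(mask))
    nt <- dim(s1_stack)[3]
    m <- vapply(seq_len(nt), function(t) {
      plane <- s1_stack[, , t]
      v <- plane[mask]
      if (anyNA(v)) stop("mask mismatch: NA values inside the mask")
      v
    }, numeric(length(mask)))
    m <- matrix(m, nrow = length(mask), ncol = nt)
  }
  attr(m, "mask_idx") <- mask
  attr(m, "provenance") <- "reconstructed_R"
  class(m) <- c("fddcs_stm", class(m))
  m
}

#' Restore masked S1 values to per-pixel frames
#'
#' Exact inverse of [build_R()] for array input.
#'
#' @param R Space-time matrix of masked values.
#' @param mask Integer linear pixel indices; defaults to the `mask_idx`
#'   attribute of `R`.
#' @param frame_dim Length-2 spatial dimensions of the output frames.
#' @return A 3-D array with the mask values in place and `NA` elsewhere.
#' @export
restore_mask <- function(R, mask = attr(R, "mask_idx"), frame_dim) {
  if (is.null(mask)) stop("mask indices required")
  if (length(mask) != nrow(R)) stop("mask size does not match matrix rows")
  out <- array(NA_real_, dim = c(frame_dim, ncol(R)))
  plane_len <- prod(frame_dim)
  for (t in seq_len(ncol(R))) {
    out[mask + (t - 1) * plane_len] <- R[, t]
  }
  out
}

## element-wise ascending sort of a list of equal-shaped numeric objects
## (bubble network of pmin/pmax passes; efficient for small lists)
elementwise_sort <- function(lst) {
  k <- length(lst)
  for (i in seq_len(max(k - 1, 0))) {
    for (j in seq_len(k - i)) {
      lo <- pmin(lst[[j]], lst[[j + 1]])
      hi <- pmax(lst[[j]], lst[[j + 1]])
      lst[[j]] <- lo
      lst[[j + 1]] <- hi
    }
  }
  lst
}

## running median of each row along columns, window n, replicate edges;
## even windows use the mean of the two central order statistics
row_running_median <- function(m, n, edge = "replicate") {
  if (n == 1) return(m)
  nt <- ncol(m)
  offsets <- seq_len(n) - 1 - ((n - 1) %/% 2)
  shifted <- lapply(offsets, function(d) {
    cols <- seq_len(nt) + d
    if (edge == "replicate") {
      cols <- pmin(pmax(cols, 1), nt)
    } else {
      stop("unknown edge policy: ", edge)
    }
    m[, cols, drop = FALSE]
  })
  s <- elementwise_sort(shifted)
  if (n %% 2 == 1) {
    s[[(n + 1) / 2]]
  } else {
    (s[[n / 2]] + s[[n / 2 + 1]]) / 2
  }
}

#' Sort-median-unsort multispeckle denoising
#'
#' (1) Each column of `R` is sorted into ascending order and the sorting
#' permutation recorded (ties broken by original index); (2) each row of
#' the sorted matrix is median filtered along the time axis with a
#' `[1 x n]` neighbourhood and the configured edge policy; (3) each
#' column's inverse permutation is applied, restoring the spatial
#' arrangement of ranks exactly.
#'
#' Even `n` is allowed; the median of an even window is the mean of the
#' two central order statistics. `n = 1` is the identity.
#'
#' @param R Space-time matrix (space x time), e.g. from [build_R()].
#' @param n Time-axis window width, `1 <= n <= n_frames`.
#' @param edge Edge policy for the time axis; `"replicate"` (nearest
#'   neighbour padding, output length equals input).
#' @return The denoised matrix, same shape and attributes as `R`.
#' @export
sort_median_unsort <- function(R, n = 3, edge = "replicate") {
  stopifnot(is.matrix(R))
  if (n < 1) stop("window n must be >= 1")
  if (n > ncol(R)) stop("window n exceeds the number of frames")
  if (n == 1) return(R)
  att <- attributes(R)
  m <- nrow(R)
  nt <- ncol(R)
  ord <- matrix(NA_integer_, m, nt)
  for (j in seq_len(nt)) ord[, j] <- order(R[, j])
  lin <- ord + rep((seq_len(nt) - 1) * m, each = m)
  sorted <- matrix(R[lin], m, nt)
  med <- row_running_median(sorted, n, edge)
  out <- matrix(NA_real_, m, nt)
  out[lin] <- med
  attributes(out) <- att
  out
}

#' Denoise a reconstruction result
#'
#' Applies [sort_median_unsort()] to the per-pixel S1 matrices of both
#' heterodyne masks and recomputes the per-frame scalars from the denoised
#' values.
#'
#' @param recon An `fddcs_recon` object.
#' @inheritParams sort_median_unsort
#' @return A new `fddcs_recon` with denoised per-pixel values and updated
#'   `s1_plus`/`s1_minus`/`s1_bar` scalars; a `denoise_n` field records the
#'   window.
#' @export
denoise_recon <- function(recon, n = 3, edge = "replicate") {
  stopifnot(inherits(recon, "fddcs_recon"))
  recon$s1_plus <- sort_median_unsort(recon$s1_plus, n, edge)
  recon$s1_minus <- sort_median_unsort(recon$s1_minus, n, edge)
  recon$scalars$s1_plus <- colMeans(recon$s1_plus)
  recon$scalars$s1_minus <- colMeans(recon$s1_minus)
  recon$scalars$s1_bar <- (recon$scalars$s1_plus + recon$scalars$s1_minus) / 2
  recon$denoise_n <- n
  recon
}
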