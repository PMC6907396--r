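#' Local intensity normalization
#'
#' Normalizes each voxel against the Gaussian-weighted mean and standard
#' deviation of its neighborhood:
#' `out(v) = (I(v) - mu_w(v)) / (sigma_w(v) + epsilon)`, with `mu_w` and
#' `sigma_w` the local mean and SD at scale `window_sigma` (in voxels,
#' isotropic; the window is a separable Gaussian with mirrored borders).
#' This evens out slow intensity drifts — e.g. darkened borders and
#' corners in scans of dense material — ahead of global thresholding.
#' The local variance is computed as `max(E[I^2] - E[I]^2, 0)` to guard
#' against tiny negative values from floating point.
#'
#' The neighborhood must remain local: `window_sigma` larger than the
#' largest volume extent is an error. For the normalization to be useful
#' the window should still span all relevant material classes around each
#' voxel; choosing that scale is up to the caller.
#'
#' @param volume an [intensity_volume()] or array.
#' @param window_sigma Gaussian window scale in voxels, `> 0`.
#' @param epsilon small positive regularizer added to the local SD.
#' @return A floating-point [intensity_volume()].
#' @export
local_normalize <- function(volume, window_sigma, epsilon = 1e-6) {
  volume <- as_intensity(volume)
  stopifnot(window_sigma > 0, epsilon > 0)
  dims <- dim(volume$data)
  if (window_sigma > max(dims))
    stop("window_sigma exceeds the volume extent; the neighborhood must be local",
         call. = FALSE)
  v <- as.vector(volume$data)
  mu <- gauss_blur_cpp(v, dims, window_sigma)
  ex2 <- gauss_blur_cpp(v * v, dims, window_sigma)
  sdv <- sqrt(pmax(ex2 - mu * mu, 0))
  out <- (v - mu) / (sdv + epsilon)
  intensity_volume(array(out, dims), volume$spacing)
}
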