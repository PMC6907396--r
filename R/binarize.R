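#' Global threshold binarization
#'
#' Foreground is every voxel with intensity at or above the threshold
#' (mineralized tissue is bright in microCT); with `invert = TRUE`,
#' at or below it (dark-foreground data).
#'
#' @param volume an [intensity_volume()] or array.
#' @param threshold finite scalar.
#' @param invert select dark voxels instead of bright ones.
#' @return A [binary_mask()].
#' @export
threshold_mask <- function(volume, threshold, invert = FALSE) {
  volume <- as_intensity(volume)
  stopifnot(is.finite(threshold))
  fg <- if (invert) volume$data <= threshold else volume$data >= threshold
  binary_mask(array(fg, dim(volume$data)), volume$spacing)
}

#' Remove small connected components or small labels
#'
#' For a mask, connected components with fewer than `min_voxels` voxels
#' become background (used e.g. to discard unconnected debris such as
#' pedicellaria before ossicle analysis). For a label volume, labels whose
#' total voxel count is below `min_voxels` become background. Idempotent.
#'
#' @param x a [binary_mask()] or [label_volume()].
#' @param min_voxels minimum surviving size, at least 1.
#' @param connectivity component adjacency for masks: 6, 18 or 26
#'   (default 26 — conservative, keeps barely-connected biology).
#' @return Same type as `x`.
#' @export
remove_small_components <- function(x, min_voxels, connectivity = 26) {
  stopifnot(min_voxels >= 1)
  if (inherits(x, "tw_labels")) {
    counts <- tabulate(x$data, nbins = max(x$data, 1L))
    drop <- which(counts > 0L & counts < min_voxels)
    d <- x$data
    d[d %in% drop] <- 0L
    return(label_volume(d, x$spacing))
  }
  x <- as_mask(x)
  lab <- cc_label_cpp(as.vector(x$data), dim(x$data), as.integer(connectivity))
  counts <- tabulate(lab, nbins = max(lab, 1L))
  keep <- array(lab > 0L & counts[pmax(lab, 1L)] >= min_voxels, dim(x$data))
  binary_mask(keep, x$spacing)
}

#' Label connected components of a mask
#'
#' @inheritParams remove_small_components
#' @param mask a [binary_mask()].
#' @return A [label_volume()] with components numbered from 1 in scan order.
#' @export
connected_components <- function(mask, connectivity = 26) {
  mask <- as_mask(mask)
  lab <- cc_label_cpp(as.vector(mask$data), dim(mask$data), as.integer(connectivity))
  label_volume(array(lab, dim(mask$data)), mask$spacing)
}
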