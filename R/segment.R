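#' Segmentation parameters
#'
#' Controls for [contour_tree_segment()]. The persistence threshold is
#' read on the scale of the distance map handed in; with
#' `normalize_first = TRUE` (default) the map is min-max normalized to
#' `[0, 1]` first, which is the scale on which a threshold such as 0.15
#' is meaningful.
#'
#' @param persistence_threshold scalar `>= 0`; 0 disables merging.
#' @param connectivity region-growing adjacency: 6, 18 or 26 (default 26,
#'   matching the walk stencil).
#' @param normalize_first apply [minmax_normalize()] before the sweep.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(persistence_threshold = 0.15, connectivity = 26,
                                normalize_first = TRUE) {
  stopifnot(persistence_threshold >= 0)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26", call. = FALSE)
  structure(list(persistence_threshold = persistence_threshold,
                 connectivity = connectivity,
                 normalize_first = isTRUE(normalize_first)),
            class = "segmentation_params")
}

#' Contour-tree segmentation with persistence merging
#'
#' Region growing from the local maxima of a distance map: foreground
#' voxels are swept in strictly decreasing value order (ties broken by
#' ascending linear index, making the sweep a pure function of its
#' input). A voxel with no labeled neighbor founds a region and records
#' its peak value; a voxel adjacent to one region joins it; a voxel
#' adjacent to several regions is a saddle, where every adjacent region
#' whose persistence (peak minus saddle value) is below the threshold is
#' merged into the adjacent region with the globally highest peak, and
#' the voxel joins the surviving adjacent region with the highest peak.
#' Regions of exactly zero persistence (fragments of one plateau) are
#' always merged, so a plateau yields one region and the threshold-0
#' label count equals the plateau-aware local-maximum count. Every
#' foreground voxel receives exactly one nonzero label; background stays
#' 0.
#'
#' @param dmap a [distance_map()].
#' @param params a [segmentation_params()].
#' @return A [label_volume()].
#' @export
contour_tree_segment <- function(dmap, params = segmentation_params()) {
  stopifnot(inherits(dmap, "tw_distance"))
  if (!any(dmap$mask$data)) stop("distance map has empty foreground", call. = FALSE)
  if (params$normalize_first) dmap <- minmax_normalize(dmap)
  lab <- ct_sweep_cpp(as.vector(dmap$data), as.vector(dmap$mask$data),
                      dim(dmap$data), params$connectivity,
                      params$persistence_threshold)
  label_volume(array(lab, dim(dmap$data)), dmap$mask$spacing)
}

#' Count plateau-aware local maxima of a distance map
#'
#' A local maximum is a connected set of equal-valued foreground voxels
#' none of whose members has a strictly greater neighbor (background
#' counts as value 0). Each plateau counts once.
#'
#' @inheritParams contour_tree_segment
#' @param connectivity adjacency: 6, 18 or 26.
#' @return Integer count.
#' @export
count_local_maxima <- function(dmap, connectivity = 26) {
  stopifnot(inherits(dmap, "tw_distance"))
  if (!any(dmap$mask$data)) stop("distance map has empty foreground", call. = FALSE)
  local_max_count_cpp(as.vector(dmap$data), as.vector(dmap$mask$data),
                      dim(dmap$data), as.integer(connectivity))
}
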