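#' Volume containers
#'
#' Lightweight S3 containers for 3D grids. All grids use axis order
#' `(z, y, x)` with `z` the slice axis; voxel `[1, 1, 1]` is the first
#' pixel of the first slice. `spacing` is the physical size of one voxel
#' along `(z, y, x)` and must be finite and positive.
#'
#' * `intensity_volume()` — scalar image data (arbitrary units).
#' * `binary_mask()` — logical foreground mask.
#' * `label_volume()` — non-negative integer labels, 0 = background.
#' * `distance_map()` — non-negative scalar distances, 0 on background,
#'   carrying the mask it was computed on and a `units` tag
#'   (`"steps"`, `"physical"` or `"normalized"`).
#'
#' @param data 3D array of the appropriate mode.
#' @param spacing numeric length-3, physical units per voxel as `(sz, sy, sx)`.
#' @param mask the [binary_mask()] a distance map was computed on.
#' @param units distance units tag.
#' @return An object of the corresponding class; all inherit `"tw_volume"`.
#' @examples
#' v <- intensity_volume(array(runif(24), c(2, 3, 4)))
#' vol_dim(v)
#' @name volumes
NULL

check_grid <- function(data, what = "volume") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop(what, " data must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop(what, " has a zero-extent axis", call. = FALSE)
  invisible(data)
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three finite positive numbers (sz, sy, sx)", call. = FALSE)
  spacing
}

#' @rdname volumes
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1)) {
  check_grid(data, "intensity")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = check_spacing(spacing)),
            class = c("tw_intensity", "tw_volume"))
}

#' @rdname volumes
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  check_grid(data, "mask")
  if (!is.logical(data)) {
    data <- array(data != 0, dim = dim(data))
  }
  structure(list(data = data, spacing = check_spacing(spacing)),
            class = c("tw_mask", "tw_volume"))
}

#' @rdname volumes
#' @export
label_volume <- function(data, spacing = c(1, 1, 1)) {
  check_grid(data, "label")
  storage.mode(data) <- "integer"
  if (any(data < 0L, na.rm = TRUE)) stop("labels must be non-negative", call. = FALSE)
  structure(list(data = data, spacing = check_spacing(spacing)),
            class = c("tw_labels", "tw_volume"))
}

#' @rdname volumes
#' @export
distance_map <- function(data, mask, units = "steps") {
  check_grid(data, "distance")
  storage.mode(data) <- "double"
  mask <- as_mask(mask)
  stopifnot(identical(dim(data), dim(mask$data)))
  structure(list(data = data, spacing = mask$spacing, mask = mask, units = units),
            class = c("tw_distance", "tw_volume"))
}

#' Coerce to the container classes
#'
#' Arrays are accepted anywhere a container is, with unit spacing assumed.
#' @param x array or `tw_volume` object.
#' @param spacing spacing used when `x` is a bare array.
#' @return The corresponding container object.
#' @export
as_mask <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "tw_mask")) return(x)
  if (inherits(x, "tw_labels")) return(binary_mask(x$data > 0L, x$spacing))
  if (inherits(x, "tw_volume")) return(binary_mask(x$data, x$spacing))
  binary_mask(x, spacing)
}

#' @rdname as_mask
#' @export
as_intensity <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "tw_intensity")) return(x)
  if (inherits(x, "tw_volume")) return(intensity_volume(x$data + 0, x$spacing))
  intensity_volume(x, spacing)
}

#' @rdname as_mask
#' @export
as_labels <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "tw_labels")) return(x)
  if (inherits(x, "tw_volume")) return(label_volume(x$data, x$spacing))
  label_volume(x, spacing)
}

#' @rdname volumes
#' @param x a `tw_volume`.
#' @export
vol_dim <- function(x) dim(x$data)

#' @rdname volumes
#' @export
vol_spacing <- function(x) x$spacing

#' @exportS3Method print tw_volume
print.tw_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d (z,y,x), spacing %s\n",
              class(x)[1], d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  if (inherits(x, "tw_labels")) {
    k <- max(x$data)
    cat(sprintf("  labels: %d, background voxels: %d\n", k, sum(x$data == 0L)))
  } else if (inherits(x, "tw_mask")) {
    cat(sprintf("  foreground: %d of %d voxels\n", sum(x$data), length(x$data)))
  } else {
    r <- range(x$data)
    cat(sprintf("  range: [%g, %g]%s\n", r[1], r[2],
                if (!is.null(x$units)) paste0(" (", x$units, ")") else ""))
  }
  invisible(x)
}
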