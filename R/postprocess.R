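#' Apply a manual merge directive
#'
#' Unifies listed label pairs with union semantics: each connected set of
#' pairs collapses to its smallest member label, so the directive is
#' order-independent. This is the batch equivalent of interactive
#' proofreading merges.
#'
#' @param labels a [label_volume()].
#' @param pairs two-column matrix or data.frame of label pairs to unify.
#' @return A [label_volume()]; the foreground voxel set is unchanged.
#' @export
apply_merges <- function(labels, pairs) {
  labels <- as_labels(labels)
  if (is.null(pairs) || NROW(pairs) == 0L) return(labels)
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2L) stop("pairs must have two columns", call. = FALSE)
  present <- sort(unique(as.vector(labels$data)))
  missing <- setdiff(unique(as.vector(pairs)), present)
  if (length(missing))
    stop("unknown label(s) in merge directive: ", paste(missing, collapse = ", "),
         call. = FALSE)
  maxl <- max(labels$data)
  parent <- seq_len(maxl)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  map <- vapply(seq_len(maxl), find, integer(1))
  d <- labels$data
  nz <- d > 0L
  d[nz] <- map[d[nz]]
  label_volume(d, labels$spacing)
}

#' Directed merging along a growth axis
#'
#' Automatic merging of over-segmented columnar structures, preferring
#' the growth direction so neighboring columns are not absorbed
#' accidentally. Adjacent label pairs (face contact) are merged when all
#' three gates pass: (a) the angle between their centroid-difference
#' vector and the growth axis is at most `angle_tolerance`; (b) their
#' axis-perpendicular footprints overlap by at least
#' `min_overlap_fraction` of the smaller footprint; (c) their extents
#' along the axis are separated by at most `max_gap` voxels. Pairs are
#' examined in ascending label order and the pass is iterated to a fixed
#' point, so the result is deterministic and idempotent.
#'
#' @param labels a [label_volume()].
#' @param growth_axis `"z"`, `"y"` or `"x"` (a grid axis).
#' @param angle_tolerance degrees, in `(0, 90)`.
#' @param min_overlap_fraction in `(0, 1]`.
#' @param max_gap voxels along the axis.
#' @return A [label_volume()].
#' @export
directed_merge <- function(labels, growth_axis = "z", angle_tolerance = 30,
                           min_overlap_fraction = 0.5, max_gap = 3) {
  labels <- as_labels(labels)
  ax <- match(growth_axis, c("z", "y", "x"))
  if (is.na(ax)) stop("growth_axis must be one of 'z', 'y', 'x'", call. = FALSE)
  stopifnot(angle_tolerance > 0, angle_tolerance < 90,
            min_overlap_fraction > 0, min_overlap_fraction <= 1, max_gap >= 0)
  perp <- setdiff(1:3, ax)
  repeat {
    d <- labels$data
    idx <- which(d > 0L)
    if (!length(idx)) return(labels)
    lab <- d[idx]
    co <- arrayInd(idx, dim(d))
    labs <- sort(unique(lab))
    cen <- vapply(1:3, function(a) tapply(co[, a], lab, mean), numeric(length(labs)))
    amin <- tapply(co[, ax], lab, min); amax <- tapply(co[, ax], lab, max)
    fkey <- co[, perp[1]] + (dim(d)[perp[1]] + 1) * co[, perp[2]]
    foot <- lapply(split(fkey, lab), unique)
    rag <- build_rag(labels, min_contact = 1)
    merges <- NULL
    if (nrow(rag$edges)) for (r in seq_len(nrow(rag$edges))) {
      a <- as.character(rag$edges$a[r]); b <- as.character(rag$edges$b[r])
      dv <- cen[b, ] - cen[a, ]
      nv <- sqrt(sum(dv^2))
      ang <- if (nv == 0) 0 else acos(pmin(1, abs(dv[ax]) / nv)) * 180 / pi
      if (ang > angle_tolerance) next
      ov <- length(intersect(foot[[a]], foot[[b]])) /
        min(length(foot[[a]]), length(foot[[b]]))
      if (ov < min_overlap_fraction) next
      gap <- max(0, max(amin[a], amin[b]) - min(amax[a], amax[b]) - 1)
      if (gap > max_gap) next
      merges <- rbind(merges, c(rag$edges$a[r], rag$edges$b[r]))
    }
    if (is.null(merges)) return(labels)
    labels <- apply_merges(labels, merges)
  }
}
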