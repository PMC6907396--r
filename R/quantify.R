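#' Region adjacency graph
#'
#' Nodes are the nonzero labels; an edge joins two labels whose voxels
#' share at least `min_contact` face-adjacent voxel pairs (6-connectivity
#' — the strictest reproducible notion of "touching"). Node degree is the
#' neighbor count used as a proxy for tile geometry (number of sides).
#'
#' @param labels a [label_volume()].
#' @param min_contact minimum face-contact count for an edge.
#' @return A list with `nodes` (label ids) and `edges`
#'   (data.frame `a`, `b`, `contact_count` with `a < b`), class `tw_rag`.
#' @export
build_rag <- function(labels, min_contact = 1) {
  labels <- as_labels(labels)
  d <- labels$data
  dims <- dim(d)
  key_a <- integer(0); key_b <- integer(0)
  grab <- function(u, v) {
    keep <- u > 0L & v > 0L & u != v
    list(a = pmin(u[keep], v[keep]), b = pmax(u[keep], v[keep]))
  }
  pr <- list(
    grab(d[-dims[1], , , drop = FALSE], d[-1, , , drop = FALSE]),
    grab(d[, -dims[2], , drop = FALSE], d[, -1, , drop = FALSE]),
    grab(d[, , -dims[3], drop = FALSE], d[, , -1, drop = FALSE])
  )
  a <- unlist(lapply(pr, `[[`, "a")); b <- unlist(lapply(pr, `[[`, "b"))
  nodes <- sort(unique(d[d > 0L]))
  if (length(a) == 0L) {
    edges <- data.frame(a = integer(0), b = integer(0), contact_count = integer(0))
  } else {
    key <- as.numeric(a) * (max(nodes) + 1) + b
    cnt <- rowsum(rep(1L, length(key)), key)
    k <- as.numeric(rownames(cnt))
    ea <- floor(k / (max(nodes) + 1)); eb <- k - ea * (max(nodes) + 1)
    keep <- cnt[, 1] >= min_contact
    edges <- data.frame(a = as.integer(ea[keep]), b = as.integer(eb[keep]),
                        contact_count = as.integer(cnt[keep, 1]))
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, min_contact = min_contact),
            class = "tw_rag")
}

#' @exportS3Method print tw_rag
print.tw_rag <- function(x, ...) {
  cat(sprintf("<tw_rag> %d labels, %d contacts (min_contact %d)\n",
              length(x$nodes), nrow(x$edges), x$min_contact))
  invisible(x)
}

rag_degree <- function(rag) {
  deg <- setNames(integer(length(rag$nodes)), rag$nodes)
  if (nrow(rag$edges)) {
    t1 <- table(factor(rag$edges$a, levels = rag$nodes))
    t2 <- table(factor(rag$edges$b, levels = rag$nodes))
    deg <- as.integer(t1 + t2)
    names(deg) <- rag$nodes
  }
  deg
}

#' Per-tile morphometrics
#'
#' One row per nonzero label: voxel count; physical volume
#' (`voxel_count * sz*sy*sx`); mean image intensity over the label's
#' voxels (a proxy for tissue mineral density); degree in the region
#' adjacency graph (neighbor count); physical centroid; and the three
#' principal extents — `4 * sqrt(eigenvalue)` of the voxel-coordinate
#' covariance per principal axis, a rotation-invariant full-width proxy —
#' sorted descending.
#'
#' @param labels a [label_volume()].
#' @param intensity optional [intensity_volume()] of the same shape.
#' @param rag optional precomputed [build_rag()] result.
#' @return A data.frame of tile statistics.
#' @export
tile_stats <- function(labels, intensity = NULL, rag = NULL) {
  labels <- as_labels(labels)
  d <- labels$data
  if (!is.null(intensity)) {
    intensity <- as_intensity(intensity)
    if (!identical(dim(intensity$data), dim(d)))
      stop("labels and intensity shapes differ", call. = FALSE)
  }
  if (is.null(rag)) rag <- build_rag(labels)
  idx <- which(d > 0L)
  lab <- d[idx]
  labs <- sort(unique(lab))
  sp <- labels$spacing
  co <- arrayInd(idx, dim(d))
  phys <- sweep(co - 0.5, 2L, sp, `*`)
  cnt <- tabulate(factor(lab, levels = labs))
  cen <- rowsum(phys, lab) / cnt
  mi <- if (is.null(intensity)) rep(NA_real_, length(labs))
        else rowsum(intensity$data[idx], lab)[, 1] / cnt
  deg <- rag_degree(rag)[as.character(labs)]
  ext <- t(vapply(split(seq_along(lab), lab), function(ii) {
    if (length(ii) == 1L) return(c(0, 0, 0))
    ev <- eigen(stats::cov(phys[ii, , drop = FALSE]) * (length(ii) - 1) / length(ii),
                symmetric = TRUE, only.values = TRUE)$values
    sort(4 * sqrt(pmax(ev, 0)), decreasing = TRUE)
  }, numeric(3)))
  data.frame(label = labs, voxel_count = cnt, volume = cnt * prod(sp),
             neighbor_count = as.integer(deg), mean_intensity = mi,
             centroid_z = cen[, 1], centroid_y = cen[, 2], centroid_x = cen[, 3],
             extent1 = ext[, 1], extent2 = ext[, 2], extent3 = ext[, 3],
             row.names = NULL)
}

#' Neighbor-count histogram
#'
#' Counts and fractions of tiles per neighbor count (the number-of-sides
#' proxy), plus the arithmetic mean.
#'
#' @param stats a [tile_stats()] data.frame (or any data.frame with a
#'   `neighbor_count` column).
#' @return list with `histogram` (data.frame `neighbors`, `count`,
#'   `fraction`) and `mean_neighbors`.
#' @export
neighbor_histogram <- function(stats) {
  stopifnot(nrow(stats) > 0)
  tb <- table(stats$neighbor_count)
  hist <- data.frame(neighbors = as.integer(names(tb)),
                     count = as.integer(tb),
                     fraction = as.numeric(tb) / nrow(stats))
  list(histogram = hist, mean_neighbors = mean(stats$neighbor_count))
}

#' Prism radius profiles along a growth axis
#'
#' For each label and each slice perpendicular to the growth axis, the
#' cross-section area `A(z)` (slice voxel count times in-plane voxel
#' area) and the area-equivalent radius `R(z) = sqrt(A/pi)`. Each label
#' gets an ordinary-least-squares slope `dR/dz` over its extent (physical
#' units), a growing/shrinking class from the slope sign, and a relative
#' curvature: the mean over its slices of `1/Rbar(z) - 1/R_i(z)`, where
#' `Rbar(z)` is that slice's mean radius over all labels present —
#' positive for columns thinner than, negative for columns thicker than,
#' the slice average (the Hillert critical-radius proxy). Labels present
#' in fewer than two slices get `NA` slope and class and should be
#' excluded from trend statistics.
#'
#' @param labels a [label_volume()].
#' @param growth_axis `"z"` (default), `"y"` or `"x"`.
#' @return list of two data.frames: `profiles` (per label) and `radii`
#'   (per label and slice), class `tw_prisms`.
#' @export
prism_profiles <- function(labels, growth_axis = "z") {
  labels <- as_labels(labels)
  ax <- match(growth_axis, c("z", "y", "x"))
  if (is.na(ax)) stop("growth_axis must be one of 'z', 'y', 'x'", call. = FALSE)
  d <- labels$data
  if (dim(d)[ax] < 2) stop("labels must span at least 2 slices along the axis", call. = FALSE)
  perp <- setdiff(1:3, ax)
  sp <- labels$spacing
  area_unit <- prod(sp[perp])
  idx <- which(d > 0L)
  lab <- d[idx]
  zc <- arrayInd(idx, dim(d))[, ax]
  labs <- sort(unique(lab))
  cnt <- table(factor(lab, levels = labs), factor(zc, levels = seq_len(dim(d)[ax])))
  A <- as.matrix(cnt) * area_unit
  Rm <- sqrt(A / pi)
  Rm[A == 0] <- NA
  rbar <- colMeans(Rm, na.rm = TRUE)
  zphys <- (seq_len(dim(d)[ax]) - 0.5) * sp[ax]
  radii <- do.call(rbind, lapply(seq_along(labs), function(i) {
    zi <- which(!is.na(Rm[i, ]))
    data.frame(label = labs[i], z = zi, z_physical = zphys[zi],
               area = A[i, zi], radius = Rm[i, zi])
  }))
  profiles <- do.call(rbind, lapply(seq_along(labs), function(i) {
    zi <- which(!is.na(Rm[i, ]))
    n <- length(zi)
    sl <- NA_real_; cls <- NA_character_
    if (n >= 2) {
      sl <- stats::coef(stats::lm(Rm[i, zi] ~ zphys[zi]))[[2]]
      cls <- if (sl > 0) "growing" else "shrinking"
    }
    rc <- mean(1 / rbar[zi] - 1 / Rm[i, zi])
    data.frame(label = labs[i], n_slices = n, slope = sl, growth_class = cls,
               relative_curvature = rc)
  }))
  rownames(profiles) <- rownames(radii) <- NULL
  structure(list(profiles = profiles, radii = radii, growth_axis = growth_axis),
            class = "tw_prisms")
}

#' @exportS3Method print tw_prisms
print.tw_prisms <- function(x, ...) {
  ok <- !is.na(x$profiles$slope)
  cat(sprintf("<tw_prisms> %d columns along %s (%d with >= 2 slices; %d growing, %d shrinking)\n",
              nrow(x$profiles), x$growth_axis, sum(ok),
              sum(x$profiles$growth_class[ok] == "growing"),
              sum(x$profiles$growth_class[ok] == "shrinking")))
  invisible(x)
}

#' Evaluate a segmentation against ground truth
#'
#' Maps each predicted label to the truth label of majority overlap and
#' reports: `n_matched_one_to_one` — truth labels claimed by exactly one
#' predicted label; `n_split` — truth labels claimed by two or more
#' predicted labels; `n_merged` — predicted labels whose majority truth
#' label covers less than 60% of their voxels, or that are the largest
#' contributor to two or more truth labels.
#'
#' @param predicted,truth [label_volume()]s of the same shape.
#' @return list with `n_truth`, `n_predicted`, `n_matched_one_to_one`,
#'   `n_split`, `n_merged`, class `tw_eval`.
#' @export
evaluate_segmentation <- function(predicted, truth) {
  predicted <- as_labels(predicted); truth <- as_labels(truth)
  if (!identical(dim(predicted$data), dim(truth$data)))
    stop("predicted and truth shapes differ", call. = FALSE)
  idx <- which(predicted$data > 0L)
  p <- predicted$data[idx]
  t <- truth$data[idx]
  plabs <- sort(unique(p))
  tlabs <- sort(unique(truth$data[truth$data > 0L]))
  if (length(tlabs) == 0L || length(plabs) == 0L)
    return(structure(list(n_truth = length(tlabs), n_predicted = length(plabs),
                          n_matched_one_to_one = 0L, n_split = 0L, n_merged = 0L),
                     class = "tw_eval"))
  psize <- tabulate(p, nbins = max(plabs, 1L))
  keep <- t > 0L
  key <- as.numeric(p[keep]) * (max(tlabs) + 1) + t[keep]
  cnt <- rowsum(rep(1L, sum(keep)), key)
  k <- as.numeric(rownames(cnt))
  op <- floor(k / (max(tlabs) + 1)); ot <- k - op * (max(tlabs) + 1)
  ov <- data.frame(p = as.integer(op), t = as.integer(ot), n = cnt[, 1])
  # majority truth per predicted label (ties: smaller truth id)
  ov <- ov[order(ov$p, -ov$n, ov$t), ]
  maj <- ov[!duplicated(ov$p), ]
  claimed <- table(factor(maj$t, levels = tlabs))
  # top predicted contributor per truth label (ties: smaller predicted id)
  ovt <- ov[order(ov$t, -ov$n, ov$p), ]
  top <- ovt[!duplicated(ovt$t), ]
  top_multi <- table(factor(top$p, levels = plabs))
  coverage <- maj$n / psize[maj$p]
  merged <- (coverage < 0.6) | (as.integer(top_multi[as.character(maj$p)]) >= 2L)
  structure(list(n_truth = length(tlabs), n_predicted = length(plabs),
                 n_matched_one_to_one = sum(claimed == 1L),
                 n_split = sum(claimed >= 2L),
                 n_merged = sum(merged)),
            class = "tw_eval")
}

#' @exportS3Method print tw_eval
print.tw_eval <- function(x, ...) {
  cat(sprintf("<tw_eval> truth %d, predicted %d: %d one-to-one, %d split, %d merged\n",
              x$n_truth, x$n_predicted, x$n_matched_one_to_one, x$n_split, x$n_merged))
  invisible(x)
}
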