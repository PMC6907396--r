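#' Synthetic tiling phantoms
#'
#' Generators for ground-truthed test volumes emulating the three tiled
#' morphologies the workflow targets: slab tilings of similar-sized units
#' joined through mid-thickness constrictions (tessellated cartilage),
#' the same with pore-type noise, and columnar prisms that coarsen along
#' a growth axis (prismatic shell layers). Every phantom is a pure
#' function of its parameter record including the seed.
#'
#' A bundle holds `image` (foreground 200, background 50 on an 8-bit-like
#' scale, plus optional additive Gaussian noise, so that thresholding at
#' 125 recovers the mask exactly when `noise_sigma = 0`), `truth` (the
#' uncarved tile labels), `mask` (the carved foreground actually handed
#' to segmentation), and `params`.
#'
#' @name phantoms
NULL

phantom_bundle <- function(image, truth, mask, params) {
  structure(list(image = image, truth = truth, mask = mask, params = params),
            class = "tw_phantom")
}

#' @exportS3Method print tw_phantom
print.tw_phantom <- function(x, ...) {
  d <- vol_dim(x$truth)
  cat(sprintf("<tw_phantom:%s> %d x %d x %d, %d tiles, seed %s\n",
              x$params$kind, d[1], d[2], d[3], max(x$truth$data),
              format(x$params$seed)))
  invisible(x)
}

# Blue-noise (best-candidate) site sampling: tiles of similar size, as the
# workflow assumes of its data.
best_candidate_sites <- function(n, ny, nx, k = 20L) {
  sites <- matrix(0, n, 2)
  sites[1, ] <- c(runif(1, 0.5, ny + 0.5), runif(1, 0.5, nx + 0.5))
  if (n > 1) for (i in 2:n) {
    cand <- cbind(runif(k, 0.5, ny + 0.5), runif(k, 0.5, nx + 0.5))
    d2 <- vapply(seq_len(k), function(j)
      min((sites[1:(i - 1), 1] - cand[j, 1])^2 + (sites[1:(i - 1), 2] - cand[j, 2])^2),
      numeric(1))
    sites[i, ] <- cand[which.max(d2), ]
  }
  sites
}

# Additively-weighted (power-diagram) planar labeling on integer pixel
# centers; weights NULL means ordinary Voronoi. Ties go to the lowest site.
planar_label <- function(ny, nx, sites, weights = NULL) {
  Y <- rep(seq_len(ny), times = nx)
  X <- rep(seq_len(nx), each = ny)
  D2 <- outer(Y, sites[, 1], function(a, b) (a - b)^2) +
        outer(X, sites[, 2], function(a, b) (a - b)^2)
  if (!is.null(weights)) D2 <- sweep(D2, 2L, weights)
  matrix(max.col(-D2, ties.method = "first"), ny, nx)
}

# In-plane 4-neighbor label boundary (both sides of every label change).
boundary2d <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  b <- matrix(FALSE, ny, nx)
  dy <- lab[-ny, , drop = FALSE] != lab[-1, , drop = FALSE]
  b[-ny, ][dy] <- TRUE; b[-1, ][dy] <- TRUE
  dx <- lab[, -nx, drop = FALSE] != lab[, -1, drop = FALSE]
  b[, -nx][dx] <- TRUE; b[, -1][dx] <- TRUE
  b
}

render_image <- function(mask, noise_sigma, fg = 200, bg = 50) {
  img <- array(bg + (fg - bg) * mask, dim(mask))
  if (noise_sigma > 0) img <- img + array(rnorm(length(img), 0, noise_sigma), dim(img))
  img
}

slab_z <- function(nz, thickness) {
  z0 <- floor((nz - thickness) / 2) + 1L
  z0:(z0 + thickness - 1L)
}

# Carve the top `fraction` and the bottom `fraction` of the slab thickness
# to background along tile boundaries, leaving a mid-thickness bridge of at
# least one voxel.
carve_constrictions <- function(mask, boundary, zs, fraction) {
  if (fraction <= 0) return(mask)
  t <- length(zs)
  n_each <- floor(fraction * t)
  n_each <- min(n_each, (t - 1L) %/% 2L)
  if (n_each < 1) return(mask)
  carved_z <- c(zs[seq_len(n_each)], zs[(t - n_each + 1L):t])
  for (z in carved_z) mask[z, , ][boundary] <- FALSE
  mask
}

#' Voronoi slab tiling phantom
#'
#' `n_tiles` blue-noise seed points in the slab mid-plane define planar
#' Voronoi cells extruded through the slab. Along inter-tile boundaries
#' the top and bottom `constriction_fraction` of the slab thickness is
#' carved to background, so adjacent tiles stay connected only through a
#' mid-thickness bridge — a constriction without a resolved boundary,
#' the geometry the distance transforms must detect. Truth keeps the full
#' uncarved labels.
#'
#' @param shape grid dims `(nz, ny, nx)`.
#' @param n_tiles number of tiles, at least 2.
#' @param slab_thickness slab extent in voxels, at most `shape[1]`.
#' @param constriction_fraction fraction of the slab thickness carved away
#'   at the top and again at the bottom of every inter-tile boundary, in
#'   `[0, 1]`; the mid-thickness bridge never drops below one voxel.
#' @param noise_sigma additive Gaussian image noise SD (0 disables).
#' @param seed RNG seed (required; phantoms are bit-reproducible).
#' @param spacing voxel spacing `(sz, sy, sx)`.
#' @return A phantom bundle (see [phantoms]).
#' @export
voronoi_tiling_phantom <- function(shape = c(16, 128, 128), n_tiles = 25,
                                   slab_thickness = 11,
                                   constriction_fraction = 0.3,
                                   noise_sigma = 0, seed,
                                   spacing = c(1, 1, 1)) {
  stopifnot(n_tiles >= 2, constriction_fraction >= 0, constriction_fraction <= 1,
            slab_thickness >= 1, slab_thickness <= shape[1])
  set.seed(seed)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  sites <- best_candidate_sites(n_tiles, ny, nx)
  lab2d <- planar_label(ny, nx, sites)
  areas <- tabulate(lab2d, nbins = n_tiles)
  if (any(areas < 9))
    stop("n_tiles exceeds the voxel budget: some cells are narrower than 3 voxels",
         call. = FALSE)
  zs <- slab_z(nz, slab_thickness)
  truth <- array(0L, shape)
  for (z in zs) truth[z, , ] <- lab2d
  mask <- truth > 0L
  mask <- carve_constrictions(mask, boundary2d(lab2d), zs, constriction_fraction)
  img <- render_image(mask, noise_sigma)
  params <- list(kind = "voronoi", shape = shape, n_tiles = n_tiles,
                 slab_thickness = slab_thickness,
                 constriction_fraction = constriction_fraction,
                 noise_sigma = noise_sigma, seed = seed, sites = sites)
  phantom_bundle(intensity_volume(img, spacing), label_volume(truth, spacing),
                 binary_mask(mask, spacing), params)
}

#' Pore-type noise injection
#'
#' Flips each foreground voxel to background independently with
#' probability `pore_rate`, emulating the black pores that threshold
#' binarization leaves inside dense tissue. Background is untouched.
#'
#' @param mask a [binary_mask()].
#' @param pore_rate flip probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return A [binary_mask()].
#' @export
inject_pore_noise <- function(mask, pore_rate = 0.01, seed = 1) {
  mask <- as_mask(mask)
  stopifnot(pore_rate >= 0, pore_rate < 1)
  if (pore_rate == 0) return(mask)
  set.seed(seed)
  fi <- which(mask$data)
  flip <- fi[runif(length(fi)) < pore_rate]
  d <- mask$data
  d[flip] <- FALSE
  binary_mask(d, mask$spacing)
}

#' Hexagonal slab tiling phantom
#'
#' A regular pointy-top hexagonal tiling (nearest-center assignment, so
#' interior tiles are exact hexagons) extruded through a slab with the
#' same constriction carving as [voronoi_tiling_phantom()]. Every
#' interior tile has exactly 6 touching neighbors in the truth labels,
#' the reference geometry for neighbor-count validation. Labels are
#' numbered row-major; `params$interior_labels` lists the interior tiles.
#'
#' @param n_rows,n_cols hex grid size, each at least 3.
#' @param tile_radius hexagon center-to-vertex radius in voxels, `>= 2`.
#' @inheritParams voronoi_tiling_phantom
#' @return A phantom bundle.
#' @export
hexagonal_tiling_phantom <- function(n_rows = 5, n_cols = 5, tile_radius = 10,
                                     slab_thickness = 8,
                                     constriction_fraction = 0.3,
                                     noise_sigma = 0, seed = 1,
                                     spacing = c(1, 1, 1)) {
  stopifnot(n_rows >= 3, n_cols >= 3)
  if (tile_radius < 2) stop("tile_radius must be at least 2 voxels", call. = FALSE)
  set.seed(seed)
  R <- tile_radius
  vy <- 1.5 * R
  hx <- sqrt(3) * R
  yc <- R + 1 + (seq_len(n_rows) - 1) * vy
  sites <- do.call(rbind, lapply(seq_len(n_rows), function(r) {
    xs <- hx / 2 + 1 + (seq_len(n_cols) - 1) * hx + if (r %% 2 == 0) hx / 2 else 0
    cbind(yc[r], xs)
  }))
  ny <- ceiling(max(sites[, 1]) + R + 1)
  nx <- ceiling(max(sites[, 2]) + hx / 2 + 1)
  nz <- slab_thickness + 6L
  lab2d <- planar_label(ny, nx, sites)
  zs <- slab_z(nz, slab_thickness)
  truth <- array(0L, c(nz, ny, nx))
  for (z in zs) truth[z, , ] <- lab2d
  mask <- truth > 0L
  mask <- carve_constrictions(mask, boundary2d(lab2d), zs, constriction_fraction)
  img <- render_image(mask, noise_sigma)
  interior <- as.vector(outer(2:(n_rows - 1), 2:(n_cols - 1),
                              function(r, c) (r - 1) * n_cols + c))
  params <- list(kind = "hex", n_rows = n_rows, n_cols = n_cols,
                 tile_radius = tile_radius, slab_thickness = slab_thickness,
                 constriction_fraction = constriction_fraction,
                 noise_sigma = noise_sigma, seed = seed,
                 interior_labels = sort(interior), sites = sites)
  phantom_bundle(intensity_volume(img, spacing), label_volume(truth, spacing),
                 binary_mask(mask, spacing), params)
}

#' Columnar prism phantom with Hillert-style coarsening
#'
#' Each z-slice is an additively-weighted planar Voronoi (power diagram)
#' of the same `n_seeds` sites; the weights evolve along z by explicit
#' Euler with one step per slice under the curvature-driven rule
#' `dw/dz = coarsening_rate * (1/R_mean(z) - 1/R_i(z))`, with
#' `R_i = sqrt(A_i / pi)` the area-equivalent radius. Columns larger than
#' the slice average grow; smaller ones shrink and eventually vanish from
#' later slices, as in coarsening prismatic shell layers. One-voxel
#' background sheets separate adjacent columns in the mask, except for
#' periodic bridge voxels (a discontinuous boundary). Truth keeps full
#' per-slice ownership; `params$column_class` records each column's
#' ground-truth growing/shrinking class and radius-profile slope,
#' measured on the truth labels.
#'
#' @param shape grid dims `(nz, ny, nx)`; z is the growth axis.
#' @param n_seeds number of columns, at least 4.
#' @param coarsening_rate Euler step scale of the weight drift
#'   (weight units per unit inverse radius per slice); 0 freezes all
#'   columns.
#' @param bridge_period keep every `bridge_period`-th boundary voxel as a
#'   foreground bridge.
#' @inheritParams voronoi_tiling_phantom
#' @return A phantom bundle.
#' @export
columnar_prism_phantom <- function(shape = c(60, 200, 200), n_seeds = 50,
                                   coarsening_rate = 200, noise_sigma = 0,
                                   seed, bridge_period = 6,
                                   spacing = c(1, 1, 1)) {
  stopifnot(n_seeds >= 4, coarsening_rate >= 0)
  set.seed(seed)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  sites <- best_candidate_sites(n_seeds, ny, nx)
  w <- numeric(n_seeds)
  truth <- array(0L, shape)
  mask <- array(FALSE, shape)
  radii <- matrix(NA_real_, nz, n_seeds)
  warned <- FALSE
  Yg <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  Xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  for (z in seq_len(nz)) {
    lab2d <- planar_label(ny, nx, sites, w)
    areas <- tabulate(lab2d, nbins = n_seeds)
    present <- areas > 0
    if (sum(present) == 1 && !warned && z < nz) {
      warning("coarsening eliminated all but one column before the top slice",
              call. = FALSE)
      warned <- TRUE
    }
    Rz <- sqrt(areas / pi)
    radii[z, present] <- Rz[present]
    truth[z, , ] <- lab2d
    b <- boundary2d(lab2d)
    bridge <- ((Yg + Xg + z) %% max(1L, as.integer(bridge_period))) == 0L
    mask[z, , ] <- !b | bridge
    if (coarsening_rate > 0) {
      rbar <- mean(Rz[present])
      w[present] <- w[present] + coarsening_rate * (1 / rbar - 1 / Rz[present])
    }
  }
  # ground-truth class from the truth-label radius profiles
  cls <- data.frame(label = seq_len(n_seeds), slope = NA_real_,
                    growth_class = NA_character_)
  for (i in seq_len(n_seeds)) {
    zi <- which(!is.na(radii[, i]))
    if (length(zi) >= 2) {
      sl <- stats::coef(stats::lm(radii[zi, i] ~ zi))[2]
      cls$slope[i] <- sl
      cls$growth_class[i] <- if (sl > 0) "growing" else "shrinking"
    }
  }
  img <- render_image(mask, noise_sigma)
  params <- list(kind = "prisms", shape = shape, n_seeds = n_seeds,
                 coarsening_rate = coarsening_rate, noise_sigma = noise_sigma,
                 bridge_period = bridge_period, seed = seed, sites = sites,
                 column_class = cls, radii = radii)
  phantom_bundle(intensity_volume(img, spacing), label_volume(truth, spacing),
                 binary_mask(mask, spacing), params)
}
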