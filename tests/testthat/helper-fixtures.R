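# Shared fixtures, memoized so expensive phantom solves are computed once
# per test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fx, inherits = FALSE)) assign(name, fn(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

fx_voronoi <- function() fixture("voronoi", function()
  voronoi_tiling_phantom(seed = 7))

fx_noisy_mask <- function() fixture("noisy_mask", function()
  inject_pore_noise(fx_voronoi()$mask, 0.01, seed = 8))

fx_rwdt_noisy <- function() fixture("rwdt_noisy", function()
  random_walk_distance(fx_noisy_mask()))

fx_rwdt_clean <- function() fixture("rwdt_clean", function()
  random_walk_distance(fx_voronoi()$mask))

fx_edt_noisy <- function() fixture("edt_noisy", function()
  euclidean_distance(fx_noisy_mask()))

fx_seg_noisy <- function() fixture("seg_noisy", function()
  contour_tree_segment(fx_rwdt_noisy(), segmentation_params(0.15)))

fx_prisms <- function() fixture("prisms", function()
  columnar_prism_phantom(n_seeds = 50, seed = 11))

fx_hex <- function() fixture("hex", function()
  hexagonal_tiling_phantom(5, 5, tile_radius = 10, seed = 3))

# a small volume for IO and normalization checks
fx_small_volume <- function() fixture("small_volume", function() {
  set.seed(42)
  intensity_volume(array(sample(0:255, 4 * 6 * 5, replace = TRUE), c(4, 6, 5)),
                   spacing = c(2, 1, 1))
})

# brute-force EDT oracle: minimum center-to-center distance to background
edt_bruteforce <- function(mask, spacing = c(1, 1, 1)) {
  fg <- mask$data
  out <- array(0, dim(fg))
  bg <- which(!fg)
  fgi <- which(fg)
  cob <- sweep(arrayInd(bg, dim(fg)), 2L, spacing, `*`)
  cof <- sweep(arrayInd(fgi, dim(fg)), 2L, spacing, `*`)
  for (start in seq(1, length(fgi), by = 512)) {
    ii <- start:min(start + 511, length(fgi))
    d2 <- outer(cof[ii, 1], cob[, 1], `-`)^2 +
          outer(cof[ii, 2], cob[, 2], `-`)^2 +
          outer(cof[ii, 3], cob[, 3], `-`)^2
    out[fgi[ii]] <- sqrt(apply(d2, 1, min))
  }
  out
}

random_mask <- function(dims, fill, seed) {
  set.seed(seed)
  binary_mask(array(runif(prod(dims)) < fill, dims))
}
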