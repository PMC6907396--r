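spec6 <- walk_spec(6)

test_that("hand-solved walk systems are reproduced to 1e-6", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  h <- random_walk_distance(binary_mask(one), spec6)
  expect_equal(h$data[2, 2, 2], 1, tolerance = 1e-6)

  two <- array(FALSE, c(3, 4, 3)); two[2, 2:3, 2] <- TRUE
  h2 <- random_walk_distance(binary_mask(two), spec6)
  expect_equal(unname(h2$data[2, 2:3, 2]), c(1.2, 1.2), tolerance = 1e-6)

  bar <- array(FALSE, c(3, 3, 5)); bar[2, 2, 2:4] <- TRUE
  h3 <- random_walk_distance(binary_mask(bar), spec6)
  expect_equal(h3$data[2, 2, 2], 21 / 17, tolerance = 1e-6)
  expect_equal(h3$data[2, 2, 3], 24 / 17, tolerance = 1e-6)
})

test_that("walk distances are at least 1, exactly 1 iff fully absorbing", {
  m <- random_mask(c(8, 8, 8), 0.5, seed = 31)
  h <- random_walk_distance(m)
  fg <- m$data
  expect_true(all(h$data[fg] >= 1 - 1e-12))
  # find a voxel whose stencil neighbors are all background
  sys <- tilewalk:::walk_system(fg, walk_spec())
  lonely <- sys$absorbers == sys$deg
  if (any(lonely)) expect_equal(unname(h$data[sys$fi[lonely]]),
                                rep(1, sum(lonely)), tolerance = 1e-9)
  not_lonely <- !lonely
  expect_true(all(h$data[sys$fi[not_lonely]] > 1 + 1e-9))
})

test_that("mirrored masks give mirrored walk distances", {
  m <- random_mask(c(6, 7, 8), 0.5, seed = 5)
  h <- random_walk_distance(m)
  flipped <- binary_mask(m$data[, , dim(m$data)[3]:1])
  h2 <- random_walk_distance(flipped)
  expect_equal(h$data, h2$data[, , dim(m$data)[3]:1], tolerance = 1e-7)
})

test_that("unreachable background is reported", {
  expect_error(random_walk_distance(binary_mask(array(TRUE, c(3, 3, 3)))),
               "unreachable")
  # absorbing border makes the same mask solvable
  h <- random_walk_distance(binary_mask(array(TRUE, c(3, 3, 3))),
                            walk_spec(6, "absorbing"))
  expect_true(all(h$data >= 1))
  expect_error(random_walk_distance(binary_mask(array(FALSE, c(2, 2, 2)))),
               "no foreground")
})

test_that("monte carlo oracle matches the solver", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  mc <- monte_carlo_walk_length(binary_mask(one), c(2, 2, 2), spec6,
                                n_walks = 200, seed = 1)
  expect_equal(mc$mean, 1)
  expect_equal(mc$standard_error, 0)

  two <- array(FALSE, c(3, 4, 3)); two[2, 2:3, 2] <- TRUE
  mc2 <- monte_carlo_walk_length(binary_mask(two), c(2, 2, 2), spec6,
                                 n_walks = 50000, seed = 2)
  expect_lt(abs(mc2$mean - 1.2), 3 * mc2$standard_error + 1e-12)
  mc2b <- monte_carlo_walk_length(binary_mask(two), c(2, 2, 2), spec6,
                                  n_walks = 50000, seed = 2)
  expect_identical(mc2, mc2b)
})

test_that("euclidean transform matches geometry and handles empty masks", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(euclidean_distance(binary_mask(one))$data[2, 2, 2], 1)
  # 3x3 plate in a single-slice volume: center 2, corners 1
  plate <- array(FALSE, c(1, 5, 5)); plate[1, 2:4, 2:4] <- TRUE
  e <- euclidean_distance(binary_mask(plate))
  expect_equal(e$data[1, 3, 3], 2)
  expect_equal(e$data[1, 2, 2], 1)
  empty <- euclidean_distance(binary_mask(array(FALSE, c(2, 2, 2))))
  expect_true(all(empty$data == 0))
  expect_error(euclidean_distance(binary_mask(array(TRUE, c(2, 2, 2)))),
               "background")
})

test_that("euclidean transform respects anisotropic spacing", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  m <- binary_mask(one, spacing = c(3, 1, 1))
  e <- euclidean_distance(m, use_spacing = TRUE)
  expect_equal(e$data[2, 2, 2], 1)  # nearest background now in-plane
  br <- edt_bruteforce(m, c(3, 1, 1))
  expect_equal(e$data, br)
})

test_that("min-max normalization maps foreground onto [0, 1]", {
  arr <- array(0, c(1, 1, 3)); arr[1, 1, ] <- c(2, 4, 6)
  dm <- distance_map(arr, binary_mask(array(TRUE, c(1, 1, 3))))
  out <- minmax_normalize(dm)
  expect_equal(as.vector(out$data), c(0, 0.5, 1))
  expect_equal(minmax_normalize(out)$data, out$data)  # idempotent on [0,1]
  const <- distance_map(array(3, c(1, 1, 2)), binary_mask(array(TRUE, c(1, 1, 2))))
  expect_equal(as.vector(minmax_normalize(const)$data), c(1, 1))
})

test_that("ensemble reduces to the single-threshold map and dips at bridges", {
  b <- voronoi_tiling_phantom(shape = c(8, 32, 32), n_tiles = 3, slab_thickness = 6, seed = 2)
  single <- ensemble_rwdt(b$image, 125)
  direct <- minmax_normalize(random_walk_distance(threshold_mask(b$image, 125)))
  expect_equal(single$data, direct$data, tolerance = 1e-12)
  twice <- ensemble_rwdt(b$image, c(100, 125))  # identical masks
  expect_equal(twice$data, direct$data, tolerance = 1e-12)

  # two tiles joined by a bridge that disappears at the higher threshold:
  # the averaged map dips at the bridge relative to both tile interiors
  arr <- array(50, c(3, 5, 11))
  arr[2, 2:4, 2:4] <- 200; arr[2, 2:4, 8:10] <- 200   # two tiles
  arr[2, 3, 5:7] <- 150                               # weaker bridge
  vol <- intensity_volume(arr)
  em <- ensemble_rwdt(vol, c(100, 175), walk_spec(6))
  bridge <- em$data[2, 3, 6]
  expect_lt(bridge, em$data[2, 3, 3])
  expect_lt(bridge, em$data[2, 3, 9])

  expect_error(ensemble_rwdt(vol, numeric(0)), "non-empty")
  expect_error(ensemble_rwdt(vol, c(2, 1)), "increasing")
  expect_warning(expect_error(ensemble_rwdt(vol, 1e6), "failed"), "skipped")
})

test_that("solver residual satisfies the declared tolerance", {
  m <- random_mask(c(10, 10, 10), 0.6, seed = 9)
  spec <- walk_spec(6, solver_tolerance = 1e-8)
  h <- random_walk_distance(m, spec)
  sys <- tilewalk:::walk_system(m$data, spec)
  L <- Matrix::Diagonal(length(sys$deg), sys$deg) - sys$A
  r <- as.numeric(L %*% h$data[sys$fi]) - sys$deg
  expect_lt(sqrt(sum(r^2)) / sqrt(sum(sys$deg^2)), 1e-8)
})

test_that("conjugate-gradient path agrees with the direct solve", {
  m <- random_mask(c(12, 12, 12), 0.6, seed = 13)
  spec <- walk_spec(6)
  sys <- tilewalk:::walk_system(m$data, spec)
  L <- methods::as(Matrix::forceSymmetric(
    Matrix::Diagonal(length(sys$deg), sys$deg) - sys$A), "CsparseMatrix")
  direct <- as.numeric(Matrix::solve(L, sys$deg))
  cg <- tilewalk:::cg_solve(L, sys$deg, 1e-10)
  expect_equal(cg, direct, tolerance = 1e-7)
})
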