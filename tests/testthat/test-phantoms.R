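test_that("voronoi phantom has the promised structure", {
  b <- fx_voronoi()
  expect_equal(length(unique(b$truth$data[b$truth$data > 0L])), 25L)
  # truth labels partition the mask: every mask voxel carries exactly one label
  expect_true(all(b$truth$data[b$mask$data] > 0L))
  expect_identical(dim(b$image$data), dim(b$truth$data))
  # binarization threshold 125 recovers the mask exactly at zero noise
  expect_identical(threshold_mask(b$image, 125)$data, b$mask$data)
})

test_that("phantoms are pure functions of their seed", {
  a <- voronoi_tiling_phantom(shape = c(8, 48, 48), n_tiles = 6, slab_thickness = 6, seed = 3)
  b <- voronoi_tiling_phantom(shape = c(8, 48, 48), n_tiles = 6, slab_thickness = 6, seed = 3)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$data, b$truth$data)
  expect_identical(a$mask$data, b$mask$data)
  p1 <- columnar_prism_phantom(shape = c(12, 48, 48), n_seeds = 6, seed = 5)
  p2 <- columnar_prism_phantom(shape = c(12, 48, 48), n_seeds = 6, seed = 5)
  expect_identical(p1$truth$data, p2$truth$data)
  expect_identical(p1$mask$data, p2$mask$data)
})

test_that("zero constriction keeps the full extruded slab", {
  b <- voronoi_tiling_phantom(shape = c(8, 48, 48), n_tiles = 6,
                              slab_thickness = 6,
                              constriction_fraction = 0, seed = 3)
  expect_identical(b$mask$data, b$truth$data > 0L)
})

test_that("constricted tiles remain 26-connected through the bridge", {
  for (b in list(voronoi_tiling_phantom(shape = c(10, 48, 48), n_tiles = 6, slab_thickness = 8,
                                        constriction_fraction = 0.4, seed = 2),
                 hexagonal_tiling_phantom(3, 3, 8, 8,
                                          constriction_fraction = 0.5, seed = 1))) {
    cc <- connected_components(b$mask, 26)
    rag <- build_rag(b$truth)
    for (r in seq_len(nrow(rag$edges))) {
      pair <- b$truth$data %in% c(rag$edges$a[r], rag$edges$b[r]) & b$mask$data
      sub <- connected_components(binary_mask(array(pair, dim(b$mask$data))), 26)
      expect_equal(max(sub$data), 1L)
    }
  }
})

test_that("pore noise flips the binomially expected voxel count", {
  b <- fx_voronoi()
  n_fg <- sum(b$mask$data)
  noisy <- inject_pore_noise(b$mask, 0.01, seed = 8)
  flipped <- n_fg - sum(noisy$data)
  expect_lt(abs(flipped - 0.01 * n_fg), 4 * sqrt(n_fg * 0.01 * 0.99))
  # background untouched, identical pattern for identical seed
  expect_true(all(noisy$data <= b$mask$data))
  expect_identical(noisy$data, inject_pore_noise(b$mask, 0.01, seed = 8)$data)
  expect_identical(inject_pore_noise(b$mask, 0, seed = 1)$data, b$mask$data)
})

test_that("hexagonal phantom interior tiles have exactly six truth neighbors", {
  b <- fx_hex()
  expect_equal(max(b$truth$data), 25L)
  expect_equal(length(b$params$interior_labels), 9L)
  expect_equal(length(hexagonal_tiling_phantom(3, 3, 8, seed = 1)$params$interior_labels), 1L)
  rag <- build_rag(b$truth)
  deg <- table(factor(c(rag$edges$a, rag$edges$b), levels = rag$nodes))
  expect_true(all(deg[as.character(b$params$interior_labels)] == 6L))
})

test_that("columnar phantom coarsens: small columns vanish, classes recorded", {
  b <- fx_prisms()
  nz <- dim(b$truth$data)[1]
  first <- length(unique(as.vector(b$truth$data[1, , ])))
  last <- length(unique(as.vector(b$truth$data[nz, , ])))
  expect_equal(first, 50L)
  expect_lt(last, 50L)
  cls <- b$params$column_class
  expect_true(all(cls$growth_class[!is.na(cls$growth_class)] %in%
                    c("growing", "shrinking")))
  expect_gt(sum(cls$growth_class == "shrinking", na.rm = TRUE), 0)
})

test_that("zero coarsening keeps per-slice areas constant", {
  b <- columnar_prism_phantom(shape = c(12, 60, 60), n_seeds = 6,
                              coarsening_rate = 0, seed = 4)
  pr <- prism_profiles(b$truth)
  for (l in unique(pr$radii$label)) {
    a <- pr$radii$area[pr$radii$label == l]
    expect_equal(length(unique(a)), 1L)  # identical slices along z
  }
})

test_that("overcrowded voronoi phantom is rejected", {
  expect_error(voronoi_tiling_phantom(shape = c(6, 12, 12), n_tiles = 30,
                                      slab_thickness = 4, seed = 1),
               "voxel budget")
  expect_error(hexagonal_tiling_phantom(3, 3, tile_radius = 1, seed = 1), "tile_radius")
})
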