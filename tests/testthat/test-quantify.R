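test_that("region adjacency counts face contacts and applies min_contact", {
  lab <- array(0L, c(2, 4, 4))
  lab[, 1:2, 1:2] <- 1L
  lab[, 3, 1:2] <- 2L     # shares a 2x2-voxel face with label 1
  rag <- build_rag(label_volume(lab))
  expect_equal(rag$edges$a, 1L)
  expect_equal(rag$edges$b, 2L)
  expect_equal(rag$edges$contact_count, 4L)
  expect_equal(nrow(build_rag(label_volume(lab), min_contact = 5)$edges), 0L)
  # diagonal-only contact is not adjacency
  dg <- array(0L, c(1, 2, 2)); dg[1, 1, 1] <- 1L; dg[1, 2, 2] <- 2L
  expect_equal(nrow(build_rag(label_volume(dg))$edges), 0L)
})

test_that("tile statistics report counts, volumes, intensities and extents", {
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, 1:2, 1:2] <- 1L
  img <- array(10, c(4, 4, 4)); img[1, 1:2, 1:2] <- 20
  st <- tile_stats(label_volume(lab, spacing = c(2, 1, 1)),
                   intensity_volume(img, spacing = c(2, 1, 1)))
  expect_equal(st$voxel_count, 8L)
  expect_equal(st$volume, 16)          # 8 voxels x (2*1*1)
  expect_equal(st$mean_intensity, 15)  # half 10, half 20
  expect_equal(st$neighbor_count, 0L)

  # a digital ball has three nearly equal principal extents
  dims <- c(21, 21, 21)
  co <- arrayInd(seq_len(prod(dims)), dims)
  ball <- array(as.integer(rowSums(sweep(co, 2, 11)^2) <= 64), dims)
  stb <- tile_stats(label_volume(ball))
  expect_lt((stb$extent1 - stb$extent3) / stb$extent1, 0.1)
  expect_gt(stb$extent1, 10)  # full-width proxy near the 16-voxel diameter

  # partition conservation
  s <- fx_seg_noisy()
  stp <- tile_stats(s)
  expect_equal(sum(stp$voxel_count), sum(s$data > 0L))
})

test_that("neighbor histograms count fractions and mean", {
  st <- data.frame(neighbor_count = c(6, 6, 5, 7))
  nh <- neighbor_histogram(st)
  expect_equal(nh$mean_neighbors, 6)
  expect_equal(nh$histogram$count[nh$histogram$neighbors == 6], 2L)
  expect_equal(sum(nh$histogram$fraction), 1)
  one <- neighbor_histogram(data.frame(neighbor_count = 4))
  expect_equal(one$mean_neighbors, 4)
})

test_that("hexagonal phantom interior tiles average exactly six neighbors", {
  b <- fx_hex()
  st <- tile_stats(b$truth)
  interior <- st[st$label %in% b$params$interior_labels, ]
  expect_true(all(interior$neighbor_count == 6L))
  expect_equal(neighbor_histogram(interior)$mean_neighbors, 6)
})

test_that("prism profiles recover analytic radius trends", {
  # voxelized cylinder: constant radius, |slope| below voxel noise
  dims <- c(40, 30, 30)
  co <- arrayInd(seq_len(prod(dims)), dims)
  cyl <- array(as.integer((co[, 2] - 15.5)^2 + (co[, 3] - 15.5)^2 <= 100), dims)
  pr <- prism_profiles(label_volume(cyl))
  expect_lt(abs(pr$profiles$slope), 0.02)
  expect_lt(max(pr$radii$radius) - min(pr$radii$radius), 1)

  # truncated cone, radius 12 -> 6 over 60 slices: slope -0.1 within 10%
  dims <- c(60, 30, 30)
  co <- arrayInd(seq_len(prod(dims)), dims)
  r_z <- 12 - 6 * (co[, 1] - 1) / 59
  cone <- array(as.integer((co[, 2] - 15.5)^2 + (co[, 3] - 15.5)^2 <= r_z^2), dims)
  pc <- prism_profiles(label_volume(cone))
  expect_lt(abs(pc$profiles$slope - (-0.1)), 0.01)
  expect_equal(pc$profiles$growth_class, "shrinking")
})

test_that("prism classification matches the phantom ground truth", {
  b <- fx_prisms()
  pr <- prism_profiles(b$truth)
  m <- merge(pr$profiles, b$params$column_class, by = "label",
             suffixes = c("", ".gen"))
  ok <- !is.na(m$slope) & !is.na(m$slope.gen)
  expect_gte(mean(m$growth_class[ok] == m$growth_class.gen[ok]), 0.95)
})

test_that("segmentation evaluation counts matches, splits and merges", {
  truth <- array(0L, c(2, 4, 8))
  truth[, , 1:4] <- 1L; truth[, , 5:8] <- 2L
  tv <- label_volume(truth)
  expect_equal(evaluate_segmentation(tv, tv)$n_matched_one_to_one, 2L)

  split <- truth
  split[, 1:2, 1:4] <- 3L      # tile 1 split in half
  ev <- evaluate_segmentation(label_volume(split), tv)
  expect_equal(ev$n_split, 1L)
  expect_equal(ev$n_matched_one_to_one, 1L)

  merged <- array(1L, c(2, 4, 8))   # both tiles under one label
  ev2 <- evaluate_segmentation(label_volume(merged), tv)
  expect_gte(ev2$n_merged, 1L)
  expect_equal(ev2$n_matched_one_to_one, 1L)  # only the majority tile is claimed
})
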