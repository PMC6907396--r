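line_map <- function(vals) {
  arr <- array(0, c(1, 1, length(vals)))
  arr[1, 1, ] <- vals
  distance_map(arr, binary_mask(array(TRUE, c(1, 1, length(vals)))))
}

test_that("sweep hand-traces: saddle joins the higher peak, merging by threshold", {
  dm <- line_map(c(1, 3, 2, 4, 1))
  s0 <- contour_tree_segment(dm, segmentation_params(0, normalize_first = FALSE))
  lab <- as.vector(s0$data)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(lab[3], lab[4])  # the value-2 saddle voxel joins the peak-4 region
  s1 <- contour_tree_segment(dm, segmentation_params(1.5, normalize_first = FALSE))
  expect_equal(length(unique(as.vector(s1$data))), 1L)
})

test_that("plateaus form a single region at any threshold", {
  dm <- line_map(rep(5, 7))
  for (thr in c(0, 0.5)) {
    s <- contour_tree_segment(dm, segmentation_params(thr, normalize_first = FALSE))
    expect_equal(max(s$data), 1L)
  }
})

test_that("local maxima are counted plateau-aware", {
  expect_equal(count_local_maxima(line_map(c(1, 3, 2, 4, 1))), 2L)
  expect_equal(count_local_maxima(line_map(rep(2, 5))), 1L)
  expect_equal(count_local_maxima(line_map(1:6)), 1L)
  expect_equal(count_local_maxima(line_map(c(1, 2, 2, 1, 3))), 2L)
})

test_that("threshold-0 label count equals the local-maximum count", {
  set.seed(21)
  m <- random_mask(c(6, 12, 12), 0.7, seed = 21)
  vals <- array(0, dim(m$data))
  vals[m$data] <- sample(1:5, sum(m$data), replace = TRUE)  # many plateaus
  dm <- distance_map(vals, m)
  for (conn in c(6, 26)) {
    s <- contour_tree_segment(dm, segmentation_params(0, conn, normalize_first = FALSE))
    expect_equal(max(s$data), count_local_maxima(dm, conn))
  }
})

test_that("label count is non-increasing in the persistence threshold", {
  dm <- fx_rwdt_noisy()
  prev <- Inf
  for (thr in seq(0, 0.9, length.out = 10)) {
    s <- contour_tree_segment(dm, segmentation_params(thr))
    n <- max(s$data)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("segmentation covers exactly the foreground and is deterministic", {
  dm <- fx_rwdt_noisy()
  s <- fx_seg_noisy()
  expect_true(all((s$data > 0L) == dm$mask$data))
  s2 <- contour_tree_segment(dm, segmentation_params(0.15))
  expect_identical(s$data, s2$data)
})
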