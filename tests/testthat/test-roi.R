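# ROI geometry, rasterization, placement and landmark detection

test_that("rectangle rasterization covers exact half-open index ranges", {
  m <- rasterize(rect_roi(0, 0, 13, 20), c(256, 256))
  expect_equal(sum(m), 260L)
  expect_true(all(m[1:20, 1:13]))

  # full containment anywhere inside the image keeps the exact area
  set.seed(11)
  for (i in 1:50) {
    w <- sample(1:20, 1)
    h <- sample(1:20, 1)
    x0 <- sample(0:(64 - w), 1)
    y0 <- sample(0:(64 - h), 1)
    expect_equal(sum(rasterize(rect_roi(x0, y0, w, h), c(64, 64))), w * h)
  }

  # clipping at the border drops outside pixels
  expect_equal(sum(rasterize(rect_roi(-2, -2, 5, 5), c(64, 64))), 9L)
  expect_error(rasterize(rect_roi(100, 100, 5, 5), c(64, 64)),
               class = "mibg_empty_roi")
})

test_that("oval rasterization uses pixel-center inclusion", {
  # unit circle at (1,1) on 3x3: center plus 4 edge neighbours, corners out
  m <- rasterize(oval_roi(1, 1, 1, 1), c(3, 3))
  expect_equal(sum(m), 5L)
  expect_false(m[1, 1] || m[1, 3] || m[3, 1] || m[3, 3])
  expect_true(m[2, 2] && m[1, 2] && m[2, 1] && m[2, 3] && m[3, 2])

  set.seed(12)
  for (i in 1:50) {
    cx <- runif(1, 10, 54); cy <- runif(1, 10, 54)
    rx <- runif(1, 1, 12); ry <- runif(1, 1, 12)
    expect_identical(rasterize(oval_roi(cx, cy, rx, ry), c(64, 64)),
                     oracle_oval_mask(cx, cy, rx, ry, 64, 64))
  }
})

test_that("polygon rasterization matches an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  # axis-aligned square through pixel-center midlines -> 16 pixels
  sq <- polygon_roi(c(-0.5, 3.5, 3.5, -0.5), c(-0.5, -0.5, 3.5, 3.5))
  expect_equal(sum(rasterize(sq, c(8, 8))), 16L)

  set.seed(13)
  for (i in 1:100) {
    poly <- random_star_polygon(sample(3:12, 1), runif(1, 20, 44),
                                runif(1, 20, 44), 2, 15)
    p <- polygon_roi(poly$x, poly$y)
    expect_identical(rasterize(p, c(64, 64)),
                     oracle_polygon_mask(poly$x, poly$y, 64, 64))
  }
})

test_that("degenerate ROI constructors are rejected", {
  expect_error(rect_roi(0, 0, 0, 5), class = "mibg_invalid_roi")
  expect_error(oval_roi(0, 0, -1, 2), class = "mibg_invalid_roi")
  expect_error(polygon_roi(c(0, 1), c(0, 1)), class = "mibg_invalid_roi")
  # bow-tie self-intersection
  expect_error(polygon_roi(c(0, 2, 2, 0), c(0, 2, 0, 2)),
               class = "mibg_invalid_roi")
})

test_that("mean_counts averages over the mask and respects translation", {
  img <- matrix(100, 32, 32)
  expect_equal(mean_counts(img, rect_roi(3, 4, 5, 6)), 100)
  expect_equal(mean_counts(img, oval_roi(15, 15, 4, 6)), 100)

  img2 <- matrix(0, 8, 8)
  img2[3, 4] <- 2; img2[4, 4] <- 4
  expect_equal(mean_counts(img2, rect_roi(3, 2, 1, 2)), 3)

  expect_error(mean_counts(img, rect_roi(500, 500, 3, 3)),
               class = "mibg_empty_roi")

  # joint translation of image and ROI leaves the mean unchanged
  set.seed(14)
  base <- matrix(rpois(64 * 64, 20), 64, 64)
  big <- matrix(7, 80, 80)
  big[9:72, 9:72] <- base
  roi1 <- rect_roi(10, 12, 6, 5)
  roi2 <- rect_roi(10 + 8, 12 + 8, 6, 5)
  expect_equal(mean_counts(base, roi1), mean_counts(big, roi2))
})

test_that("semi-automatic placement follows the landmark-square rule", {
  sq <- landmark_square(top = 0, bottom = 100, left = 0, right = 100)
  placed <- place_semiautomatic_rois(sq)
  expect_equal(placed$med_center, c(50, 25))
  expect_equal(placed$cardiac_center, c(75, 75))
  expect_equal(c(placed$mediastinal$w, placed$mediastinal$h), c(13L, 20L))
  expect_equal(c(placed$cardiac$rx, placed$cardiac$ry), c(30, 35))

  # too small for the mediastinal rectangle
  expect_error(
    place_semiautomatic_rois(landmark_square(10, 20, 0, 100)),
    class = "mibg_placement"
  )

  # translation equivariance
  sq2 <- landmark_square(7, 107, 11, 111)
  placed2 <- place_semiautomatic_rois(sq2)
  expect_equal(placed2$med_center, placed$med_center + c(11, 7))
  expect_equal(placed2$cardiac_center, placed$cardiac_center + c(11, 7))
  expect_equal(placed2$mediastinal$x0 - placed$mediastinal$x0, 11)
  expect_equal(placed2$mediastinal$y0 - placed$mediastinal$y0, 7)
})

test_that("landmark detection recovers the true square on a noise-free phantom", {
  rec <- local_noisefree_record()
  truth <- rec$truth$square
  det <- detect_landmark_square(rec$early)
  for (edge in c("top", "bottom", "left", "right")) {
    expect_lt(abs(det[[edge]] - truth[[edge]]), 2 + 1e-9)
  }
  # determinism
  det2 <- detect_landmark_square(rec$early)
  expect_identical(det, det2)
})

test_that("landmark detection fails cleanly without thoracic structure", {
  flat <- planar_image(matrix(50, 128, 128), "early")
  expect_error(detect_landmark_square(flat), class = "mibg_landmark")
})
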