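test_that("HOG produces 9 cells x 9 bins for any valid image", {
  for (img in list(matrix(0, 28, 28), step_edge_image(),
                   matrix(runif(784), 28, 28))) {
    h <- compute_hog(img)
    expect_identical(dim(h), c(9L, 9L))
    expect_true(all(h >= 0))
  }
  expect_error(compute_hog(matrix(0, 27, 28)), "28x28")
  expect_error(compute_hog(matrix(c(NA, rep(0, 783)), 28, 28)), "finite")
})

test_that("constant image gives all-zero histograms", {
  expect_true(all(compute_hog(matrix(0.7, 28, 28)) == 0))
})

test_that("a vertical step edge dominates the horizontal-gradient bin,
           matching a brute-force per-pixel gradient oracle", {
  img <- step_edge_image()
  h <- compute_hog(img)
  # brute-force oracle: recompute gradient orientation per pixel directly
  gx <- gy <- matrix(0, 28, 28)
  for (r in 1:28) for (cc in 2:27) gx[r, cc] <- (img[r, cc + 1] - img[r, cc - 1]) / 2
  for (cc in 1:28) for (r in 2:27) gy[r, cc] <- (img[r + 1, cc] - img[r - 1, cc]) / 2
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  mag <- sqrt(gx^2 + gy^2)
  dominant_bin <- min(floor(ang[mag > 0] / 20)) + 1  # all edge pixels agree
  expect_true(all(unique(floor(ang[mag > 0] / 20) + 1) == dominant_bin))
  # every cell the edge crosses puts all its mass in that bin
  crossed <- which(h[, dominant_bin] > 0)
  expect_true(length(crossed) > 0)
  for (cell in crossed) {
    expect_equal(h[cell, dominant_bin], max(h[cell, ]))
    expect_equal(sum(h[cell, -dominant_bin]), 0)
  }
})

test_that("binarisation yields a one-hot-blocked 324-vector with 81 ones", {
  set.seed(1)
  hogs <- lapply(1:6, function(i) compute_hog(matrix(runif(784), 28, 28)))
  breaks <- hog_level_breaks(hogs)
  expect_length(breaks, 3)
  for (h in hogs) {
    v <- binarize(h, breaks)
    expect_silent(validate_feature_vector(v))
    expect_equal(sum(v), 81)
  }
})

test_that("binarisation maps zero to level 0 and saturates above the top
           boundary", {
  breaks <- c(0.1, 0.2, 0.3)
  h <- matrix(0, 9, 9)
  v <- binarize(h, breaks)
  expect_true(all(matrix(v, nrow = 4)[1, ] == 1))     # all level-0
  h[] <- 0.9
  v <- binarize(h, breaks)
  expect_true(all(matrix(v, nrow = 4)[4, ] == 1))     # all level-3
  expect_error(binarize(matrix(-1, 9, 9), breaks), "non-negative")
})

test_that("feature vectors are deterministic functions of the image", {
  img <- matrix(runif(784), 28, 28)
  breaks <- c(0.05, 0.15, 0.4)
  set.seed(1); v1 <- binarize(compute_hog(img), breaks)
  set.seed(999); v2 <- binarize(compute_hog(img), breaks)
  expect_identical(v1, v2)
})

test_that("feature drive targets exactly the active thalamic cells with the
           configured efficacy", {
  v <- random_feature()
  drv <- features_to_drive(v, rate = 30000, eff = 8)
  expect_equal(sort(drv$targets[[1]]), which(v == 1))
  expect_equal(drv$rate, 30000)
  expect_equal(drv$eff, 8)
  expect_equal(nrow(features_to_drive(integer(324))), 0)
  expect_error(features_to_drive(integer(100)), "324")
})

test_that("toy stroke images are reproducible and class-separable in
           feature space", {
  set.seed(7)
  a <- make_toy_images(3, 3)
  set.seed(7)
  b <- make_toy_images(3, 3)
  expect_identical(a, b)
  enc <- encode_images(a$images)
  agree <- function(i, j) block_agreement(enc$features[[i]], enc$features[[j]])
  same <- c(agree(1, 2), agree(4, 5), agree(7, 8))
  cross <- c(agree(1, 4), agree(4, 7), agree(1, 7))
  expect_gt(mean(same), mean(cross))
})
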