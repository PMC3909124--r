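test_that("TV denoising preserves constants and approaches identity as weight -> 0", {
  cv <- volume3d(array(42, c(12, 12, 12)))
  out <- tv_denoise(cv, weight = 10, iters = 20)
  expect_lt(max(abs(out$data - 42)), 1e-9)

  v <- volume3d(array(rnorm(12^3, 0, 10), c(12, 12, 12)))
  out <- tv_denoise(v, weight = 1e-4, iters = 20)
  expect_lt(max(abs(out$data - v$data)), 1e-2)

  expect_error(tv_denoise(v, weight = 0), "> 0")
  expect_error(tv_denoise(v, weight = 10, iters = 0), ">= 1")
  bad <- v; bad$data[1] <- NA
  expect_error(volume3d(bad$data), "finite")
})

test_that("TV denoising halves flat-region noise while keeping the step edge sharp", {
  d <- c(32, 32, 32)
  X <- array(seq_len(d[1]), d)
  clean <- ifelse(X <= 16, 0, 200)
  withr::with_seed(7, noisy <- clean + array(rnorm(prod(d), 0, 20), d))
  v <- volume3d(noisy, c(1, 1, 1))
  den <- tv_denoise(v, weight = 20, iters = 40)
  flat <- X <= 10
  expect_lt(sd(den$data[flat]), 0.5 * sd(noisy[flat]))
  expect_lte(total_variation(den), total_variation(v))
  # 10-90% transition width of the mean edge profile grows by at most 1 voxel
  width <- function(a) {
    prof <- apply(a[10:24, , ], 1, mean)
    lo <- 0.1 * 200; hi <- 0.9 * 200
    sum(prof > lo & prof < hi)
  }
  expect_lte(width(den$data), width(clean) + 1)
})

test_that("Otsu threshold separates modes and matches a brute-force maximizer", {
  x <- c(rep(-900, 500), rep(0, 500))
  thr <- otsu_threshold(volume3d(array(sample(x), c(10, 10, 10))))
  expect_gt(thr, -900); expect_lt(thr, 0)

  withr::with_seed(11, {
    y <- c(rnorm(4000, -850, 30), rnorm(4000, -50, 30))
    thr2 <- otsu_threshold(volume3d(array(sample(y), c(20, 20, 20))))
  })
  expect_gte(thr2, -600); expect_lte(thr2, -300)

  # brute-force oracle over histogram bins on random mixtures
  brute_otsu <- function(x, nbins = 256) {
    breaks <- seq(min(x), max(x), length.out = nbins + 1)
    bin <- pmin(findInterval(x, breaks, rightmost.closed = TRUE), nbins)
    bcv <- rep(-Inf, nbins - 1)
    mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
    for (k in 1:(nbins - 1)) {
      g1 <- bin <= k; g2 <- bin > k
      if (!any(g1) || !any(g2)) next
      bcv[k] <- sum(g1) * sum(g2) * (mean(mids[bin[g1]]) - mean(mids[bin[g2]]))^2
    }
    ks <- which(bcv >= max(bcv) - 1e-9 * abs(max(bcv)))
    mean(breaks[ks + 1])
  }
  withr::with_seed(13, {
    for (rep in 1:10) {
      x <- c(rnorm(300, -800, 50), rnorm(300, -300, 60), rnorm(200, 100, 40))
      expect_equal(otsu_threshold(x), brute_otsu(x), tolerance = 1e-12)
    }
  })
  expect_error(otsu_threshold(volume3d(array(5, c(4, 4, 4)))), "constant")
})

test_that("lung segmentation recovers phantom ellipsoids and closes vessel holes", {
  ph <- make_tube_volume("straight", radius_mm = 2, dims = c(64, 64, 64),
                         spacing_mm = 1, noise_sd = 0, seed = 1)
  lung <- segment_lung(ph$volume)
  expect_gte(dice_coef(lung$data, ph$lung_mask$data), 0.99)
  # the bright 2 mm-radius tube inside the lung is absorbed by closing
  tube <- ph$volume$data > 0 & ph$lung_mask$data > 0
  expect_gt(mean(lung$data[tube]), 0.99)
  expect_error(segment_lung(volume3d(array(-1000, c(16, 16, 16)))),
               "segmentation failure")
})

test_that("lung segmentation is robust to added noise", {
  ph0 <- make_tube_volume("straight", radius_mm = 2, dims = c(64, 64, 64),
                          spacing_mm = 1, noise_sd = 0, seed = 2)
  phn <- make_tube_volume("straight", radius_mm = 2, dims = c(64, 64, 64),
                          spacing_mm = 1, noise_sd = 10, seed = 2)
  l0 <- segment_lung(ph0$volume)
  ln <- segment_lung(tv_denoise(phn$volume, 20, 30))
  d0 <- dice_coef(l0$data, ph0$lung_mask$data)
  dn <- dice_coef(ln$data, ph0$lung_mask$data)
  expect_lt(abs(d0 - dn), 0.02)
})

test_that("airway segmentation finds the carina and splits the tree", {
  sc <- make_lung_scene(seed = 4)
  v <- tv_denoise(sc$volume, 20, 40)
  lung <- segment_lung(v)
  aw <- segment_airways(v, lung)
  expect_gte(dice_coef(aw$airway_mask$data, sc$airway_mask$data), 0.9)
  err_vox <- sqrt(sum((aw$carina - sc$carina)^2)) / sc$volume$spacing[1]
  expect_lt(err_vox, 2)
  # each daughter tree covers exactly one side
  xl <- mean(which(aw$left_tree$data > 0, arr.ind = TRUE)[, 1])
  xr <- mean(which(aw$right_tree$data > 0, arr.ind = TRUE)[, 1])
  expect_gt(xl, xr)
  expect_equal(sum(aw$left_tree$data * aw$right_tree$data), 0)
})

test_that("degenerate airway topologies are reported", {
  sc <- make_lung_scene(with_airway = FALSE, seed = 5)
  v <- tv_denoise(sc$volume, 20, 40)
  lung <- segment_lung(v)
  expect_error(segment_airways(v, lung), "trachea")

  # straight unbranched tube: carina undetected, single tree with warning
  d <- c(48, 48, 48)
  X <- array(seq_len(d[1]), d)
  Y <- array(rep(seq_len(d[2]), each = d[1]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  a <- array(40, d)
  lungm <- (X - 24)^2 + (Y - 24)^2 <= 18^2
  a[lungm] <- -850
  a[(X - 24)^2 + (Y - 24)^2 <= 3^2 & Z > 12] <- -1000
  v2 <- volume3d(a, c(1, 1, 1))
  lung2 <- mask3d(array(as.numeric(lungm), d), c(1, 1, 1))
  expect_warning(aw2 <- segment_airways(v2, lung2), "single")
  expect_true(all(is.na(aw2$carina)))
  expect_gt(sum(aw2$left_tree$data), 0)
})

test_that("the ROI removes the dilated airway and never intersects it", {
  sc <- make_lung_scene(seed = 6)
  v <- tv_denoise(sc$volume, 20, 40)
  lung <- segment_lung(v)
  aw <- segment_airways(v, lung)
  roi0 <- build_roi(lung, aw$airway_mask, 0)
  expect_identical(roi0$data > 0,
                   (lung$data > 0) & !(aw$airway_mask$data > 0))
  roi2 <- build_roi(lung, aw$airway_mask, 2)
  expect_equal(sum(roi2$data * aw$airway_mask$data), 0)
  expect_lte(sum(roi2$data), sum(roi0$data))
  # margin = 2 mm: no ROI voxel within trachea_radius + margin of the
  # trachea axis in the trachea's z range
  d <- dim(v$data); sp <- v$spacing
  ctr <- (d[1:2] - 1) * sp[1:2] / 2
  idx <- which(roi2$data > 0, arr.ind = TRUE)
  mm <- sweep(idx - 1, 2, sp, "*")
  high <- mm[, 3] > sc$carina[3] + 5
  if (any(high)) {
    rr <- sqrt((mm[high, 1] - ctr[1])^2 + (mm[high, 2] - ctr[2])^2)
    expect_gt(min(rr), 3 + 2 - sp[1]) # radius + margin, one voxel slack
  }
  # empty airway: ROI equals the lung mask
  empty <- mask3d(array(0, dim(lung$data)), lung$spacing)
  expect_identical(build_roi(lung, empty, 2)$data, lung$data)
  expect_error(build_roi(lung, empty, -1), ">= 0")
})

test_that("left/right split labels every lung voxel by the nearer subtree", {
  sc <- make_lung_scene(seed = 7)
  v <- tv_denoise(sc$volume, 20, 40)
  lung <- segment_lung(v)
  aw <- segment_airways(v, lung)
  lab <- split_left_right(lung, aw$left_tree, aw$right_tree)
  inl <- lung$data > 0
  expect_true(all(lab$data[inl] %in% c(1, 2)))
  expect_true(all(lab$data[!inl] == 0))
  # mirror-symmetric phantom: label volumes equal within a few percent
  n1 <- sum(lab$data == 1); n2 <- sum(lab$data == 2)
  expect_lt(abs(n1 - n2) / (n1 + n2), 0.05)
  # ground-truth sides
  expect_gt(mean(lab$data[sc$left_lung_mask$data > 0] == 1), 0.95)
  expect_gt(mean(lab$data[sc$right_lung_mask$data > 0] == 2), 0.95)
  expect_warning(single <- split_left_right(lung, aw$left_tree, NULL),
                 "single-label")
  expect_true(all(single$data[inl] == 1))
})
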