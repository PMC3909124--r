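test_that("Hessian eigenanalysis matches closed forms for blob and cylinder", {
  d <- c(41, 41, 41)
  X <- array(seq_len(d[1]) - 21, d)
  Y <- array(rep(seq_len(d[2]) - 21, each = d[1]), d)
  Z <- array(rep(seq_len(d[3]) - 21, each = d[1] * d[2]), d)
  # isotropic Gaussian blob: at the center all three eigenvalues equal, < 0
  blob <- volume3d(1000 * exp(-(X^2 + Y^2 + Z^2) / (2 * 16)), c(1, 1, 1))
  h <- hessian_eigen(blob, 2)
  ctr <- c(21, 21, 21)
  lams <- c(h$lam1[21, 21, 21], h$lam2[21, 21, 21], h$lam3[21, 21, 21])
  expect_true(all(lams < 0))
  expect_lt(max(abs(diff(sort(lams)))) / abs(mean(lams)), 0.05)

  # bright cylinder along z: |lam1| << |lam2| ~ |lam3|, direction along z
  cyl <- volume3d(1000 * exp(-(X^2 + Y^2) / (2 * 4)), c(1, 1, 1))
  h2 <- hessian_eigen(cyl, 2)
  i <- (21 - 1) + (21 - 1) * d[1] + (21 - 1) * d[1] * d[2] + 1
  expect_lt(abs(h2$lam1[21, 21, 21]), 0.05 * abs(h2$lam2[21, 21, 21]))
  expect_lt(abs(h2$lam2[21, 21, 21] - h2$lam3[21, 21, 21]) /
              abs(h2$lam3[21, 21, 21]), 0.05)
  ang <- acos(min(1, abs(h2$v1[i, 3]))) * 180 / pi
  expect_lt(ang, 5)

  const <- volume3d(array(3, c(8, 8, 8)))
  h3 <- hessian_eigen(const, 2)
  expect_equal(max(abs(h3$lam3)), 0)
  expect_error(hessian_eigen(const, 0.5), "spacing")
})

test_that("offset-medialness peaks at the matching radius and aligned direction", {
  v <- small_tube_scene(radius = 3)
  ctr <- (48 + 1) / 2
  p <- c((ctr - 1), (ctr - 1), 23) # axis position in mm (spacing 1, origin 0)
  radii <- seq(1.5, 6, by = 0.5)
  scores <- vapply(radii, function(r)
    offset_medialness(v, p, c(0, 0, 1), r), numeric(1))
  expect_equal(radii[which.max(scores)], 3, tolerance = 0.51)
  aligned <- offset_medialness(v, p, c(0, 0, 1), 3)
  perp <- offset_medialness(v, p, c(1, 0, 0), 3)
  expect_lt(perp, aligned)
  const <- volume3d(array(10, c(16, 16, 16)))
  expect_equal(offset_medialness(const, c(8, 8, 8), c(0, 0, 1), 3), 0)
  expect_error(offset_medialness(v, p, c(0, 0, 1), -1), "> 0")
})

test_that("VEF response is maximal on the tube axis and rejects blobs", {
  d <- c(64, 64, 64)
  X <- array(seq_len(d[1]), d)
  Y <- array(rep(seq_len(d[2]), each = d[1]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  mk <- function(sel) {
    a <- array(-850, d); a[sel] <- 300
    volume3d(a, c(1, 1, 1))
  }
  # 2 mm diameter tube at 1 mm voxels: the stated detection limit
  tube <- mk((X - 32)^2 + (Y - 32)^2 <= 1)
  roi <- full_roi(tube)
  p <- scale_space_params(sigmas = c(1, 1.5, 2.25, 3.4, 5))
  vv <- vef_response(tube, roi, p)
  on_axis <- vv$response$data[32, 32, 8:56]
  off_axis <- vv$response$data[34, 32, 8:56] # 2 voxels off
  expect_gte(mean(on_axis > off_axis), 0.95)

  sphere <- mk((X - 32)^2 + (Y - 32)^2 + (Z - 32)^2 <= 15^2)
  vs <- vef_response(sphere, roi, p)
  expect_lt(max(vs$response$data), 0.2 * max(vv$response$data))
})

test_that("response is zero outside the ROI and empty ROI warns", {
  v <- small_tube_scene()
  half <- array(0, dim(v$data)); half[1:20, , ] <- 1
  roi <- mask3d(half, v$spacing)
  vv <- vef_response(v, roi, scale_space_params(sigmas = c(1, 1.5)))
  expect_true(all(vv$response$data >= 0))
  expect_true(all(vv$response$data[roi$data == 0] == 0))
  empty <- mask3d(array(0, dim(v$data)), v$spacing)
  expect_warning(v0 <- vef_response(v, empty), "empty ROI")
  expect_equal(max(v0$response$data), 0)
})

test_that("non-maxima suppression thins a tube to its axis and handles edge cases", {
  v <- small_tube_scene(radius = 2)
  vv <- vef_response(v, full_roi(v), scale_space_params(sigmas = c(1, 1.5, 2.25)))
  cands <- non_maxima_suppression(vv)
  ctr <- (48 - 1) / 2
  r <- sqrt((cands$x_mm - ctr)^2 + (cands$y_mm - ctr)^2)
  expect_true(all(r < 1)) # within 1 voxel of the true axis
  covered <- vapply(5:43, function(k) any(abs(cands$z_mm - (k - 1)) <= 0.5 & r < 1),
                    logical(1))
  expect_gte(mean(covered), 0.9)

  # constant response volume: nothing is a strict cross-sectional maximum
  const <- as_vesselness(volume3d(array(5, c(10, 10, 10))))
  expect_equal(nrow(non_maxima_suppression(const, threshold = 1)), 0)

  # a single isolated bright voxel is retained
  a <- array(0, c(11, 11, 11)); a[6, 6, 6] <- 10
  lone <- as_vesselness(volume3d(a))
  out <- non_maxima_suppression(lone, threshold = 1)
  expect_equal(nrow(out), 1)
  expect_equal(unname(unlist(out[1, c("i", "j", "k")])), c(6, 6, 6))
})

test_that("candidate extraction commutes with 90-degree rotations", {
  d <- c(48, 48, 48)
  X <- array(seq_len(d[1]), d)
  Y <- array(rep(seq_len(d[2]), each = d[1]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  mk <- function(sel) { a <- array(-850, d); a[sel] <- 300; volume3d(a, c(1, 1, 1)) }
  tz <- mk((X - 24)^2 + (Y - 24)^2 <= 4)
  tx <- mk((Z - 24)^2 + (Y - 24)^2 <= 4)
  p <- scale_space_params(sigmas = c(1, 1.5, 2.25))
  cz <- non_maxima_suppression(vef_response(tz, full_roi(tz), p))
  cx <- non_maxima_suppression(vef_response(tx, full_roi(tx), p))
  expect_equal(nrow(cz), nrow(cx))
  a <- cbind(cz$x_mm, cz$y_mm, cz$z_mm)
  b <- cbind(cx$z_mm, cx$y_mm, cx$x_mm) # rotate back (swap x and z)
  nn <- vapply(seq_len(nrow(b)), function(i)
    min(sqrt(rowSums(sweep(a, 2, b[i, ])^2))), numeric(1))
  expect_lt(max(nn), 1)
})

test_that("contrast scaling keeps candidates when the threshold scales too", {
  v <- small_tube_scene(radius = 2)
  p <- scale_space_params(sigmas = c(1, 1.5))
  vv1 <- vef_response(v, full_roi(v), p)
  v2 <- volume3d(v$data * 3, v$spacing)
  vv2 <- vef_response(v2, full_roi(v2), p)
  thr <- 0.5 * max(vv1$response$data)
  c1 <- non_maxima_suppression(vv1, thr)
  c2 <- non_maxima_suppression(vv2, 3 * thr)
  expect_equal(nrow(c1), nrow(c2))
  expect_true(all(vv2$response$data >= 0))
})
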