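test_that("distance metric matches analytic values for line, semicircle and helix", {
  expect_identical(distance_metric(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))), 1)
  th <- seq(0, pi, length.out = 1000)
  expect_equal(distance_metric(cbind(3 * cos(th), 3 * sin(th), 0)), pi / 2,
               tolerance = 1e-4)
  t <- seq(0, 6 * pi, length.out = 3000) # 3 whole turns, 1000 samples/turn
  expect_equal(distance_metric(cbind(cos(t), sin(t), t)), sqrt(2),
               tolerance = 1e-3)
  expect_error(distance_metric(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0))),
               "coincident")
})

test_that("distance metric is invariant under rigid motions and uniform scaling", {
  withr::with_seed(21, {
    p <- cbind(cumsum(rnorm(50)), cumsum(rnorm(50)), seq(0, 49))
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  })
  dm <- distance_metric(p)
  expect_equal(distance_metric(p %*% R), dm, tolerance = 1e-9)
  expect_equal(distance_metric(sweep(p, 2, c(10, -4, 7), "+")), dm,
               tolerance = 1e-9)
  expect_equal(distance_metric(p * 3.7), dm, tolerance = 1e-9)
  expect_gte(dm, 1)
})

test_that("mean distance metric averages admissible segments only", {
  s1 <- vessel_segment(cbind(0, 0, 0:9)) # dm 1
  th <- seq(0, pi, length.out = 100)
  s2 <- vessel_segment(cbind(cos(th), sin(th), 0)) # dm pi/2
  expect_equal(mean_distance_metric(list(s1, s1)), 1)
  expect_equal(mean_distance_metric(list(s1, s2)), (1 + pi / 2) / 2,
               tolerance = 1e-3)
  short <- vessel_segment(rbind(c(0, 0, 0), c(0, 0, 0.1), c(0, 0, 0.2)))
  expect_equal(mean_distance_metric(list(s1, short), min_chord_mm = 1), 1)
  expect_error(mean_distance_metric(list(short), min_chord_mm = 1),
               "no admissible")
})

test_that("box counting matches direct counts and a brute-force hash oracle", {
  expect_equal(box_count(rbind(c(3, 3, 3)), 5), 1)
  expect_equal(box_count(rbind(c(3, 3, 3)), 1), 1)
  line <- cbind(0:511, 0, 0)
  expect_equal(box_count(line, 8), 64)
  brute <- function(p, dl, origin) {
    keys <- apply(floor(sweep(p, 2, origin, "-") / dl), 1, paste, collapse = ",")
    length(unique(keys))
  }
  withr::with_seed(31, {
    for (rep in 1:100) {
      p <- matrix(runif(3 * sample(5:200, 1), 0, 50), ncol = 3)
      dl <- sample(1:10, 1)
      o <- apply(p, 2, min)
      expect_identical(box_count(p, dl, o), brute(p, dl, o))
    }
  })
  expect_equal(box_count(matrix(numeric(0), ncol = 3), 2), 0L)
})

test_that("box-count curves follow analytic scaling laws and stay monotone", {
  # stay within the scaling regime: at cube sizes close to the line length
  # the +1 box of the partial tail biases the count upward
  line <- cbind(0:511, 0:511, 0)
  cv <- box_count_curve(line, 1, 50)
  expect_equal(select_linear_range(cv)$fd, 1, tolerance = 0.02)
  cube <- make_fractal_set("cube", 100)
  cv2 <- box_count_curve(cube)
  expect_equal(select_linear_range(cv2)$fd, 3, tolerance = 0.1)
  # monotone counts for every generated set
  withr::with_seed(41, {
    for (rep in 1:10) {
      p <- matrix(runif(3 * 500, 0, 120), ncol = 3)
      cvr <- box_count_curve(p)
      expect_true(all(diff(cvr$counts) < 0))
      expect_true(all(diff(cvr$deltas) > 0))
      expect_true(all(cvr$counts >= 1))
    }
  })
  expect_error(box_count_curve(rbind(c(0, 0, 0))), "at least 2")
})

test_that("linear-range selection keeps exact power laws and drops plateaus", {
  mkcurve <- function(deltas, counts) {
    structure(list(deltas = deltas, counts = counts),
              class = "box_count_curve")
  }
  # exactly log-linear: every point retained, slope recovered to 1e-9
  deltas <- c(1:10, 12, 15, 20, 27, 35, 46, 60, 78, 100)
  counts <- 1e6 * deltas^(-1.7)
  fit <- select_linear_range(mkcurve(deltas, counts), r2_good = 0.99)
  expect_true(all(fit$used))
  expect_equal(fit$fd, 1.7, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # resolution saturation: counts plateau at small sizes, plateau dropped
  sat <- pmin(counts[1] / 30, counts)
  fit2 <- select_linear_range(mkcurve(deltas, sat), r2_good = 0.99)
  expect_false(fit2$used[1])
  expect_equal(fit2$fd, 1.7, tolerance = 0.05)
  # hopeless curve: fit-failure error carrying the best attempt
  withr::with_seed(51, bad <- mkcurve(deltas, exp(runif(19, 0, 10))))
  err <- tryCatch(select_linear_range(bad, r2_good = 0.999),
                  vastrac_fit_error = function(e) e)
  expect_s3_class(err, "vastrac_fit_error")
  expect_false(is.null(err$best))
})

test_that("fractal dimension recovers the similarity dimension of oracle sets", {
  expect_equal(fractal_dimension(make_fractal_set("line", 1024))$fd, 1,
               tolerance = 0.05)
  expect_equal(fractal_dimension(make_fractal_set("plane", 256))$fd, 2,
               tolerance = 0.05)
  expect_equal(fractal_dimension(make_fractal_set("cube", 100))$fd, 3,
               tolerance = 0.1)
  expect_equal(fractal_dimension(make_fractal_set("cantor3d", 5))$fd,
               log(8) / log(3), tolerance = 0.1)
  expect_equal(fractal_dimension(make_fractal_set("menger", 4))$fd,
               log(20) / log(3), tolerance = 0.1)
})

test_that("fractal dimension is bounded and permutation invariant", {
  withr::with_seed(61, {
    p <- matrix(runif(3 * 2000, 0, 100), ncol = 3)
    perm <- sample(nrow(p))
  })
  f1 <- fractal_dimension(p)
  f2 <- fractal_dimension(p[perm, ])
  expect_identical(f1$fd, f2$fd)
  expect_gte(f1$fd, 0); expect_lte(f1$fd, 3)
  expect_gte(f1$n_used, 5)
})
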