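test_that("Spearman correlation handles monotone transforms and ties", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, -x^3)$rho, -1)
  expect_error(spearman(x, rep(1, 7)), "constant")
  expect_error(spearman(1:3, 1:3), "at least 4")
  # midrank-Pearson oracle on tied data
  withr::with_seed(101, {
    for (rep in 1:100) {
      n <- sample(5:30, 1)
      x <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 0.01 * (rep %% 2))
      y <- sample(1:6, n, replace = TRUE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      oracle <- {
        rx <- rank(x); ry <- rank(y)
        sum((rx - mean(rx)) * (ry - mean(ry))) /
          sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
      }
      expect_equal(spearman(x, y)$rho, oracle, tolerance = 1e-9)
    }
  })
  # spearman(x, y) = spearman(rank(x), rank(y)) exactly
  withr::with_seed(103, { x <- rnorm(20); y <- rnorm(20) })
  expect_equal(spearman(x, y)$rho, spearman(rank(x), rank(y))$rho,
               tolerance = 1e-12)
})

test_that("linear regression recovers exact lines and satisfies the R^2 identity", {
  x <- seq(-3, 5, by = 0.5)
  fit <- linear_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  withr::with_seed(107, {
    xb <- rnorm(5000); yb <- rnorm(5000)
  })
  nullfit <- linear_regression(xb, yb)
  expect_lt(abs(nullfit$r), 0.05)
  expect_lt(abs(nullfit$slope), 0.05)
  withr::with_seed(109, { xr <- rnorm(40); yr <- 0.7 * xr + rnorm(40) })
  f <- linear_regression(xr, yr)
  pred <- f$intercept + f$slope * xr
  r2_oracle <- 1 - sum((yr - pred)^2) / sum((yr - mean(yr))^2)
  expect_equal(f$r^2, r2_oracle, tolerance = 1e-9)
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "variance")
})

test_that("summary-statistics t-test matches raw-data t-tests exactly", {
  same <- summary_stats(5, 1, 10)
  res <- ttest_from_summary(same, same)
  expect_equal(res$t, 0); expect_equal(res$p, 1)
  # construct raw samples with the exact moments and compare with t.test
  withr::with_seed(113, {
    for (rep in 1:50) {
      n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
      a <- rnorm(n1); a <- (a - mean(a)) / sd(a) * runif(1, 0.5, 3) + rnorm(1)
      b <- rnorm(n2); b <- (b - mean(b)) / sd(b) * runif(1, 0.5, 3) + rnorm(1)
      s1 <- summary_stats(mean(a), sd(a), n1)
      s2 <- summary_stats(mean(b), sd(b), n2)
      for (ve in c(TRUE, FALSE)) {
        mine <- ttest_from_summary(s1, s2, var_equal = ve)
        ref <- t.test(a, b, var.equal = ve)
        expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
        expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
        expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
      }
    }
  })
  # zero-SD conventions
  z <- summary_stats(3, 0, 5)
  expect_equal(ttest_from_summary(z, z)$p, 1)
  expect_equal(ttest_from_summary(z, summary_stats(4, 0, 5))$p, 0)
})

test_that("Kruskal-Wallis wraps the rank test and matches the rank-sum formula", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
  # completely separated groups, hand-computable rank sums
  g <- list(1:5, 6:10, 11:15)
  H_hand <- {
    n <- 15; R <- c(sum(1:5), sum(6:10), sum(11:15))
    12 / (n * (n + 1)) * sum(R^2 / 5) - 3 * (n + 1)
  }
  expect_equal(kruskal_wallis(g)$H, H_hand, tolerance = 1e-9)
  # tie-corrected formula oracle on random data
  withr::with_seed(127, {
    for (rep in 1:100) {
      k <- sample(2:5, 1)
      gr <- lapply(seq_len(k), function(i) sample(1:10, sample(3:10, 1),
                                                  replace = TRUE))
      vals <- unlist(gr)
      if (length(unique(vals)) < 2) next
      r <- rank(vals)
      sizes <- lengths(gr)
      idx <- split(seq_along(vals), rep(seq_len(k), sizes))
      n <- length(vals)
      H <- 12 / (n * (n + 1)) *
        sum(vapply(idx, function(ii) sum(r[ii])^2, numeric(1)) / sizes) -
        3 * (n + 1)
      ties <- table(vals)
      H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
      expect_equal(kruskal_wallis(gr)$H, H, tolerance = 1e-9)
    }
  })
  # invariance under strictly monotone transforms
  g2 <- list(rnorm(8), rnorm(8, 1))
  expect_equal(kruskal_wallis(g2)$H, kruskal_wallis(lapply(g2, exp))$H,
               tolerance = 1e-12)
})

test_that("ROC analysis matches concordance oracles and Youden's cutoff", {
  r <- roc_analysis(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)
  expect_gt(r$optimal_cutoff, 3); expect_lt(r$optimal_cutoff, 11)
  # null: AUC ~ 0.5
  withr::with_seed(131, {
    s <- rnorm(2000); l <- rbinom(2000, 1, 0.5)
  })
  expect_equal(roc_analysis(s, l)$auc, 0.5, tolerance = 0.03)
  # concordant-pair oracle (ties get half credit)
  withr::with_seed(137, {
    for (rep in 1:100) {
      n <- sample(8:40, 1)
      s <- sample(1:10, n, replace = TRUE)
      l <- rbinom(n, 1, 0.5)
      if (length(unique(l)) < 2) next
      pos <- s[l == 1]; neg <- s[l == 0]
      pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      expect_equal(roc_analysis(s, l)$auc, mean(pairs), tolerance = 1e-9)
    }
  })
  # AUC(scores) + AUC(-scores) = 1 without ties
  withr::with_seed(139, { s <- rnorm(50); l <- rbinom(50, 1, 0.5) })
  expect_equal(roc_analysis(s, l)$auc + roc_analysis(-s, l)$auc, 1,
               tolerance = 1e-9)
  expect_error(roc_analysis(rnorm(10), rep(1, 10)), "both")
})

test_that("the cohort report has the full correlation grid and sane groups", {
  co <- make_synthetic_cohort(noise_scale = 0, seed = 2)
  rep <- cohort_report(co)
  expect_equal(nrow(rep$correlations), 7 * 3)
  expect_setequal(unique(rep$correlations$covariate),
                  c("mPAP", "PVR", "AVDO2", "artSO2", "venSO2", "age", "BSA"))
  expect_setequal(unique(rep$correlations$metric),
                  c("mean_dm", "fd", "n_segments"))
  dm_mpap <- subset(rep$correlations, metric == "mean_dm" & covariate == "mPAP")
  expect_equal(dm_mpap$rho, 1)
  expect_equal(rep$roc$auc, 1)
  expect_equal(nrow(rep$group_summary), 9)
  expect_true(all(c("pooled") %in% rep$group_tests$method))

  co2 <- co; co2$PVR <- NULL
  expect_warning(r2 <- cohort_report(co2), "skipped")
  expect_equal(nrow(r2$correlations), 6 * 3)
  expect_error(cohort_report(co[1:4, ]), "at least 6")
  co3 <- co; co3$ph_label <- TRUE
  expect_error(cohort_report(co3), "both PH labels")
})

test_that("shuffled-link cohorts rarely exceed the significance bound", {
  crit <- qt(0.975, 22)
  bound <- crit / sqrt(22 + crit^2)
  hits <- 0
  for (i in 1:30) {
    cn <- make_synthetic_cohort(shuffle_link = TRUE, seed = 500 + i)
    if (abs(spearman(cn$mean_dm, cn$mPAP)$rho) > bound) hits <- hits + 1
  }
  expect_lte(hits / 30, 0.2)
})

test_that("published summary statistics load with the expected shape", {
  tab <- published_cohort_summaries()
  expect_true(all(c("variable", "group", "mean", "sd", "n") %in% names(tab)))
  expect_setequal(unique(tab$group), c("all", "no_ph", "ph"))
  expect_true(all(c("distance_metric", "PVR", "artSO2", "mPAP") %in%
                    tab$variable))
  expect_true(all(tab$n[tab$group == "ph"] == 18))
  expect_true(all(tab$n[tab$group == "no_ph"] == 6))
})

test_that("reports serialise to disk", {
  co <- make_synthetic_cohort(seed = 4)
  rep <- cohort_report(co)
  dir <- withr::local_tempdir()
  write_cohort_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$n, 24)
  expect_true(file.exists(file.path(dir, "roc_curve.csv")))
})
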