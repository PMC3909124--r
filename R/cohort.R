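# Cohort statistics layer: Spearman correlation, linear regression,
# two-sample t-tests recomputable from printed summary statistics,
# Kruskal-Wallis across WHO functional classes, and ROC analysis for the
# presence of pulmonary hypertension (mPAP >= 25 mmHg).

#' Summary statistics triple
#'
#' `(mean, sd, n)` as printed in cohort tables; enough to recompute a
#' pooled-variance two-sample t-test.
#'
#' @param mean,sd,n group mean, standard deviation (>= 0) and size (>= 2).
#' @return A list of class `summary_stats`.
#' @export
summary_stats <- function(mean, sd, n) {
  if (sd < 0) stop("`sd` must be >= 0")
  if (n < 2) stop("`n` must be >= 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties; two-sided p-value from the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return A list with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 4) stop("need at least 4 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("undefined correlation: constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Least-squares linear regression with Pearson correlation
#'
#' @param x,y numeric vectors (length >= 3, `x` non-constant).
#' @return A list with `slope`, `intercept`, `r` (Pearson coefficient).
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (var(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = if (var(y) == 0) 0 else cor(x, y))
}

#' Two-sample t-test from summary statistics
#'
#' Student's two-sided two-sample t-test computed from group means, SDs and
#' sizes alone, as needed to recompute significance tests on printed
#' `mean +/- SD (n)` tables. Pooled variance by default; Welch's variant
#' behind `var_equal = FALSE`.
#'
#' @param a,b [summary_stats()] objects (or lists with mean/sd/n).
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return A list with `t`, `df`, `p`, `method`.
#' @export
ttest_from_summary <- function(a, b, var_equal = TRUE) {
  m1 <- a$mean; s1 <- a$sd; n1 <- a$n
  m2 <- b$mean; s2 <- b$sd; n2 <- b$n
  if (s1 < 0 || s2 < 0 || n1 < 2 || n2 < 2) stop("invalid summary statistics")
  if (s1 == 0 && s2 == 0) {
    p <- if (m1 == m2) 1 else 0
    return(list(t = if (m1 == m2) 0 else sign(m1 - m2) * Inf,
                df = n1 + n2 - 2, p = p,
                method = if (var_equal) "pooled" else "welch"))
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       method = if (var_equal) "pooled" else "welch")
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based one-way analysis of variance with tie correction; p-value from
#' the chi-square approximation on k - 1 degrees of freedom.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return A list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  values <- unlist(groups)
  if (length(unique(values)) < 2) stop("degenerate ranks: all values identical")
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(values, fac)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Receiver-operating-characteristic analysis
#'
#' Threshold sweep over the observed scores (higher score predicts the
#' positive class), trapezoidal AUC (equal to the Mann-Whitney concordance
#' probability), and the optimal cutoff by Youden's J = sensitivity +
#' specificity - 1.
#'
#' @param scores numeric predictor.
#' @param labels binary outcome (0/1 or logical); both classes must occur.
#' @return A list of class `roc_result`: `thresholds`, `sensitivities`,
#'   `specificities`, `auc`, `optimal_cutoff`, `sensitivity`, `specificity`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2)
    stop("both label classes must be present")
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  cc <- pROC::coords(r, "all", ret = c("threshold", "sensitivity",
                                       "specificity"), transpose = FALSE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, ]
  structure(list(thresholds = cc$threshold,
                 sensitivities = cc$sensitivity,
                 specificities = cc$specificity,
                 auc = as.numeric(pROC::auc(r)),
                 optimal_cutoff = best$threshold,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f; cutoff %.4g (sens %.2f, spec %.2f)\n",
              x$auc, x$optimal_cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' Full cohort report
#'
#' Correlates the morphometric readouts (`mean_dm`, `fd`, `n_segments`)
#' with the hemodynamic covariates (`mPAP`, `PVR`, `AVDO2`, `artSO2`,
#' `venSO2`, `age`, `BSA`) by Spearman rank correlation, summarises both
#' patient groups as mean +/- SD, tests group differences (t-test on the
#' group summaries), compares WHO functional classes by Kruskal-Wallis, and
#' runs ROC analysis of `mean_dm` for the presence of PH. Raw p-values are
#' reported without multiple-testing correction; p <= 0.05 is flagged
#' significant.
#'
#' @param records data frame with one row per patient; required columns
#'   `mean_dm` and logical `ph_label`, plus any of the covariates above and
#'   optionally `who_class`.
#' @param var_equal t-test variant (see [ttest_from_summary()]).
#' @return An object of class `cohort_report` with elements `correlations`,
#'   `group_summary`, `group_tests`, `kruskal`, `roc`, `n`.
#' @export
cohort_report <- function(records, var_equal = TRUE) {
  records <- as.data.frame(records)
  if (nrow(records) < 6) stop("need at least 6 patient records")
  if (!all(c("mean_dm", "ph_label") %in% names(records)))
    stop("records must contain `mean_dm` and `ph_label`")
  ph <- as.logical(records$ph_label)
  if (length(unique(ph)) < 2) stop("both PH labels must be present")
  metrics <- intersect(c("mean_dm", "fd", "n_segments"), names(records))
  covars <- c("mPAP", "PVR", "AVDO2", "artSO2", "venSO2", "age", "BSA")
  missing_cov <- setdiff(covars, names(records))
  if (length(missing_cov) > 0)
    warning("missing covariates skipped: ", paste(missing_cov, collapse = ", "))
  covars <- intersect(covars, names(records))
  cors <- do.call(rbind, lapply(covars, function(cv) {
    do.call(rbind, lapply(metrics, function(mt) {
      s <- spearman(records[[mt]], records[[cv]])
      data.frame(covariate = cv, metric = mt, rho = s$rho, p = s$p,
                 significant = s$p <= 0.05)
    }))
  }))
  summarise <- function(x) c(mean = mean(x), sd = sd(x), n = length(x),
                             min = min(x), max = max(x))
  groups <- list(all = rep(TRUE, nrow(records)), no_ph = !ph, ph = ph)
  group_summary <- do.call(rbind, lapply(metrics, function(mt) {
    do.call(rbind, lapply(names(groups), function(gn) {
      st <- summarise(records[[mt]][groups[[gn]]])
      data.frame(metric = mt, group = gn, mean = st["mean"], sd = st["sd"],
                 n = st["n"], min = st["min"], max = st["max"],
                 row.names = NULL)
    }))
  }))
  group_tests <- do.call(rbind, lapply(metrics, function(mt) {
    a <- summary_stats(mean(records[[mt]][ph]), sd(records[[mt]][ph]), sum(ph))
    b <- summary_stats(mean(records[[mt]][!ph]), sd(records[[mt]][!ph]), sum(!ph))
    tt <- ttest_from_summary(a, b, var_equal)
    data.frame(metric = mt, t = tt$t, df = tt$df, p = tt$p,
               method = tt$method, significant = tt$p <= 0.05)
  }))
  kw <- NULL
  if ("who_class" %in% names(records)) {
    cls <- factor(records$who_class)
    keep <- levels(cls)[table(cls) > 0]
    kw <- do.call(rbind, lapply(metrics, function(mt) {
      g <- split(records[[mt]], factor(cls, levels = keep))
      res <- tryCatch(kruskal_wallis(g), error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(metric = mt, H = res$H, df = res$df, p = res$p)
    }))
  }
  roc <- roc_analysis(records$mean_dm, ph)
  structure(list(correlations = cors, group_summary = group_summary,
                 group_tests = group_tests, kruskal = kw, roc = roc,
                 n = nrow(records)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d\n\nSpearman correlations:\n", x$n))
  print(x$correlations, row.names = FALSE, digits = 3)
  cat("\nGroup comparison (PH vs no PH):\n")
  print(x$group_tests, row.names = FALSE, digits = 3)
  if (!is.null(x$kruskal)) {
    cat("\nKruskal-Wallis across WHO classes:\n")
    print(x$kruskal, row.names = FALSE, digits = 3)
  }
  cat("\nROC (mean_dm for PH): ")
  print(x$roc)
  invisible(x)
}

#' Write a cohort report to disk
#'
#' @param report a `cohort_report`.
#' @param dir output directory (created if needed); writes
#'   `report.json`, `correlations.csv`, `group_summary.csv`,
#'   `roc_curve.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(n = report$n,
         correlations = report$correlations,
         group_tests = report$group_tests,
         kruskal = report$kruskal,
         roc = list(auc = report$roc$auc,
                    optimal_cutoff = report$roc$optimal_cutoff,
                    sensitivity = report$roc$sensitivity,
                    specificity = report$roc$specificity)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, null = "null")
  write.csv(report$correlations, file.path(dir, "correlations.csv"),
            row.names = FALSE)
  write.csv(report$group_summary, file.path(dir, "group_summary.csv"),
            row.names = FALSE)
  write.csv(data.frame(threshold = report$roc$thresholds,
                       sensitivity = report$roc$sensitivities,
                       specificity = report$roc$specificities),
            file.path(dir, "roc_curve.csv"), row.names = FALSE)
  invisible(dir)
}

#' Published cohort summary statistics
#'
#' Printed `mean +/- SD (range)` summary statistics of a published
#' 24-patient pulmonary-hypertension cohort (18 PH, 6 non-PH), covering the
#' hemodynamic covariates and the morphometric readouts. These allow the
#' printed group-significance tests to be recomputed from summary
#' statistics alone via [ttest_from_summary()].
#'
#' @return A data frame with columns `variable`, `group` (`all`, `no_ph`,
#'   `ph`), `mean`, `sd`, `n`, `range_lo`, `range_hi`.
#' @export
published_cohort_summaries <- function() {
  path <- system.file("extdata", "ph_cohort_summary.csv", package = "vastrac",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
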