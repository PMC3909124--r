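# The two headline morphometric readouts: distance-metric tortuosity of
# vessel segments and the 3D box-counting fractal dimension of the
# centerline point set.

#' Distance-metric tortuosity of a vessel segment
#'
#' The 3D path length of the segment divided by the Euclidean distance
#' between its endpoints. Dimensionless, >= 1, with equality exactly for a
#' straight, monotonically traversed polyline; invariant under rigid motions
#' and uniform scaling.
#'
#' @param seg a `vessel_segment` or an `n x 3` matrix of ordered points (mm).
#' @return A single number >= 1.
#' @export
distance_metric <- function(seg) {
  if (inherits(seg, "vessel_segment")) {
    L <- seg$length_mm; C <- seg$chord_mm
  } else {
    p <- as.matrix(seg)
    if (nrow(p) < 2) stop("need at least 2 points")
    L <- sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE])^2)))
    C <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  }
  if (C <= 0) stop("excluded segment: coincident endpoints (zero chord)")
  L / C
}

#' Mean distance metric over admissible segments
#'
#' Unweighted arithmetic mean of the per-segment distance metric, the
#' per-patient tortuosity readout. Degenerate segments (fewer than
#' `min_points` points, or chord at most `min_chord_mm`) are excluded.
#'
#' @param segs list of `vessel_segment` objects.
#' @param min_points,min_chord_mm admissibility filter (the pipeline default
#'   excludes segments with < 3 points or chord below one working voxel).
#' @return The mean distance metric (>= 1).
#' @export
mean_distance_metric <- function(segs, min_points = 3, min_chord_mm = 0) {
  segs <- admissible_segments(segs, min_points, min_chord_mm)
  if (length(segs) == 0) stop("no admissible segments for distance metric")
  mean(vapply(segs, distance_metric, numeric(1)))
}

#' Box-count a 3D point set at one cube size
#'
#' Partitions space into axis-aligned cubes of side `delta` anchored at
#' `grid_origin` and counts the cubes containing at least one point.
#'
#' @param points `n x 3` matrix of coordinates (voxel units for the
#'   pipeline's pixel-denominated cube sizes).
#' @param delta cube side (>= minimum resolution, > 0).
#' @param grid_origin grid anchor; defaults to the bounding-box minimum
#'   corner, keeping counts deterministic.
#' @return The number of occupied cubes.
#' @export
box_count <- function(points, delta, grid_origin = NULL) {
  points <- as.matrix(points)
  if (nrow(points) == 0) return(0L)
  if (delta <= 0) stop("`delta` must be > 0")
  if (is.null(grid_origin)) grid_origin <- apply(points, 2, min)
  key <- floor(sweep(points, 2, grid_origin, "-") / delta)
  K <- apply(key, 2, function(x) max(x) - min(x) + 1)
  k0 <- apply(key, 2, min)
  code <- (key[, 1] - k0[1]) + K[1] * ((key[, 2] - k0[2]) +
                                         K[2] * (key[, 3] - k0[3]))
  length(unique(code))
}

# delta grid: all integers up to 10, then geometric steps (ratio ~1.15)
box_count_deltas <- function(delta_min = 1, delta_max = 100, ratio = 1.15) {
  small <- seq(ceiling(delta_min), min(10, delta_max))
  g <- 10 * ratio^seq_len(ceiling(log(delta_max / 10) / log(ratio)))
  g <- unique(round(g[g <= delta_max]))
  deltas <- sort(unique(c(small, g, delta_max)))
  deltas[deltas >= delta_min & deltas <= delta_max]
}

#' Box-counting curve of a point set
#'
#' Counts occupied cubes over a range of cube sizes: every integer size up
#' to 10, then geometrically spaced sizes (ratio about 1.15) up to
#' `delta_max`, about 40 sizes in total. The grid is anchored at the
#' bounding-box minimum corner. Because successive grids are not nested, a
#' raw count can exceed the count at a smaller cube size when the coarser
#' grid is misaligned with the structure; such sizes carry no new scaling
#' information, so the curve keeps only the sizes attaining a new minimum
#' count (the covering-number lower envelope), which makes the counts
#' non-increasing by construction. The raw counts are retained in
#' attributes `raw_deltas` / `raw_counts`.
#'
#' @param points `n x 3` matrix (n >= 2).
#' @param delta_min,delta_max smallest and largest cube side (defaults 1 and
#'   100, in pixels).
#' @return An object of class `box_count_curve` with fields `deltas` and
#'   `counts`.
#' @export
box_count_curve <- function(points, delta_min = 1, delta_max = 100) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points for a box-count curve")
  if (!(delta_max > delta_min && delta_min >= 1))
    stop("require delta_max > delta_min >= 1")
  deltas <- box_count_deltas(delta_min, delta_max)
  origin <- apply(points, 2, min)
  counts <- vapply(deltas, function(dl) box_count(points, dl, origin),
                   numeric(1))
  keep <- c(TRUE, counts[-1] < cummin(counts)[-length(counts)])
  out <- structure(list(deltas = deltas[keep], counts = counts[keep]),
                   class = "box_count_curve")
  attr(out, "raw_deltas") <- deltas
  attr(out, "raw_counts") <- counts
  out
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat(sprintf("<box_count_curve> %d cube sizes, delta [%g, %g], N [%g, %g]\n",
              length(x$deltas), min(x$deltas), max(x$deltas),
              min(x$counts), max(x$counts)))
  invisible(x)
}

#' Select the linear range of a box-counting curve and fit it
#'
#' Fits a least-squares line to log(count) versus log(cube size) over the
#' linear regime of the curve. Data points are discarded from the small-size
#' end (resolution saturation) and then from the large-size end (grid
#' quantisation) until the retained contiguous range fits well
#' (r^2 >= `r2_good`); among all acceptable ranges the largest is kept, so a
#' curve that is already log-linear retains every point. The fractal
#' dimension is the magnitude of the fitted slope.
#'
#' @param curve a [box_count_curve()] with at least 8 points.
#' @param r2_good goodness-of-fit threshold (default 0.99).
#' @param min_points minimum retained points (default 5).
#' @return An object of class `fd_fit`: `fd`, `intercept`, `r2`,
#'   `used` (logical vector over curve points), `n_used`.
#' @export
select_linear_range <- function(curve, r2_good = 0.99, min_points = 5) {
  stopifnot(inherits(curve, "box_count_curve"))
  np <- length(curve$deltas)
  if (np < min_points)
    stop("need at least ", min_points, " curve points to select a linear range")
  ld <- log(curve$deltas); ln <- log(curve$counts)
  # prefix sums make each window fit O(1)
  c1 <- cumsum(ld); c2 <- cumsum(ld^2); c3 <- cumsum(ln); c4 <- cumsum(ln^2)
  c5 <- cumsum(ld * ln)
  win_fit <- function(lo, hi) {
    n <- hi - lo + 1
    s1 <- c1[hi] - if (lo > 1) c1[lo - 1] else 0
    s2 <- c2[hi] - if (lo > 1) c2[lo - 1] else 0
    s3 <- c3[hi] - if (lo > 1) c3[lo - 1] else 0
    s4 <- c4[hi] - if (lo > 1) c4[lo - 1] else 0
    s5 <- c5[hi] - if (lo > 1) c5[lo - 1] else 0
    sxx <- s2 - s1^2 / n; syy <- s4 - s3^2 / n; sxy <- s5 - s1 * s3 / n
    slope <- sxy / sxx
    r2 <- if (syy < 1e-300) { if (abs(sxy) < 1e-12) 1 else 0 } else sxy^2 / (sxx * syy)
    list(slope = slope, intercept = (s3 - slope * s1) / n, r2 = r2, n = n)
  }
  best <- NULL; best_any <- list(fit = list(r2 = -Inf), lo = 1, hi = np)
  # scan windows preferring (1) more points, (2) fewer small-delta points
  # dropped -- the fixed point of iteratively discarding small-delta then
  # large-delta points while keeping the fit good
  for (n in seq(np, min_points)) {
    for (lo in seq_len(np - n + 1)) {
      hi <- lo + n - 1
      f <- win_fit(lo, hi)
      if (f$r2 > best_any$fit$r2) best_any <- list(fit = f, lo = lo, hi = hi)
      if (f$r2 >= r2_good) { best <- list(fit = f, lo = lo, hi = hi); break }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    cond <- structure(class = c("vastrac_fit_error", "error", "condition"),
                      list(message = sprintf(
                        "no sub-range reaches r2 >= %g with >= %d points (best r2 = %.5f)",
                        r2_good, min_points, best_any$fit$r2),
                        call = sys.call(-1), best = best_any))
    stop(cond)
  }
  used <- rep(FALSE, np); used[best$lo:best$hi] <- TRUE
  structure(list(fd = -best$fit$slope, intercept = best$fit$intercept,
                 r2 = best$fit$r2, used = used, n_used = best$fit$n,
                 deltas = curve$deltas, counts = curve$counts),
            class = "fd_fit")
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("<fd_fit> FD = %.4f (r2 = %.5f, %d of %d points used)\n",
              x$fd, x$r2, x$n_used, length(x$used)))
  invisible(x)
}

#' 3D box-counting fractal dimension
#'
#' Composition of [box_count_curve()] and [select_linear_range()]: the
#' fractal dimension is the magnitude of the slope of log(occupied cube
#' count) versus log(cube size) over the automatically selected linear
#' regime.
#'
#' @param points `n x 3` matrix (>= 2 points), typically centerline
#'   coordinates in voxel units.
#' @param delta_min,delta_max cube-size range in pixels.
#' @param r2_good linear-fit threshold passed to [select_linear_range()].
#' @return An `fd_fit` object; the dimension itself is in `$fd`.
#' @export
fractal_dimension <- function(points, delta_min = 1, delta_max = 100,
                              r2_good = 0.99) {
  curve <- box_count_curve(points, delta_min, delta_max)
  select_linear_range(curve, r2_good)
}
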