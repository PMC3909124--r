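# Synthetic phantoms with analytic ground truth: tube scenes emulating a
# contrast-enhanced thorax (bright vessels in dark lung inside a tissue
# shell inside air), branching centerline trees, exact fractal point sets,
# and a pseudo-hemodynamic cohort. All generators are deterministic under a
# fixed seed.

default_hu <- function() list(air = -1000, lung = -850, vessel = 300, body = 40)

# minimum distance field from voxel centers to a densely sampled path (mm);
# only voxels within `rmax` of the path are touched
path_distance_field <- function(d, spacing, origin, path_mm, rmax) {
  dist <- array(Inf, d)
  box <- ceiling(rmax / spacing) + 1L
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(d[a]) - 1) * spacing[a])
  for (r in seq_len(nrow(path_mm))) {
    p <- path_mm[r, ]
    ctr <- round((p - origin) / spacing) + 1
    i0 <- pmax(1, ctr - box); i1 <- pmin(d, ctr + box)
    if (any(i0 > i1)) next
    xs <- ax[[1]][i0[1]:i1[1]] - p[1]
    ys <- ax[[2]][i0[2]:i1[2]] - p[2]
    zs <- ax[[3]][i0[3]:i1[3]] - p[3]
    dd <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
    sub <- dist[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
    dist[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- pmin(sub, dd)
  }
  dist
}

# blend a tube of radius r into a background array with a one-voxel
# partial-volume ramp
stamp_tube <- function(arr, dist, radius, vessel_hu, spacing) {
  vox <- min(spacing)
  w <- pmin(pmax((radius + 0.5 * vox - dist) / vox, 0), 1)
  sel <- w > 0
  arr[sel] <- arr[sel] * (1 - w[sel]) + vessel_hu * w[sel]
  arr
}

# thorax-like background: air everywhere, an elliptic tissue cylinder
# spanning the full z extent, a lung compartment inside
scene_background <- function(d, spacing, hu, lung_axes_frac = c(0.34, 0.34, 0.34),
                             two_lungs = FALSE) {
  ext <- (d - 1) * spacing
  ctr <- ext / 2
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spacing[a])
  X <- array(ax[[1]], d)
  Y <- array(rep(ax[[2]], each = d[1]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  body <- ((X - ctr[1]) / (0.45 * ext[1]))^2 + ((Y - ctr[2]) / (0.45 * ext[2]))^2 <= 1
  arr <- array(hu$air, d)
  arr[body] <- hu$body
  if (two_lungs) {
    la <- c(0.17, 0.3, 0.3) * ext
    lung1 <- ((X - (ctr[1] - 0.22 * ext[1])) / la[1])^2 +
      ((Y - ctr[2]) / la[2])^2 + ((Z - ctr[3]) / la[3])^2 <= 1
    lung2 <- ((X - (ctr[1] + 0.22 * ext[1])) / la[1])^2 +
      ((Y - ctr[2]) / la[2])^2 + ((Z - ctr[3]) / la[3])^2 <= 1
    lung <- lung1 | lung2
    arr[lung] <- hu$lung
    list(arr = arr, lung = lung, lung_left = lung2, lung_right = lung1,
         ctr = ctr, ext = ext, X = X, Y = Y, Z = Z)
  } else {
    la <- lung_axes_frac * ext
    lung <- ((X - ctr[1]) / la[1])^2 + ((Y - ctr[2]) / la[2])^2 +
      ((Z - ctr[3]) / la[3])^2 <= 1
    arr[lung] <- hu$lung
    list(arr = arr, lung = lung, ctr = ctr, ext = ext, X = X, Y = Y, Z = Z)
  }
}

#' Tube phantom volume with analytic centerline
#'
#' Generates a thorax-like scene (air background, tissue cylinder, dark lung
#' compartment) containing one bright tube: either a straight axial tube or
#' a helix with radius `helix_radius` and pitch parameter `helix_pitch` (the
#' helix `(r cos t, r sin t, c t)` has distance metric
#' `sqrt(r^2 + c^2) / c` over whole turns). Intensities follow
#' contrast-enhanced CT magnitudes with a one-voxel partial-volume ramp at
#' the tube wall and optional additive Gaussian noise.
#'
#' @param kind `"straight"` or `"helix"`.
#' @param radius_mm tube radius in mm (must be at least the voxel spacing).
#' @param helix_radius,helix_pitch,turns helix geometry (`r`, `c`, number of
#'   whole turns).
#' @param dims,spacing_mm grid size and isotropic voxel spacing.
#' @param hu intensity model (`air`, `lung`, `vessel`, `body`), HU.
#' @param noise_sd additive Gaussian noise SD in HU.
#' @param seed RNG seed fixing all randomness.
#' @return A list: `volume` ([volume3d()]), `centerline` (dense ground-truth
#'   polyline, mm), `lung_mask` ([mask3d()]), `dm_truth`.
#' @export
make_tube_volume <- function(kind = c("straight", "helix"), radius_mm = 1,
                             helix_radius = 4, helix_pitch = 2, turns = 3,
                             dims = c(128, 128, 128), spacing_mm = 0.6,
                             hu = default_hu(), noise_sd = 15, seed = 1) {
  kind <- match.arg(kind)
  d <- as.integer(dims); spacing <- rep(spacing_mm, 3); origin <- c(0, 0, 0)
  if (radius_mm < spacing_mm)
    stop("tube radius below the voxel spacing is unresolvable")
  bg <- scene_background(d, spacing, hu)
  ctr <- bg$ctr; ext <- bg$ext
  if (kind == "straight") {
    zs <- seq(ctr[3] - 0.3 * ext[3], ctr[3] + 0.3 * ext[3], by = 0.25 * spacing_mm)
    path <- cbind(ctr[1], ctr[2], zs)
  } else {
    tmax <- 2 * pi * turns
    ts <- seq(0, tmax, by = 0.25 * spacing_mm / sqrt(helix_radius^2 + helix_pitch^2))
    path <- cbind(ctr[1] + helix_radius * cos(ts),
                  ctr[2] + helix_radius * sin(ts),
                  ctr[3] + helix_pitch * (ts - tmax / 2))
  }
  dist <- path_distance_field(d, spacing, origin, path, radius_mm + 2 * spacing_mm)
  arr <- stamp_tube(bg$arr, dist, radius_mm, hu$vessel, spacing)
  if (noise_sd > 0)
    arr <- withr::with_seed(seed, arr + array(rnorm(prod(d), 0, noise_sd), d))
  list(volume = volume3d(arr, spacing, origin),
       centerline = path,
       lung_mask = mask3d(array(as.numeric(bg$lung), d), spacing, origin),
       dm_truth = distance_metric(path),
       kind = kind)
}

#' Lung scene phantom with a bifurcating airway
#'
#' Two lung ellipsoids inside a tissue cylinder, with an air-filled trachea
#' entering from the superior face and splitting at a carina into two
#' daughter bronchi, one per lung. Used to exercise lung segmentation,
#' airway extraction and the left/right split with known ground truth.
#'
#' @param dims,spacing_mm grid geometry.
#' @param trachea_radius,bronchus_radius airway radii in mm.
#' @param with_airway include the airway (FALSE gives a plain two-lung scene).
#' @param hu,noise_sd,seed intensity model and noise.
#' @return A list: `volume`, `lung_mask`, `airway_mask` (ground truth),
#'   `carina` (mm), `left_lung_mask`, `right_lung_mask`.
#' @export
make_lung_scene <- function(dims = c(96, 96, 96), spacing_mm = 0.8,
                            trachea_radius = 3, bronchus_radius = 2.2,
                            with_airway = TRUE, hu = default_hu(),
                            noise_sd = 15, seed = 1) {
  d <- as.integer(dims); spacing <- rep(spacing_mm, 3); origin <- c(0, 0, 0)
  bg <- scene_background(d, spacing, hu, two_lungs = TRUE)
  ctr <- bg$ctr; ext <- bg$ext
  arr <- bg$arr
  airway <- array(FALSE, d)
  carina <- c(NA_real_, NA_real_, NA_real_)
  if (with_airway) {
    ztop <- ext[3]
    zcar <- ctr[3] + 0.12 * ext[3]
    # the trachea axis stops one radius above the carina: its end-cap then
    # reaches exactly down to the bifurcation without merging the daughters
    tr_path <- cbind(ctr[1], ctr[2],
                     seq(zcar + trachea_radius, ztop, by = 0.25 * spacing_mm))
    zlo <- ctr[3] - 0.15 * ext[3]
    # daughters diverge steeply at the carina (as real main bronchi do), so
    # the lumen split happens within a voxel or two of the axis bifurcation
    zknee <- zcar - 0.06 * ext[3]
    knee_dx <- 0.13 * ext[1]
    mk_branch <- function(sgn) {
      t1 <- seq(0, 1, by = 0.25 * spacing_mm / (zcar - zknee))
      seg1 <- cbind(ctr[1] + sgn * t1 * knee_dx, ctr[2] + 0 * t1,
                    zcar - t1 * (zcar - zknee))
      t2 <- seq(0, 1, by = 0.25 * spacing_mm / (zknee - zlo))
      seg2 <- cbind(ctr[1] + sgn * (knee_dx + t2 * (0.20 * ext[1] - knee_dx)),
                    ctr[2] + 0 * t2, zknee - t2 * (zknee - zlo))
      rbind(seg1, seg2)
    }
    right_path <- mk_branch(-1)
    left_path <- mk_branch(1)
    dtr <- path_distance_field(d, spacing, origin, tr_path,
                               trachea_radius + 2 * spacing_mm)
    dbr <- pmin(path_distance_field(d, spacing, origin, right_path,
                                    bronchus_radius + 2 * spacing_mm),
                path_distance_field(d, spacing, origin, left_path,
                                    bronchus_radius + 2 * spacing_mm))
    airway <- dtr <= trachea_radius | dbr <= bronchus_radius
    arr[airway] <- hu$air
    # the anatomical carina is the top of the septum between the two
    # daughter lumens, which for tubes slanted by theta from the vertical
    # lies r/sin(theta) below the axis bifurcation
    tan_th <- knee_dx / (zcar - zknee)
    sin_th <- tan_th / sqrt(1 + tan_th^2)
    carina <- c(ctr[1], ctr[2], zcar - bronchus_radius / sin_th)
  }
  if (noise_sd > 0)
    arr <- withr::with_seed(seed, arr + array(rnorm(prod(d), 0, noise_sd), d))
  list(volume = volume3d(arr, spacing, origin),
       lung_mask = mask3d(array(as.numeric(bg$lung), d), spacing, origin),
       airway_mask = mask3d(array(as.numeric(airway), d), spacing, origin),
       carina = carina,
       left_lung_mask = mask3d(array(as.numeric(bg$lung_left), d), spacing, origin),
       right_lung_mask = mask3d(array(as.numeric(bg$lung_right), d), spacing, origin))
}

# unit vector helpers for tree construction
perp_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(u[2] * ref[3] - u[3] * ref[2], u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# one tree segment: straight run plus an in-plane sinusoidal perturbation of
# amplitude `amp` vanishing at both endpoints (so branch points stay fixed)
tree_segment_points <- function(p0, u, L, amp, phase, n_halfwaves = 2,
                                n_samples = 200) {
  t <- seq(0, 1, length.out = n_samples)
  pb <- perp_basis(u)
  dirp <- cos(phase) * pb$e1 + sin(phase) * pb$e2
  off <- amp * sin(pi * n_halfwaves * t)
  base <- outer(t * L, u)
  sweep(base + outer(off, dirp), 2, p0, "+")
}

#' Bifurcating vascular tree phantom
#'
#' Recursive binary tree of tube segments with a per-segment sinusoidal
#' perturbation whose amplitude is the tortuosity parameter; a tree with
#' `depth` levels of bifurcation has `2^(depth+1) - 1` segments. Ground
#' truth (per-segment polylines and distance metrics) is exact by
#' construction; optionally the tree is rendered into a lung-scene volume.
#'
#' @param depth bifurcation levels (0-6).
#' @param tortuosity sinusoidal perturbation amplitude in mm (0 = straight).
#' @param base_length_mm root segment length; children shrink by
#'   `length_ratio`.
#' @param branch_angle_deg half-angle between daughters.
#' @param length_ratio geometric shrink factor per level.
#' @param radius_mm root tube radius (shrinks by 0.8 per level when
#'   rendered).
#' @param n_halfwaves half-periods of the perturbation per segment.
#' @param render stamp tubes into a volume (`FALSE` returns geometry only).
#' @param dims,spacing_mm,hu,noise_sd,seed rendering controls.
#' @return A list: `segments` (list of dense polylines, mm),
#'   `dm_per_segment`, `n_segments`, `tips`, and when rendered `volume` and
#'   `lung_mask`.
#' @export
make_branching_tree <- function(depth = 2, tortuosity = 0, base_length_mm = 20,
                                branch_angle_deg = 45, length_ratio = 0.7,
                                radius_mm = 1.5, n_halfwaves = 2,
                                render = FALSE, dims = c(128, 128, 128),
                                spacing_mm = 0.6, hu = default_hu(),
                                noise_sd = 15, seed = 1) {
  if (depth > 6) stop("`depth` must be <= 6")
  d <- as.integer(dims); spacing <- rep(spacing_mm, 3); origin <- c(0, 0, 0)
  ext <- (d - 1) * spacing
  ctr <- ext / 2
  start <- c(ctr[1], ctr[2], ctr[3] - 0.3 * ext[3])
  segs <- list(); radii <- numeric(0)
  ang <- branch_angle_deg * pi / 180
  recurse <- function(p0, u, L, lev, idx) {
    phase <- (idx * 2.399963) %% (2 * pi) # deterministic golden-angle phases
    pts <- tree_segment_points(p0, u, L, tortuosity, phase, n_halfwaves)
    segs[[length(segs) + 1]] <<- pts
    radii[length(radii) + 1] <<- radius_mm * 0.8^lev
    p1 <- pts[nrow(pts), ]
    if (lev < depth) {
      pb <- perp_basis(u)
      az <- lev * pi / 2 + idx # rotate the branching plane level to level
      w <- cos(az) * pb$e1 + sin(az) * pb$e2
      for (sgn in c(-1, 1)) {
        v <- cos(ang) * u + sgn * sin(ang) * w
        v <- v / sqrt(sum(v^2))
        recurse(p1, v, L * length_ratio, lev + 1, 2 * idx + (sgn + 1) / 2)
      }
    }
  }
  recurse(start, c(0, 0, 1), base_length_mm, 0, 1)
  allp <- do.call(rbind, segs)
  out_of_bounds <- any(allp < 0) || any(sweep(allp, 2, ext, ">") )
  if (out_of_bounds) warning("tree branches escape the volume bounds")
  dms <- vapply(segs, distance_metric, numeric(1))
  res <- list(segments = segs, dm_per_segment = dms,
              n_segments = length(segs),
              tips = t(vapply(segs, function(s) s[nrow(s), ], numeric(3))),
              spacing = spacing, origin = origin)
  if (render) {
    bg <- scene_background(d, spacing, hu)
    arr <- bg$arr
    for (s in seq_along(segs)) {
      dist <- path_distance_field(d, spacing, origin, segs[[s]],
                                  radii[s] + 2 * spacing_mm)
      arr <- stamp_tube(arr, dist, radii[s], hu$vessel, spacing)
    }
    if (noise_sd > 0)
      arr <- withr::with_seed(seed, arr + array(rnorm(prod(d), 0, noise_sd), d))
    res$volume <- volume3d(arr, spacing, origin)
    res$lung_mask <- mask3d(array(as.numeric(bg$lung), d), spacing, origin)
  }
  res
}

#' Deterministic point sets with known fractal dimension
#'
#' Generates oracle inputs for box counting: a line (dimension 1), a plane
#' (2), a filled cube lattice (3), 3D Cantor dust (keep the 8 corner
#' sub-cubes of each cube at scale 1/3; dimension log8/log3 ~ 1.893) and the
#' Menger sponge skeleton (keep 20 of 27 sub-cubes; log20/log3 ~ 2.727).
#'
#' @param kind one of `"line"`, `"plane"`, `"cube"`, `"cantor3d"`,
#'   `"menger"`.
#' @param level for `line` the number of points, for `plane`/`cube` the side
#'   length of the lattice, for `cantor3d`/`menger` the construction depth.
#' @return An `n x 3` numeric matrix of points (voxel-unit coordinates).
#' @export
make_fractal_set <- function(kind = c("line", "plane", "cube", "cantor3d",
                                      "menger"), level = 4) {
  kind <- match.arg(kind)
  if (level < 1) stop("`level` must be >= 1")
  npts <- switch(kind, line = level, plane = level^2, cube = level^3,
                 cantor3d = 8^level, menger = 20^level)
  if (npts > 1e7) stop("`level` would produce more than 1e7 points")
  if (kind == "line") {
    i <- seq_len(level) - 1
    return(cbind(i, i, i))
  }
  if (kind == "plane") {
    g <- seq_len(level) - 1
    return(cbind(rep(g, each = level), rep(g, times = level), 0))
  }
  if (kind == "cube") {
    g <- seq_len(level) - 1
    return(as.matrix(expand.grid(x = g, y = g, z = g)))
  }
  # iterated-function-system sets on the 3^level grid
  keep <- if (kind == "cantor3d") {
    as.matrix(expand.grid(x = c(0, 2), y = c(0, 2), z = c(0, 2)))
  } else {
    cells <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))
    cells[rowSums(cells == 1) < 2, , drop = FALSE]
  }
  pts <- matrix(0, nrow = 1, ncol = 3)
  for (l in seq_len(level)) {
    scale <- 3^(level - l)
    pts <- do.call(rbind, lapply(seq_len(nrow(keep)), function(r)
      sweep(pts, 2, keep[r, ] * scale, "+")))
  }
  unname(pts)
}

# logistic link from latent severity (0 = healthy .. 1 = severe) to the
# sinusoidal tortuosity amplitude of the phantom tree, calibrated so cohort
# mean DM spans roughly 1.20-1.27, the clinically observed range
amplitude_link <- function(s) 1.22 + 0.2 * stats::plogis((s - 0.35) / 0.2)

#' Synthetic patient cohort with pseudo-hemodynamics
#'
#' Emulates the structure of a 24-patient pulmonary-hypertension cohort
#' (default 18 PH / 6 non-PH). Each patient has a latent severity `s` drawn
#' from a two-component distribution calibrated to the printed group means
#' (non-PH mPAP 17 +/- 2 mmHg, PH 43 +/- 12 mmHg); a strictly increasing
#' logistic link maps severity to the tortuosity amplitude of a fixed
#' phantom vessel tree, whose exact geometric mean distance metric is the
#' ground-truth morphometric readout. Pseudo-hemodynamics (mPAP, PVR,
#' AVDO2, saturations) are affine or monotone functions of severity plus
#' noise; the PH label is pseudo-mPAP >= 25 mmHg. With `noise_scale = 0`
#' the cohort is a deterministic monotone transform of severity, so the
#' Spearman correlation between ground-truth DM and pseudo-mPAP is exactly
#' 1.
#'
#' @param n_patients cohort size (>= 6).
#' @param n_ph number of patients drawn from the PH severity component.
#' @param noise_scale multiplier on all noise SDs (0 = noise free).
#' @param tree_depth bifurcation depth of the morphometry phantom tree.
#' @param shuffle_link permute severities before computing DM (breaks the
#'   DM-hemodynamics link; used for null-calibration experiments).
#' @param seed RNG seed; the same seed reproduces the cohort exactly.
#' @return A data frame with columns `patient_id`, `severity`, `amplitude`,
#'   `mean_dm`, `fd`, `n_segments`, `mPAP`, `PVR`, `AVDO2`, `artSO2`,
#'   `venSO2`, `age`, `BSA`, `who_class`, `ph_label`. Hemodynamic columns
#'   are pseudo-values in the units of their clinical counterparts.
#' @export
make_synthetic_cohort <- function(n_patients = 24, n_ph = 18, noise_scale = 1,
                                  tree_depth = 3, shuffle_link = FALSE,
                                  seed = 1) {
  if (n_patients < 6) stop("`n_patients` must be >= 6")
  if (n_ph >= n_patients || n_ph < 1) stop("invalid PH/non-PH split")
  withr::with_seed(seed, {
    n_lo <- n_patients - n_ph
    # the group draw already carries the biological spread, so it is the
    # pseudo-measurement itself; the 18/6 split is then exact by the clips
    mpap0 <- c(pmin(pmax(rnorm(n_lo, 17, 2), 14), 20),
               pmin(pmax(rnorm(n_ph, 43, 12), 26), 66))
    s <- (mpap0 - 14) / 52
    s_for_dm <- if (shuffle_link) sample(s) else s
    amp <- amplitude_link(s_for_dm) *
      (1 + noise_scale * rnorm(n_patients, 0, 0.015))
    mean_dm <- vapply(amp, function(a) {
      tr <- make_branching_tree(depth = tree_depth, tortuosity = a,
                                render = FALSE)
      mean(tr$dm_per_segment)
    }, numeric(1))
    mPAP <- mpap0
    PVR <- pmax(60, 100 + 1900 * s^2 + noise_scale * rnorm(n_patients, 0, 50))
    AVDO2 <- pmax(2, 3.9 + 2.3 * s + noise_scale * rnorm(n_patients, 0, 0.3))
    artSO2 <- pmin(100, 96.3 - 5.9 * s + noise_scale * rnorm(n_patients, 0, 0.8))
    venSO2 <- pmin(100, 74.5 - 15 * s + noise_scale * rnorm(n_patients, 0, 2.5))
    fd <- pmin(pmax(rnorm(n_patients, 2.35, 0.06), 2.21), 2.44)
    n_segments <- round(pmin(pmax(rnorm(n_patients, 12427, 3508), 5922), 20434))
    age <- round(pmin(pmax(rnorm(n_patients, 60, 13), 27), 76))
    BSA <- round(pmin(pmax(rnorm(n_patients, 2.0, 0.3), 1.6), 2.9), 2)
    who <- cut(s, breaks = c(-Inf, 0.03, 0.35, 0.75, Inf),
               labels = c("I", "II", "III", "IV"))
    data.frame(patient_id = sprintf("P%02d", seq_len(n_patients)),
               severity = s, amplitude = amp, mean_dm = mean_dm, fd = fd,
               n_segments = n_segments, mPAP = mPAP, PVR = PVR,
               AVDO2 = AVDO2, artSO2 = artSO2, venSO2 = venSO2, age = age,
               BSA = BSA, who_class = as.character(who),
               ph_label = mPAP >= 25, stringsAsFactors = FALSE)
  })
}

#' Write a synthetic cohort to CSV
#'
#' @param cohort data frame from [make_synthetic_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
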