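#' 3D scalar volume with physical metadata
#'
#' Container for a 3D image grid with voxel spacing and origin in millimetres.
#' Voxel index `i` (0-based) maps to physical position `origin + i * spacing`
#' (voxel-center convention), so all downstream geometry (tortuosity, box
#' counting) can be computed in physical units.
#'
#' @param data numeric 3D array (Hounsfield units or filter response).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @return An object of class `volume3d` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing = c(0.6, 0.6, 0.6))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 voxels per axis")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  if (any(!is.finite(data)))
    stop("volume contains non-finite values")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm, range [%.4g, %.4g]\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ","),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary mask aligned to a volume
#'
#' @param data logical/0-1 3D array.
#' @param spacing,origin physical metadata, as in [volume3d()].
#' @param parent optional `volume3d` supplying metadata and shape check.
#' @return An object of class `mask3d` (subclass of `volume3d`) with 0/1 data.
#' @export
mask3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0), parent = NULL) {
  if (!is.null(parent)) {
    stopifnot(inherits(parent, "volume3d"))
    if (!identical(dim(data), dim(parent$data)))
      stop("mask shape differs from its parent volume")
    spacing <- parent$spacing; origin <- parent$origin
  }
  if (is.logical(data)) { mode(data) <- "double" }
  if (!all(data %in% c(0, 1))) stop("mask values must be 0/1")
  v <- volume3d(data, spacing, origin)
  class(v) <- c("mask3d", class(v))
  v
}

#' @rdname mask3d
#' @param x object to test.
#' @export
is_mask3d <- function(x) inherits(x, "mask3d")

# physical coordinates (mm) of 1-based voxel indices
voxel_to_mm <- function(idx, v) {
  sweep(sweep(idx - 1, 2, v$spacing, "*"), 2, v$origin, "+")
}

# continuous 0-based voxel coordinates of physical points (mm)
mm_to_voxel <- function(pts, v) {
  sweep(sweep(pts, 2, v$origin, "-"), 2, v$spacing, "/")
}

# linear (0-based) index helpers
lin_index <- function(ijk, d) {
  (ijk[, 1] - 1) + (ijk[, 2] - 1) * d[1] + (ijk[, 3] - 1) * d[1] * d[2]
}

ijk_from_lin <- function(lin, d) {
  # lin is 1-based R index into the array
  lin0 <- lin - 1
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind(i + 1, j + 1, k + 1)
}

#' Read a volumetric image
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) via RNifti and MetaImage
#' (`.mha`, `.mhd`). Spacing is taken from the file header (mm); the origin is
#' taken from the NIfTI xform translation or the MetaImage `Offset` field.
#'
#' @param path file path.
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    if (file.info(path)$size == 0) stop("parse error: empty file: ", path)
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("parse error reading NIfTI: ",
                                             conditionMessage(e)))
    a <- array(as.numeric(img), dim = dim(img))
    if (length(dim(a)) != 3L) stop("expected a 3D NIfTI volume")
    sp <- RNifti::pixdim(img)[1:3]
    orig <- tryCatch(RNifti::xform(img)[1:3, 4], error = function(e) c(0, 0, 0))
    volume3d(a, spacing = sp, origin = as.numeric(orig))
  } else if (grepl("\\.(mha|mhd)$", lower)) {
    read_metaimage(path)
  } else {
    stop("unsupported format (expected .nii, .nii.gz, .mha or .mhd): ", path)
  }
}

#' Write a volumetric image
#'
#' @param v a [volume3d()] (or [mask3d()]).
#' @param path output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`, `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume3d"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$spacing
    aff <- diag(c(v$spacing, 1))
    aff[1:3, 4] <- v$origin
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(mha|mhd)$", lower)) {
    write_metaimage(v, path)
  } else {
    stop("unsupported format for writing: ", path)
  }
  invisible(path)
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation for intensity volumes, nearest neighbour for masks.
#' The physical extent is preserved to within one voxel; the origin is kept.
#' Needed because non-maxima suppression and box counting assume cubic voxels.
#'
#' @param v a [volume3d()].
#' @param target isotropic voxel size in mm (> 0, smaller than the volume
#'   extent).
#' @param mode `"linear"` or `"nearest"`; defaults to `"nearest"` for masks.
#' @return A resampled [volume3d()] with spacing `c(target, target, target)`.
#' @export
resample_isotropic <- function(v, target = 0.6,
                               mode = if (is_mask3d(v)) "nearest" else "linear") {
  stopifnot(inherits(v, "volume3d"))
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("`target` must be a single positive number (mm)")
  d <- dim(v$data)
  extent <- (d - 1) * v$spacing
  if (target > max(extent)) stop("`target` larger than the volume extent")
  mode <- match.arg(mode, c("linear", "nearest"))
  nd <- pmax(2L, as.integer(floor(extent / target + 1e-9)) + 1L)
  # 0-based source voxel coordinates of the new grid
  g1 <- (seq_len(nd[1]) - 1) * target / v$spacing[1]
  g2 <- (seq_len(nd[2]) - 1) * target / v$spacing[2]
  g3 <- (seq_len(nd[3]) - 1) * target / v$spacing[3]
  pts <- cbind(rep(g1, times = nd[2] * nd[3]),
               rep(rep(g2, each = nd[1]), times = nd[3]),
               rep(g3, each = nd[1] * nd[2]))
  if (mode == "nearest") {
    idx <- cbind(pmin(round(pts[, 1]), d[1] - 1),
                 pmin(round(pts[, 2]), d[2] - 1),
                 pmin(round(pts[, 3]), d[3] - 1)) + 1
    vals <- v$data[idx]
  } else {
    vals <- trilin_cpp(v$data, pts)
  }
  out <- array(vals, dim = nd)
  if (is_mask3d(v)) mask3d(out, rep(target, 3), v$origin)
  else volume3d(out, rep(target, 3), v$origin)
}
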