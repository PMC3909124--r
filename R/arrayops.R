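# Internal array utilities: smoothing, derivatives, FFT-based binary
# morphology. All operate on plain 3D arrays; physical units are handled by
# the callers.

gaussian_blur <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  blur3d_cpp(a, sigma_vox)
}

# central differences, one-sided at the borders; spacing in mm per axis
gradient3 <- function(a, spacing = c(1, 1, 1)) {
  d <- dim(a)
  gr <- function(axis) {
    n <- d[axis]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    denom <- (ip - im) * spacing[axis]
    if (axis == 1) (a[ip, , , drop = FALSE] - a[im, , , drop = FALSE]) /
        array(denom, dim = d)
    else if (axis == 2) (a[, ip, , drop = FALSE] - a[, im, , drop = FALSE]) /
        array(rep(denom, each = d[1]), dim = d)
    else (a[, , ip, drop = FALSE] - a[, , im, drop = FALSE]) /
        array(rep(denom, each = d[1] * d[2]), dim = d)
  }
  list(x = gr(1), y = gr(2), z = gr(3))
}

shift_arr <- function(a, s) {
  # shift array by integer offsets s (replicating the border)
  d <- dim(a)
  idx1 <- pmin(pmax(seq_len(d[1]) + s[1], 1L), d[1])
  idx2 <- pmin(pmax(seq_len(d[2]) + s[2], 1L), d[2])
  idx3 <- pmin(pmax(seq_len(d[3]) + s[3], 1L), d[3])
  a[idx1, idx2, idx3, drop = FALSE]
}

# full Hessian (6 unique components) by central second differences
hessian3 <- function(a, spacing = c(1, 1, 1)) {
  s <- spacing
  d2 <- function(ax) {
    (shift_arr(a, ifelse(1:3 == ax, 1L, 0L)) - 2 * a +
       shift_arr(a, ifelse(1:3 == ax, -1L, 0L))) / s[ax]^2
  }
  dxy <- function(ax1, ax2) {
    e1 <- ifelse(1:3 == ax1, 1L, 0L); e2 <- ifelse(1:3 == ax2, 1L, 0L)
    (shift_arr(a, e1 + e2) + shift_arr(a, -e1 - e2) -
       shift_arr(a, e1 - e2) - shift_arr(a, e2 - e1)) / (4 * s[ax1] * s[ax2])
  }
  list(xx = d2(1), yy = d2(2), zz = d2(3),
       xy = dxy(1, 2), xz = dxy(1, 3), yz = dxy(2, 3))
}

ball_kernel <- function(radius_mm, spacing) {
  r_vox <- radius_mm / spacing
  half <- pmax(0L, as.integer(floor(r_vox)))
  gx <- seq(-half[1], half[1]); gy <- seq(-half[2], half[2]); gz <- seq(-half[3], half[3])
  k <- outer(outer((gx * spacing[1])^2, (gy * spacing[2])^2, "+"),
             (gz * spacing[3])^2, "+") <= radius_mm^2 + 1e-9
  array(as.numeric(k), dim = c(length(gx), length(gy), length(gz)))
}

# zero-padded FFT convolution of a binary array with a small kernel,
# returning the "same"-sized count of overlapping kernel voxels
fft_conv_count <- function(mask, kernel) {
  d <- dim(mask); kd <- dim(kernel)
  pd <- mapply(function(a, b) stats::nextn(a + b - 1L, c(2, 3, 5)), d, kd)
  pa <- array(0, pd); pk <- array(0, pd)
  pa[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask
  pk[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kernel
  cc <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) / prod(pd)
  off <- (kd - 1L) %/% 2L
  cc[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])]
}

dilate_mask <- function(mask, radius_mm, spacing) {
  if (radius_mm <= 0) return(mask)
  k <- ball_kernel(radius_mm, spacing)
  if (all(dim(k) == 1L)) return(mask)
  fft_conv_count(mask, k) > 0.5
}

erode_mask <- function(mask, radius_mm, spacing) {
  if (radius_mm <= 0) return(mask)
  k <- ball_kernel(radius_mm, spacing)
  if (all(dim(k) == 1L)) return(mask)
  fft_conv_count(mask, k) > sum(k) - 0.5
}

close_mask <- function(mask, radius_mm, spacing) {
  erode_mask(dilate_mask(mask, radius_mm, spacing), radius_mm, spacing)
}
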