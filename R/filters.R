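# Separable Gaussian filtering and noise fields.
#
# The blur operates in physical units: sigma is given in mm and converted to
# voxels per axis, so anisotropic grids (e.g. 1 x 1 x 4 mm axial stacks) are
# smoothed isotropically in space. Kernels are truncated at 3 sigma and
# renormalised at the array edges (no implicit zero padding).

blur_axis <- function(arr, axis, sigma_vox) {
  if (sigma_vox <= 1e-8) return(arr)
  d <- dim(arr)
  n <- d[axis]
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  off <- seq(-r, r)
  k <- exp(-0.5 * (off / sigma_vox)^2)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  out <- K %*% m
  a <- array(out, dim(a))
  aperm(a, order(perm))
}

gauss_blur <- function(arr, sigma_mm, spacing) {
  sigma_mm <- rep_len(sigma_mm, 3)
  for (ax in 1:3) arr <- blur_axis(arr, ax, sigma_mm[ax] / spacing[ax])
  arr
}

# Gaussian smoothing restricted to a mask (normalised convolution): values
# outside the mask do not leak in, and the result is defined wherever the
# blurred mask weight is positive.
gauss_blur_masked <- function(arr, mask, sigma_mm, spacing) {
  w <- gauss_blur(arr * mask, sigma_mm, spacing)
  m <- gauss_blur(mask * 1, sigma_mm, spacing)
  out <- arr
  inside <- mask > 0 & m > 1e-12
  out[inside] <- w[inside] / m[inside]
  out
}

# Smooth zero-mean unit-variance random field with correlation length
# `scale_mm` (used for tissue texture and the speckled fibroglandular
# pattern).
smooth_noise_field <- function(dims, spacing, scale_mm) {
  z <- array(stats::rnorm(prod(dims)), dims)
  z <- gauss_blur(z, scale_mm, spacing)
  (z - mean(z)) / stats::sd(z)
}

# Rician magnitude noise: Gaussian noise of sd `sigma` on two quadrature
# channels, the true signal on the real channel.
add_rician_noise <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  n1 <- array(stats::rnorm(length(arr), sd = sigma), dim(arr))
  n2 <- array(stats::rnorm(length(arr), sd = sigma), dim(arr))
  sqrt((arr + n1)^2 + n2^2)
}
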