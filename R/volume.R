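#' Create a 3-D image volume
#'
#' A lightweight container for a 3-D scalar grid: a numeric array together
#' with its voxel spacing and physical origin. It is the carrier for
#' T1-weighted volumes, diffusion-weighted signals, ADC maps, bias fields and
#' masks throughout the package.
#'
#' Arrays are indexed `[row, col, slice]`, 1-based. Rows run
#' anterior-to-posterior, columns left-to-right, slices craniocaudally.
#' Physical coordinates (mm) of the voxel centre at index `(i, j, k)` are
#' `origin + (c(i, j, k) - 1) * spacing`, in the same axis order.
#'
#' @param data A numeric 3-D array (a matrix is promoted to a single-slice
#'   volume).
#' @param spacing Voxel spacing in mm per axis, length 3, all positive. For
#'   slice-gapped acquisitions the slice spacing is thickness plus gap.
#' @param origin Physical position (mm) of the centre of voxel `(1, 1, 1)`.
#' @return An object of class `img_volume`.
#' @examples
#' v <- img_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 4))
#' dim(v)
#' voxel_volume(v)
#' @export
img_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "img_volume"
  )
}

#' @rdname img_volume
#' @param x An object.
#' @export
is_img_volume <- function(x) inherits(x, "img_volume")

#' @export
dim.img_volume <- function(x) dim(x$data)

#' @export
print.img_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<img_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf(
    "  origin (%.3g, %.3g, %.3g) mm; intensity range [%.4g, %.4g]\n",
    x$origin[1], x$origin[2], x$origin[3],
    suppressWarnings(min(x$data, na.rm = TRUE)),
    suppressWarnings(max(x$data, na.rm = TRUE))
  ))
  invisible(x)
}

#' @rdname img_volume
#' @param vol An `img_volume`.
#' @export
voxel_volume <- function(vol) {
  stopifnot(is_img_volume(vol))
  prod(vol$spacing)
}

# New volume on the same grid as `vol` but with different data.
vol_like <- function(vol, data) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  img_volume(data, spacing = vol$spacing, origin = vol$origin)
}

same_grid <- function(a, b, tol = 1e-8) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Voxel indices to physical coordinates
#'
#' @param vol An `img_volume`.
#' @param idx An n x 3 matrix of 1-based voxel indices (row, col, slice).
#' @return An n x 3 matrix of physical coordinates in mm.
#' @export
vox_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx, 2, c(1, 1, 1)), 2, vol$spacing, `*`) +
    matrix(vol$origin, nrow(idx), 3, byrow = TRUE)
}

#' Physical coordinates to (fractional) voxel indices
#'
#' @param vol An `img_volume`.
#' @param pts An n x 3 matrix of physical coordinates in mm.
#' @return An n x 3 matrix of 1-based fractional voxel indices.
#' @export
world_to_vox <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(sweep(pts, 2, vol$origin), 2, vol$spacing, `/`) + 1
}

# Grid of all voxel-centre physical coordinates, optionally strided.
grid_world_coords <- function(vol, stride = c(1L, 1L, 1L)) {
  d <- dim(vol$data)
  ii <- seq(1L, d[1], by = stride[1])
  jj <- seq(1L, d[2], by = stride[2])
  kk <- seq(1L, d[3], by = stride[3])
  idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  list(idx = idx, world = vox_to_world(vol, idx))
}

#' Sample a volume at physical points
#'
#' Interpolates voxel values at arbitrary physical coordinates. Points
#' outside the grid are flagged invalid and returned as `NA`, never
#' zero-filled.
#'
#' @param vol An `img_volume`.
#' @param pts An n x 3 matrix of physical coordinates (mm).
#' @param method `"linear"` (trilinear) for intensity images or
#'   `"nearest"` for label masks.
#' @return A list with `values` (length n, `NA` where invalid) and `valid`
#'   (logical length n).
#' @export
sample_volume <- function(vol, pts, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(vol$data)
  # fractional voxel indices, column-wise for speed
  v1 <- (pts[, 1] - vol$origin[1]) / vol$spacing[1] + 1
  v2 <- (pts[, 2] - vol$origin[2]) / vol$spacing[2] + 1
  v3 <- (pts[, 3] - vol$origin[3]) / vol$spacing[3] + 1
  n <- length(v1)
  g <- vol$data
  d1 <- d[1]; d12 <- d[1] * d[2]
  if (method == "nearest") {
    i1 <- round(v1); i2 <- round(v2); i3 <- round(v3)
    valid <- i1 >= 1 & i1 <= d[1] & i2 >= 1 & i2 <= d[2] &
      i3 >= 1 & i3 <= d[3]
    vals <- rep(NA_real_, n)
    if (any(valid)) {
      vals[valid] <- g[i1[valid] + d1 * (i2[valid] - 1) +
                         d12 * (i3[valid] - 1)]
    }
    return(list(values = vals, valid = valid))
  }
  # trilinear; points up to the far voxel centre (inclusive) are valid
  valid <- v1 >= 1 & v1 <= d[1] & v2 >= 1 & v2 <= d[2] &
    v3 >= 1 & v3 <= d[3]
  vals <- rep(NA_real_, n)
  if (any(valid)) {
    v1 <- v1[valid]; v2 <- v2[valid]; v3 <- v3[valid]
    f1 <- pmin(floor(v1), d[1] - 1); f2 <- pmin(floor(v2), d[2] - 1)
    f3 <- pmin(floor(v3), d[3] - 1)
    w1 <- v1 - f1; w2 <- v2 - f2; w3 <- v3 - f3
    base <- f1 + d1 * (f2 - 1) + d12 * (f3 - 1)
    c00 <- g[base] * (1 - w1) + g[base + 1] * w1
    c10 <- g[base + d1] * (1 - w1) + g[base + d1 + 1] * w1
    c01 <- g[base + d12] * (1 - w1) + g[base + d12 + 1] * w1
    c11 <- g[base + d1 + d12] * (1 - w1) + g[base + d1 + d12 + 1] * w1
    c0 <- c00 * (1 - w2) + c10 * w2
    c1 <- c01 * (1 - w2) + c11 * w2
    vals[valid] <- c0 * (1 - w3) + c1 * w3
  }
  list(values = vals, valid = valid)
}
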