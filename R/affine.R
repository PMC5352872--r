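#' Affine transforms in physical coordinates
#'
#' Transforms are 3 x 4 matrices `[R | t]` acting on physical (mm) points in
#' the package's axis order (row/anterior-posterior, col/left-right, slice).
#' The convention throughout is fixed-to-moving: registration returns the
#' transform that maps a point of the fixed image into the moving image, so
#' that resampling pulls moving-image intensities onto the fixed grid.
#'
#' @param linear A 3 x 3 invertible matrix.
#' @param translation A length-3 translation in mm.
#' @return A 3 x 4 matrix of class `affine3`.
#' @examples
#' a <- affine_identity()
#' b <- affine_rigid(translation = c(0, 3, 0), angles_deg = c(2, 0, 0))
#' affine_compose(b, affine_invert(b)) # ~ identity
#' @export
affine3 <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  if (abs(det(linear)) < 1e-12) {
    stop("affine3: linear part is not invertible")
  }
  structure(cbind(linear, as.numeric(translation)), class = "affine3")
}

#' @rdname affine3
#' @export
affine_identity <- function() affine3()

#' @rdname affine3
#' @param angles_deg Rotation angles in degrees about the slice, row and col
#'   axes (applied in that order).
#' @param scale Per-axis scale factors.
#' @export
affine_rigid <- function(translation = c(0, 0, 0), angles_deg = c(0, 0, 0),
                         scale = c(1, 1, 1)) {
  th <- angles_deg * pi / 180
  # rotation about slice axis mixes (row, col); about row axis mixes
  # (col, slice); about col axis mixes (row, slice)
  r1 <- rbind(
    c(cos(th[1]), -sin(th[1]), 0),
    c(sin(th[1]), cos(th[1]), 0),
    c(0, 0, 1)
  )
  r2 <- rbind(
    c(1, 0, 0),
    c(0, cos(th[2]), -sin(th[2])),
    c(0, sin(th[2]), cos(th[2]))
  )
  r3 <- rbind(
    c(cos(th[3]), 0, -sin(th[3])),
    c(0, 1, 0),
    c(sin(th[3]), 0, cos(th[3]))
  )
  affine3(r1 %*% r2 %*% r3 %*% diag(as.numeric(scale)), translation)
}

#' @rdname affine3
#' @param a,b `affine3` transforms; the composition applies `b` first.
#' @export
affine_compose <- function(a, b) {
  affine3(a[, 1:3] %*% b[, 1:3], a[, 1:3] %*% b[, 4] + a[, 4])
}

#' @rdname affine3
#' @export
affine_invert <- function(a) {
  ri <- solve(a[, 1:3])
  affine3(ri, -ri %*% a[, 4])
}

#' @rdname affine3
#' @param pts An n x 3 matrix of physical points (mm).
#' @export
affine_apply <- function(a, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  pts %*% t(a[, 1:3]) + matrix(a[, 4], nrow(pts), 3, byrow = TRUE)
}

# Transform about a physical centre point: x -> R (x - c) + c + t.
affine_about <- function(centre, translation, angles_deg, scale = c(1, 1, 1)) {
  r <- affine_rigid(c(0, 0, 0), angles_deg, scale)
  t_full <- centre - r[, 1:3] %*% centre + translation
  affine3(r[, 1:3], t_full)
}
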