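#' Normalized mutual information between two volumes
#'
#' Computes `NMI = (H(A) + H(B)) / H(A, B)` from the joint intensity
#' histogram of two same-grid volumes, using `n_bins` equal-width bins per
#' image over its finite range. The measure lies in [1, 2]: 1 for
#' independent images, 2 for a bijective intensity relationship. A
#' constant image has zero marginal entropy; the independence limit 1 is
#' returned with a warning.
#'
#' @param a,b [img_volume()]s on the same grid (voxels that are `NA` in
#'   either are ignored).
#' @param n_bins Number of histogram bins per image (>= 2, default 32).
#' @return The NMI value.
#' @export
nmi <- function(a, b, n_bins = 32) {
  stopifnot(is_img_volume(a), is_img_volume(b), n_bins >= 2)
  if (!identical(dim(a$data), dim(b$data))) {
    stop("nmi: volumes are on different grids")
  }
  nmi_values(as.vector(a$data), as.vector(b$data), n_bins)
}

nmi_values <- function(x, y, n_bins, warn_constant = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop("nmi: no jointly finite voxels")
  bin_of <- function(v) {
    r <- range(v)
    if (diff(r) <= 0) return(NULL)
    pmin(pmax(floor((v - r[1]) / diff(r) * n_bins) + 1L, 1L), n_bins)
  }
  ia <- bin_of(x); ib <- bin_of(y)
  if (is.null(ia) || is.null(ib)) {
    if (warn_constant) warning("nmi: constant image; returning independence limit 1")
    return(1)
  }
  joint <- tabulate(ia + n_bins * (ib - 1L), n_bins * n_bins)
  p <- joint / sum(joint)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  pj <- matrix(p, n_bins, n_bins)
  ha <- ent(rowSums(pj)); hb <- ent(colSums(pj)); hab <- ent(p)
  if (hab <= 0) return(2) # single occupied joint bin on both axes
  (ha + hb) / hab
}

# NMI objective for a candidate fixed->moving transform, evaluated at a
# fixed set of sample points (physical coords) with known fixed values.
nmi_at <- function(theta, centre, fixed_pts, fixed_vals, moving, n_bins,
                   with_scale) {
  tr <- theta_to_affine(theta, centre, with_scale)
  sm <- sample_volume(moving, affine_apply(tr, fixed_pts), "linear")
  ok <- sm$valid
  if (mean(ok) < 0.05) return(NA_real_)
  suppressWarnings(nmi_values(fixed_vals[ok], sm$values[ok], n_bins,
                              warn_constant = FALSE))
}

theta_to_affine <- function(theta, centre, with_scale) {
  scale <- if (with_scale) exp(theta[7:9]) else c(1, 1, 1)
  affine_about(centre, theta[1:3], theta[4:6], scale)
}

#' Affine coregistration by normalized mutual information
#'
#' Finds the affine transform (fixed-to-moving convention) that maximises
#' the normalized mutual information between the fixed image and the
#' moving image resampled onto it. Optimisation is multi-resolution
#' Nelder-Mead: a rigid stage on a strided sample of fixed voxels, then a
#' denser stage, then an optional scale polish (9 parameters). The
#' procedure is deterministic: initialisation is the intensity
#' centre-of-mass offset, and no random numbers are used.
#'
#' @param moving,fixed [img_volume()]s with overlapping fields of view.
#' @param n_bins Histogram bins for the metric (default 32).
#' @param with_scale Add per-axis log-scale parameters in the final stage.
#' @param max_iter Nelder-Mead iteration budget per stage.
#' @return A list of class `registration` with `transform` (an
#'   [affine3()]), `nmi` (final metric), `nmi_initial`, and `converged`.
#' @export
register_affine <- function(moving, fixed, n_bins = 32, with_scale = TRUE,
                            max_iter = 200) {
  stopifnot(is_img_volume(moving), is_img_volume(fixed))
  d <- dim(fixed$data)
  centre <- vox_to_world(fixed, matrix((d + 1) / 2, 1))[1, ]

  # sample points: fixed voxels inside the bounding box of signal
  fin <- is.finite(fixed$data)
  thr <- stats::quantile(fixed$data[fin], 0.5, names = FALSE)
  sig <- which(fin & fixed$data > thr, arr.ind = TRUE)
  if (nrow(sig) < 100) stop("register_affine: fixed image has no usable signal")
  lo <- pmax(apply(sig, 2, min) - 4, 1)
  hi <- pmin(apply(sig, 2, max) + 4, d)
  sample_pts <- function(stride) {
    idx <- as.matrix(expand.grid(
      i = seq(lo[1], hi[1], by = stride[1]),
      j = seq(lo[2], hi[2], by = stride[2]),
      k = seq(lo[3], hi[3], by = stride[3])
    ))
    list(pts = vox_to_world(fixed, idx), vals = fixed$data[idx])
  }

  # centre-of-mass initialisation for the translation
  com <- function(vol) {
    fin <- is.finite(vol$data)
    w <- pmax(vol$data - stats::quantile(vol$data[fin], 0.5, names = FALSE), 0)
    w[!fin] <- 0
    idx <- which(w > 0, arr.ind = TRUE)
    ww <- w[w > 0]
    vox_to_world(vol, matrix(colSums(idx * ww) / sum(ww), 1))[1, ]
  }
  t0 <- com(moving) - com(fixed)

  stages <- list(
    list(stride = c(3, 3, 2), scale = FALSE, iter = max_iter),
    list(stride = c(2, 2, 1), scale = with_scale, iter = max_iter %/% 3)
  )
  stages <- Filter(Negate(is.null), stages)

  theta <- c(t0, 0, 0, 0)
  sp0 <- sample_pts(c(1, 1, 1))
  nmi_init <- nmi_at(c(0, 0, 0, 0, 0, 0), centre, sp0$pts, sp0$vals,
                     moving, n_bins, FALSE)
  best <- list(theta = theta, scale = FALSE)
  for (st in stages) {
    sp <- sample_pts(st$stride)
    th <- best$theta
    if (st$scale && length(th) == 6) th <- c(th, 0, 0, 0)
    obj <- function(p) {
      v <- nmi_at(p, centre, sp$pts, sp$vals, moving, n_bins, st$scale)
      if (is.na(v)) 10 else -v
    }
    step <- c(rep(2, 3), rep(1, 3), rep(0.05, 3))[seq_along(th)]
    opt <- stats::optim(th, obj, method = "Nelder-Mead",
                        control = list(maxit = st$iter,
                                       parscale = step, reltol = 1e-7))
    best <- list(theta = opt$par, scale = st$scale)
  }
  tr <- theta_to_affine(best$theta, centre, best$scale)
  nmi_final <- nmi_at(best$theta, centre, sp0$pts, sp0$vals, moving, n_bins,
                      best$scale)
  if (is.na(nmi_final) || is.na(nmi_init)) {
    stop("register_affine: insufficient overlap between the volumes")
  }
  if (nmi_final < nmi_init) {
    # never return a transform worse than the identity-start metric
    tr <- theta_to_affine(c(t0, 0, 0, 0), centre, FALSE)
    nmi_final <- nmi_at(c(t0, 0, 0, 0), centre, sp0$pts, sp0$vals,
                        moving, n_bins, FALSE)
    if (is.na(nmi_final) || nmi_final < nmi_init) {
      tr <- affine_identity()
      nmi_final <- nmi_init
    }
  }
  structure(
    list(transform = tr, nmi = nmi_final, nmi_initial = nmi_init,
         converged = TRUE),
    class = "registration"
  )
}

#' @export
print.registration <- function(x, ...) {
  cat(sprintf("<registration> NMI %.4f (initial %.4f)\n", x$nmi, x$nmi_initial))
  cat("fixed -> moving transform:\n")
  print(round(unclass(x$transform), 4))
  invisible(x)
}

#' Resample a volume through an affine transform onto a target grid
#'
#' Pulls moving-image values onto the target grid: each target voxel
#' centre is mapped through `transform` (fixed-to-moving) and the moving
#' image is interpolated there. Intensities use trilinear interpolation;
#' masks must use nearest-neighbour so the output stays label-valued.
#' Voxels mapping outside the moving field of view are `NA` (invalid),
#' never zero-filled.
#'
#' @param volume The moving [img_volume()].
#' @param transform An [affine3()] (or a `registration` object).
#' @param target An [img_volume()] defining the output grid.
#' @param method `"linear"` or `"nearest"`.
#' @return An [img_volume()] on the target grid.
#' @export
resample_to <- function(volume, transform, target,
                        method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (inherits(transform, "registration")) transform <- transform$transform
  stopifnot(is_img_volume(volume), is_img_volume(target),
            inherits(transform, "affine3"))
  g <- grid_world_coords(target)
  sm <- sample_volume(volume, affine_apply(transform, g$world), method)
  out <- array(sm$values, dim(target$data))
  vol_like(target, out)
}
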