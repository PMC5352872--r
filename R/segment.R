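#' Segmentation configuration
#'
#' @param k_clusters Number of k-means intensity clusters (default 6).
#' @param n_ft_clusters How many of the lowest-centroid clusters form the
#'   fibroglandular class (default 3; presumes non-fat-suppressed T1
#'   contrast where fibroglandular tissue is dark and fat bright).
#' @param landmark_mode `"auto"` to detect chest landmarks, `"provided"` to
#'   require them from the caller.
#' @param propagation Propagate the middle-slice mask through the stack.
#' @param stop_frac Stop propagation when a slice's breast area falls below
#'   this fraction of the middle-slice area.
#' @param seed Seed controlling k-means initialisation reproducibility.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(k_clusters = 6L, n_ft_clusters = 3L,
                                landmark_mode = c("auto", "provided"),
                                propagation = TRUE, stop_frac = 0.02,
                                seed = 1L) {
  landmark_mode <- match.arg(landmark_mode)
  stopifnot(n_ft_clusters >= 1, n_ft_clusters < k_clusters,
            stop_frac >= 0, stop_frac < 1)
  structure(
    list(k_clusters = as.integer(k_clusters),
         n_ft_clusters = as.integer(n_ft_clusters),
         landmark_mode = landmark_mode, propagation = propagation,
         stop_frac = stop_frac, seed = as.integer(seed)),
    class = "segmentation_config"
  )
}

#' Exact one-dimensional k-means
#'
#' Globally optimal k-means clustering of scalar values by dynamic
#' programming over a fine binning of the data (sum-of-squares objective).
#' Unlike Lloyd iterations from a particular initialisation, the result is
#' deterministic and free of local-optimum artefacts, which matters for
#' the tissue split: near allocation transitions, Lloyd fixed points from
#' quantile seeds can misplace the class boundary by several intensity
#' clusters.
#'
#' @param x Numeric values to cluster.
#' @param k Number of clusters (1 <= k <= number of distinct values).
#' @param nbins Binning resolution of the DP (default 512; exact when the
#'   data have fewer distinct values).
#' @return A list with `centers` (sorted cluster means), `boundaries`
#'   (k - 1 cut points between adjacent clusters) and `cluster` (1-based
#'   cluster index per input value, in centre-sorted order).
#' @export
kmeans_1d <- function(x, k, nbins = 512) {
  stopifnot(k >= 1)
  ux <- unique(x)
  if (k > length(ux)) stop("kmeans_1d: k exceeds the number of distinct values")
  if (length(ux) <= nbins) {
    mids <- sort(ux)
    cnt <- tabulate(match(x, mids), length(mids))
  } else {
    br <- seq(min(x), max(x), length.out = nbins + 1)
    idx <- findInterval(x, br, rightmost.closed = TRUE)
    cnt <- tabulate(idx, nbins)
    mids <- (br[-1] + br[-length(br)]) / 2
    keep <- cnt > 0
    mids <- mids[keep]
    cnt <- cnt[keep]
  }
  B <- length(mids)
  if (k == 1) {
    ctr <- sum(cnt * mids) / sum(cnt)
    return(list(centers = ctr, boundaries = numeric(0),
                cluster = rep(1L, length(x))))
  }
  cw <- cumsum(cnt)
  cwx <- cumsum(cnt * mids)
  cwx2 <- cumsum(cnt * mids^2)
  cw0 <- c(0, cw); cwx0 <- c(0, cwx); cwx20 <- c(0, cwx2)
  seg_cost <- function(i, j) { # vectorised over i, fixed j
    w <- cw[j] - cw0[i]
    sx <- cwx[j] - cwx0[i]
    sx2 <- cwx2[j] - cwx20[i]
    pmax(sx2 - sx^2 / pmax(w, 1), 0)
  }
  D <- matrix(Inf, k, B)
  A <- matrix(0L, k, B)
  D[1, ] <- cwx2 - cwx^2 / cw
  for (m in 2:k) {
    for (j in m:B) {
      i <- m:j
      v <- D[m - 1, i - 1] + seg_cost(i, j)
      b <- which.min(v)
      D[m, j] <- v[b]
      A[m, j] <- i[b]
    }
  }
  cuts <- integer(k - 1) # first bin index of clusters 2..k
  j <- B
  for (m in k:2) {
    cuts[m - 1] <- A[m, j]
    j <- A[m, j] - 1L
  }
  lo <- c(1L, cuts)
  hi <- c(cuts - 1L, B)
  centers <- vapply(seq_len(k), function(m) {
    w <- cw[hi[m]] - cw0[lo[m]]
    (cwx[hi[m]] - cwx0[lo[m]]) / w
  }, numeric(1))
  boundaries <- (mids[cuts - 1L] + mids[cuts]) / 2
  cl <- findInterval(x, boundaries) + 1L
  list(centers = centers, boundaries = boundaries, cluster = cl)
}

# Two-class threshold on a vector of intensities; returns the boundary
# between the classes and a between/within separation ratio used to
# reject structureless (noise-only) inputs.
fg_threshold <- function(vals) {
  vals <- vals[is.finite(vals)]
  if (diff(range(vals)) < 1e-12) return(list(threshold = Inf, separation = 0))
  km <- kmeans_1d(vals, 2)
  within_sd <- sqrt(max(stats::var(vals - km$centers[km$cluster]), 1e-12))
  list(threshold = km$boundaries[1],
       separation = (km$centers[2] - km$centers[1]) / within_sd)
}

middle_slice_index <- function(vol) as.integer(round((dim(vol$data)[3] + 1) / 2))

#' Detect chest landmarks on the middle slice
#'
#' Locates the three body landmarks used for the V-shape chest cut: the
#' thoracic spine (posterior midline structure) and the two lateral tips of
#' the pectoral/chest-wall band. Detection is intensity-based: a two-class
#' threshold separates body from air, the spine is the centroid of the
#' posterior-most foreground in a midline strip, and the pectoral points
#' are the anterior-most foreground voxels at the extreme lateral columns.
#'
#' @param t1 A T1-weighted [img_volume()].
#' @param slice Slice to analyse (default: middle slice).
#' @return A list of class `chest_landmarks` with `spine`, `pect_left`,
#'   `pect_right` (each `c(row, col)`) and `slice`.
#' @export
detect_landmarks <- function(t1, slice = middle_slice_index(t1)) {
  stopifnot(is_img_volume(t1))
  sl <- t1$data[, , slice]
  th <- fg_threshold(as.vector(sl))
  if (th$separation < 3) {
    stop("detect_landmarks: no coherent chest structure found ",
         "(foreground/background separation too weak); ",
         "provide landmarks manually")
  }
  fg <- sl > th$threshold
  frac <- mean(fg)
  if (frac < 0.02 || frac > 0.8) {
    stop("detect_landmarks: implausible foreground fraction ",
         sprintf("(%.1f%%); provide landmarks manually", 100 * frac))
  }
  nr <- nrow(sl); nc <- ncol(sl)
  cx <- round((nc + 1) / 2)
  strip_cols <- max(1, cx - 2):min(nc, cx + 2)
  strip <- which(fg[, strip_cols, drop = FALSE], arr.ind = TRUE)
  if (nrow(strip) == 0) {
    stop("detect_landmarks: no posterior midline structure; ",
         "provide landmarks manually")
  }
  max_row <- max(strip[, 1])
  post <- strip[strip[, 1] >= max_row - 6, , drop = FALSE]
  spine <- c(mean(post[, 1]), mean(strip_cols[post[, 2]]))

  fg_idx <- which(fg, arr.ind = TRUE)
  col_lo <- min(fg_idx[, 2]); col_hi <- max(fg_idx[, 2])
  pl <- c(min(fg_idx[fg_idx[, 2] == col_lo, 1]), col_lo)
  pr <- c(min(fg_idx[fg_idx[, 2] == col_hi, 1]), col_hi)
  if (spine[2] - pl[2] < 5 || pr[2] - spine[2] < 5) {
    stop("detect_landmarks: pectoral tips not lateral to the spine; ",
         "provide landmarks manually")
  }
  if (spine[1] - pl[1] < 3 || spine[1] - pr[1] < 3) {
    stop("detect_landmarks: spine not posterior to the pectoral tips; ",
         "provide landmarks manually")
  }
  structure(
    list(spine = spine, pect_left = pl, pect_right = pr,
         slice = as.integer(slice)),
    class = "chest_landmarks"
  )
}

#' @rdname detect_landmarks
#' @param spine,pect_left,pect_right `c(row, col)` coordinates on `slice`.
#' @export
chest_landmarks <- function(spine, pect_left, pect_right, slice) {
  structure(list(spine = as.numeric(spine), pect_left = as.numeric(pect_left),
                 pect_right = as.numeric(pect_right),
                 slice = as.integer(slice)),
            class = "chest_landmarks")
}

# Posterior boundary row per column: the lower envelope of the two infinite
# lines spine->pectoral, linearly extended beyond the pectoral tips.
v_boundary_rows <- function(lm, nc) {
  s <- lm$spine; pl <- lm$pect_left; pr <- lm$pect_right
  if (s[1] - pl[1] < 1e-9 || s[1] - pr[1] < 1e-9 ||
      abs(s[2] - pl[2]) < 1e-9 || abs(s[2] - pr[2]) < 1e-9) {
    stop("v_boundary_rows: degenerate landmark geometry (collinear or ",
         "coincident landmarks)")
  }
  cols <- seq_len(nc)
  line_l <- pl[1] + (s[1] - pl[1]) * (cols - pl[2]) / (s[2] - pl[2])
  line_r <- pr[1] + (s[1] - pr[1]) * (cols - pr[2]) / (s[2] - pr[2])
  pmin(line_l, line_r)
}

largest_component <- function(mask2d) {
  lab <- EBImage::bwlabel(mask2d * 1)
  if (max(lab) == 0) return(mask2d & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# Fill interior holes of a 2-D mask: dark fibroglandular tissue falls below
# the body/air threshold, so the thresholded breast is an annulus of fat
# whose holes are tissue, not air.
fill_holes <- function(mask2d) {
  EBImage::fillHull(mask2d * 1) > 0
}

#' Breast mask on the middle slice from the V-shape chest cut
#'
#' Keeps foreground (body, by two-class intensity threshold) strictly
#' anterior to the two line segments from the spine to the pectoral tips,
#' then selects the largest connected component as the breast.
#'
#' @param t1 A T1-weighted [img_volume()].
#' @param lm [chest_landmarks()].
#' @return An [img_volume()] 0/1 mask, nonzero only on the landmark slice;
#'   attribute `middle_slice` records the slice index.
#' @export
vshape_breast_mask <- function(t1, lm) {
  stopifnot(is_img_volume(t1), inherits(lm, "chest_landmarks"))
  sl <- t1$data[, , lm$slice]
  th <- fg_threshold(as.vector(sl))
  fg <- sl > th$threshold
  ybound <- v_boundary_rows(lm, ncol(sl))
  anterior <- outer(seq_len(nrow(sl)), ybound, `<`)
  cand <- fg & anterior
  if (!any(cand)) stop("vshape_breast_mask: no foreground anterior to the V cut")
  breast <- fill_holes(largest_component(cand)) & anterior
  out <- array(0L, dim(t1$data))
  out[, , lm$slice] <- as.integer(breast)
  res <- vol_like(t1, out)
  attr(res, "middle_slice") <- lm$slice
  attr(res, "threshold") <- th$threshold
  attr(res, "v_boundary") <- ybound
  res
}

#' Propagate the middle-slice breast mask through the stack
#'
#' Works outward from the middle slice: each slice's candidate foreground
#' (same intensity threshold and V boundary as the middle slice) is
#' labelled, and components overlapping the neighbouring slice's accepted
#' mask are kept. Propagation stops in each direction when the slice area
#' falls below `stop_frac` of the middle-slice area.
#'
#' @param t1 A T1-weighted [img_volume()].
#' @param middle_mask Output of [vshape_breast_mask()].
#' @param stop_frac Area-stopping fraction (default 0.02).
#' @return A 3-D [img_volume()] 0/1 breast mask.
#' @export
propagate_mask <- function(t1, middle_mask, stop_frac = 0.02) {
  stopifnot(is_img_volume(t1), is_img_volume(middle_mask))
  k0 <- attr(middle_mask, "middle_slice")
  if (is.null(k0)) k0 <- middle_slice_index(t1)
  thr <- attr(middle_mask, "threshold")
  ybound <- attr(middle_mask, "v_boundary")
  if (is.null(thr)) thr <- fg_threshold(as.vector(t1$data[, , k0]))$threshold
  d <- dim(t1$data)
  if (is.null(ybound)) ybound <- rep(d[1] + 1, d[2])
  anterior <- outer(seq_len(d[1]), ybound, `<`)
  out <- array(0L, d)
  mid <- middle_mask$data[, , k0] > 0
  if (!any(mid)) stop("propagate_mask: empty middle-slice mask")
  out[, , k0] <- as.integer(mid)
  min_area <- stop_frac * sum(mid)
  for (dir in c(1L, -1L)) {
    prev <- mid
    k <- k0 + dir
    while (k >= 1 && k <= d[3]) {
      cand <- (t1$data[, , k] > thr) & anterior
      if (!any(cand)) break
      lab <- EBImage::bwlabel(cand * 1)
      keep_labs <- setdiff(unique(lab[prev & lab > 0]), 0)
      if (length(keep_labs) == 0) break
      cur <- fill_holes(array(lab %in% keep_labs, dim(cand))) & anterior
      if (sum(cur) < min_area) break
      out[, , k] <- as.integer(cur)
      prev <- cur
      k <- k + dir
    }
  }
  vol_like(t1, out)
}

#' Split breast voxels into fibroglandular and fatty tissue by k-means
#'
#' One-dimensional k-means on the bias-corrected in-mask intensities with
#' `k_clusters` classes (default 6), centroid-sorted; the union of the
#' `n_ft_clusters` lowest-centroid clusters is the fibroglandular class
#' (dark on non-fat-suppressed T1), the rest is fat. The clustering is
#' solved to global optimality with [kmeans_1d()], so the split is
#' deterministic and independent of initialisation. If the mask holds
#' fewer distinct intensities than `k_clusters`, `k` is reduced (and
#' `n_ft_clusters` rescaled) with a warning; a constant image yields an
#' empty fibroglandular mask and status `"degenerate"`.
#'
#' @param t1_corrected Bias-corrected T1 [img_volume()].
#' @param breast_mask 0/1 [img_volume()] of the breast.
#' @param cfg A [segmentation_config()].
#' @return A list with `ft_mask`, `fat_mask` (0/1 [img_volume()]s),
#'   `centers` (sorted centroids), `k_used`, `threshold` (intensity
#'   boundary between the classes) and `status`.
#' @export
kmeans_tissue_split <- function(t1_corrected, breast_mask,
                                cfg = segmentation_config()) {
  stopifnot(is_img_volume(t1_corrected), is_img_volume(breast_mask))
  inmask <- breast_mask$data > 0
  if (!any(inmask)) stop("kmeans_tissue_split: empty breast mask")
  vals <- t1_corrected$data[inmask]
  uq <- unique(vals)
  k <- cfg$k_clusters
  n_ft <- cfg$n_ft_clusters
  status <- "ok"
  if (length(uq) < 2) {
    warning("kmeans_tissue_split: constant intensities in mask; ",
            "fibroglandular mask is empty")
    empty <- vol_like(t1_corrected, array(0L, dim(t1_corrected$data)))
    fat <- vol_like(t1_corrected, array(as.integer(inmask), dim(t1_corrected$data)))
    return(list(ft_mask = empty, fat_mask = fat, centers = mean(vals),
                k_used = 1L, threshold = -Inf, status = "degenerate"))
  }
  if (length(uq) < k) {
    k <- length(uq)
    n_ft <- max(1L, min(k - 1L, as.integer(round(cfg$n_ft_clusters * k /
                                                   cfg$k_clusters))))
    warning(sprintf("kmeans_tissue_split: only %d distinct intensities; k reduced to %d", k, k))
    status <- "reduced_k"
  }
  km <- kmeans_1d(vals, k)
  is_ft <- km$cluster <= n_ft
  ft <- array(0L, dim(t1_corrected$data))
  fat <- array(0L, dim(t1_corrected$data))
  ft[inmask] <- as.integer(is_ft)
  fat[inmask] <- as.integer(!is_ft)
  ctr_sorted <- km$centers
  thr <- if (n_ft < k) km$boundaries[n_ft] else Inf
  list(ft_mask = vol_like(t1_corrected, ft),
       fat_mask = vol_like(t1_corrected, fat),
       centers = ctr_sorted, k_used = as.integer(k),
       threshold = thr, status = status)
}

#' Percent breast density
#'
#' Percent density is the fibroglandular tissue volume over the breast
#' volume times 100; volumes are voxel counts times the voxel volume.
#'
#' @param ft_mask,breast_mask 0/1 [img_volume()]s on the same grid, with
#'   the fibroglandular mask contained in the breast mask.
#' @return A one-row tibble: `pd`, `breast_volume_cm3`, `ft_volume_cm3`,
#'   `n_breast`, `n_ft`.
#' @export
percent_density <- function(ft_mask, breast_mask) {
  stopifnot(is_img_volume(ft_mask), is_img_volume(breast_mask))
  if (!same_grid(ft_mask, breast_mask)) {
    stop("percent_density: masks on different grids")
  }
  nb <- sum(breast_mask$data > 0)
  if (nb == 0) stop("percent_density: empty breast mask")
  if (any(ft_mask$data > 0 & breast_mask$data == 0)) {
    stop("percent_density: fibroglandular mask extends outside the breast mask")
  }
  nf <- sum(ft_mask$data > 0)
  vv <- voxel_volume(breast_mask) / 1000 # mm^3 -> cm^3
  tibble::tibble(
    pd = 100 * nf / nb,
    breast_volume_cm3 = nb * vv,
    ft_volume_cm3 = nf * vv,
    n_breast = nb, n_ft = nf
  )
}

#' Full breast segmentation driver
#'
#' Landmarks, V-shape cut, slice propagation and (optionally supplied)
#' bias-corrected k-means tissue split in one call.
#'
#' @param t1 Raw T1-weighted [img_volume()] (used for the geometric steps).
#' @param t1_corrected Bias-corrected T1 (defaults to `t1`).
#' @param cfg A [segmentation_config()].
#' @param landmarks Optional [chest_landmarks()] (required when
#'   `cfg$landmark_mode == "provided"`).
#' @return A list with `breast_mask`, `ft_mask`, `fat_mask`, `landmarks`,
#'   `split` (the [kmeans_tissue_split()] result) and `density` (the
#'   [percent_density()] tibble).
#' @export
segment_breast <- function(t1, t1_corrected = t1,
                           cfg = segmentation_config(), landmarks = NULL) {
  if (is.null(landmarks)) {
    if (cfg$landmark_mode == "provided") {
      stop("segment_breast: cfg requires provided landmarks")
    }
    landmarks <- detect_landmarks(t1)
  }
  mid <- vshape_breast_mask(t1, landmarks)
  breast <- if (cfg$propagation) {
    propagate_mask(t1, mid, cfg$stop_frac)
  } else {
    mid
  }
  split <- kmeans_tissue_split(t1_corrected, breast, cfg)
  dens <- percent_density(split$ft_mask, breast)
  list(breast_mask = breast, ft_mask = split$ft_mask,
       fat_mask = split$fat_mask, landmarks = landmarks,
       split = split, density = dens)
}
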