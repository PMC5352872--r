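#' ADC analysis configuration
#'
#' Validity limits, histogram layout and small-ROI constraints for ADC
#' measurement. ADC values below `lower_valid` are treated as noise and
#' values above `upper_valid` as free water; both bounds are inclusive
#' (only strictly "below"/"above" values are excluded). The histogram has
#' `n_bins` bins whose centres span `[hist_lo, hist_hi]` uniformly
#' (`bin_mode = "centers"`, the default, giving 100-wide bins centred at
#' 100, 200, ..., 3200); `bin_mode = "edges"` instead places `n_bins`
#' equal bins between the limits (width (3200 - 100) / 32).
#'
#' @param lower_valid,upper_valid Validity limits, 1e-6 mm^2/s.
#' @param n_bins Number of histogram bins.
#' @param hist_lo,hist_hi Histogram limits, 1e-6 mm^2/s.
#' @param bin_mode `"centers"` or `"edges"` (see above).
#' @param roi_area_min,roi_area_max Small-ROI area limits in mm^2
#'   (defaults reproduce the 10.7-66.1 mm^2 range of manually placed
#'   ROIs).
#' @param homogeneity_cv_max Maximum coefficient of variation for a small
#'   ROI to count as homogeneous fibroglandular tissue.
#' @return A list of class `adc_config`.
#' @export
adc_config <- function(lower_valid = 100, upper_valid = 3200,
                       n_bins = 32, hist_lo = 100, hist_hi = 3200,
                       bin_mode = c("centers", "edges"),
                       roi_area_min = 10.7, roi_area_max = 66.1,
                       homogeneity_cv_max = 0.15) {
  bin_mode <- match.arg(bin_mode)
  stopifnot(lower_valid < upper_valid, n_bins >= 2,
            hist_lo >= lower_valid, hist_hi <= upper_valid,
            hist_lo < hist_hi,
            roi_area_min < roi_area_max, roi_area_min > 0,
            homogeneity_cv_max > 0)
  structure(
    list(lower_valid = lower_valid, upper_valid = upper_valid,
         n_bins = as.integer(n_bins), hist_lo = hist_lo, hist_hi = hist_hi,
         bin_mode = bin_mode, roi_area_min = roi_area_min,
         roi_area_max = roi_area_max,
         homogeneity_cv_max = homogeneity_cv_max),
    class = "adc_config"
  )
}

#' Histogram bin edges for an ADC configuration
#'
#' @param cfg An [adc_config()].
#' @return Numeric vector of `n_bins + 1` edges.
#' @export
adc_hist_breaks <- function(cfg) {
  if (cfg$bin_mode == "centers") {
    w <- (cfg$hist_hi - cfg$hist_lo) / (cfg$n_bins - 1)
    seq(cfg$hist_lo - w / 2, cfg$hist_hi + w / 2, by = w)
  } else {
    seq(cfg$hist_lo, cfg$hist_hi, length.out = cfg$n_bins + 1)
  }
}

adc_hist_counts <- function(values, cfg) {
  br <- adc_hist_breaks(cfg)
  idx <- findInterval(values, br, rightmost.closed = TRUE)
  tabulate(idx[idx >= 1 & idx <= cfg$n_bins], cfg$n_bins)
}

#' Keep ROI voxels with physiologically valid ADC
#'
#' Retains ROI voxels whose ADC lies within `[lower_valid, upper_valid]`
#' (bounds inclusive) and is finite (resampling validity: out-of-field
#' voxels are `NA` and never enter statistics).
#'
#' @param adc An ADC [img_volume()] (may contain `NA`).
#' @param roi A 0/1 [img_volume()] on the same grid.
#' @param cfg An [adc_config()].
#' @return A 0/1 [img_volume()]; a warning is raised if nothing survives.
#' @export
valid_mask <- function(adc, roi, cfg = adc_config()) {
  stopifnot(is_img_volume(adc), is_img_volume(roi))
  if (!same_grid(adc, roi)) stop("valid_mask: grids differ")
  keep <- roi$data > 0 & is.finite(adc$data) &
    adc$data >= cfg$lower_valid & adc$data <= cfg$upper_valid
  if (!any(keep) && any(roi$data > 0)) {
    warning("valid_mask: no valid ADC voxel in the ROI")
  }
  vol_like(adc, array(as.integer(keep), dim(adc$data)))
}

#' Central slice with the most fibroglandular tissue
#'
#' Argmax over slices of the fibroglandular voxel count; ties go to the
#' slice nearest the volume centre, then to the lowest index.
#'
#' @param ft_mask A 0/1 [img_volume()].
#' @return The slice index.
#' @export
select_central_slice <- function(ft_mask) {
  stopifnot(is_img_volume(ft_mask))
  counts <- apply(ft_mask$data > 0, 3, sum)
  if (all(counts == 0)) stop("select_central_slice: empty fibroglandular mask")
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    centre <- (length(counts) + 1) / 2
    best <- best[order(abs(best - centre), best)]
  }
  as.integer(best[1])
}

disc_offsets <- function(r_vox) {
  r <- ceiling(r_vox)
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= r_vox^2, , drop = FALSE]
}

#' Place a small homogeneous fibroglandular ROI
#'
#' Deterministic surrogate for a radiologist's manual ROI: the
#' fibroglandular mask on the chosen slice is eroded by one voxel to
#' exclude boundary partial volume, disc-shaped candidates with areas
#' inside `[roi_area_min, roi_area_max]` are slid over the remaining
#' tissue (largest feasible disc first), and the candidate minimising the
#' local ADC coefficient of variation is accepted if its CV does not
#' exceed `homogeneity_cv_max`. In fatty or fragmented breasts no disc
#' fits or none is homogeneous; that outcome is the status
#' `"not_measurable"`, not an error.
#'
#' @param adc_slice Matrix of ADC values on the slice (may contain `NA`).
#' @param ft_slice Logical/0-1 matrix of fibroglandular tissue on the
#'   slice.
#' @param cfg An [adc_config()].
#' @param spacing In-plane voxel spacing in mm, length 2.
#' @return A list with `status` (`"measured"` or `"not_measurable"`) and,
#'   when measured, `roi` (logical matrix), `mean`, `sd`, `cv`, `n`,
#'   `area_mm2`, `centre` (row, col) and `radius_mm`.
#' @export
place_small_roi <- function(adc_slice, ft_slice, cfg = adc_config(),
                            spacing = c(1, 1)) {
  stopifnot(is.matrix(adc_slice), all(dim(adc_slice) == dim(ft_slice)))
  pix_area <- prod(spacing[1:2])
  ft <- (ft_slice > 0) * 1
  if (!any(ft > 0)) return(list(status = "not_measurable"))
  eroded <- EBImage::erode(ft, EBImage::makeBrush(3, "box"))
  usable <- eroded > 0 & is.finite(adc_slice) &
    adc_slice >= cfg$lower_valid & adc_slice <= cfg$upper_valid
  if (!any(usable)) return(list(status = "not_measurable"))
  r_hi <- sqrt(cfg$roi_area_max / pi) / sqrt(pix_area)
  r_lo <- sqrt(cfg$roi_area_min / pi) / sqrt(pix_area)
  radii <- seq(r_hi, r_lo, by = -0.5)
  a <- adc_slice
  a[!usable] <- 0
  a2 <- a^2
  u <- usable * 1
  for (r in radii) {
    off <- disc_offsets(r)
    n_disc <- nrow(off)
    if (n_disc * pix_area < cfg$roi_area_min ||
        n_disc * pix_area > cfg$roi_area_max) next
    side <- 2 * ceiling(r) + 1
    ker <- matrix(0, side, side)
    ker[cbind(off$di + ceiling(r) + 1, off$dj + ceiling(r) + 1)] <- 1
    cnt <- EBImage::filter2(u, ker, boundary = 0)
    fits <- cnt > n_disc - 0.5
    if (!any(fits)) next
    s1 <- EBImage::filter2(a, ker, boundary = 0)
    s2 <- EBImage::filter2(a2, ker, boundary = 0)
    mu <- s1 / n_disc
    va <- pmax(s2 / n_disc - mu^2, 0)
    cv <- sqrt(va) / pmax(mu, 1e-9)
    cv[!fits] <- Inf
    best <- which.min(cv)
    if (cv[best] <= cfg$homogeneity_cv_max) {
      ctr <- arrayInd(best, dim(a))[1, ]
      roi <- matrix(FALSE, nrow(a), ncol(a))
      roi[cbind(ctr[1] + off$di, ctr[2] + off$dj)] <- TRUE
      vals <- adc_slice[roi]
      return(list(status = "measured", roi = roi,
                  mean = mean(vals), sd = stats::sd(vals),
                  cv = cv[best], n = n_disc,
                  area_mm2 = n_disc * pix_area,
                  centre = ctr, radius_mm = r * sqrt(pix_area)))
    }
  }
  list(status = "not_measurable")
}

#' Measure ADC with the four ROI strategies
#'
#' Computes the four ADC summaries of one subject from the coregistered
#' ADC map in T1 space: whole breast (`adc_wb`), fibroglandular tissue of
#' all slices (`adc_wf`), fibroglandular tissue on the central slice
#' (`adc_sf`), and a small homogeneous fibroglandular ROI on that slice
#' (`adc_sr`, possibly not measurable). All use validity filtering; the
#' 32-bin histogram is built from the whole-volume fibroglandular voxels.
#'
#' @param adc ADC [img_volume()] resampled into T1 space.
#' @param breast_mask,ft_mask 0/1 [img_volume()]s on the same grid.
#' @param cfg An [adc_config()].
#' @return A one-row tibble: means, SDs and voxel counts per strategy,
#'   `central_slice`, `sr_status`, `sr_cv`, `sr_area_mm2`, and a
#'   list-column `histogram` (integer counts of length `n_bins`).
#' @export
measure_four <- function(adc, breast_mask, ft_mask, cfg = adc_config()) {
  stopifnot(is_img_volume(adc))
  if (!same_grid(adc, breast_mask) || !same_grid(adc, ft_mask)) {
    stop("measure_four: grids differ")
  }
  vb <- valid_mask(adc, breast_mask, cfg)
  vf <- valid_mask(adc, ft_mask, cfg)
  stat3 <- function(vals) {
    if (length(vals) == 0) return(c(NA_real_, NA_real_, 0))
    c(mean(vals), stats::sd(vals), length(vals))
  }
  wb <- stat3(adc$data[vb$data > 0])
  wf_vals <- adc$data[vf$data > 0]
  wf <- stat3(wf_vals)
  k <- select_central_slice(vf)
  sf <- stat3(adc$data[, , k][vf$data[, , k] > 0])
  sr <- place_small_roi(adc$data[, , k], ft_mask$data[, , k] > 0, cfg,
                        adc$spacing[1:2])
  tibble::tibble(
    adc_wb = wb[1], adc_wb_sd = wb[2], n_wb = as.integer(wb[3]),
    adc_wf = wf[1], adc_wf_sd = wf[2], n_wf = as.integer(wf[3]),
    adc_sf = sf[1], adc_sf_sd = sf[2], n_sf = as.integer(sf[3]),
    adc_sr = if (sr$status == "measured") sr$mean else NA_real_,
    adc_sr_sd = if (sr$status == "measured") sr$sd else NA_real_,
    n_sr = if (sr$status == "measured") as.integer(sr$n) else 0L,
    central_slice = k,
    sr_status = sr$status,
    sr_cv = if (sr$status == "measured") sr$cv else NA_real_,
    sr_area_mm2 = if (sr$status == "measured") sr$area_mm2 else NA_real_,
    histogram = list(adc_hist_counts(wf_vals, cfg))
  )
}

#' Slice-by-slice fibroglandular ADC profile
#'
#' Mean ADC and valid fibroglandular voxel count per slice, in
#' craniocaudal order. Slices without valid fibroglandular voxels give
#' `NA` means.
#'
#' @param adc ADC [img_volume()] in T1 space.
#' @param ft_mask 0/1 [img_volume()] on the same grid.
#' @param cfg An [adc_config()].
#' @return A tibble with columns `slice`, `n_ft`, `mean_adc`.
#' @export
slice_profile <- function(adc, ft_mask, cfg = adc_config()) {
  stopifnot(is_img_volume(adc))
  vf <- valid_mask(adc, ft_mask, cfg)
  nz <- dim(adc$data)[3]
  purrr::map_dfr(seq_len(nz), function(k) {
    vals <- adc$data[, , k][vf$data[, , k] > 0]
    tibble::tibble(
      slice = k, n_ft = length(vals),
      mean_adc = if (length(vals)) mean(vals) else NA_real_
    )
  })
}
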