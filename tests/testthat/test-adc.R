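test_that("validity filtering keeps the inclusive bounds", {
  vals <- c(50, 100, 1000, 3200, 3300)
  adc <- img_volume(array(vals, c(5, 1, 1)))
  roi <- img_volume(array(1L, c(5, 1, 1)))
  vm <- valid_mask(adc, roi)
  expect_identical(as.vector(vm$data), c(0L, 1L, 1L, 1L, 0L))
  # all valid: the mask is the ROI itself
  adc2 <- img_volume(array(1500, c(5, 1, 1)))
  expect_identical(valid_mask(adc2, roi)$data, roi$data)
  # nothing valid: empty mask with a warning
  adc3 <- img_volume(array(10, c(5, 1, 1)))
  expect_warning(vm3 <- valid_mask(adc3, roi), "no valid")
  expect_equal(sum(vm3$data), 0)
})

test_that("central-slice choice is the argmax with centre-then-low ties", {
  mk <- function(counts) {
    d <- c(60, 10, length(counts))
    arr <- array(0L, d)
    for (k in seq_along(counts)) {
      if (counts[k] > 0) arr[seq_len(counts[k]), 1, k] <- 1L
    }
    img_volume(arr)
  }
  expect_equal(select_central_slice(mk(c(0, 10, 50, 30))), 3L)
  expect_equal(select_central_slice(mk(c(0, 40, 40, 0))), 2L)
  expect_error(select_central_slice(mk(c(0, 0, 0))), "empty")
})

test_that("a homogeneous core admits a compliant small ROI", {
  d <- c(40, 40)
  adc <- matrix(1839.3, d[1], d[2])
  ft <- matrix(FALSE, d[1], d[2]); ft[10:30, 10:30] <- TRUE
  roi <- place_small_roi(adc, ft)
  expect_equal(roi$status, "measured")
  expect_gte(roi$area_mm2, 10.7)
  expect_lte(roi$area_mm2, 66.1)
  expect_lte(roi$cv, 0.15)
  expect_equal(roi$mean, 1839.3) # noise-free: exact
  expect_true(all(ft[roi$roi]))
})

test_that("fragmented fibroglandular tissue is not measurable", {
  # a 2-pixel-wide ribbon erodes away entirely: no disc can fit
  adc <- matrix(1800, 40, 40)
  ft <- matrix(FALSE, 40, 40); ft[20:21, 5:35] <- TRUE
  expect_equal(place_small_roi(adc, ft)$status, "not_measurable")
})

test_that("an inhomogeneous core fails the homogeneity screen", {
  set.seed(4)
  adc <- matrix(1500, 40, 40) + matrix(rnorm(1600, sd = 600), 40, 40)
  adc <- pmax(pmin(adc, 3200), 100)
  ft <- matrix(FALSE, 40, 40); ft[10:30, 10:30] <- TRUE
  expect_equal(place_small_roi(adc, ft)$status, "not_measurable")
})

test_that("four-ROI measurement is exact on a clean phantom", {
  ph <- fixture_clean_phantom(pd = 20, pv = 0)
  adc <- ph$truth$adc_field
  m <- measure_four(adc, ph$truth$breast_mask, ph$truth$ft_mask)
  p <- ph$truth$true_pd / 100
  expect_equal(m$adc_sr, 1839.3, tolerance = 1e-9)
  expect_equal(m$adc_sf, 1839.3, tolerance = 1e-9)
  expect_equal(m$adc_wf, 1839.3, tolerance = 1e-9)
  expect_equal(m$adc_wb, p * 1839.3 + (1 - p) * 400, tolerance = 1e-9)
  expect_equal(m$sr_status, "measured")
})

test_that("the histogram accounts for every whole-volume FT voxel", {
  ph <- fixture_phantom(pd = 25, seed = 9)
  adc <- ph$truth$adc_field
  m <- measure_four(adc, ph$truth$breast_mask, ph$truth$ft_mask)
  expect_equal(sum(m$histogram[[1]]), m$n_wf)
})

test_that("histogram bin layout follows the configuration", {
  cfg_c <- adc_config(bin_mode = "centers")
  br_c <- adc_hist_breaks(cfg_c)
  expect_equal(length(br_c), 33)
  expect_equal(unique(round(diff(br_c), 9)), 100)
  centres <- (br_c[-1] + br_c[-33]) / 2
  expect_equal(centres[1], 100)
  expect_equal(centres[32], 3200)
  cfg_e <- adc_config(bin_mode = "edges")
  br_e <- adc_hist_breaks(cfg_e)
  expect_equal(br_e[1], 100)
  expect_equal(br_e[33], 3200)
  expect_equal(unique(round(diff(br_e), 9)), round((3200 - 100) / 32, 9))
})

test_that("histogram counts are invariant to voxel visiting order", {
  set.seed(8)
  vals <- runif(500, 100, 3200)
  cfg <- adc_config()
  h1 <- breastdwi:::adc_hist_counts(vals, cfg)
  h2 <- breastdwi:::adc_hist_counts(sample(vals), cfg)
  expect_identical(h1, h2)
  expect_equal(sum(h1), 500)
})

test_that("growing partial volume depresses WF and SF more than SR", {
  ms <- lapply(c(0, 1, 2), function(pv) {
    ph <- fixture_clean_phantom(pd = 25, pv = pv, seed = 19)
    measure_four(ph$truth$adc_field, ph$truth$breast_mask,
                 ph$truth$ft_mask)
  })
  wf <- vapply(ms, function(m) m$adc_wf, numeric(1))
  sf <- vapply(ms, function(m) m$adc_sf, numeric(1))
  sr <- vapply(ms, function(m) m$adc_sr, numeric(1))
  expect_true(all(diff(wf) < 0))
  expect_true(all(diff(sf) < 0))
  # the eroded, homogeneity-screened ROI is far less contaminated
  expect_lt(abs(sr[3] - sr[1]), abs(wf[3] - wf[1]))
  expect_lt(abs(sr[3] - sr[1]), abs(sf[3] - sf[1]))
})

test_that("slice profiles track tissue abundance and order", {
  ph <- fixture_phantom(pd = 25, seed = 9)
  prof <- slice_profile(ph$truth$adc_field, ph$truth$ft_mask)
  expect_equal(nrow(prof), dim(ph$t1)[3])
  expect_identical(prof$slice, seq_len(dim(ph$t1)[3]))
  expect_true(all(is.na(prof$mean_adc[prof$n_ft == 0])))
  # the fibroglandular count profile is unimodal by construction
  nz <- which(prof$n_ft > 0)
  peak <- nz[which.max(prof$n_ft[nz])]
  expect_true(all(diff(prof$n_ft[nz[nz <= peak]]) >= -3))
  expect_true(all(diff(prof$n_ft[nz[nz >= peak]]) <= 3))
  # central (count-maximal) slice has higher mean ADC than the edge slice
  expect_gte(prof$mean_adc[peak], prof$mean_adc[nz[1]])
})

test_that("a uniform ADC field gives equal per-slice means", {
  ph <- fixture_clean_phantom(pd = 20, pv = 0)
  prof <- slice_profile(ph$truth$adc_field, ph$truth$ft_mask)
  m <- prof$mean_adc[prof$n_ft > 0]
  expect_lt(max(m) - min(m), 1e-9)
})

test_that("single-slice fibroglandular tissue yields one finite entry", {
  d <- c(10, 10, 5)
  adc <- img_volume(array(1500, d))
  ft <- array(0L, d); ft[3:6, 3:6, 3] <- 1L
  prof <- slice_profile(adc, img_volume(ft))
  expect_equal(sum(is.finite(prof$mean_adc)), 1)
  expect_equal(which(is.finite(prof$mean_adc)), 3)
})
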