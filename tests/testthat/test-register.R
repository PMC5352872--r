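test_that("NMI of an image with itself is 2", {
  v <- fixture_smooth_volume()
  expect_equal(nmi(v, v), 2, tolerance = 1e-9)
})

test_that("NMI on 2x2 toy tables matches hand-computed entropies", {
  # perfectly dependent: joint {(0,0): 2, (1,1): 2}
  a <- img_volume(array(c(0, 0, 1, 1), c(4, 1, 1)))
  b <- img_volume(array(c(0, 0, 1, 1), c(4, 1, 1)))
  expect_equal(nmi(a, b, n_bins = 2), 2, tolerance = 1e-12)
  # independent uniform: joint {(0,0), (0,1), (1,0), (1,1)} once each
  # H(A) = H(B) = log 2, H(A,B) = log 4, NMI = 2 log2 / log4 = 1
  b2 <- img_volume(array(c(0, 1, 0, 1), c(4, 1, 1)))
  expect_equal(nmi(a, b2, n_bins = 2), 1, tolerance = 1e-12)
})

test_that("NMI of a volume against its shuffled copy is near 1", {
  v <- fixture_smooth_volume(seed = 6, dims = c(32, 32, 8))
  set.seed(1)
  shuf <- img_volume(array(sample(v$data), dim(v$data)), v$spacing)
  val <- nmi(v, shuf)
  expect_gte(val, 1)
  expect_lte(val, 1.1)
})

test_that("a constant image yields the independence limit with a warning", {
  v <- fixture_smooth_volume()
  const <- img_volume(array(7, dim(v$data)), v$spacing)
  expect_warning(val <- nmi(v, const), "constant")
  expect_equal(val, 1)
})

test_that("self-registration recovers the identity", {
  ph <- fixture_phantom(pd = 20, seed = 8)
  reg <- register_affine(ph$t1, ph$t1, with_scale = FALSE, max_iter = 80)
  expect_lt(sqrt(sum(reg$transform[, 4]^2)), 0.1)
  expect_lt(max(abs(reg$transform[, 1:3] - diag(3))), 1e-3)
})

test_that("registration recovers the phantom's applied misalignment", {
  ph <- fixture_phantom(pd = 20, seed = 8)
  adc <- adc_from_dwi(ph$dwi_b0, ph$dwi_b1000, 1000)
  reg <- register_affine(adc, ph$t1)
  # the recovered transform composed with the applied one should be the
  # identity; residual displacement at the breast must be under half an
  # ADC voxel (min in-plane spacing 3.2 mm)
  comp <- affine_compose(ph$truth$applied_transform, reg$transform)
  pts <- vox_to_world(ph$t1, rbind(c(40, 32, 12), c(30, 20, 10),
                                   c(30, 44, 14)))
  resid <- sqrt(rowSums((affine_apply(comp, pts) - pts)^2))
  expect_lt(max(resid), 0.5 * 3.2)
  expect_gte(reg$nmi, reg$nmi_initial)
})

test_that("tidy and glance summarise a registration", {
  ph <- fixture_phantom(pd = 20, seed = 8)
  reg <- register_affine(ph$t1, ph$t1, with_scale = FALSE, max_iter = 30)
  td <- tidy(reg)
  expect_equal(nrow(td), 12)
  gl <- glance(reg)
  expect_true(gl$nmi >= gl$nmi_initial)
})

test_that("identity resampling on the same grid is exact", {
  v <- fixture_smooth_volume()
  out <- resample_to(v, affine_identity(), v)
  expect_equal(out$data, v$data, tolerance = 1e-12)
})

test_that("masks stay binary through nearest-neighbour resampling", {
  ph <- fixture_phantom(pd = 20, seed = 8)
  tr <- affine_rigid(translation = c(1.7, -2.3, 0.4),
                     angles_deg = c(3, 0, 0))
  out <- resample_to(ph$truth$ft_mask, tr, ph$t1, method = "nearest")
  expect_true(all(out$data[!is.na(out$data)] %in% c(0, 1)))
})

test_that("a pure translation moves a delta peak by the stated offset", {
  d <- c(16, 16, 8)
  arr <- array(0, d); arr[8, 9, 4] <- 100
  v <- img_volume(arr, spacing = c(1, 1, 2))
  # fixed->moving translation of (-2, -3, -2) mm pulls the peak to
  # (10, 12, 5) on the fixed grid (2 rows, 3 cols, 1 slice)
  tr <- affine3(diag(3), c(-2, -3, -2))
  out <- resample_to(v, tr, v)
  peak <- which(out$data == max(out$data, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(10, 12, 5))
})

test_that("resampling round trip is accurate on smooth data", {
  v <- fixture_smooth_volume(seed = 13, dims = c(32, 32, 12))
  tr <- affine_rigid(translation = c(1.2, -0.8, 0.5),
                     angles_deg = c(4, 0, 0))
  fwd <- resample_to(v, tr, v)
  fwd$data[is.na(fwd$data)] <- 0
  back <- resample_to(fwd, affine_invert(tr), v)
  core <- !is.na(back$data) &
    slice.index(back$data, 1) %in% 6:26 &
    slice.index(back$data, 2) %in% 6:26 &
    slice.index(back$data, 3) %in% 3:10
  rms <- sqrt(mean((back$data[core] - v$data[core])^2))
  expect_lt(rms, 0.02 * diff(range(v$data)))
})

test_that("mask transfer preserves fibroglandular-within-breast nesting", {
  ph <- fixture_phantom(pd = 20, seed = 8)
  tr <- affine_rigid(translation = c(2, 1, -1), angles_deg = c(2, 0, 0))
  ft <- resample_to(ph$truth$ft_mask, tr, ph$t1, method = "nearest")
  breast <- resample_to(ph$truth$breast_mask, tr, ph$t1, method = "nearest")
  both <- !is.na(ft$data) & !is.na(breast$data)
  expect_true(all(breast$data[both][ft$data[both] > 0] > 0))
})
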