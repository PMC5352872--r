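test_that("exact 1-D k-means matches brute-force contiguous partitioning", {
  # 1-D optimal k-means clusters are contiguous in sorted order, so the
  # global optimum can be found by enumerating all boundary placements
  brute <- function(x, k) {
    x <- sort(x)
    n <- length(x)
    cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
    best <- Inf
    for (cc in cuts) {
      lo <- c(1, cc + 1)
      hi <- c(cc, n)
      ss <- sum(vapply(seq_len(k), function(m) {
        v <- x[lo[m]:hi[m]]
        sum((v - mean(v))^2)
      }, numeric(1)))
      if (ss < best) best <- ss
    }
    best
  }
  set.seed(5)
  for (k in 2:4) {
    x <- c(rnorm(6, 0), rnorm(5, 10), rnorm(4, 25))
    km <- kmeans_1d(x, k)
    ss <- sum((x - km$centers[km$cluster])^2)
    expect_equal(ss, brute(x, k), tolerance = 1e-9)
  }
})

test_that("tissue split on delta peaks equals the threshold oracle", {
  d <- c(50, 100, 1)
  vals <- c(rep(100, 500), rep(1000, 4500))
  vol <- img_volume(array(vals, d))
  mask <- img_volume(array(1L, d))
  expect_warning(sp <- kmeans_tissue_split(vol, mask), "distinct")
  expect_equal(sp$status, "reduced_k")
  # oracle: any threshold between the peaks labels exactly the low peak
  expect_identical(sp$ft_mask$data > 0, vol$data < 550)
  expect_equal(sum(sp$ft_mask$data), 500)
})

test_that("constant intensities give an empty fibroglandular mask", {
  d <- c(10, 10, 2)
  vol <- img_volume(array(700, d))
  mask <- img_volume(array(1L, d))
  expect_warning(sp <- kmeans_tissue_split(vol, mask), "constant")
  expect_equal(sp$status, "degenerate")
  expect_equal(sum(sp$ft_mask$data), 0)
  expect_equal(sum(sp$fat_mask$data), prod(d))
})

test_that("the tissue split is deterministic across repeated calls", {
  ph <- fixture_phantom(pd = 14.8, seed = 101)
  mask <- ph$truth$breast_mask
  first <- kmeans_tissue_split(ph$t1, mask)
  for (i in 1:9) {
    again <- kmeans_tissue_split(ph$t1, mask,
                                 segmentation_config(seed = i))
    expect_identical(again$ft_mask$data, first$ft_mask$data)
  }
})

test_that("landmarks are found near their true positions", {
  ph <- fixture_phantom(pd = 14.8, seed = 101)
  lm <- detect_landmarks(ph$t1)
  tru <- ph$truth$landmarks
  expect_lt(sqrt(sum((lm$spine - tru$spine)^2)), 2)
  expect_lt(abs(lm$pect_left[2] - tru$pect_left[2]), 2)
  expect_lt(abs(lm$pect_right[2] - tru$pect_right[2]), 2)
  # symmetric phantom: pectoral tips mirror about the midline
  mid <- (dim(ph$t1)[2] + 1) / 2
  expect_lt(abs((mid - lm$pect_left[2]) - (lm$pect_right[2] - mid)), 2)
  expect_lt(abs(lm$pect_left[1] - lm$pect_right[1]), 2)
})

test_that("landmark detection fails gracefully on pure noise", {
  set.seed(12)
  noise <- img_volume(array(rnorm(64 * 64 * 8, 500, 100), c(64, 64, 8)))
  expect_error(detect_landmarks(noise), "manually")
})

test_that("the V-shape cut matches the true breast on the middle slice", {
  ph <- fixture_phantom(pd = 14.8, seed = 101)
  lm <- detect_landmarks(ph$t1)
  mid <- vshape_breast_mask(ph$t1, lm)
  k <- attr(mid, "middle_slice")
  expect_gte(dice_coef(mid$data[, , k], ph$truth$breast_mask$data[, , k]),
             0.95)
})

test_that("no mask voxel lies posterior to the V boundary", {
  ph <- fixture_phantom(pd = 14.8, seed = 101)
  lm <- detect_landmarks(ph$t1)
  mid <- vshape_breast_mask(ph$t1, lm)
  k <- attr(mid, "middle_slice")
  yb <- attr(mid, "v_boundary")
  idx <- which(mid$data[, , k] > 0, arr.ind = TRUE)
  expect_true(all(idx[, 1] < yb[idx[, 2]]))
})

test_that("degenerate landmark geometry is rejected", {
  lm <- chest_landmarks(spine = c(40, 32), pect_left = c(40, 10),
                        pect_right = c(40, 54), slice = 6)
  ph <- fixture_phantom(pd = 14.8, seed = 101)
  expect_error(vshape_breast_mask(ph$t1, lm), "degenerate")
})

test_that("slice propagation recovers the 3-D breast", {
  ph <- fixture_phantom(pd = 14.8, seed = 101)
  lm <- detect_landmarks(ph$t1)
  mid <- vshape_breast_mask(ph$t1, lm)
  breast <- propagate_mask(ph$t1, mid)
  expect_gte(dice_coef(breast$data, ph$truth$breast_mask$data), 0.93)
  # per-slice areas are unimodal: no regrowth past the breast poles
  areas <- apply(breast$data > 0, 3, sum)
  nz <- which(areas > 0)
  peak <- nz[which.max(areas[nz])]
  expect_true(all(diff(areas[nz[nz <= peak]]) >= 0 |
                    abs(diff(areas[nz[nz <= peak]])) < 0.15 * max(areas)))
  expect_true(all(diff(areas[nz[nz >= peak]]) <= 0 |
                    abs(diff(areas[nz[nz >= peak]])) < 0.15 * max(areas)))
})

test_that("a single-slice volume propagates to the V-cut mask itself", {
  ph <- fixture_phantom(pd = 14.8, seed = 101)
  k <- middle_slice_index(ph$t1)
  single <- img_volume(ph$t1$data[, , k, drop = FALSE], ph$t1$spacing)
  lm <- detect_landmarks(single, slice = 1)
  mid <- vshape_breast_mask(single, lm)
  out <- propagate_mask(single, mid)
  expect_identical(out$data, mid$data)
})

test_that("percent density follows the voxel-count formula", {
  d <- c(20, 25, 10)
  breast <- array(0L, d); breast[1:10, 1:25, 1:10] <- 1L # 2500 voxels
  ft <- array(0L, d); ft[1:5, 1:10, 1:5] <- 1L # 250 voxels
  bm <- img_volume(breast, spacing = c(1, 1, 4))
  fm <- img_volume(ft, spacing = c(1, 1, 4))
  res <- percent_density(fm, bm)
  expect_equal(res$pd, 10)
  expect_equal(res$breast_volume_cm3, 2500 * 4 / 1000)
  expect_equal(res$pd, 100 * res$ft_volume_cm3 / res$breast_volume_cm3,
               tolerance = 1e-9)
  # edge cases: full and empty fibroglandular masks
  expect_equal(percent_density(bm, bm)$pd, 100)
  empty <- img_volume(array(0L, d), spacing = c(1, 1, 4))
  expect_equal(percent_density(empty, bm)$pd, 0)
  expect_error(percent_density(bm, empty), "empty")
  expect_error(percent_density(bm, fm), "outside")
})

test_that("percent density is invariant to uniform spacing rescaling", {
  ph <- fixture_phantom(pd = 20, seed = 8)
  a <- percent_density(ph$truth$ft_mask, ph$truth$breast_mask)
  ft2 <- img_volume(ph$truth$ft_mask$data, spacing = c(2, 2, 8))
  bm2 <- img_volume(ph$truth$breast_mask$data, spacing = c(2, 2, 8))
  b <- percent_density(ft2, bm2)
  expect_equal(a$pd, b$pd)
})

test_that("the default pipeline recovers the fibroglandular mask", {
  ph <- fixture_phantom(pd = 14.8, seed = 101)
  seg <- segment_breast(ph$t1)
  fit <- estimate_bias_fcm(ph$t1, seg$breast_mask)
  sp <- kmeans_tissue_split(fit$corrected, seg$breast_mask)
  expect_gte(dice_coef(sp$ft_mask$data, ph$truth$ft_mask$data), 0.90)
})
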