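test_that("Pearson correlation handles exact linear relationships", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  # hand-computed oracle for a small permutation
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$r, 0.5, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 2), c(1, 2)), "fewer than 3")
})

test_that("Pearson correlation drops incomplete pairs", {
  x <- c(1, 2, 3, 4, NA)
  y <- c(2, 4, 6, NA, 10)
  res <- pearson_r(x, y)
  expect_equal(res$n, 3)
  expect_equal(res$r, 1, tolerance = 1e-12)
})

test_that("Pearson correlation is invariant to affine rescaling", {
  set.seed(10)
  x <- rnorm(30); y <- x + rnorm(30, sd = 0.5)
  r0 <- pearson_r(x, y)$r
  expect_equal(pearson_r(5 * x - 3, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.1 * y + 100)$r, r0, tolerance = 1e-12)
})

test_that("ICC(A,1) matches the ANOVA mean-squares oracle", {
  # 4-subject toy table, oracle arithmetic spelled out
  x <- c(9, 6, 8, 7)
  y <- c(10, 6, 9, 8)
  m <- cbind(x, y)
  n <- 4; k <- 2
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_agreement(x, y)$icc, oracle, tolerance = 1e-12)
})

test_that("ICC is 1 for identical measurements and punishes offsets", {
  x <- c(3, 7, 5, 9, 4)
  expect_equal(icc_agreement(x, x)$icc, 1, tolerance = 1e-12)
  shifted <- icc_agreement(x, x + 50)
  expect_lt(shifted$icc, 0.2)
  expect_equal(pearson_r(x, x + 50)$r, 1, tolerance = 1e-12)
})

test_that("paired method comparisons flag degenerate inputs", {
  tbl <- tibble::tibble(
    adc_wb = c(900, 950, 880, 920, 910, 935, 895, 925),
    adc_wf = c(900, 950, 880, 920, 910, 935, 895, 925),
    adc_sf = c(1400, 1460, 1370, 1425, 1410, 1435, 1390, 1418),
    adc_sr = c(1800, 1857, 1771, 1826, 1812, 1838, 1790, 1819)
  )
  cmp <- compare_methods(tbl)
  expect_equal(nrow(cmp), 6)
  wbwf <- cmp[cmp$method_a == "adc_wb" & cmp$method_b == "adc_wf", ]
  expect_equal(wbwf$flag, "zero_variance")
  expect_true(is.na(wbwf$p_value))
  # constant shift far beyond the noise: essentially certain difference
  wbsf <- cmp[cmp$method_a == "adc_wb" & cmp$method_b == "adc_sf", ]
  expect_equal(wbsf$flag, "ok")
  expect_lt(wbsf$p_value, 1e-6)
  # closed-form paired-t oracle for that pair: constant difference -500
  # has sd 0 -> but here differences vary; verify against t.test directly
  d <- tbl$adc_wb - tbl$adc_sf
  expect_equal(wbsf$t, mean(d) / (sd(d) / sqrt(length(d))),
               tolerance = 1e-12)
})

test_that("t-test p-values stay in (0, 1]", {
  set.seed(2)
  tbl <- tibble::tibble(
    adc_wb = rnorm(10, 900, 50), adc_wf = rnorm(10, 1250, 50),
    adc_sf = rnorm(10, 1380, 50), adc_sr = rnorm(10, 1840, 50)
  )
  cmp <- compare_methods(tbl)
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
})

test_that("stratification splits at the cutoff with >= going high", {
  tbl <- tibble::tibble(
    pd = c(5, 15),
    adc_wb = c(600, 1100), adc_wf = c(1100, 1500),
    adc_sf = c(1300, 1600), adc_sr = c(1650, 1950)
  )
  st <- stratify_and_summarize(tbl)
  expect_equal(unique(st$n_low), 1)
  expect_equal(unique(st$n_high), 1)
  # boundary: pd exactly at the cutoff belongs to the high group
  tbl2 <- tibble::tibble(pd = c(5, 10), adc_wb = c(1, 2), adc_wf = c(1, 2),
                         adc_sf = c(1, 2), adc_sr = c(1, 2))
  st2 <- stratify_and_summarize(tbl2)
  expect_equal(unique(st2$n_high), 1)
  expect_equal(st2$mean_high[st2$method == "adc_wb"], 2)
})

test_that("missing small-ROI values are excluded pairwise", {
  set.seed(3)
  n <- 20
  tbl <- tibble::tibble(
    pd = runif(n, 3, 50),
    adc_wb = rnorm(n, 900, 100), adc_wf = rnorm(n, 1250, 100),
    adc_sf = rnorm(n, 1380, 100),
    adc_sr = c(rnorm(n - 6, 1840, 100), rep(NA, 6))
  )
  cmp <- compare_methods(tbl)
  expect_true(all(cmp$n[cmp$method_b == "adc_sr"] == n - 6))
  expect_true(all(cmp$n[cmp$method_b != "adc_sr" &
                          cmp$method_a != "adc_sr"] == n))
  co <- cohort_correlations(tbl)
  expect_equal(co$n[co$method == "adc_sr"], n - 6)
})

test_that("the cohort report normalises densities and regenerates identically", {
  set.seed(6)
  n <- 12
  cfg <- adc_config()
  tbl <- tibble::tibble(
    id = seq_len(n),
    pd = runif(n, 3, 50),
    adc_wb = rnorm(n, 900, 100), adc_wf = rnorm(n, 1250, 100),
    adc_sf = rnorm(n, 1380, 100), adc_sr = rnorm(n, 1840, 100),
    histogram = lapply(seq_len(n), function(i) {
      breastdwi:::adc_hist_counts(runif(300, 100, 3200), cfg)
    })
  )
  rep1 <- cohort_report(tbl, cfg)
  # each group's probability-density curve integrates to 1
  width <- diff(adc_hist_breaks(cfg))[1]
  integrals <- tapply(rep1$density_curves$density,
                      rep1$density_curves$group, function(d) sum(d) * width)
  expect_true(all(abs(integrals - 1) < 1e-6))
  # scatter rows: one per subject and method
  expect_equal(nrow(rep1$scatter), n * 4)
  # regeneration writes bit-identical CSVs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cohort_report(tbl, cfg, out_dir = d1)
  cohort_report(tbl, cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
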