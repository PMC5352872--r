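#' Pearson correlation with pairwise-complete observations
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values
#'   are dropped (mirroring subjects whose small-ROI ADC was not
#'   measurable).
#' @return A one-row tibble: `r`, `n`, `p_value`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pearson_r: fewer than 3 complete pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), n = length(x),
                 p_value = ct$p.value)
}

#' Intraclass correlation for absolute agreement
#'
#' Two-way mixed-effects, absolute-agreement, single-measure intraclass
#' correlation, ICC(A,1), computed from the two-way ANOVA mean squares of
#' a subjects-by-methods table:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`.
#' Unlike Pearson correlation it penalises systematic offsets between
#' methods.
#'
#' @param x,y Paired measurements (two methods on the same subjects);
#'   incomplete pairs are dropped.
#' @return A one-row tibble: `icc`, `n`.
#' @export
icc_agreement <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  m <- cbind(x[ok], y[ok])
  n <- nrow(m)
  if (n < 3) stop("icc_agreement: fewer than 3 complete pairs")
  k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  tibble::tibble(icc = icc, n = n)
}

adc_methods <- c("adc_wb", "adc_wf", "adc_sf", "adc_sr")

#' Pairwise comparison of the four ADC measurement methods
#'
#' Paired t-tests across subjects for the six method pairs (the same
#' subjects are measured four ways). Pairs with zero-variance differences
#' are flagged rather than silently reported.
#'
#' @param table A cohort tibble with columns `adc_wb`, `adc_wf`,
#'   `adc_sf`, `adc_sr` (the small-ROI column may contain `NA`).
#' @param methods Column names to compare (default the four ADC methods).
#' @return A tibble with one row per pair: `method_a`, `method_b`,
#'   `mean_diff`, `t`, `df`, `p_value`, `n`, `flag`.
#' @export
compare_methods <- function(table, methods = adc_methods) {
  stopifnot(all(methods %in% names(table)))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- table[[pr[1]]]; b <- table[[pr[2]]]
    ok <- is.finite(a) & is.finite(b)
    d <- a[ok] - b[ok]
    if (length(d) < 3) {
      return(tibble::tibble(method_a = pr[1], method_b = pr[2],
                            mean_diff = mean(d), t = NA_real_,
                            df = NA_real_, p_value = NA_real_,
                            n = length(d), flag = "too_few_pairs"))
    }
    if (stats::sd(d) < 1e-12) {
      return(tibble::tibble(method_a = pr[1], method_b = pr[2],
                            mean_diff = mean(d), t = NA_real_,
                            df = length(d) - 1, p_value = NA_real_,
                            n = length(d), flag = "zero_variance"))
    }
    tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
    tibble::tibble(method_a = pr[1], method_b = pr[2],
                   mean_diff = unname(tt$estimate),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value, n = length(d), flag = "ok")
  })
}

#' Stratify the cohort by a percent-density cutoff and compare groups
#'
#' Splits subjects into low and high density groups (high when
#' `pd >= cutoff`), summarises each ADC method per group and compares
#' groups with two-sample Student t-tests, multiplicity-corrected over
#' the four methods.
#'
#' @param table A cohort tibble with `pd` and the four ADC columns.
#' @param cutoff Percent-density cutoff (default 10).
#' @param correction Multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"bonferroni"`).
#' @return A tibble with one row per method: group means, SDs, sizes,
#'   `p_value` and `p_adj`.
#' @export
stratify_and_summarize <- function(table, cutoff = 10,
                                   correction = "bonferroni") {
  stopifnot("pd" %in% names(table))
  high <- table$pd >= cutoff
  out <- purrr::map_dfr(adc_methods, function(mtd) {
    v <- table[[mtd]]
    lo <- v[!high & is.finite(v)]
    hi <- v[high & is.finite(v)]
    p <- if (length(lo) >= 2 && length(hi) >= 2) {
      stats::t.test(lo, hi, var.equal = TRUE)$p.value
    } else {
      NA_real_
    }
    tibble::tibble(
      method = mtd,
      mean_low = mean(lo), sd_low = stats::sd(lo), n_low = length(lo),
      mean_high = mean(hi), sd_high = stats::sd(hi), n_high = length(hi),
      p_value = p
    )
  })
  out$p_adj <- stats::p.adjust(out$p_value, method = correction)
  out
}

#' Correlation of percent density with each ADC method
#'
#' @param table A cohort tibble with `pd` and the four ADC columns.
#' @return A tibble with one row per method: `method`, `r`, `n`,
#'   `p_value`.
#' @export
cohort_correlations <- function(table) {
  purrr::map_dfr(adc_methods, function(mtd) {
    res <- pearson_r(table$pd, table[[mtd]])
    tibble::tibble(method = mtd, r = res$r, n = res$n,
                   p_value = res$p_value)
  })
}

#' Assemble the cohort-level report
#'
#' Collects every cohort statistic in one bundle: correlations of percent
#' density with each ADC method, pairwise method comparisons, the
#' single-slice versus whole-volume agreement (Pearson and intraclass
#' correlation), the density-stratified summary, per-subject histograms,
#' and group-averaged probability-density curves (each subject's
#' histogram normalised to unit area, then averaged within group).
#'
#' @param table A cohort tibble as produced by [run_pipeline()]: per
#'   subject `id`, `pd`, the four ADC columns and a `histogram`
#'   list-column.
#' @param cfg An [adc_config()] (defines the histogram bin layout).
#' @param cutoff Percent-density cutoff for stratification.
#' @param out_dir If non-`NULL`, CSV files of every component are written
#'   there.
#' @return A list of class `cohort_report`: `correlations`,
#'   `method_comparisons`, `agreement`, `stratified`, `histograms` (long
#'   tibble), `density_curves` (per group), `scatter` (long tibble of pd
#'   versus each method).
#' @export
cohort_report <- function(table, cfg = adc_config(), cutoff = 10,
                          out_dir = NULL) {
  correlations <- cohort_correlations(table)
  comparisons <- compare_methods(table)
  agr_p <- pearson_r(table$adc_sf, table$adc_wf)
  agr_i <- icc_agreement(table$adc_sf, table$adc_wf)
  agreement <- tibble::tibble(
    pair = "adc_sf_vs_adc_wf", pearson_r = agr_p$r, icc = agr_i$icc,
    n = agr_p$n
  )
  stratified <- stratify_and_summarize(table, cutoff)

  br <- adc_hist_breaks(cfg)
  centres <- (br[-1] + br[-length(br)]) / 2
  width <- diff(br)[1]
  hist_long <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
    h <- table$histogram[[i]]
    tibble::tibble(id = table$id[i], pd = table$pd[i],
                   bin_centre = centres, count = h)
  })
  dens <- hist_long |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(density = .data$count / pmax(sum(.data$count), 1) / width) |>
    dplyr::ungroup() |>
    dplyr::mutate(group = ifelse(.data$pd >= cutoff, "high", "low")) |>
    dplyr::group_by(.data$group, .data$bin_centre) |>
    dplyr::summarize(density = mean(.data$density), .groups = "drop")

  scatter <- table |>
    dplyr::select("id", "pd", dplyr::all_of(adc_methods)) |>
    tidyr::pivot_longer(dplyr::all_of(adc_methods),
                        names_to = "method", values_to = "adc")

  out <- structure(
    list(correlations = correlations, method_comparisons = comparisons,
         agreement = agreement, stratified = stratified,
         histograms = hist_long, density_curves = dens, scatter = scatter,
         cutoff = cutoff),
    class = "cohort_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("correlations", "method_comparisons", "agreement",
                 "stratified", "histograms", "density_curves", "scatter")) {
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat("Correlation of percent density with each ADC method:\n")
  print(as.data.frame(x$correlations), row.names = FALSE)
  cat(sprintf(
    "Single-slice vs whole-volume FT ADC: Pearson r = %.3f, ICC = %.3f (n = %d)\n",
    x$agreement$pearson_r, x$agreement$icc, x$agreement$n
  ))
  cat(sprintf("Stratification cutoff: %g%% density\n", x$cutoff))
  invisible(x)
}
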