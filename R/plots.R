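#' Scatter plots of percent density against each ADC method
#'
#' One panel per ROI strategy with a least-squares line and the Pearson
#' correlation in the panel label, mirroring the standard presentation of
#' density-ADC association.
#'
#' @param table A cohort tibble with `pd` and the four ADC columns.
#' @return A ggplot object.
#' @export
plot_pd_adc <- function(table) {
  long <- table |>
    dplyr::select("id", "pd", dplyr::all_of(adc_methods)) |>
    tidyr::pivot_longer(dplyr::all_of(adc_methods),
                        names_to = "method", values_to = "adc") |>
    dplyr::filter(is.finite(.data$adc))
  labs <- long |>
    dplyr::group_by(.data$method) |>
    dplyr::summarize(r = stats::cor(.data$pd, .data$adc), .groups = "drop") |>
    dplyr::mutate(label = sprintf("%s (r = %.2f)", .data$method, .data$r))
  long <- dplyr::left_join(long, labs, by = "method")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pd, y = .data$adc)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "Percent density (%)",
                  y = expression(ADC ~ (10^-6 ~ mm^2 / s))) +
    ggplot2::theme_minimal()
}

#' Plot a craniocaudal fibroglandular ADC profile
#'
#' @param profile Output of [slice_profile()].
#' @return A ggplot object with the per-slice mean ADC and the
#'   fibroglandular pixel count.
#' @export
plot_slice_profile <- function(profile) {
  p <- profile |> dplyr::filter(.data$n_ft > 0)
  scale_f <- max(p$mean_adc, na.rm = TRUE) / max(p$n_ft)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$slice)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_ft * scale_f),
                      fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_adc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_adc)) +
    ggplot2::scale_y_continuous(
      name = expression(Mean ~ FT ~ ADC ~ (10^-6 ~ mm^2 / s)),
      sec.axis = ggplot2::sec_axis(~ . / scale_f, name = "FT pixel count")
    ) +
    ggplot2::labs(x = "Slice (craniocaudal)") +
    ggplot2::theme_minimal()
}

#' Plot group-averaged ADC probability-density curves
#'
#' @param report A [cohort_report()].
#' @return A ggplot object.
#' @export
plot_density_curves <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  ggplot2::ggplot(report$density_curves,
                  ggplot2::aes(x = .data$bin_centre, y = .data$density,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(ADC ~ (10^-6 ~ mm^2 / s)),
                  y = "Probability density",
                  colour = sprintf("Density group\n(cutoff %g%%)",
                                   report$cutoff)) +
    ggplot2::theme_minimal()
}

#' Middle-slice montage of a phantom
#'
#' T1 intensities with the ground-truth breast and fibroglandular
#' contours overlaid; a quick visual check of the synthetic anatomy.
#'
#' @param object A `breast_phantom`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.breast_phantom <- function(object, ...) {
  k <- middle_slice_index(object$t1)
  df <- expand.grid(row = seq_len(dim(object$t1$data)[1]),
                    col = seq_len(dim(object$t1$data)[2]))
  df$t1 <- as.vector(object$t1$data[, , k])
  df$breast <- as.vector(object$truth$breast_mask$data[, , k]) > 0
  df$ft <- as.vector(object$truth$ft_mask$data[, , k]) > 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$t1)) +
    ggplot2::geom_point(data = df[df$ft, ], colour = "red", size = 0.3,
                        alpha = 0.5) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "T1 signal", x = NULL, y = NULL,
                  title = sprintf("Middle slice (true PD %.1f%%)",
                                  object$truth$true_pd)) +
    ggplot2::theme_void()
}
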