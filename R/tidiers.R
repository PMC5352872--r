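#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns per-component estimates as a tibble; `glance()`
#' returns a one-row model summary.
#'
#' @param x A `registration`, `bias_fit` or `cohort_result` object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidiers
#' @export
tidy.registration <- function(x, ...) {
  m <- unclass(x$transform)
  tibble::tibble(
    term = c(paste0("linear[", rep(1:3, 3), ",", rep(1:3, each = 3), "]"),
             paste0("translation[", 1:3, "]")),
    estimate = c(as.vector(m[, 1:3]), m[, 4])
  )
}

#' @rdname tidiers
#' @export
glance.registration <- function(x, ...) {
  tibble::tibble(nmi = x$nmi, nmi_initial = x$nmi_initial,
                 improvement = x$nmi - x$nmi_initial,
                 converged = x$converged)
}

#' @rdname tidiers
#' @export
tidy.bias_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective),
                 objective = x$objective)
}

#' @rdname tidiers
#' @export
glance.bias_fit <- function(x, ...) {
  b <- x$model$bias_field$data
  tibble::tibble(n_iter = x$n_iter, status = x$status,
                 bias_min = min(b), bias_max = max(b))
}

#' @rdname tidiers
#' @export
tidy.cohort_result <- function(x, ...) {
  x$table[setdiff(names(x$table), "histogram")]
}

#' @rdname tidiers
#' @export
glance.cohort_result <- function(x, ...) {
  ok <- x$table$status == "ok"
  out <- tibble::tibble(
    n_subjects = nrow(x$table),
    n_ok = sum(ok),
    n_sr_measured = sum(x$table$sr_status[ok] == "measured", na.rm = TRUE)
  )
  if (!is.null(x$report)) {
    r <- x$report$correlations
    out$r_wb_pd <- r$r[r$method == "adc_wb"]
    out$r_sf_wf <- x$report$agreement$pearson_r
  }
  out
}
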