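#' Specify a synthetic cohort
#'
#' Population-level description of a simulated study: the percent-density
#' distribution across subjects, the between-subject distributions of the
#' compartment ADCs, and an optional coupling between density and
#' fibroglandular ADC. Defaults emulate a 38-woman cohort whose percent
#' density follows a truncated normal with mean 14.8, sd 14.4 on
#' [2.2, 51.6] and whose small-ROI fibroglandular ADC is centred at
#' 1839.3 +/- 343.2 (1e-6 mm^2/s).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param pd_distribution `"truncnorm"` (default) or `"point"` (degenerate
#'   at `pd_mean`, for testing).
#' @param pd_mean,pd_sd,pd_bounds Parameters of the percent-density
#'   distribution (percent).
#' @param ft_adc_mean,ft_adc_sd Between-subject distribution of the
#'   fibroglandular ADC (1e-6 mm^2/s).
#' @param fat_adc_mean,fat_adc_sd Between-subject distribution of the fat
#'   ADC (1e-6 mm^2/s).
#' @param pd_adc_coupling Correlation in [-1, 1] between the latent
#'   percent-density score and the subject fibroglandular ADC.
#' @param seed Integer seed for the cohort draw (per-subject phantom seeds
#'   are derived from it reproducibly).
#' @param phantom Baseline [phantom_params()] whose geometry/noise settings
#'   every subject inherits (per-subject density, ADC means and seed are
#'   overridden).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 38,
                        pd_distribution = c("truncnorm", "point"),
                        pd_mean = 14.8, pd_sd = 14.4,
                        pd_bounds = c(2.2, 51.6),
                        ft_adc_mean = 1839.3, ft_adc_sd = 343.2,
                        fat_adc_mean = 400, fat_adc_sd = 80,
                        pd_adc_coupling = 0.3,
                        seed = 1L,
                        phantom = phantom_params()) {
  pd_distribution <- match.arg(pd_distribution)
  stopifnot(
    n_subjects >= 2,
    length(pd_bounds) == 2, pd_bounds[1] < pd_bounds[2],
    pd_bounds[1] > 0, pd_bounds[2] < 100,
    abs(pd_adc_coupling) <= 1,
    ft_adc_sd >= 0, fat_adc_sd >= 0
  )
  if (pd_distribution == "truncnorm" && pd_sd <= 0 &&
      (pd_mean < pd_bounds[1] || pd_mean > pd_bounds[2])) {
    stop("degenerate pd distribution: sd <= 0 and mean outside pd_bounds")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      pd_distribution = pd_distribution,
      pd_mean = pd_mean, pd_sd = pd_sd, pd_bounds = pd_bounds,
      ft_adc_mean = ft_adc_mean, ft_adc_sd = ft_adc_sd,
      fat_adc_mean = fat_adc_mean, fat_adc_sd = fat_adc_sd,
      pd_adc_coupling = pd_adc_coupling,
      seed = as.integer(seed), phantom = phantom
    ),
    class = "cohort_spec"
  )
}

# Truncated-normal draw by inverse-CDF; returns values and their latent
# standard-normal scores (used for the density/ADC coupling).
rtruncnorm_scored <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) {
    if (mean < lo || mean > hi) {
      stop("degenerate distribution: point mass outside bounds")
    }
    return(list(x = rep(mean, n), z = rep(0, n)))
  }
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  z <- stats::qnorm(u)
  list(x = mean + sd * z, z = z)
}

#' Draw a synthetic cohort
#'
#' Draws per-subject percent-density targets and compartment ADC means from
#' a [cohort_spec()], assigns reproducible per-subject seeds, and returns
#' the cohort truth table. Phantom image bundles are generated lazily with
#' [subject_phantom()] (or eagerly with `materialize = TRUE`).
#'
#' @param spec A [cohort_spec()].
#' @param materialize If `TRUE`, also generate every subject's image bundle
#'   (memory-hungry for large cohorts).
#' @return A list of class `breast_cohort` with elements `subjects` (a
#'   tibble: `id`, `seed`, `pd_target`, `ft_adc`, `fat_adc`), `spec`, and
#'   optionally `phantoms`.
#' @examples
#' co <- make_cohort(cohort_spec(n_subjects = 3, seed = 7))
#' co$subjects
#' @export
make_cohort <- function(spec = cohort_spec(), materialize = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  if (spec$pd_distribution == "point") {
    pd <- list(x = rep(spec$pd_mean, n), z = rep(0, n))
  } else {
    pd <- rtruncnorm_scored(n, spec$pd_mean, spec$pd_sd,
                            spec$pd_bounds[1], spec$pd_bounds[2])
  }
  zs <- if (stats::sd(pd$z) > 0) (pd$z - mean(pd$z)) / stats::sd(pd$z) else pd$z
  rho <- spec$pd_adc_coupling
  ft <- spec$ft_adc_mean + spec$ft_adc_sd *
    (rho * zs + sqrt(1 - rho^2) * stats::rnorm(n))
  fat <- stats::rnorm(n, spec$fat_adc_mean, spec$fat_adc_sd)
  fat <- pmax(fat, 50) # keep fat ADC physical and below the FT ADC
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- tibble::tibble(
    id = seq_len(n), seed = seeds,
    pd_target = pd$x, ft_adc = ft, fat_adc = fat
  )
  out <- structure(list(subjects = subjects, spec = spec), class = "breast_cohort")
  if (materialize) {
    out$phantoms <- purrr::map(seq_len(n), function(i) subject_phantom(out, i))
  }
  out
}

#' @rdname make_cohort
#' @param cohort A `breast_cohort`.
#' @param i Subject index.
#' @export
subject_phantom <- function(cohort, i) {
  stopifnot(inherits(cohort, "breast_cohort"))
  s <- cohort$subjects[i, ]
  base <- cohort$spec$phantom
  p <- phantom_params(
    grid_shape = base$grid_shape, t1_spacing = base$t1_spacing,
    adc_spacing = base$adc_spacing,
    pd_target = s$pd_target,
    fat_adc_mean = s$fat_adc, ft_adc_mean = s$ft_adc,
    fat_adc_sd = base$fat_adc_sd, ft_adc_sd = base$ft_adc_sd,
    b_values = base$b_values, noise_sd = base$noise_sd,
    bias_amplitude = base$bias_amplitude,
    pv_smooth_sigma = base$pv_smooth_sigma,
    misalign_translation = base$misalign_translation,
    misalign_rotation_deg = base$misalign_rotation_deg,
    seed = s$seed
  )
  make_phantom(p)
}
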