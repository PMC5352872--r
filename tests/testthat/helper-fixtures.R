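# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default-appearance phantom at a given density
fixture_phantom <- function(pd = 14.8, seed = 101, ...) {
  key <- paste0("ph_", pd, "_", seed, "_", paste(c(...), collapse = "_"))
  cached(key, make_phantom(phantom_params(pd_target = pd, seed = seed, ...)))
}

# deterministic, noise-free phantom whose ADC grid matches the T1 grid
# (no misalignment): ADC values are exactly the compartment means
fixture_clean_phantom <- function(pd = 20, pv = 0, seed = 7) {
  key <- paste0("clean_", pd, "_", pv, "_", seed)
  cached(key, make_phantom(phantom_params(
    pd_target = pd, seed = seed,
    noise_sd = 0, bias_amplitude = 0, pv_smooth_sigma = pv,
    ft_adc_sd = 0, fat_adc_sd = 0,
    adc_spacing = c(1, 1, 4),
    misalign_translation = c(0, 0, 0), misalign_rotation_deg = 0
  )))
}

dice_coef <- function(a, b) {
  a <- a > 0; b <- b > 0
  2 * sum(a & b) / (sum(a) + sum(b))
}

# smooth deterministic volume for interpolation/registration fixtures
fixture_smooth_volume <- function(seed = 42, dims = c(24, 24, 12)) {
  key <- paste0("smooth_", seed, "_", paste(dims, collapse = "x"))
  cached(key, {
    ii <- slice.index(array(0, dims), 1)
    jj <- slice.index(array(0, dims), 2)
    kk <- slice.index(array(0, dims), 3)
    z <- sin(ii / 4 + seed) + cos(jj / 5) + 0.5 * sin(kk / 3 + jj / 9)
    img_volume(z, spacing = c(1, 1, 2))
  })
}
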