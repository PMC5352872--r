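#' Parameters for a synthetic breast MRI phantom
#'
#' Defines one synthetic subject: an axial non-fat-suppressed T1-weighted
#' stack (fat bright, fibroglandular tissue dark) plus a pair of
#' diffusion-weighted volumes on a coarser, slightly misaligned grid from
#' which an ADC map can be derived. The defaults emulate a 3 mm / 1 mm-gap
#' T1 acquisition (4 mm slice spacing), a 3.2 x 3.5 mm in-plane DWI grid
#' with 4 mm + 1 mm-gap slices, and b-values 0 and 1000 s/mm^2.
#'
#' The fibroglandular compartment is generated as a speckled, strand-like
#' central region rather than a solid blob: real fibroglandular tissue is
#' branched, and the resulting broad partial-volume bridge of intermediate
#' T1 intensities is what makes intensity-cluster tissue splitting
#' meaningful. `pv_smooth_sigma` controls the width of the fat/FT mixing
#' zone applied to both T1 intensities and the ADC field.
#'
#' @param grid_shape T1 grid size, `c(rows, cols, slices)`.
#' @param t1_spacing T1 voxel spacing in mm (slice spacing = thickness + gap).
#' @param adc_spacing DWI/ADC grid spacing in mm.
#' @param pd_target Percent density to construct, in (0, 100).
#' @param fat_adc_mean,ft_adc_mean Compartment ADC means, 1e-6 mm^2/s. The
#'   fibroglandular default matches the small-ROI population mean of the
#'   cohort this generator emulates; the fat default is an assumption (see
#'   vignette) chosen so whole-breast ADC at vanishing density approaches
#'   the low end of the reported whole-breast range.
#' @param fat_adc_sd,ft_adc_sd Within-subject voxelwise ADC heterogeneity
#'   (smooth texture), 1e-6 mm^2/s.
#' @param b_values The two diffusion weightings, s/mm^2.
#' @param noise_sd Rician noise sd in signal units; the default gives
#'   SNR ~ 30 at b = 0.
#' @param bias_amplitude Peak-to-peak range of the multiplicative coil bias
#'   applied to the T1 volume (field spans `1 +/- bias_amplitude / 2`).
#' @param pv_smooth_sigma Partial-volume mixing width in mm.
#' @param misalign_translation,misalign_rotation_deg Rigid misalignment of
#'   the DWI/ADC grid relative to the T1 anatomy (mm; degrees about the
#'   slice axis), recorded in the ground truth for registration tests.
#' @param seed Integer seed; identical parameters and seed give a
#'   bit-identical phantom.
#' @return A list of class `phantom_params`.
#' @examples
#' p <- phantom_params(pd_target = 20, seed = 1)
#' ph <- make_phantom(p)
#' ph$truth$true_pd
#' @export
phantom_params <- function(grid_shape = c(64, 64, 24),
                           t1_spacing = c(1, 1, 4),
                           adc_spacing = c(3.5, 3.2, 5),
                           pd_target = 14.8,
                           fat_adc_mean = 400,
                           ft_adc_mean = 1839.3,
                           fat_adc_sd = 40,
                           ft_adc_sd = 120,
                           b_values = c(0, 1000),
                           noise_sd = 27,
                           bias_amplitude = 0.2,
                           pv_smooth_sigma = 1.2,
                           misalign_translation = c(0, 3, 0),
                           misalign_rotation_deg = 2,
                           seed = 1L) {
  stopifnot(
    length(grid_shape) == 3, all(grid_shape >= 16),
    all(t1_spacing > 0), all(adc_spacing > 0),
    pd_target > 0, pd_target < 100,
    fat_adc_mean > 0, ft_adc_mean > 0,
    fat_adc_sd >= 0, ft_adc_sd >= 0,
    length(b_values) == 2, b_values[2] > b_values[1],
    noise_sd >= 0, bias_amplitude >= 0, pv_smooth_sigma >= 0
  )
  if (fat_adc_mean >= ft_adc_mean) {
    warning("fat_adc_mean >= ft_adc_mean: outside the fat-suppressed regime ",
            "this generator emulates")
  }
  structure(
    list(
      grid_shape = as.integer(grid_shape), t1_spacing = t1_spacing,
      adc_spacing = adc_spacing, pd_target = pd_target,
      fat_adc_mean = fat_adc_mean, ft_adc_mean = ft_adc_mean,
      fat_adc_sd = fat_adc_sd, ft_adc_sd = ft_adc_sd,
      b_values = b_values, noise_sd = noise_sd,
      bias_amplitude = bias_amplitude, pv_smooth_sigma = pv_smooth_sigma,
      misalign_translation = misalign_translation,
      misalign_rotation_deg = misalign_rotation_deg,
      seed = as.integer(seed)
    ),
    class = "phantom_params"
  )
}

# Fixed tissue appearance of the phantom (signal units are arbitrary).
# Fat carries only fine-scale texture: its broad intensity variation is
# smooth coil shading, expressed through the bias field and removable by
# bias correction, as on real non-fat-suppressed T1. The T1 spin-echo
# noise is a fixed fraction of the (EPI-DWI) noise level.
.phantom_tissue <- list(
  t1_ft = 250, t1_ft_sd = 60, t1_fat = 1000, t1_fat_sd = 10,
  t1_chest = 600, t1_spine = 800, t1_noise_frac = 0.55,
  s0_breast = 800, s0_chest = 700, s0_spine = 600,
  adc_chest = 1400, adc_spine = 700,
  texture_scale = c(4, 4, 8), speckle_scale = c(3, 3, 6),
  centre_weight = 1.1, envelope_fill = 0.8
)

# Deterministic geometry of the phantom: chest-wall band whose anterior
# edge follows the V between the spine and the two pectoral tips, a spine
# rod, and a breast region anterior to the band.
phantom_geometry <- function(params) {
  d <- params$grid_shape
  nr <- d[1]; nc <- d[2]; nz <- d[3]
  cx <- (nc + 1) / 2
  zc <- (nz + 1) / 2
  r_spine <- 0.90 * nr
  spine_rad <- max(2, 0.04 * nr)
  pect_row <- 0.69 * nr
  band_th <- max(3, round(0.06 * nr))
  band_col_lo <- max(2L, round(0.06 * nc))
  band_col_hi <- nc + 1L - band_col_lo
  slope <- (r_spine - pect_row) / (cx - (band_col_lo + 1))

  ii <- slice.index(array(0, d), 1)
  jj <- slice.index(array(0, d), 2)
  kk <- slice.index(array(0, d), 3)

  yedge_col <- pmax(pect_row, r_spine - slope * abs(seq_len(nc) - cx))
  yedge <- array(yedge_col[as.vector(jj)], d)

  band <- ii >= yedge & ii < yedge + band_th &
    jj >= band_col_lo & jj <= band_col_hi
  spine <- (ii - r_spine)^2 + (jj - cx)^2 <= spine_rad^2

  br_c <- c(0.69 * nr, cx, zc)
  br_ax <- c(0.47 * nr, 0.375 * nc, 0.46 * nz)
  breast <- ((ii - br_c[1]) / br_ax[1])^2 + ((jj - br_c[2]) / br_ax[2])^2 +
    ((kk - br_c[3]) / br_ax[3])^2 <= 1
  # keep an air gap to the chest-wall band and to the anterior tip of the
  # spine rod so the breast never touches chest structures
  breast <- breast & ii <= yedge - 2 & ii <= r_spine - spine_rad - 2 &
    !band & !spine

  # fibroglandular envelope kept clear of the skin surface by a
  # subcutaneous fat rind (anterior margin of a few voxels)
  env_c <- c(0.50 * nr, cx, zc)
  env_ax <- c(0.25 * nr, 0.32 * nc, 0.42 * nz)
  rho2 <- ((ii - env_c[1]) / env_ax[1])^2 + ((jj - env_c[2]) / env_ax[2])^2 +
    ((kk - env_c[3]) / env_ax[3])^2
  inner <- ((ii - br_c[1]) / (0.92 * br_ax[1]))^2 +
    ((jj - br_c[2]) / (0.92 * br_ax[2]))^2 +
    ((kk - br_c[3]) / (0.92 * br_ax[3]))^2 <= 1
  envelope <- rho2 <= 1 & breast & inner & ii <= yedge - 5

  list(
    breast = breast, band = band, spine = spine,
    envelope = envelope, env_rho2 = rho2,
    landmarks = list(
      spine = c(r_spine, cx),
      pect_left = c(pect_row, band_col_lo),
      pect_right = c(pect_row, band_col_hi),
      slice = as.integer(round(zc))
    )
  )
}

# Speckled fibroglandular mask hitting the target percent density by exact
# voxel count. The tissue is confined to a central sub-envelope sized so
# that it fills a roughly constant fraction of it: fatty breasts carry a
# compact (retroareolar-like) fibroglandular core rather than strands
# dispersed through the whole breast, which also keeps the fat/FT
# interface area proportionate to the tissue volume at every density.
make_ft_mask <- function(geom, params) {
  n_breast <- sum(geom$breast)
  n_env <- sum(geom$envelope)
  k_ft <- round(params$pd_target / 100 * n_breast)
  if (k_ft > n_env) {
    stop(sprintf(
      "pd_target = %.1f%% is not achievable with this geometry; maximum is %.1f%%",
      params$pd_target, 100 * n_env / n_breast
    ))
  }
  if (k_ft < 1) stop("pd_target too small: no fibroglandular voxel to place")
  fill <- .phantom_tissue$envelope_fill
  n_sub <- min(n_env, ceiling(k_ft / fill))
  rho_env <- geom$env_rho2[geom$envelope]
  rho_cut <- sort(rho_env)[n_sub]
  sub <- geom$envelope & geom$env_rho2 <= rho_cut
  w <- smooth_noise_field(dim(geom$breast), params$t1_spacing,
                          .phantom_tissue$speckle_scale)
  w <- w + .phantom_tissue$centre_weight * (1 - pmin(geom$env_rho2, 1))
  we <- w[sub]
  thr <- sort(we, decreasing = TRUE)[k_ft]
  ft <- sub & w >= thr
  # ties could overshoot the count; trim deterministically if so
  extra <- sum(ft) - k_ft
  if (extra > 0) {
    idx <- which(ft & w == thr)
    ft[idx[seq_len(extra)]] <- FALSE
  }
  ft
}

#' Generate one synthetic breast MRI subject
#'
#' Builds the T1-weighted volume, the two diffusion-weighted volumes on the
#' coarser misaligned DWI grid, and a ground-truth record (masks, percent
#' density by voxel count, compartment ADCs, applied bias field and
#' misalignment transform, landmark positions).
#'
#' The breast is a half-ellipsoid-like region anterior to a chest-wall band
#' with three detectable landmarks (spine rod, two pectoral tips). T1
#' intensities are fat-bright / FT-dark; DWI signals decay
#' mono-exponentially with the compartment ADC, partial-volume-mixed at
#' FT/fat boundaries; the multiplicative bias field and Rician noise are
#' applied last, and the truth records the pre-noise masks.
#'
#' @param params A [phantom_params()] object.
#' @return A list of class `breast_phantom` with elements `t1`, `dwi_b0`,
#'   `dwi_b1000` (all [img_volume()]) and `truth`.
#' @export
make_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  set.seed(params$seed)
  tis <- .phantom_tissue
  d <- params$grid_shape
  sp <- params$t1_spacing
  geom <- phantom_geometry(params)
  ft <- make_ft_mask(geom, params)
  n_breast <- sum(geom$breast)
  true_pd <- 100 * sum(ft) / n_breast

  # partial-volume fraction field: smoothed FT indicator within the breast
  f <- ft * 1
  if (params$pv_smooth_sigma > 0) {
    f <- gauss_blur(f, params$pv_smooth_sigma, sp)
    f[!geom$breast] <- 0
    f <- pmin(pmax(f, 0), 1)
  }

  # T1-weighted appearance
  i_ft <- tis$t1_ft + tis$t1_ft_sd *
    smooth_noise_field(d, sp, tis$texture_scale)
  i_fat <- tis$t1_fat + tis$t1_fat_sd *
    smooth_noise_field(d, sp, tis$texture_scale)
  t1 <- array(0, d)
  t1[geom$breast] <- (f * i_ft + (1 - f) * i_fat)[geom$breast]
  t1[geom$band] <- tis$t1_chest
  t1[geom$spine] <- tis$t1_spine

  # multiplicative coil bias (smooth, deterministic pattern)
  jjn <- (slice.index(array(0, d), 2) - 1) / (d[2] - 1)
  iin <- (slice.index(array(0, d), 1) - 1) / (d[1] - 1)
  pat <- 0.7 * (jjn - 0.5) + 0.3 * (2 * (iin - 0.5)^2 - 0.5)
  pat <- (pat - min(pat)) / (max(pat) - min(pat)) - 0.5
  bias <- 1 + params$bias_amplitude * pat
  t1_obs <- add_rician_noise(t1 * bias, params$noise_sd * tis$t1_noise_frac)

  # ADC field (1e-6 mm^2/s) and DWI signals on the T1 grid
  a_ft <- params$ft_adc_mean + params$ft_adc_sd *
    smooth_noise_field(d, sp, tis$texture_scale)
  a_fat <- params$fat_adc_mean + params$fat_adc_sd *
    smooth_noise_field(d, sp, tis$texture_scale)
  adc <- array(0, d)
  adc[geom$breast] <- (f * a_ft + (1 - f) * a_fat)[geom$breast]
  adc[geom$band] <- tis$adc_chest
  adc[geom$spine] <- tis$adc_spine
  body <- geom$breast | geom$band | geom$spine
  s0 <- array(0, d)
  s0[geom$breast] <- tis$s0_breast
  s0[geom$band] <- tis$s0_chest
  s0[geom$spine] <- tis$s0_spine
  b <- params$b_values[2]
  sb <- s0 * exp(-b * 1e-6 * adc)

  # DWI/ADC grid: same field of view, coarser voxels, rigid misalignment
  t1_vol <- img_volume(t1_obs, sp)
  extent <- d * sp
  nd <- pmax(4L, floor(extent / params$adc_spacing))
  leftover <- extent - nd * params$adc_spacing
  origin_d <- -sp / 2 + leftover / 2 + params$adc_spacing / 2
  dwi_template <- img_volume(array(0, nd), params$adc_spacing, origin_d)
  centre_mm <- vox_to_world(t1_vol, matrix((d + 1) / 2, 1))[1, ]
  applied <- affine_about(centre_mm, params$misalign_translation,
                          c(params$misalign_rotation_deg, 0, 0))

  s0_vol <- img_volume(s0 * bias, sp)
  sb_vol <- img_volume(sb * bias, sp)
  dwi_b0 <- downsample_through(s0_vol, dwi_template, applied)
  dwi_b1000 <- downsample_through(sb_vol, dwi_template, applied)
  dwi_b0$data <- add_rician_noise(dwi_b0$data, params$noise_sd)
  dwi_b1000$data <- add_rician_noise(dwi_b1000$data, params$noise_sd)

  truth <- list(
    breast_mask = img_volume(array(as.integer(geom$breast), d), sp),
    ft_mask = img_volume(array(as.integer(ft), d), sp),
    true_pd = true_pd,
    true_ft_adc = params$ft_adc_mean,
    true_fat_adc = params$fat_adc_mean,
    bias_field = img_volume(bias, sp),
    applied_transform = applied,
    landmarks = geom$landmarks,
    adc_field = img_volume(adc, sp),
    body_mask = img_volume(array(as.integer(body), d), sp),
    params = params
  )
  structure(
    list(t1 = t1_vol, dwi_b0 = dwi_b0, dwi_b1000 = dwi_b1000, truth = truth),
    class = "breast_phantom"
  )
}

# Pull a fine-grid volume onto a coarse target grid through an affine that
# maps target physical points into the source anatomy, averaging a 2x2x2
# sub-voxel stencil per target voxel to approximate block averaging (this
# is the partial-volume mechanism of the coarse DWI grid). When the target
# grid is not coarser than the source there is nothing to average: the
# volume is sampled at the voxel centres directly, so a matched-grid
# acquisition reproduces the source values exactly.
downsample_through <- function(src, target, transform) {
  g <- grid_world_coords(target)
  if (all(target$spacing <= src$spacing + 1e-9)) {
    sm <- sample_volume(src, affine_apply(transform, g$world), "linear")
    v <- sm$values
    v[!sm$valid] <- 0
    return(vol_like(target, array(v, dim(target$data))))
  }
  offs <- as.matrix(expand.grid(
    r = c(-0.25, 0.25) * target$spacing[1],
    c = c(-0.25, 0.25) * target$spacing[2],
    s = c(-0.25, 0.25) * target$spacing[3]
  ))
  acc <- 0
  for (m in seq_len(nrow(offs))) {
    pts <- sweep(g$world, 2, offs[m, ], `+`)
    sm <- sample_volume(src, affine_apply(transform, pts), "linear")
    v <- sm$values
    v[!sm$valid] <- 0
    acc <- acc + v
  }
  vol_like(target, array(acc / nrow(offs), dim(target$data)))
}

#' Derive an ADC map from a two-point DWI acquisition
#'
#' Applies the standard two-point estimate `ADC = ln(s0 / sb) / b`,
#' reported in 1e-6 mm^2/s. Voxels where `s0 <= 0` (no signal, e.g. air)
#' are flagged invalid and returned as `NA`; voxels with positive `s0` but
#' non-positive `sb` are likewise flagged per voxel, never a global
#' failure.
#'
#' @param s0 [img_volume()] at the lower b-value.
#' @param sb [img_volume()] at the higher b-value, same grid.
#' @param b The b-value difference in s/mm^2, positive.
#' @return An [img_volume()] ADC map with `NA` at invalid voxels.
#' @examples
#' v0 <- img_volume(array(1000, c(2, 2, 2)))
#' v1 <- img_volume(array(1000 * exp(-1), c(2, 2, 2)))
#' adc_from_dwi(v0, v1, 1000)$data[1] # 1000
#' @export
adc_from_dwi <- function(s0, sb, b) {
  stopifnot(is_img_volume(s0), is_img_volume(sb), b > 0)
  if (!same_grid(s0, sb)) stop("adc_from_dwi: s0 and sb are on different grids")
  adc <- array(NA_real_, dim(s0$data))
  ok <- is.finite(s0$data) & is.finite(sb$data) & s0$data > 0 & sb$data > 0
  adc[ok] <- log(s0$data[ok] / sb$data[ok]) / b * 1e6
  vol_like(s0, adc)
}
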