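#' Bias-correction model settings
#'
#' Configuration for multiplicative intensity-inhomogeneity correction of
#' T1-weighted volumes by a fuzzy C-means scheme with a spatially
#' low-pass gain field (adaptive FCM in the Pham-Prince spirit). The
#' estimated bias is strictly positive and normalised to mean 1 over the
#' mask, so corrected intensities keep the input's overall scale.
#'
#' @param n_classes Number of fuzzy tissue classes (default 2:
#'   fibroglandular and fat).
#' @param smoothness Low-pass scale of the gain field in mm (default 25).
#'   Variation broader than this is treated as coil bias; variation finer
#'   is treated as anatomy.
#' @param max_iter Maximum outer iterations.
#' @param tol Relative change of the fuzzy objective below which iteration
#'   stops.
#' @param fuzziness Fuzzy exponent m (fixed default 2, the standard
#'   choice).
#' @return A list of class `bias_model`.
#' @export
bias_model <- function(n_classes = 2L, smoothness = 25, max_iter = 25L,
                       tol = 1e-5, fuzziness = 2) {
  stopifnot(n_classes >= 2, smoothness > 0, max_iter >= 1, tol > 0,
            fuzziness > 1)
  structure(
    list(n_classes = as.integer(n_classes), smoothness = smoothness,
         max_iter = as.integer(max_iter), tol = tol, fuzziness = fuzziness),
    class = "bias_model"
  )
}

#' Estimate and remove multiplicative intensity inhomogeneity
#'
#' Alternates fuzzy C-means membership/centroid updates with a smoothed
#' multiplicative gain estimate: each voxel's predicted clean intensity is
#' its membership-weighted centroid, the ratio of observed to predicted
#' intensity is low-pass filtered (normalised convolution inside the
#' mask) to give the bias field, and the image is divided by it. Iterates
#' until the relative change of the fuzzy objective falls below `tol` or
#' `max_iter` is reached. Voxels outside the mask are returned untouched.
#'
#' A constant image inside the mask carries no class structure to
#' estimate from; the identity bias is returned with status
#' `"degenerate"` and a warning rather than an error.
#'
#' @param volume An [img_volume()] with non-negative intensities.
#' @param mask A 0/1 [img_volume()] on the same grid, nonempty.
#' @param model A [bias_model()].
#' @return A list with `corrected` (an [img_volume()]), `model` (the input
#'   model plus `bias_field`, an [img_volume()] that is 1 outside the
#'   mask), `status` (`"ok"` or `"degenerate"`), `n_iter` and `objective`
#'   (trace of the fuzzy objective).
#' @examples
#' ph <- make_phantom(phantom_params(seed = 2))
#' fit <- estimate_bias_fcm(ph$t1, ph$truth$breast_mask)
#' range(fit$model$bias_field$data)
#' @export
estimate_bias_fcm <- function(volume, mask, model = bias_model()) {
  stopifnot(is_img_volume(volume), is_img_volume(mask),
            inherits(model, "bias_model"))
  if (!same_grid(volume, mask)) stop("estimate_bias_fcm: grids differ")
  inmask <- mask$data > 0
  if (!any(inmask)) stop("estimate_bias_fcm: empty mask")
  y <- volume$data[inmask]
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("estimate_bias_fcm: intensities must be finite and non-negative")
  }
  m <- model$fuzziness
  k <- model$n_classes
  if (diff(range(y)) < 1e-9 * max(abs(y), 1)) {
    warning("estimate_bias_fcm: constant image in mask; returning identity bias")
    model$bias_field <- vol_like(volume, array(1, dim(volume$data)))
    return(structure(
      list(corrected = volume, model = model, status = "degenerate",
           n_iter = 0L, objective = numeric(0)),
      class = "bias_fit"
    ))
  }
  maskw <- inmask * 1
  bias_full <- array(1, dim(volume$data))
  obj_trace <- numeric(0)
  centres <- stats::quantile(y, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  for (it in seq_len(model$max_iter)) {
    x <- y / bias_full[inmask]
    # fuzzy memberships u_ij = d_ij^(-2/(m-1)) / sum_l d_il^(-2/(m-1))
    d2 <- outer(x, centres, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-12)
    u <- d2^(-1 / (m - 1))
    u <- u / rowSums(u)
    um <- u^m
    centres <- colSums(um * x) / colSums(um)
    pred <- (um %*% centres) / rowSums(um)
    obj <- sum(um * d2)
    obj_trace <- c(obj_trace, obj)
    # residual gain of the *corrected* image, low-pass filtered within
    # the mask and accumulated multiplicatively: the smoothed field tends
    # to 1 as iterations proceed, so the low-pass filter does not
    # re-attenuate curvature already captured in the bias estimate.
    # Partial-volume voxels sit between centroids and bias the ratio, so
    # the smoothing is confidence-weighted by the dominant membership.
    g <- array(1, dim(volume$data))
    g[inmask] <- x / pmax(pred[, 1], 1e-9)
    conf <- array(0, dim(volume$data))
    conf[inmask] <- apply(u, 1, max)^2
    num <- gauss_blur(g * conf * maskw, model$smoothness, volume$spacing)
    den <- gauss_blur(conf * maskw, model$smoothness, volume$spacing)
    g[inmask] <- ifelse(den[inmask] > 1e-12, num[inmask] / den[inmask], 1)
    bias_full[inmask] <- pmax(bias_full[inmask] * g[inmask], 1e-6)
    bias_full[inmask] <- bias_full[inmask] / mean(bias_full[inmask])
    if (it > 1) {
      rel <- abs(obj_trace[it] - obj_trace[it - 1]) /
        max(obj_trace[it - 1], 1e-12)
      if (rel < model$tol) break
    }
  }
  corrected <- volume$data
  corrected[inmask] <- y / bias_full[inmask]
  model$bias_field <- vol_like(volume, bias_full)
  structure(
    list(corrected = vol_like(volume, corrected), model = model,
         status = "ok", n_iter = it, objective = obj_trace),
    class = "bias_fit"
  )
}
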