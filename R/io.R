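#' Read and write volumes as NIfTI
#'
#' NIfTI-1 input/output with voxel spacing and origin preserved (the
#' package's axis order row/col/slice maps directly onto the NIfTI
#' i/j/k axes). A float32 round trip is lossless at single precision.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns an [img_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1L))
  if (length(dim(arr)) != 3) {
    stop("read_volume: expected a 3-D volume, got ",
         length(dim(arr)), " dimensions")
  }
  sp <- RNifti::pixdim(img)[1:3]
  hdr <- RNifti::niftiHeader(img)
  # the package stores its (row, col, slice) origin verbatim in the
  # qoffset fields; anatomical orientation codes are not interpreted
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  if (any(!is.finite(origin))) origin <- c(0, 0, 0)
  img_volume(arr, spacing = sp, origin = origin)
}

#' @rdname read_volume
#' @param vol An [img_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_img_volume(vol))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  hdr <- list(qoffset_x = vol$origin[1], qoffset_y = vol$origin[2],
              qoffset_z = vol$origin[3], qform_code = 1L)
  img <- RNifti::asNifti(img, hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

config_to_list <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), config_to_list)
  } else {
    x
  }
}

#' Save and restore a pipeline configuration as YAML
#'
#' The snapshot written beside pipeline outputs; `read_config()`
#' reconstructs the typed configuration objects from it.
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lst <- config_to_list(cfg)
  lst$cohort$phantom <- config_to_list(cfg$cohort$phantom)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  lst <- yaml::read_yaml(path)
  ph <- do.call(phantom_params, lst$cohort$phantom)
  co <- do.call(cohort_spec, c(
    lst$cohort[setdiff(names(lst$cohort), "phantom")],
    list(phantom = ph)
  ))
  pipeline_config(
    cohort = co,
    seg = do.call(segmentation_config, lst$seg),
    bias = do.call(bias_model, lst$bias[setdiff(names(lst$bias), "bias_field")]),
    adc = do.call(adc_config, lst$adc),
    register_scale = lst$register_scale,
    register_iter = lst$register_iter,
    cutoff = lst$cutoff,
    out_dir = lst$out_dir
  )
}
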