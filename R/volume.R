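#' Construct a PET volume object
#'
#' A light container for a 3-D nonnegative intensity grid with a voxel-to-mm
#' affine and a units tag (`"SUV"` for raw, `"normalized"` after intensity
#' normalization).
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-index-to-mm matrix.
#' @param units `"SUV"` or `"normalized"`.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(data, affine = diag(c(4, 4, 4, 1)), units = "SUV") {
  if (length(dim(data)) != 3L) abort("`data` must be a 3-D array")
  if (!all(is.finite(data))) abort("`data` must be finite")
  units <- match.arg(units, c("SUV", "normalized"))
  structure(list(data = data, affine = affine, units = units),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("<pet_volume>", paste(dim(x$data), collapse = "x"),
      sprintf("[%s] range %.4g..%.4g\n", x$units, min(x$data), max(x$data)))
  invisible(x)
}

#' Default volume-generator parameters
#'
#' @param shape Grid dimensions.
#' @param voxel_size Voxel edge in mm.
#' @param voxel_noise Within-region Gaussian voxel noise SD.
#' @param parenchyma_baseline Mean uptake of the non-striatal brain
#'   compartment (normalized units before global scaling).
#' @param global_meanlog,global_sdlog Log-normal parameters of the
#'   per-subject global intensity scale factor, emulating between-subject
#'   acquisition differences that intensity normalization must remove.
#' @param global_scale If non-`NULL`, a fixed global scale overriding the
#'   log-normal draw (useful for controlled tests).
#' @return A list of class `volume_params`.
#' @export
volume_generator_params <- function(shape = c(40L, 48L, 40L),
                                    voxel_size = 4,
                                    voxel_noise = 0.04,
                                    parenchyma_baseline = 0.8,
                                    global_meanlog = 0,
                                    global_sdlog = 0.25,
                                    global_scale = NULL) {
  if (any(shape <= 0)) abort("`shape` must be positive")
  if (!is.null(global_scale) && global_scale <= 0) {
    abort("`global_scale` must be strictly positive")
  }
  structure(
    list(shape = as.integer(shape), voxel_size = voxel_size,
         voxel_noise = voxel_noise,
         parenchyma_baseline = parenchyma_baseline,
         global_meanlog = global_meanlog, global_sdlog = global_sdlog,
         global_scale = global_scale),
    class = "volume_params"
  )
}

#' Simulate one subject's PET-like volume
#'
#' Voxels inside each atlas region are drawn about that subject's ROI value
#' (the parenchyma about its fixed baseline), outside-brain voxels are 0,
#' and the whole volume is multiplied by a per-subject global intensity
#' scale so raw volumes differ in range — the situation band-based intensity
#' normalization is meant to fix.
#'
#' @param roi_values Named numeric vector (or one-row data frame) of the
#'   subject's region uptake values; names must cover every striatal region
#'   in the atlas.
#' @param atlas An `roi_atlas`.
#' @param params A `volume_params` list.
#' @param seed Integer seed.
#' @return A `pet_volume` in `"SUV"` units.
#' @export
generate_pet_volume <- function(roi_values, atlas,
                                params = volume_generator_params(), seed) {
  if (missing(seed)) abort("`seed` is required for reproducible generation")
  if (is.data.frame(roi_values)) {
    roi_values <- unlist(roi_values[1, setdiff(names(roi_values), "subject_id")])
  }
  if (!identical(as.integer(dim(atlas$labels)), as.integer(params$shape))) {
    abort("`params$shape` does not match the atlas grid")
  }
  regions <- atlas$name_map[atlas$name_map != "parenchyma"]
  missing_r <- setdiff(unname(regions), names(roi_values))
  if (length(missing_r)) {
    abort(paste0("`roi_values` missing region(s): ",
                 paste(missing_r, collapse = ", ")))
  }
  labs <- atlas$labels
  vol <- array(0, dim = dim(labs))
  withr::with_seed(seed, {
    g <- if (is.null(params$global_scale)) {
      exp(rnorm(1, params$global_meanlog, params$global_sdlog))
    } else {
      params$global_scale
    }
    for (lab in as.integer(names(atlas$name_map))) {
      idx <- which(labs == lab)
      mu <- if (atlas$name_map[[as.character(lab)]] == "parenchyma") {
        params$parenchyma_baseline
      } else {
        roi_values[[atlas$name_map[[as.character(lab)]]]]
      }
      vol[idx] <- mu + rnorm(length(idx), sd = params$voxel_noise)
    }
  })
  vol <- vol * g
  vol[vol < 0] <- 0
  pet_volume(vol, affine = atlas$affine, units = "SUV")
}

#' Write / read a PET volume as NIfTI-1
#' @param vol A `pet_volume`.
#' @param path Path ending in `.nii` or `.nii.gz`.
#' @return `write_pet_volume` returns `path` invisibly.
#' @export
write_pet_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_pet_volume
#' @param units Units tag to attach on read.
#' @export
read_pet_volume <- function(path, units = "SUV") {
  img <- RNifti::readNifti(path)
  pet_volume(array(as.numeric(img), dim = dim(img)),
             affine = unclass(RNifti::xform(img)), units = units)
}
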