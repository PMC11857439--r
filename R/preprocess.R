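#' Band-based intensity normalization
#'
#' Divides every voxel by the mean of the voxels lying within the 40-90%
#' band of the maximum voxel intensity, computed on the input volume:
#' `B = {v : 0.4*max <= v <= 0.9*max}` (both bounds inclusive), output
#' `vol / mean(B)`. After normalization the mean of the output over `B` is
#' exactly 1, and the result is invariant to any positive rescaling of the
#' input. Used to remove between-subject global intensity differences
#' before voxel-wise or ROI analysis.
#'
#' @param vol A `pet_volume` with positive maximum intensity.
#' @return A `pet_volume` tagged `"normalized"`.
#' @examples
#' v <- pet_volume(array(c(10, 8, 6, 4, 2, 0), dim = c(6, 1, 1)))
#' intensity_normalize(v)$data[, 1, 1]   # band {8,6,4}, mean 6
#' @export
intensity_normalize <- function(vol) {
  stopifnot(inherits(vol, "pet_volume"))
  x <- vol$data
  mx <- max(x)
  if (!is.finite(mx) || mx <= 0) {
    abort("intensity_normalize: maximum voxel intensity is not positive")
  }
  band <- x >= 0.4 * mx & x <= 0.9 * mx
  if (!any(band)) {
    abort("intensity_normalize: the 40-90%-of-max intensity band is empty")
  }
  m <- mean(x[band])
  pet_volume(x / m, affine = vol$affine, units = "normalized")
}

#' Mean uptake per atlas region
#'
#' @param vol A `pet_volume`, same grid as the atlas.
#' @param atlas An `roi_atlas`.
#' @param regions Optional character subset of region names.
#' @return Named numeric vector of per-region arithmetic means.
#' @export
extract_roi_means <- function(vol, atlas, regions = NULL) {
  stopifnot(inherits(vol, "pet_volume"), inherits(atlas, "roi_atlas"))
  if (!identical(dim(vol$data), dim(atlas$labels))) {
    abort("volume and atlas grids have different shapes")
  }
  nm <- atlas$name_map
  if (!is.null(regions)) nm <- nm[nm %in% regions]
  out <- vapply(names(nm), function(lab) {
    idx <- atlas$labels == as.integer(lab)
    if (!any(idx)) {
      abort(sprintf("region '%s' has zero voxels in the atlas", nm[[lab]]))
    }
    mean(vol$data[idx])
  }, numeric(1))
  setNames(out, unname(nm))
}

#' ROI table for a set of subject volumes
#'
#' Normalizes each volume (optional) and extracts per-region means,
#' returning the subjects-by-regions table downstream stages consume.
#'
#' @param volumes Named list of `pet_volume` objects (names = subject ids).
#' @param atlas An `roi_atlas`.
#' @param normalize Apply [intensity_normalize()] first (default `TRUE`).
#' @param regions Optional subset of region names.
#' @return Tibble: `subject_id` plus one column per region.
#' @export
extract_roi_table <- function(volumes, atlas, normalize = TRUE,
                              regions = NULL) {
  if (is.null(names(volumes))) {
    abort("`volumes` must be a named list keyed by subject id")
  }
  rows <- purrr::imap(volumes, function(v, id) {
    if (normalize) v <- intensity_normalize(v)
    m <- extract_roi_means(v, atlas, regions = regions)
    dplyr::bind_cols(tibble::tibble(subject_id = id),
                     tibble::as_tibble(as.list(m)))
  })
  dplyr::bind_rows(rows)
}

#' Global mean uptake over the brain mask
#'
#' Mean over all voxels carrying a nonzero atlas label; used as the nuisance
#' "global" covariate in the voxel-wise regression.
#'
#' @inheritParams extract_roi_means
#' @return A single numeric value.
#' @export
global_mean <- function(vol, atlas) {
  stopifnot(inherits(vol, "pet_volume"), inherits(atlas, "roi_atlas"))
  if (!identical(dim(vol$data), dim(atlas$labels))) {
    abort("volume and atlas grids have different shapes")
  }
  mask <- atlas$labels > 0L
  if (!any(mask)) abort("global_mean: brain mask is empty")
  mean(vol$data[mask])
}
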