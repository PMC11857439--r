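#' Region labels used by the synthetic atlas
#' @return Named character vector mapping integer labels to region names.
#' @export
atlas_label_names <- function() {
  c(`1` = "caudate_L", `2` = "caudate_R",
    `3` = "putamen_L", `4` = "putamen_R",
    `5` = "parenchyma")
}

#' Build a synthetic striatal label atlas
#'
#' Lays out five disjoint regions on a 3-D grid: bilateral caudate and
#' putamen as boxes mirrored across the mid-sagittal plane (first axis),
#' embedded in an ellipsoidal "parenchyma" brain compartment; background is
#' label 0. Each striatal region contains at least 60 voxels so a 50-voxel
#' cluster-extent rule has room to act.
#'
#' @param shape Integer grid dimensions, default `c(40, 48, 40)`.
#' @param voxel_size Isotropic voxel edge length in mm (diagonal affine).
#' @return An object of class `roi_atlas`: list with integer 3-D `labels`,
#'   `name_map`, and a 4x4 `affine`.
#' @export
generate_atlas <- function(shape = c(40L, 48L, 40L), voxel_size = 4) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L)) {
    abort("`shape` must be three positive integers")
  }
  if (any(shape < c(24L, 28L, 24L))) {
    abort("`shape` too small to place five disjoint regions (need >= 24x28x24)")
  }
  sx <- shape[1]; sy <- shape[2]; sz <- shape[3]
  labels <- array(0L, dim = shape)

  # brain compartment: ellipsoid with semi-axes 0.4 * shape about the centre
  ctr <- (shape + 1) / 2
  ax <- 0.4 * shape
  g <- expand.grid(i = seq_len(sx), j = seq_len(sy), k = seq_len(sz))
  inside <- ((g$i - ctr[1]) / ax[1])^2 + ((g$j - ctr[2]) / ax[2])^2 +
    ((g$k - ctr[3]) / ax[3])^2 <= 1
  labels[as.matrix(g)[inside, , drop = FALSE]] <- 5L

  # left-hemisphere boxes anchored to the midline with disjoint x-ranges;
  # the right counterparts are exact mirrors, so left stays left of centre
  mid <- sx %/% 2L
  box <- function(x0, y0, z0) {
    list(x = x0:(x0 + 3L), y = y0:(y0 + 4L), z = z0:(z0 + 4L))
  }
  mirror_x <- function(b) { b$x <- sort(sx + 1L - b$x); b }
  caud_L <- box(mid - 5L, round(0.52 * sy), round(0.48 * sz))
  puta_L <- box(mid - 10L, round(0.38 * sy), round(0.42 * sz))
  boxes <- list(caud_L, mirror_x(caud_L), puta_L, mirror_x(puta_L))

  for (lab in seq_along(boxes)) {
    b <- boxes[[lab]]
    if (max(b$x) > sx || max(b$y) > sy || max(b$z) > sz ||
        min(unlist(b)) < 1L) {
      abort("`shape` too small: a striatal box falls outside the grid")
    }
    if (any(labels[b$x, b$y, b$z] %in% 1:4)) {
      abort("`shape` too small: striatal boxes overlap")
    }
    labels[b$x, b$y, b$z] <- as.integer(lab)
  }
  sizes <- tabulate(labels[labels > 0L], nbins = 5L)
  if (any(sizes[1:4] < 60L)) {
    abort("`shape` too small: a striatal region has fewer than 60 voxels")
  }
  affine <- diag(c(rep(voxel_size, 3), 1))
  structure(
    list(labels = labels, name_map = atlas_label_names(), affine = affine),
    class = "roi_atlas"
  )
}

#' @export
print.roi_atlas <- function(x, ...) {
  sizes <- table(x$labels[x$labels > 0])
  cat("<roi_atlas> grid", paste(dim(x$labels), collapse = "x"), "\n")
  for (lab in names(x$name_map)) {
    cat(sprintf("  %s (%s): %d voxels\n", x$name_map[[lab]], lab,
                if (lab %in% names(sizes)) sizes[[lab]] else 0L))
  }
  invisible(x)
}

#' Write / read an atlas as NIfTI plus a JSON label sidecar
#'
#' @param atlas An `roi_atlas`.
#' @param path Output path ending in `.nii` or `.nii.gz`; the label name map
#'   is written next to it with extension `.labels.json`.
#' @return `write_atlas` returns `path` invisibly; `read_atlas` the atlas.
#' @export
write_atlas <- function(atlas, path) {
  img <- RNifti::asNifti(atlas$labels)
  RNifti::sform(img) <- structure(atlas$affine, code = 2L)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  jsonlite::write_json(as.list(atlas$name_map), sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  name_map <- unlist(jsonlite::read_json(sidecar))
  structure(
    list(labels = array(as.integer(img), dim = dim(img)),
         name_map = name_map,
         affine = unclass(RNifti::xform(img))),
    class = "roi_atlas"
  )
}
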